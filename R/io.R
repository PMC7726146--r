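## Readers and writers for spike tables, module maps and protocol logs.
## Time unit is seconds throughout; recordings start at t = 0 unless the file
## declares otherwise. Delimited tables are comma-separated, dot decimal,
## UTF-8, one header line; timestamps are written with 9 decimals (1 ns),
## HDF5 round trips are bit-identical.

.is_hdf5_path <- function(path)
  grepl("\\.(h5|hdf5|hdf)$", path, ignore.case = TRUE)

#' Read a spike table into a RecordingSession
#'
#' Delimited tables carry one \code{electrode_id,time_s} row per spike, with
#' the recording interval (and optionally the full electrode roster, so that
#' silent electrodes survive the round trip) declared in \code{# key=value}
#' header lines. HDF5 files use one dataset per electrode under
#' \code{/spikes} plus \code{/t_start}, \code{/t_stop}, \code{/electrodes}
#' datasets. Per-electrode timestamps are sorted on read.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"csv"} or \code{"hdf5"}.
#' @param tStart,tStop interval bounds, required if the file does not declare
#'   them; values in the file take precedence.
#'
#' @return a validated [RecordingSession-class].
#' @seealso [writeSession()]
#' @export
readSpikeTable <- function(path, format = c("auto", "csv", "hdf5"),
                           tStart = NULL, tStop = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (.is_hdf5_path(path)) "hdf5" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "hdf5") .read_spikes_h5(path) else
    .read_spikes_csv(path, tStart, tStop)
}

.read_spikes_csv <- function(path, tStart, tStop) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    meta[[trimws(key)]] <- trimws(val)
  }
  if (!is.null(meta$t_start)) tStart <- as.numeric(meta$t_start)
  if (!is.null(meta$t_stop)) tStop <- as.numeric(meta$t_stop)
  if (is.null(tStart)) tStart <- 0
  if (is.null(tStop))
    stop("t_stop neither declared in file header nor supplied")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("format error: missing header row")
  cols <- strsplit(body[[1L]], ",", fixed = TRUE)[[1L]]
  if (!all(c("electrode_id", "time_s") %in% trimws(cols)))
    stop("format error: columns 'electrode_id' and 'time_s' required, found: ",
         paste(cols, collapse = ", "))
  if (length(body) > 1L) {
    df <- utils::read.csv(text = body, header = TRUE,
                          colClasses = c(electrode_id = "character",
                                         time_s = "numeric"))
  } else {
    df <- data.frame(electrode_id = character(), time_s = numeric())
  }
  roster <- if (!is.null(meta$electrodes))
    strsplit(meta$electrodes, ";", fixed = TRUE)[[1L]] else
    unique(df$electrode_id)
  roster <- union(roster, unique(df$electrode_id))
  trains <- lapply(roster, function(id) {
    SpikeTrain(id, df$time_s[df$electrode_id == id], tStart, tStop)
  })
  sr <- if (!is.null(meta$sampling_rate)) as.numeric(meta$sampling_rate) else
    NA_real_
  RecordingSession(trains, samplingRate = sr)
}

.read_spikes_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  tStart <- as.numeric(rhdf5::h5read(path, "t_start"))
  tStop <- as.numeric(rhdf5::h5read(path, "t_stop"))
  roster <- as.character(rhdf5::h5read(path, "electrodes"))
  present <- rhdf5::h5ls(path)
  present <- present$name[present$group == "/spikes"]
  trains <- lapply(roster, function(id) {
    ts <- if (id %in% present)
      as.numeric(rhdf5::h5read(path, paste0("spikes/", id))) else numeric()
    SpikeTrain(id, ts, tStart, tStop)
  })
  sr <- if ("sampling_rate" %in% rhdf5::h5ls(path)$name)
    as.numeric(rhdf5::h5read(path, "sampling_rate")) else NA_real_
  RecordingSession(trains, samplingRate = sr)
}

#' Write a RecordingSession to disk
#'
#' Inverse of [readSpikeTable()]: \code{readSpikeTable(writeSession(s, p), p)}
#' reproduces the session, bit-identically for HDF5 and to 9 decimals (1 ns)
#' for delimited text. Silent electrodes are preserved through the roster
#' header.
#'
#' @param session a [RecordingSession-class].
#' @param path output file path.
#' @param format \code{"auto"}, \code{"csv"} or \code{"hdf5"}.
#' @return \code{path}, invisibly.
#' @export
writeSession <- function(session, path, format = c("auto", "csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (.is_hdf5_path(path)) "hdf5" else "csv"
  stopifnot(is(session, "RecordingSession"))
  validObject(session)
  if (format == "hdf5") .write_spikes_h5(session, path) else
    .write_spikes_csv(session, path)
  invisible(path)
}

.write_spikes_csv <- function(session, path) {
  ids <- electrodeIds(session)
  hdr <- c(sprintf("# t_start=%.9f", tStart(session)),
           sprintf("# t_stop=%.9f", tStop(session)),
           sprintf("# electrodes=%s", paste(ids, collapse = ";")))
  if (!is.na(session@samplingRate))
    hdr <- c(hdr, sprintf("# sampling_rate=%g", session@samplingRate))
  rows <- unlist(lapply(ids, function(id) {
    ts <- session@trains[[id]]@times
    if (!length(ts)) return(character())
    sprintf("%s,%.9f", id, ts)
  }), use.names = FALSE)
  writeLines(c(hdr, "electrode_id,time_s", rows), path, useBytes = TRUE)
}

.write_spikes_h5 <- function(session, path) {
  if (file.exists(path)) unlink(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  rhdf5::h5write(tStart(session), path, "t_start")
  rhdf5::h5write(tStop(session), path, "t_stop")
  rhdf5::h5write(electrodeIds(session), path, "electrodes")
  if (!is.na(session@samplingRate))
    rhdf5::h5write(session@samplingRate, path, "sampling_rate")
  rhdf5::h5createGroup(path, "spikes")
  for (id in electrodeIds(session)) {
    ts <- session@trains[[id]]@times
    if (length(ts)) rhdf5::h5write(ts, path, paste0("spikes/", id))
  }
}

#' Read a module map from a YAML or JSON config
#'
#' The config maps module labels to electrode id vectors, either directly at
#' the top level or under a \code{modules} key, with optional
#' \code{control_label} and \code{excluded} keys. The control label (default
#' \code{CTRL}) flags electrodes in unconnected control networks.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a validated [ModuleMap-class].
#' @export
readModuleMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE) else
    yaml::read_yaml(path)
  if (!is.list(cfg) || !length(cfg)) stop("module map config is empty")
  control <- cfg$control_label
  excluded <- as.character(cfg$excluded %||% character())
  modules <- cfg$modules %||%
    cfg[setdiff(names(cfg), c("control_label", "excluded"))]
  if (!length(modules)) stop("module map config declares no modules")
  ModuleMap(modules, controlLabel = control %||% "CTRL", excluded = excluded)
}

#' Check that a map covers a session
#'
#' Every electrode of a session must either be mapped to a module or appear
#' in the map's excluded list; unmapped electrodes are reported.
#'
#' @param map a [ModuleMap-class].
#' @param session a [RecordingSession-class].
#' @param strict error (TRUE) or warn (FALSE, default) on unmapped electrodes.
#' @return character vector of unmapped electrode ids, invisibly.
#' @export
checkMapCoverage <- function(map, session, strict = FALSE) {
  unmapped <- setdiff(electrodeIds(session),
                      c(names(map@assignment), map@excluded))
  if (length(unmapped)) {
    msg <- paste("electrodes neither mapped nor excluded:",
                 paste(unmapped, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  invisible(unmapped)
}

#' Read a neuromodulation protocol
#'
#' A protocol is a list of suppression epochs, each with a target module, a
#' power density (opaque metadata, mW/mm^2), the illumination window
#' \code{[on_s, off_s)} and a trial index. Accepted as YAML/JSON (list of
#' records, or under an \code{epochs} key) or CSV with those columns.
#'
#' @param path path to \code{.yaml}, \code{.json} or \code{.csv}.
#' @return data.frame with columns \code{target}, \code{power}, \code{on},
#'   \code{off}, \code{trial}, sorted by onset.
#' @export
readProtocol <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
  } else {
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE) else
      yaml::read_yaml(path)
    if (!is.null(cfg$epochs)) cfg <- cfg$epochs
    df <- if (is.data.frame(cfg)) cfg else
      do.call(rbind, lapply(cfg, function(e) as.data.frame(e)))
  }
  if (is.null(df) || !nrow(df)) return(
    data.frame(target = character(), power = numeric(), on = numeric(),
               off = numeric(), trial = integer()))
  names(df)[names(df) == "power_mw_mm2"] <- "power"
  names(df)[names(df) == "on_s"] <- "on"
  names(df)[names(df) == "off_s"] <- "off"
  need <- c("target", "power", "on", "off")
  if (!all(need %in% names(df)))
    stop("protocol must provide columns: ", paste(need, collapse = ", "))
  if (is.null(df$trial)) df$trial <- seq_len(nrow(df))
  if (any(df$off <= df$on)) stop("protocol epochs must have off > on")
  df <- df[order(df$on), c("target", "power", "on", "off", "trial")]
  rownames(df) <- NULL
  df
}

#' Read an electrical-stimulation trial log
#'
#' CSV with columns \code{stim_electrode,time_s}, or YAML/JSON with fields
#' \code{stim_electrode} and \code{times} (or a list of such records).
#'
#' @param path file path.
#' @return data.frame with columns \code{stim_electrode}, \code{time_s},
#'   sorted by time within electrode.
#' @export
readStimLog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, colClasses = c(stim_electrode = "character",
                                               time_s = "numeric"))
  } else {
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE) else
      yaml::read_yaml(path)
    if (!is.null(cfg$stim_electrode)) cfg <- list(cfg)
    df <- do.call(rbind, lapply(cfg, function(e)
      data.frame(stim_electrode = e$stim_electrode,
                 time_s = as.numeric(unlist(e$times)))))
  }
  if (!all(c("stim_electrode", "time_s") %in% names(df)))
    stop("stim log must provide columns stim_electrode, time_s")
  df <- df[order(df$stim_electrode, df$time_s), ]
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
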