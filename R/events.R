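## Burst and synchronized-event detection. A burst is a maximal run of
## successive spikes on one electrode whose inter-spike gaps are all within
## 200 ms. Synchronized bursting events (SBEs) are windows where bursts
## overlap on two or more electrodes (closed intervals, merged transitively);
## inter-network synchronized events (SEs) are SBEs whose participants span
## two or more network modules. SEs carry association degrees and
## first-spike-based propagation-direction labels.

#' Detect bursts on one electrode
#'
#' Groups successive spikes whose gaps are at most \code{isiThreshold}
#' (boundary included: a gap exactly at the threshold stays within the
#' burst) and keeps maximal runs of at least \code{minSpikes} spikes. The
#' burst window spans first to last spike of the run.
#'
#' @param train a [SpikeTrain-class].
#' @param isiThreshold maximum in-burst inter-spike interval in seconds
#'   (default 0.2).
#' @param minSpikes minimum spikes per burst (default 3; at least 2).
#' @return data.frame with columns \code{electrode_id}, \code{start},
#'   \code{end}, \code{n_spikes}.
#' @export
detectBursts <- function(train, isiThreshold = 0.2, minSpikes = 3) {
  if (isiThreshold <= 0) stop("isiThreshold must be positive")
  if (minSpikes < 2) stop("minSpikes must be at least 2")
  ts <- train@times
  empty <- data.frame(electrode_id = character(), start = numeric(),
                      end = numeric(), n_spikes = integer())
  if (length(ts) < minSpikes) return(empty)
  grp <- cumsum(c(0, diff(ts) > isiThreshold))
  starts <- tapply(ts, grp, min)
  ends <- tapply(ts, grp, max)
  ns <- tapply(ts, grp, length)
  keep <- ns >= minSpikes
  if (!any(keep)) return(empty)
  data.frame(electrode_id = train@electrodeId,
             start = as.numeric(starts[keep]), end = as.numeric(ends[keep]),
             n_spikes = as.integer(ns[keep]), row.names = NULL)
}

#' Detect bursts on every electrode of a session
#'
#' @param session a [RecordingSession-class].
#' @inheritParams detectBursts
#' @return row-bound burst table over all electrodes (see [detectBursts()]).
#' @export
sessionBursts <- function(session, isiThreshold = 0.2, minSpikes = 3) {
  do.call(rbind, lapply(session@trains, detectBursts,
                        isiThreshold = isiThreshold, minSpikes = minSpikes))
}

#' Detect synchronized bursting events (SBEs)
#'
#' Builds the overlap graph of all burst windows (closed intervals, touching
#' endpoints count as overlap) and merges overlapping bursts transitively, so
#' a chain of pairwise-overlapping bursts becomes one event. Each connected
#' component whose bursts come from two or more distinct electrodes is an
#' SBE; its window is the union span of the participating bursts.
#'
#' @param bursts burst table from [sessionBursts()].
#' @return data.frame with columns \code{start}, \code{end},
#'   \code{n_electrodes}, and list-columns \code{electrodes} (participating
#'   electrode ids) and \code{bursts} (row indices into \code{bursts}).
#' @export
detectSBEs <- function(bursts) {
  empty <- data.frame(start = numeric(), end = numeric(),
                      n_electrodes = integer())
  empty$electrodes <- list()
  empty$bursts <- list()
  if (is.null(bursts) || !nrow(bursts)) return(empty)
  o <- order(bursts$start, bursts$end)
  b <- bursts[o, ]
  ## sweep: closed intervals merge when the next start does not pass the
  ## running maximum end; connected components of the interval-overlap graph
  ## are exactly these maximal merged runs
  comp <- integer(nrow(b))
  cur <- 1L
  cur_end <- b$end[1L]
  comp[1L] <- cur
  for (i in seq_len(nrow(b))[-1L]) {
    if (b$start[i] > cur_end) {
      cur <- cur + 1L
      cur_end <- b$end[i]
    } else {
      cur_end <- max(cur_end, b$end[i])
    }
    comp[i] <- cur
  }
  rows <- split(seq_len(nrow(b)), comp)
  recs <- lapply(rows, function(idx) {
    el <- unique(b$electrode_id[idx])
    if (length(el) < 2L) return(NULL)
    list(start = min(b$start[idx]), end = max(b$end[idx]),
         electrodes = sort(el), bursts = sort(o[idx]))
  })
  recs <- recs[!vapply(recs, is.null, logical(1L))]
  if (!length(recs)) return(empty)
  out <- data.frame(start = vapply(recs, `[[`, numeric(1L), "start"),
                    end = vapply(recs, `[[`, numeric(1L), "end"),
                    n_electrodes = vapply(recs, function(r)
                      length(r$electrodes), integer(1L)))
  out$electrodes <- lapply(recs, `[[`, "electrodes")
  out$bursts <- lapply(recs, `[[`, "bursts")
  out[order(out$start), , drop = FALSE]
}

#' Classify SBEs into inter-network synchronized events (SEs)
#'
#' An SBE is an SE when its participating electrodes span two or more
#' non-control modules. With \code{singleSpikeRule = TRUE} (used for
#' two-electrode-per-network layouts), a single-module SBE is also promoted
#' when any electrode of another module fires at least one spike inside the
#' SBE window; such electrodes join the participant set.
#'
#' @param sbes SBE table from [detectSBEs()].
#' @param map a [ModuleMap-class] covering all burst electrodes.
#' @param session the [RecordingSession-class]; required for the
#'   single-spike rule and for per-module first-spike times.
#' @param singleSpikeRule logical (default FALSE).
#' @return the event table with added columns \code{kind} (\code{"SBE"} or
#'   \code{"SE"}) and list-column \code{modules} (participating non-control
#'   modules).
#' @export
classifySEs <- function(sbes, map, session = NULL, singleSpikeRule = FALSE) {
  if (!nrow(sbes)) {
    sbes$kind <- character()
    sbes$modules <- list()
    return(sbes)
  }
  unknown <- setdiff(unique(unlist(sbes$electrodes)), names(map@assignment))
  if (length(unknown))
    stop("burst electrodes not covered by the module map: ",
         paste(unknown, collapse = ", "))
  if (singleSpikeRule && is.null(session))
    stop("the single-spike rule needs the session's spike trains")
  ctrl <- map@controlLabel
  mods_of <- function(el) {
    m <- unique(unname(map@assignment[el]))
    sort(m[m != ctrl])
  }
  electrodes <- sbes$electrodes
  modules <- lapply(electrodes, mods_of)
  if (singleSpikeRule) {
    mapped <- names(map@assignment)[map@assignment != ctrl]
    for (i in seq_len(nrow(sbes))) {
      if (length(modules[[i]]) != 1L) next
      others <- setdiff(mapped[map@assignment[mapped] != modules[[i]]],
                        electrodes[[i]])
      hit <- others[vapply(others, function(id) {
        if (!id %in% electrodeIds(session)) return(FALSE)
        ts <- session@trains[[id]]@times
        any(ts >= sbes$start[i] & ts <= sbes$end[i])
      }, logical(1L))]
      if (length(hit)) {
        electrodes[[i]] <- sort(union(electrodes[[i]], hit))
        modules[[i]] <- mods_of(electrodes[[i]])
      }
    }
  }
  sbes$electrodes <- electrodes
  sbes$n_electrodes <- lengths(electrodes)
  sbes$kind <- ifelse(lengths(modules) >= 2L, "SE", "SBE")
  sbes$modules <- modules
  sbes
}

#' Synchronized events of a session in one call
#'
#' Burst detection, SBE detection and SE classification chained with the
#' package defaults.
#'
#' @param session a [RecordingSession-class].
#' @param map a [ModuleMap-class].
#' @inheritParams detectBursts
#' @inheritParams classifySEs
#' @return the classified event table (see [classifySEs()]).
#' @export
sessionEvents <- function(session, map, isiThreshold = 0.2, minSpikes = 3,
                          singleSpikeRule = FALSE) {
  bursts <- sessionBursts(session, isiThreshold, minSpikes)
  classifySEs(detectSBEs(bursts), map, session = session,
              singleSpikeRule = singleSpikeRule)
}

#' Association degree with synchronized events
#'
#' Fraction of each electrode's spikes that fall inside the union of SE
#' windows (closed). Electrodes with zero spikes have undefined degree (NA).
#'
#' @param session a [RecordingSession-class].
#' @param events event table from [classifySEs()] / [sessionEvents()]; only
#'   rows with \code{kind == "SE"} are used.
#' @param map optional [ModuleMap-class] to annotate electrodes with modules.
#' @return data.frame with columns \code{electrode_id}, \code{module} (if a
#'   map is given), \code{n_spikes}, \code{n_in_se}, \code{degree}.
#' @export
associationDegree <- function(session, events, map = NULL) {
  se <- events[events$kind == "SE", , drop = FALSE]
  o <- order(se$start)
  starts <- se$start[o]
  ends <- se$end[o]
  ## union of the (closed) SE windows: merge any overlapping or touching runs
  if (length(starts) > 1L) {
    ms <- starts[1L]
    me <- ends[1L]
    for (k in 2L:length(starts)) {
      if (starts[k] <= me[length(me)]) {
        me[length(me)] <- max(me[length(me)], ends[k])
      } else {
        ms <- c(ms, starts[k])
        me <- c(me, ends[k])
      }
    }
    starts <- ms
    ends <- me
  }
  ids <- electrodeIds(session)
  n_in <- vapply(ids, function(id) {
    ts <- session@trains[[id]]@times
    if (!length(ts) || !length(starts)) return(0L)
    idx <- findInterval(ts, starts)
    sum(idx >= 1L & ts <= ends[pmax(idx, 1L)])
  }, integer(1L))
  n_tot <- vapply(ids, function(id) length(session@trains[[id]]@times),
                  integer(1L))
  out <- data.frame(electrode_id = ids,
                    n_spikes = unname(n_tot), n_in_se = unname(n_in),
                    degree = ifelse(n_tot > 0, n_in / n_tot, NA_real_),
                    row.names = NULL)
  if (!is.null(map))
    out <- cbind(out[1L], module = unname(map@assignment[ids]),
                 out[-1L])
  out
}

#' Per-module mean association degree
#'
#' Averages [associationDegree()] over the electrodes of each non-control
#' module (electrodes with undefined degree dropped).
#'
#' @param assoc output of [associationDegree()] including a \code{module}
#'   column.
#' @param controlLabel control label to exclude (default \code{"CTRL"}).
#' @return data.frame with columns \code{module}, \code{mean_degree},
#'   \code{sd_degree}, \code{n_electrodes}.
#' @export
moduleAssociation <- function(assoc, controlLabel = "CTRL") {
  a <- assoc[!is.na(assoc$degree) & assoc$module != controlLabel, ]
  if (!nrow(a))
    return(data.frame(module = character(), mean_degree = numeric(),
                      sd_degree = numeric(), n_electrodes = integer()))
  agg <- split(a$degree, a$module)
  data.frame(module = names(agg),
             mean_degree = vapply(agg, mean, numeric(1L)),
             sd_degree = vapply(agg, stats::sd, numeric(1L)),
             n_electrodes = lengths(agg), row.names = NULL)
}

#' Propagation-direction labels for synchronized events
#'
#' For each SE, the first-spike time of every participating module is the
#' minimum spike time, within the event window, over that module's
#' participating electrodes. Modules are ordered by these times to give the
#' propagation sequence (e.g. \code{N2->N1}). When any two adjacent modules
#' in the ordering differ by less than \code{tieTolerance} the event is
#' flagged ambiguous and excluded from direction tallies.
#'
#' @param events event table from [classifySEs()] (SE rows are labeled).
#' @param session the [RecordingSession-class].
#' @param map a [ModuleMap-class].
#' @param tieTolerance minimum resolvable lead time in seconds
#'   (default 0.001, well below typical 15--35 ms inter-module delays).
#' @return data.frame with columns \code{event} (row index into
#'   \code{events}), \code{sequence} (modules joined by \code{->}),
#'   \code{ambiguous}, \code{n_modules}, and list-column \code{first_spikes}
#'   (named per-module first-spike times).
#' @export
propagationLabels <- function(events, session, map, tieTolerance = 0.001) {
  se_rows <- which(events$kind == "SE")
  recs <- lapply(se_rows, function(i) {
    el <- events$electrodes[[i]]
    mods <- events$modules[[i]]
    ft <- vapply(mods, function(m) {
      members <- intersect(el, electrodesOf(map, m))
      tmin <- Inf
      for (id in members) {
        ts <- session@trains[[id]]@times
        ts <- ts[ts >= events$start[i] & ts <= events$end[i]]
        if (length(ts)) tmin <- min(tmin, ts[1L])
      }
      tmin
    }, numeric(1L))
    ft <- ft[is.finite(ft)]
    if (length(ft) < 2L) return(NULL)
    ft <- sort(ft)
    list(event = i,
         sequence = paste(names(ft), collapse = "->"),
         ambiguous = any(diff(ft) < tieTolerance),
         n_modules = length(ft),
         first_spikes = ft)
  })
  recs <- recs[!vapply(recs, is.null, logical(1L))]
  out <- data.frame(event = vapply(recs, `[[`, numeric(1L), "event"),
                    sequence = vapply(recs, `[[`, character(1L), "sequence"),
                    ambiguous = vapply(recs, `[[`, logical(1L), "ambiguous"),
                    n_modules = vapply(recs, function(r)
                      as.integer(r$n_modules), integer(1L)))
  out$first_spikes <- lapply(recs, `[[`, "first_spikes")
  out
}

#' Proportions of propagation directions
#'
#' Counts the distinct module sequences over unambiguous labels and
#' normalizes to sum to one.
#'
#' @param labels output of [propagationLabels()].
#' @return data.frame with columns \code{sequence}, \code{n},
#'   \code{proportion}, sorted by decreasing proportion.
#' @export
propagationProportions <- function(labels) {
  lab <- labels[!labels$ambiguous, , drop = FALSE]
  if (!nrow(lab)) stop("no unambiguous propagation labels")
  tab <- table(lab$sequence)
  out <- data.frame(sequence = names(tab), n = as.integer(tab),
                    proportion = as.numeric(tab) / sum(tab), row.names = NULL)
  out[order(-out$proportion), , drop = FALSE]
}
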