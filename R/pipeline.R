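## Config-driven orchestration: run the full analysis chain (connectivity,
## events, association, propagation, influence, PSTH) on one or more
## sessions and emit deterministic machine-readable reports.

#' Analysis configuration with the package's default parameters
#'
#' Central defaults ledger. Every analysis parameter has its conventional
#' value: 0.1 s rate bins smoothed with a 5-bin Gaussian, 0.05 Hz
#' active-electrode filter, 0.2 s in-burst inter-spike threshold with a
#' 3-spike minimum, 1 ms propagation tie tolerance, 50 ms evoked window with
#' 2 ms artifact blank, alpha = 0.01, -6 SD detection threshold with 1 ms
#' dead time, and a 90% full-suppression criterion for influence.
#'
#' @param ... overrides of any default, by name.
#' @return named list of analysis parameters.
#' @export
analysisConfig <- function(...) {
  cfg <- list(
    binWidth = 0.1, kernelBins = 5L, sigmaBins = 1.25, minRate = 0.05,
    smooth = TRUE,
    isiThreshold = 0.2, minSpikes = 3L, singleSpikeRule = FALSE,
    tieTolerance = 0.001,
    kSd = 6, deadTime = 0.001, noiseEstimator = "robust_mad",
    blank = 0.002, psthBin = 0.001, evokedWindow = 0.05,
    responseWindow = c(0.015, 0.035), earlyMax = 0.010,
    alpha = 0.01, fullSuppression = 90,
    baselineDuration = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown analysis parameters: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

.as_session <- function(x) {
  if (is(x, "RecordingSession")) x else readSpikeTable(x)
}

.as_map <- function(x) {
  if (is(x, "ModuleMap")) x else readModuleMap(x)
}

#' Connectivity report for one or more sessions
#'
#' Runs [connectivity()] per session and collects the correlation matrices
#' with their intra-/inter-CC summaries into one longitudinal report, e.g.
#' over recording days.
#'
#' @param sessions a [RecordingSession-class], a path, or a (optionally
#'   named) list of either.
#' @param map a [ModuleMap-class] or config path.
#' @param config an [analysisConfig()] list.
#' @return list with one entry per session: \code{matrix}, \code{active},
#'   \code{intra_cc}, \code{inter_cc}, \code{intra_by_module},
#'   \code{inter_by_pair}, \code{control_cc}; plus a \code{table} data.frame
#'   of the pooled intra/inter values across sessions.
#' @export
runConnectivity <- function(sessions, map, config = analysisConfig()) {
  map <- .as_map(map)
  if (is(sessions, "RecordingSession") || is.character(sessions))
    sessions <- list(session1 = sessions)
  if (is.null(names(sessions)))
    names(sessions) <- paste0("session", seq_along(sessions))
  reports <- lapply(sessions, function(s) {
    s <- .as_session(s)
    cn <- connectivity(s, map, binWidth = config$binWidth,
                       kernelBins = config$kernelBins,
                       sigmaBins = config$sigmaBins,
                       minRate = config$minRate, smooth = config$smooth)
    sm <- cn$summary
    list(matrix = cn$matrix, active = cn$active,
         intra_cc = sm@intraOverall, inter_cc = sm@interOverall,
         intra_by_module = as.list(sm@intraModule),
         inter_by_pair = sm@interPairs,
         control_cc = sm@control)
  })
  tab <- data.frame(
    session = names(reports),
    intra_cc = vapply(reports, `[[`, numeric(1L), "intra_cc"),
    inter_cc = vapply(reports, `[[`, numeric(1L), "inter_cc"),
    row.names = NULL)
  c(reports, list(table = tab))
}

#' Full analysis report bundle
#'
#' Composes all stages on one session: connectivity, synchronized events,
#' association degree, propagation directions, influence (when a suppression
#' protocol is given) and PSTH/response-probability mapping (when a
#' stimulation log is given). Stage failures are isolated: a failing stage is
#' reported as an error entry without aborting the others. The manifest
#' records all parameters so a rerun with the same inputs reproduces the
#' report exactly.
#'
#' @param session a [RecordingSession-class] or spike-table path.
#' @param map a [ModuleMap-class] or config path.
#' @param config an [analysisConfig()] list.
#' @param protocol optional suppression protocol (data.frame or path); the
#'   influence stage is skipped with a warning when absent or empty.
#' @param stimLog optional stimulation log (data.frame with
#'   \code{stim_electrode}, \code{time_s}, or path).
#' @param influencePairs optional data.frame with columns \code{source},
#'   \code{target} naming the influence pairs to evaluate (default: protocol
#'   target versus every other non-control module).
#' @return nested report list with elements \code{manifest},
#'   \code{connectivity}, \code{events}, \code{association},
#'   \code{propagation}, \code{influence}, \code{psth}.
#' @export
runFull <- function(session, map, config = analysisConfig(), protocol = NULL,
                    stimLog = NULL, influencePairs = NULL) {
  session <- .as_session(session)
  map <- .as_map(map)
  if (is.character(protocol)) protocol <- readProtocol(protocol)
  if (is.character(stimLog)) stimLog <- readStimLog(stimLog)
  report <- list(manifest = list(
    package_version = as.character(utils::packageVersion("meamod")),
    parameters = config[!vapply(config, is.null, logical(1L))],
    n_electrodes = length(electrodeIds(session)),
    n_spikes = nSpikes(session),
    duration_s = duration(session)))
  stage <- function(expr) {
    tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
  }
  report$connectivity <- stage({
    r <- runConnectivity(session, map, config)[[1L]]
    r$matrix <- NULL  # matrices go to CSV side-tables, not the JSON report
    r
  })
  events <- stage(sessionEvents(session, map,
                                isiThreshold = config$isiThreshold,
                                minSpikes = config$minSpikes,
                                singleSpikeRule = config$singleSpikeRule))
  if (!is.null(events$error)) {
    report$events <- events
  } else {
    report$events <- list(
      n_sbe = sum(events$kind == "SBE"), n_se = sum(events$kind == "SE"),
      se_windows = events[events$kind == "SE", c("start", "end")])
    report$association <- stage({
      assoc <- associationDegree(session, events, map)
      list(per_electrode = assoc,
           per_module = moduleAssociation(assoc, map@controlLabel))
    })
    report$propagation <- stage({
      labels <- propagationLabels(events, session, map,
                                  tieTolerance = config$tieTolerance)
      list(n_labeled = sum(!labels$ambiguous),
           n_ambiguous = sum(labels$ambiguous),
           proportions = propagationProportions(labels))
    })
  }
  if (is.null(protocol) || !nrow(protocol)) {
    warning("no suppression protocol; influence stage skipped")
    report$influence <- list(skipped = "no suppression protocol")
  } else {
    report$influence <- stage({
      curve <- suppressionCurve(session, protocol, map,
                                baselineDuration = config$baselineDuration)
      src <- unique(protocol$target)
      if (length(src) != 1L)
        stop("influence expects a protocol targeting a single module")
      if (is.null(influencePairs)) {
        targets <- setdiff(moduleLabels(map), src)
        influencePairs <- data.frame(source = src, target = targets)
      }
      infl <- lapply(seq_len(nrow(influencePairs)), function(i)
        influence(curve, influencePairs$source[i], influencePairs$target[i],
                  fullSuppression = config$fullSuppression))
      trials <- attr(curve, "trials")
      pmax_ <- max(curve$power)
      tests <- if (any(trials$module == map@controlLabel)) {
        lapply(stats::setNames(nm = setdiff(unique(trials$module),
                                            map@controlLabel)), function(m) {
          xs <- trials$pct_change[trials$module == m & trials$power == pmax_]
          ys <- trials$pct_change[trials$module == map@controlLabel &
                                    trials$power == pmax_]
          if (sum(!is.na(xs)) >= 3L && sum(!is.na(ys)) >= 3L)
            mannWhitneyExact(xs[!is.na(xs)], ys[!is.na(ys)])$p.value else
              NA_real_
        })
      } else NULL
      attr(curve, "trials") <- NULL
      list(curve = curve, influence = infl, mann_whitney_vs_control = tests)
    })
  }
  if (!is.null(stimLog) && nrow(stimLog)) {
    report$psth <- stage({
      stim_electrodes <- unique(stimLog$stim_electrode)
      times <- sort(stimLog$time_s)
      mp <- meanPSTH(session, times,
                     excludeElectrodes = stim_electrodes,
                     binWidth = config$psthBin, window = config$evokedWindow,
                     blank = config$blank)
      probs <- vapply(setdiff(electrodeIds(session), stim_electrodes),
                      function(id)
                        responseProbability(session@trains[[id]], times,
                                            config$responseWindow),
                      numeric(1L))
      list(mean_rate = mp$rate, edges = mp$edges, masked = mp$masked,
           response_probability = as.list(probs))
    })
  } else {
    report$psth <- list(skipped = "no stimulation log")
  }
  report
}

#' Write a report bundle to JSON (with CSV side-tables)
#'
#' Serializes the report deterministically (fixed field order, full numeric
#' precision) so identical analyses produce byte-identical files.
#'
#' @param report output of [runFull()] or [runConnectivity()].
#' @param dir output directory (created if needed).
#' @param name base file name (default \code{"report"}).
#' @return the JSON path, invisibly.
#' @export
writeReports <- function(report, dir, name = "report") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null",
                       force = TRUE)
  invisible(path)
}
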