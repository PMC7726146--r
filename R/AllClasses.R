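#' @import methods
NULL

#' SpikeTrain: spike timestamps for one electrode
#'
#' Ordered spike times, in seconds, recorded on a single electrode over a
#' fixed interval \code{[tStart, tStop)}. All analyses in this package operate
#' on multi-unit, per-electrode trains; no unit isolation is attempted.
#'
#' @slot electrodeId single character label.
#' @slot times strictly increasing numeric vector of spike times (s), all in
#'   \code{[tStart, tStop)}.
#' @slot tStart,tStop recording interval bounds (s), \code{tStop > tStart}.
#'
#' @seealso [SpikeTrain()] for construction, [RecordingSession-class]
#' @exportClass SpikeTrain
setClass("SpikeTrain",
  representation(
    electrodeId = "character",
    times = "numeric",
    tStart = "numeric",
    tStop = "numeric"
  )
)

setValidity("SpikeTrain", function(object) {
  msg <- character()
  if (length(object@electrodeId) != 1L || is.na(object@electrodeId) ||
      !nzchar(object@electrodeId))
    msg <- c(msg, "'electrodeId' must be a single non-empty string")
  if (length(object@tStart) != 1L || length(object@tStop) != 1L ||
      !is.finite(object@tStart) || !is.finite(object@tStop))
    msg <- c(msg, "'tStart' and 'tStop' must be single finite numbers")
  else if (object@tStop <= object@tStart)
    msg <- c(msg, "'tStop' must be greater than 'tStart'")
  ts <- object@times
  if (length(ts)) {
    if (anyNA(ts) || !all(is.finite(ts)))
      msg <- c(msg, sprintf("electrode %s: non-finite spike times",
                            object@electrodeId))
    else {
      if (is.unsorted(ts, strictly = TRUE))
        msg <- c(msg, sprintf(
          "electrode %s: spike times must be strictly increasing (no duplicates)",
          object@electrodeId))
      if (length(object@tStart) == 1L && length(object@tStop) == 1L &&
          (ts[1L] < object@tStart || ts[length(ts)] >= object@tStop))
        msg <- c(msg, sprintf(
          "electrode %s: spike times must lie in [tStart, tStop)",
          object@electrodeId))
    }
  }
  if (length(msg)) msg else TRUE
})

#' RecordingSession: a set of spike trains sharing one recording interval
#'
#' Container for all electrodes of one MEA recording. Every train shares the
#' same \code{[tStart, tStop)} interval and electrode ids are unique.
#'
#' @slot trains named list of [SpikeTrain-class] objects, names equal to the
#'   electrode ids.
#' @slot samplingRate acquisition rate in Hz for trace-derived sessions
#'   (\code{NA_real_} when the session was built from timestamps only).
#' @slot annotations free-form list of protocol metadata.
#'
#' @exportClass RecordingSession
setClass("RecordingSession",
  representation(
    trains = "list",
    samplingRate = "numeric",
    annotations = "list"
  ),
  prototype(samplingRate = NA_real_, annotations = list())
)

setValidity("RecordingSession", function(object) {
  msg <- character()
  tr <- object@trains
  if (!all(vapply(tr, is, logical(1L), class2 = "SpikeTrain")))
    return("all elements of 'trains' must be SpikeTrain objects")
  ids <- vapply(tr, function(x) x@electrodeId, character(1L))
  if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicated electrode ids: %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (!identical(unname(names(tr)), unname(ids)) && length(tr))
    msg <- c(msg, "'trains' must be named by electrode id")
  if (length(tr) > 1L) {
    t0 <- vapply(tr, function(x) x@tStart, numeric(1L))
    t1 <- vapply(tr, function(x) x@tStop, numeric(1L))
    if (length(unique(t0)) > 1L || length(unique(t1)) > 1L)
      msg <- c(msg, "all trains must share identical [tStart, tStop)")
  }
  if (length(object@samplingRate) != 1L)
    msg <- c(msg, "'samplingRate' must be a single number (may be NA)")
  else if (!is.na(object@samplingRate) && object@samplingRate <= 0)
    msg <- c(msg, "'samplingRate' must be positive")
  if (length(msg)) msg else TRUE
})

#' ModuleMap: assignment of electrodes to network modules
#'
#' Maps electrode ids to named network modules (e.g. \code{N1}, \code{N2});
#' control electrodes in unconnected networks carry the reserved control
#' label. Electrodes may also be explicitly excluded from analysis.
#'
#' @slot assignment named character vector, electrode id -> module label.
#' @slot controlLabel the reserved label marking control electrodes
#'   (default \code{"CTRL"}).
#' @slot excluded electrode ids explicitly excluded from all analyses.
#'
#' @exportClass ModuleMap
setClass("ModuleMap",
  representation(
    assignment = "character",
    controlLabel = "character",
    excluded = "character"
  ),
  prototype(controlLabel = "CTRL", excluded = character())
)

setValidity("ModuleMap", function(object) {
  msg <- character()
  a <- object@assignment
  if (length(a) == 0L)
    msg <- c(msg, "module map contains no electrodes")
  if (is.null(names(a)) || any(!nzchar(names(a))))
    msg <- c(msg, "'assignment' must be named by electrode id")
  else if (anyDuplicated(names(a)))
    msg <- c(msg, sprintf("electrode assigned to more than one module: %s",
                          paste(unique(names(a)[duplicated(names(a))]),
                                collapse = ", ")))
  if (length(object@controlLabel) != 1L || !nzchar(object@controlLabel))
    msg <- c(msg, "'controlLabel' must be a single non-empty string")
  if (length(a) && all(a == object@controlLabel))
    msg <- c(msg, "map must contain at least one non-control module")
  if (any(object@excluded %in% names(a)))
    msg <- c(msg, "excluded electrodes must not also be assigned to a module")
  if (length(msg)) msg else TRUE
})

#' TraceBlock: raw multi-channel voltage traces
#'
#' A channels-by-samples matrix of extracellular voltages in microvolts at a
#' fixed sampling rate, as delivered by an MEA acquisition chain after
#' band-pass filtering (150--4000 Hz in the hardware this package targets).
#'
#' @slot samples numeric matrix, channels x samples, microvolts.
#' @slot samplingRate sampling rate in Hz (e.g. 25000).
#' @slot channelIds character vector of channel (electrode) ids, one per row.
#'
#' @exportClass TraceBlock
setClass("TraceBlock",
  representation(
    samples = "matrix",
    samplingRate = "numeric",
    channelIds = "character"
  )
)

setValidity("TraceBlock", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "'samplingRate' must be a single positive number")
  if (!is.numeric(object@samples))
    msg <- c(msg, "'samples' must be a numeric matrix")
  if (nrow(object@samples) != length(object@channelIds))
    msg <- c(msg, "one channel id per row of 'samples' required")
  if (anyDuplicated(object@channelIds))
    msg <- c(msg, "channel ids must be unique")
  if (length(msg)) msg else TRUE
})

#' RateHistogram: binned firing rate for one electrode
#'
#' Firing rate of one electrode in consecutive half-open time bins
#' \code{[a, a + binWidth)}. Unsmoothed rates are \code{count / binWidth} in
#' Hz; smoothing convolves with a discrete Gaussian kernel under a
#' count-conserving edge policy (see [smoothRates()]).
#'
#' @slot electrodeId electrode label.
#' @slot binWidth bin width in seconds (default convention 0.1 s).
#' @slot rates per-bin firing rate in Hz, length \code{floor(duration/binWidth)}.
#' @slot tStart time of the left edge of the first bin (s).
#' @slot smoothed logical, whether Gaussian smoothing has been applied.
#' @slot kernelBins kernel support in bins (odd; 0 when unsmoothed).
#'
#' @exportClass RateHistogram
setClass("RateHistogram",
  representation(
    electrodeId = "character",
    binWidth = "numeric",
    rates = "numeric",
    tStart = "numeric",
    smoothed = "logical",
    kernelBins = "integer"
  ),
  prototype(smoothed = FALSE, kernelBins = 0L)
)

setValidity("RateHistogram", function(object) {
  msg <- character()
  if (length(object@binWidth) != 1L || object@binWidth <= 0)
    msg <- c(msg, "'binWidth' must be a single positive number")
  if (any(object@rates < -1e-12, na.rm = TRUE))
    msg <- c(msg, "rates must be non-negative")
  if (length(msg)) msg else TRUE
})

#' CCSummary: intra- and inter-network correlation summary
#'
#' Means of pairwise Pearson correlation coefficients grouped by module
#' membership: within-module (intra-CC), between-module (inter-CC, per module
#' pair and pooled), and pairs involving control electrodes (reported
#' separately). Undefined coefficients (zero-variance channels) are excluded
#' from all means.
#'
#' @slot intraModule named numeric, mean intra-CC per module (NA and flagged
#'   when a module has fewer than two active electrodes).
#' @slot intraOverall mean over all within-module pairs pooled.
#' @slot interPairs data.frame with columns \code{module1}, \code{module2},
#'   \code{cc}, \code{n_pairs}.
#' @slot interOverall mean over all between-module pairs pooled.
#' @slot control mean correlation of pairs involving control electrodes
#'   (NA when no control electrodes are present).
#' @slot nPairs named integer: numbers of intra, inter and control pairs used.
#' @slot flagged character vector of modules with undefined intra-CC.
#'
#' @exportClass CCSummary
setClass("CCSummary",
  representation(
    intraModule = "numeric",
    intraOverall = "numeric",
    interPairs = "data.frame",
    interOverall = "numeric",
    control = "numeric",
    nPairs = "integer",
    flagged = "character"
  )
)

#' PSTH: peri-stimulus time histogram
#'
#' Spike counts in half-open bins over \code{[0, window)} after each stimulus,
#' pooled over trials. Bins lying fully inside the artifact blanking window
#' are flagged as masked rather than reported as zero.
#'
#' @slot electrodeId recording electrode (or a pooled label).
#' @slot binWidth bin width in seconds.
#' @slot counts integer spike counts per bin, pooled over trials.
#' @slot rate normalized rate per bin, \code{counts / (nTrials * binWidth)}, Hz.
#' @slot edges bin left edges (s post-stimulus).
#' @slot masked logical per bin; TRUE when the bin lies inside the blank.
#' @slot nTrials number of stimuli.
#' @slot window analysis window length (s).
#' @slot blank blanking window length (s).
#'
#' @exportClass PSTH
setClass("PSTH",
  representation(
    electrodeId = "character",
    binWidth = "numeric",
    counts = "numeric",
    rate = "numeric",
    edges = "numeric",
    masked = "logical",
    nTrials = "integer",
    window = "numeric",
    blank = "numeric"
  )
)

#' SimConfig: parameters of the modular-network simulator
#'
#' Complete parameterization of a synthetic modular MEA session: per-module
#' bursting statistics, directed inter-module couplings, suppression factors
#' per illumination power density, and evoked-response parameters. A single
#' integer seed fixes all randomness downstream.
#'
#' @slot modules list of module descriptions built with [simModule()].
#' @slot couplings list of directed couplings built with [simCoupling()].
#' @slot duration session length in seconds.
#' @slot suppression data.frame mapping \code{power} (mW/mm^2, opaque
#'   metadata) to \code{factor}, the rate-scaling in [0, 1] applied to the
#'   targeted module during an epoch (0 = complete suppression).
#' @slot stimResponse list of evoked-response descriptions built with
#'   [simStimResponse()].
#'
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    modules = "list",
    couplings = "list",
    duration = "numeric",
    suppression = "data.frame",
    stimResponse = "list"
  ),
  prototype(couplings = list(), suppression = data.frame(),
            stimResponse = list())
)

setValidity("SimConfig", function(object) {
  msg <- character()
  labs <- vapply(object@modules, `[[`, character(1L), "label")
  if (length(labs) == 0L) msg <- c(msg, "at least one module required")
  if (anyDuplicated(labs)) msg <- c(msg, "module labels must be unique")
  for (m in object@modules) {
    if (m$participation < 0 || m$participation > 1)
      msg <- c(msg, sprintf("module %s: participation must be in [0,1]", m$label))
    if (m$drivenFraction < 0 || m$drivenFraction > 1)
      msg <- c(msg, sprintf("module %s: drivenFraction must be in [0,1]", m$label))
    if (m$burstRate < 0 || m$backgroundRate < 0 || m$burstDuration <= 0)
      msg <- c(msg, sprintf("module %s: rates must be >= 0, burstDuration > 0",
                            m$label))
  }
  for (cp in object@couplings) {
    if (!cp$source %in% labs || !cp$target %in% labs)
      msg <- c(msg, sprintf("coupling %s->%s references unknown module",
                            cp$source, cp$target))
    if (cp$p < 0 || cp$p > 1)
      msg <- c(msg, sprintf("coupling %s->%s: p must be in [0,1]",
                            cp$source, cp$target))
    if (cp$delayMean <= 0 || cp$delaySd < 0)
      msg <- c(msg, sprintf("coupling %s->%s: delays must be > 0",
                            cp$source, cp$target))
  }
  if (length(object@duration) != 1L || object@duration <= 0)
    msg <- c(msg, "'duration' must be a single positive number")
  if (nrow(object@suppression)) {
    if (!all(c("power", "factor") %in% names(object@suppression)))
      msg <- c(msg, "'suppression' needs columns power, factor")
    else if (any(object@suppression$factor < 0 | object@suppression$factor > 1))
      msg <- c(msg, "suppression factors must be in [0,1]")
  }
  if (length(msg)) msg else TRUE
})
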