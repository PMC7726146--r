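## Threshold-based spike detection from band-pass-filtered extracellular
## traces. Spikes are negative deflections; a spike is timestamped at the
## first sample crossing below -k_sd * sigma, where sigma is the background
## noise level of the channel, and subsequent crossings within the dead time
## are ignored so one waveform is counted once.

#' Estimate the background noise SD of a trace
#'
#' The robust default estimates sigma as \code{median(|x - median(x)|) /
#' 0.6745}, the MAD scaled to the SD of a Gaussian; unlike the global sample
#' SD it is insensitive to the rare large spike deflections riding on the
#' noise, which would otherwise inflate the detection threshold.
#'
#' @param trace numeric vector, single-channel voltages (microvolts).
#' @param method \code{"robust_mad"} (default) or \code{"global_sd"}.
#' @return positive scalar noise SD in the units of \code{trace}.
#' @export
estimateNoiseSD <- function(trace, method = c("robust_mad", "global_sd")) {
  method <- match.arg(method)
  if (length(trace) < 1000L)
    stop("trace too short for noise estimation (need >= 1000 samples)")
  est <- switch(method,
    robust_mad = stats::median(abs(trace - stats::median(trace))) / 0.6745,
    global_sd = stats::sd(trace))
  if (!is.finite(est) || est <= 0)
    stop("degenerate signal: estimated noise SD is zero (constant trace?)")
  est
}

#' Detect spikes by negative threshold crossing
#'
#' Timestamps the first sample of every excursion below \code{-kSd * sigma}
#' (sample index / sampling rate, first sample at t = 0). After a detection,
#' crossings within \code{deadTime} are ignored. Only the negative threshold
#' is applied. The trace is assumed band-pass filtered (in this package's
#' target hardware, 150--4000 Hz before digitization); [bandpassFilter()] is
#' available when software filtering is needed.
#'
#' @param trace numeric vector (microvolts) or a [TraceBlock-class] row.
#' @param samplingRate sampling rate in Hz.
#' @param kSd threshold multiplier (default 6; threshold is \code{-kSd*sigma}).
#' @param deadTime refractory window in seconds after each detection
#'   (default 0.001).
#' @param noiseEstimator passed to [estimateNoiseSD()].
#' @param electrodeId label for the returned train.
#' @param noiseSD optionally supply sigma and skip estimation.
#' @return a [SpikeTrain-class] over \code{[0, length(trace)/samplingRate)}.
#' @export
detectSpikes <- function(trace, samplingRate, kSd = 6, deadTime = 0.001,
                         noiseEstimator = c("robust_mad", "global_sd"),
                         electrodeId = "ch1", noiseSD = NULL) {
  if (samplingRate <= 0) stop("samplingRate must be positive")
  if (kSd <= 0) stop("kSd must be positive")
  if (deadTime < 0) stop("deadTime must be >= 0")
  sigma <- if (is.null(noiseSD))
    estimateNoiseSD(trace, match.arg(noiseEstimator)) else noiseSD
  thr <- -kSd * sigma
  below <- trace < thr
  ## first sample of each sub-threshold excursion
  onset <- which(below & !c(FALSE, below[-length(below)]))
  times <- (onset - 1) / samplingRate
  if (deadTime > 0 && length(times) > 1L) {
    keep <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= deadTime) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep]
  }
  SpikeTrain(electrodeId, times, tStart = 0,
             tStop = length(trace) / samplingRate, sort = FALSE)
}

#' Detect spikes on every channel of a TraceBlock
#'
#' @param traces a [TraceBlock-class].
#' @inheritParams detectSpikes
#' @return a [RecordingSession-class] with one train per channel.
#' @export
detectSessionSpikes <- function(traces, kSd = 6, deadTime = 0.001,
                                noiseEstimator = c("robust_mad", "global_sd")) {
  stopifnot(is(traces, "TraceBlock"))
  noiseEstimator <- match.arg(noiseEstimator)
  trains <- lapply(seq_len(nrow(traces@samples)), function(i) {
    detectSpikes(traces@samples[i, ], traces@samplingRate, kSd = kSd,
                 deadTime = deadTime, noiseEstimator = noiseEstimator,
                 electrodeId = traces@channelIds[i])
  })
  RecordingSession(trains, samplingRate = traces@samplingRate)
}

#' Remove spikes inside stimulation-artifact windows
#'
#' Deterministic artifact handling: every spike falling in
#' \code{[t_stim, t_stim + blankWindow)} for any stimulus is removed, all
#' other spikes are preserved. This package performs no spike sorting, so
#' residual artifact waveforms are excluded by this blanking rule instead.
#'
#' @param train a [SpikeTrain-class].
#' @param stimTimes sorted stimulus onset times (s).
#' @param blankWindow blanking window length in seconds (default 0.002).
#' @return a [SpikeTrain-class] without the blanked spikes.
#' @export
blankStimulusArtifacts <- function(train, stimTimes, blankWindow = 0.002) {
  if (blankWindow < 0) stop("blankWindow must be >= 0")
  if (!length(stimTimes) || blankWindow == 0) return(train)
  stimTimes <- sort(stimTimes)
  idx <- findInterval(train@times, stimTimes)
  blanked <- idx >= 1L & (train@times - stimTimes[pmax(idx, 1L)]) < blankWindow
  initialize(train, times = train@times[!blanked])
}

#' Zero-phase band-pass filter for extracellular traces
#'
#' Butterworth band-pass applied forward and backward (zero phase lag, so
#' spike timestamps are not shifted). A second-order design filtered twice
#' gives an effective fourth-order response. Provided for raw traces that
#' were not already filtered in hardware.
#'
#' @param trace numeric vector of voltages.
#' @param samplingRate sampling rate in Hz.
#' @param low,high pass-band corner frequencies in Hz (defaults 150, 4000).
#' @param order Butterworth design order per pass (default 2).
#' @return filtered numeric vector of the same length.
#' @export
bandpassFilter <- function(trace, samplingRate, low = 150, high = 4000,
                           order = 2) {
  nyq <- samplingRate / 2
  if (high >= nyq) stop("upper corner must be below the Nyquist frequency")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, trace))
}
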