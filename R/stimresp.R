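## Peri-stimulus time histograms and evoked-response statistics for
## electrical stimulation trials (the package convention mirrors common MEA
## protocols: ~20 biphasic pulses delivered every 3 s, evoked spikes counted
## within 50 ms). Responses within <10 ms of the pulse are treated as
## direct/antidromic activation of the stimulated network; responses in the
## 15-35 ms window indicate synaptic propagation from another module.

#' Build a peri-stimulus time histogram
#'
#' Re-references every spike to the nearest preceding stimulus and counts
#' spikes in half-open bins over \code{[0, window)} post-stimulus, pooled
#' over trials. Bins lying fully inside the artifact blanking window are
#' flagged as masked (their counts are reported but should not be
#' interpreted). The normalized rate is \code{counts / (nTrials * binWidth)}.
#'
#' @param train a [SpikeTrain-class] (artifact-blanked, or rely on
#'   \code{blank}).
#' @param stimTimes strictly increasing stimulus times (s); consecutive
#'   stimuli must be at least \code{window} apart.
#' @param binWidth bin width in seconds (default 0.001).
#' @param window analysis window length in seconds (default 0.05).
#' @param blank artifact blanking window in seconds (default 0.002); bins
#'   with upper edge at or below it are masked.
#' @return a [PSTH-class].
#' @export
buildPSTH <- function(train, stimTimes, binWidth = 0.001, window = 0.05,
                      blank = 0.002) {
  if (!length(stimTimes)) stop("no stimulus times")
  if (is.unsorted(stimTimes, strictly = TRUE))
    stop("stimTimes must be strictly increasing")
  if (length(stimTimes) > 1L && min(diff(stimTimes)) < window)
    stop("stimulus spacing shorter than the analysis window (overlap)")
  if (blank < 0) stop("blank must be >= 0")
  nbins <- floor(window / binWidth + 1e-9)
  if (nbins < 1L) stop("window shorter than one bin")
  ts <- train@times
  ref <- findInterval(ts, stimTimes)
  dt <- ts - stimTimes[pmax(ref, 1L)]
  dt <- dt[ref >= 1L & dt >= 0 & dt < nbins * binWidth]
  ## small relative guard so a latency nominally on a bin edge is assigned
  ## to the right-hand (half-open) bin despite floating-point subtraction
  counts <- tabulate(floor(dt / binWidth + 1e-9) + 1L, nbins)
  edges <- (seq_len(nbins) - 1L) * binWidth
  new("PSTH", electrodeId = train@electrodeId, binWidth = binWidth,
      counts = as.numeric(counts),
      rate = counts / (length(stimTimes) * binWidth),
      edges = edges, masked = edges + binWidth <= blank + 1e-12,
      nTrials = length(stimTimes), window = window, blank = blank)
}

#' Mean PSTH over recording electrodes
#'
#' Averages per-electrode PSTH rates over a set of recording electrodes,
#' excluding the stimulated electrodes (the package convention for
#' array-level evoked-response maps).
#'
#' @param session a [RecordingSession-class].
#' @param stimTimes stimulus times (s).
#' @param electrodes recording electrodes to pool (default: all).
#' @param excludeElectrodes electrodes to drop, typically the stimulation
#'   sites.
#' @inheritParams buildPSTH
#' @return list with \code{rate} (mean rate per bin, Hz), \code{sd} (across
#'   electrodes), \code{edges}, \code{masked}, \code{electrodes} and the
#'   per-electrode [PSTH-class] objects in \code{psths}.
#' @export
meanPSTH <- function(session, stimTimes, electrodes = electrodeIds(session),
                     excludeElectrodes = character(), binWidth = 0.005,
                     window = 0.05, blank = 0.002) {
  electrodes <- setdiff(electrodes, excludeElectrodes)
  if (!length(electrodes)) stop("no recording electrodes left to pool")
  psths <- lapply(electrodes, function(id)
    buildPSTH(session@trains[[id]], stimTimes, binWidth, window, blank))
  rates <- vapply(psths, function(p) p@rate, numeric(length(psths[[1L]]@rate)))
  rates <- matrix(rates, ncol = length(psths))
  list(rate = rowMeans(rates),
       sd = apply(rates, 1L, stats::sd),
       edges = psths[[1L]]@edges, masked = psths[[1L]]@masked,
       electrodes = electrodes, psths = psths)
}

#' Evoked-response probability
#'
#' Fraction of stimulation trials with at least one spike in the response
#' window \code{[a, b)} (seconds post-stimulus). Stimulus times from several
#' stimulation electrodes may be pooled by concatenating them (sorted).
#'
#' @param train a [SpikeTrain-class].
#' @param stimTimes stimulus times (s); spacing must be at least \code{b}.
#' @param responseWindow numeric length-2, \code{c(a, b)} with \code{b > a}
#'   (default \code{c(0.015, 0.035)}, the synaptic propagation window).
#' @return fraction in [0, 1].
#' @export
responseProbability <- function(train, stimTimes,
                                responseWindow = c(0.015, 0.035)) {
  a <- responseWindow[1L]
  b <- responseWindow[2L]
  if (b <= a) stop("response window must have b > a")
  stimTimes <- sort(stimTimes)
  if (length(stimTimes) > 1L && min(diff(stimTimes)) < b)
    stop("stimulus spacing shorter than the response window (overlap)")
  ts <- train@times
  hits <- vapply(stimTimes, function(s)
    any(ts >= s + a & ts < s + b), logical(1L))
  mean(hits)
}

#' Early/late split of a PSTH
#'
#' Summarizes the response mass in the early (direct/antidromic, below
#' \code{earlyMax} s) and late (synaptic propagation,
#' \code{[lateWindow[1], lateWindow[2])} s) sub-windows. Bin edges must align
#' with the sub-window boundaries; masked (blanked) bins are excluded from
#' the early summary.
#'
#' @param psth a [PSTH-class].
#' @param earlyMax upper edge of the early window (default 0.010 s).
#' @param lateWindow late window, default \code{c(0.015, 0.035)} s.
#' @return list of two lists (\code{early}, \code{late}), each with
#'   \code{window}, \code{spikes_per_trial} and \code{mean_rate} (Hz).
#' @export
earlyLateSplit <- function(psth, earlyMax = 0.010,
                           lateWindow = c(0.015, 0.035)) {
  bw <- psth@binWidth
  aligned <- function(t) abs(t / bw - round(t / bw)) < 1e-9
  if (!aligned(earlyMax) || !all(vapply(lateWindow, aligned, logical(1L))))
    stop("bin edges must align with the 10/15/35 ms sub-window boundaries")
  lo <- psth@edges
  hi <- psth@edges + bw
  early_sel <- hi <= earlyMax + 1e-12 & !psth@masked
  late_sel <- lo >= lateWindow[1L] - 1e-12 & hi <= lateWindow[2L] + 1e-12
  summ <- function(sel, win) list(
    window = win,
    spikes_per_trial = sum(psth@counts[sel]) / psth@nTrials,
    mean_rate = if (any(sel)) mean(psth@rate[sel]) else 0)
  list(early = summ(early_sel, c(psth@blank, earlyMax)),
       late = summ(late_sel, lateWindow))
}
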