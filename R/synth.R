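## Seeded generator of synthetic modular MEA sessions. Activity is modeled at
## the burst-event level: each module emits intrinsic burst events as a
## Poisson process; a directed coupling lets every burst of the source module
## trigger a burst in the target module with probability p after a truncated
## Gaussian delay, recursively (a triggered burst triggers onward), so
## reverberating two-way loops arise naturally as long as the loop gain
## (product of the cycle's coupling probabilities) stays below one.
## Within a burst, each electrode of the module participates with a fixed
## probability and fires a Poisson number of spikes uniformly over the burst
## duration; independent Poisson background spikes are added per electrode.
## Suppression epochs delete the targeted module's bursts (and, through the
## recorded provenance, every burst they would have triggered downstream) and
## thin its background spikes by the configured factor. Every spike is
## attributable to background, a burst, or an evoked response, and the full
## provenance is exported as ground truth.

#' Describe one simulated network module
#'
#' @param label module label (e.g. \code{"N1"}).
#' @param nElectrodes electrodes in the module (default 4, matching a
#'   four-electrode well).
#' @param backgroundRate per-electrode background firing rate, Hz
#'   (default 0.2).
#' @param burstRate nominal burst-event rate, events/min (default 10).
#' @param burstDuration burst length in seconds (default 0.25).
#' @param spikesPerBurst mean spikes per electrode per burst (Poisson,
#'   default 15).
#' @param participation probability that an electrode joins a given burst
#'   (default 0.9).
#' @param drivenFraction fraction of this module's bursts expected to be
#'   triggered by incoming couplings; the intrinsic Poisson rate is
#'   \code{burstRate * (1 - drivenFraction)}, and the couplings supply the
#'   driven share when their probabilities are chosen consistently.
#' @param control flag the module's electrodes as controls (an unconnected
#'   network used as a null reference).
#' @return a module description list for [simConfig()].
#' @export
simModule <- function(label, nElectrodes = 4, backgroundRate = 0.2,
                      burstRate = 10, burstDuration = 0.25,
                      spikesPerBurst = 15, participation = 0.9,
                      drivenFraction = 0, control = FALSE) {
  list(label = as.character(label), nElectrodes = as.integer(nElectrodes),
       backgroundRate = backgroundRate, burstRate = burstRate,
       burstDuration = burstDuration, spikesPerBurst = spikesPerBurst,
       participation = participation, drivenFraction = drivenFraction,
       control = isTRUE(control))
}

#' Describe a directed inter-module coupling
#'
#' @param source,target module labels.
#' @param p probability that a source burst triggers a target burst.
#' @param delayMean,delaySd burst-onset propagation delay in seconds
#'   (Gaussian truncated to positive values; defaults 0.03 and 0.008,
#'   in the 15--35 ms range typical of inter-module synaptic propagation).
#' @param active optional \code{c(t0, t1)}: the coupling only operates for
#'   source bursts with onset in \code{[t0, t1)} (used to emulate a
#'   structural disconnection mid-session).
#' @return a coupling description list for [simConfig()].
#' @export
simCoupling <- function(source, target, p, delayMean = 0.03,
                        delaySd = 0.008, active = NULL) {
  list(source = as.character(source), target = as.character(target),
       p = p, delayMean = delayMean, delaySd = delaySd, active = active)
}

#' Describe an evoked response to electrical stimulation
#'
#' @param module responding module label.
#' @param probability per-trial probability that the module responds.
#' @param delayMean,delaySd response latency in seconds (Gaussian truncated
#'   positive; defaults 0.02 and 0.003).
#' @param jitterSd per-electrode jitter around the trial latency (s).
#' @return an evoked-response description list for [simConfig()].
#' @export
simStimResponse <- function(module, probability, delayMean = 0.02,
                            delaySd = 0.003, jitterSd = 0.0005) {
  list(module = as.character(module), probability = probability,
       delayMean = delayMean, delaySd = delaySd, jitterSd = jitterSd)
}

#' Assemble a simulator configuration
#'
#' @param modules list of [simModule()] descriptions.
#' @param couplings list of [simCoupling()] descriptions.
#' @param duration session length in seconds (default 600).
#' @param suppression data.frame with columns \code{power} (mW/mm^2,
#'   metadata) and \code{factor} (rate scaling in [0, 1] applied to the
#'   targeted module during an epoch at that power; 0 = full suppression).
#' @param stimResponse list of [simStimResponse()] descriptions.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(modules, couplings = list(), duration = 600,
                      suppression = data.frame(power = numeric(),
                                               factor = numeric()),
                      stimResponse = list()) {
  new("SimConfig", modules = modules, couplings = couplings,
      duration = as.numeric(duration), suppression = suppression,
      stimResponse = stimResponse)
}

.rtrunc_norm_pos <- function(n, mean, sd) {
  if (n == 0L) return(numeric())
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

.module_electrodes <- function(m) paste0(m$label, "_ch", seq_len(m$nElectrodes))

#' Module map implied by a simulator configuration
#'
#' Non-control modules keep their labels; electrodes of control modules are
#' pooled under the control label.
#'
#' @param config a [SimConfig-class].
#' @param controlLabel control label (default \code{"CTRL"}).
#' @return a [ModuleMap-class].
#' @export
simModuleMap <- function(config, controlLabel = "CTRL") {
  mods <- list()
  ctrl <- character()
  for (m in config@modules) {
    if (m$control) ctrl <- c(ctrl, .module_electrodes(m))
    else mods[[m$label]] <- .module_electrodes(m)
  }
  if (length(ctrl)) mods[[controlLabel]] <- ctrl
  ModuleMap(mods, controlLabel = controlLabel)
}

#' Simulate the burst process of one module in isolation
#'
#' Intrinsic burst onsets as a Poisson process at the module's nominal burst
#' rate, with the per-electrode spike trains they generate plus background
#' spikes. No couplings are applied; see [generateSession()] for the full
#' cascade.
#'
#' @param config a [SimConfig-class].
#' @param module module label.
#' @param seed integer seed.
#' @return list with \code{bursts} (data.frame \code{onset}, \code{end}) and
#'   \code{session} (a [RecordingSession-class] of the module's electrodes).
#' @export
simulateModuleBursts <- function(config, module, seed) {
  set.seed(seed)
  m <- .find_module(config, module)
  dur <- config@duration
  n <- stats::rpois(1L, m$burstRate / 60 * dur)
  onsets <- sort(stats::runif(n, 0, dur))
  bursts <- data.frame(onset = onsets, end = onsets + m$burstDuration)
  spikes <- .burst_spikes(m, onsets, dur)
  bg <- .background_spikes(m, dur)
  trains <- .assemble_trains(m, rbind(spikes, bg), dur)
  list(bursts = bursts, session = RecordingSession(trains))
}

#' Trigger target-module bursts from a source burst sequence
#'
#' Each source burst triggers a target burst with the coupling probability
#' after a truncated-Gaussian delay; intrinsic target bursts are added at the
#' rate that makes the module's configured driven fraction hold in
#' expectation (for \code{drivenFraction} d and an observed triggered rate r,
#' intrinsic bursts arrive at rate \code{r (1 - d) / d}; with d = 0 the
#' module falls back to its nominal intrinsic rate).
#'
#' @param config a [SimConfig-class] with a coupling from \code{source} to
#'   \code{target}.
#' @param sourceBursts data.frame with an \code{onset} column.
#' @param source,target module labels.
#' @param seed integer seed.
#' @return data.frame with \code{onset}, \code{end}, \code{triggered_by}
#'   (source burst row or NA for intrinsic) and \code{delay}, sorted by onset.
#' @export
coupleModules <- function(config, sourceBursts, source, target, seed) {
  set.seed(seed)
  cp <- NULL
  for (k in config@couplings)
    if (k$source == source && k$target == target) cp <- k
  if (is.null(cp)) stop("no coupling ", source, "->", target, " in config")
  m <- .find_module(config, target)
  dur <- config@duration
  hit <- stats::runif(nrow(sourceBursts)) < cp$p
  delays <- rep(NA_real_, nrow(sourceBursts))
  delays[hit] <- .rtrunc_norm_pos(sum(hit), cp$delayMean, cp$delaySd)
  trig <- data.frame(onset = sourceBursts$onset[hit] + delays[hit],
                     triggered_by = which(hit), delay = delays[hit])
  trig <- trig[trig$onset < dur, , drop = FALSE]
  d <- m$drivenFraction
  lambda_int <- if (d > 0) (nrow(trig) / dur) * (1 - d) / d else
    m$burstRate / 60
  n_int <- stats::rpois(1L, lambda_int * dur)
  intr <- data.frame(onset = stats::runif(n_int, 0, dur),
                     triggered_by = rep(NA_integer_, n_int),
                     delay = rep(NA_real_, n_int))
  out <- rbind(trig, intr)
  out$end <- out$onset + m$burstDuration
  out <- out[order(out$onset), c("onset", "end", "triggered_by", "delay")]
  rownames(out) <- NULL
  out
}

.find_module <- function(config, label) {
  for (m in config@modules) if (m$label == label) return(m)
  stop("unknown module: ", label)
}

## spikes emitted by a vector of burst onsets of one module
## returns data.frame(electrode, time, burst)
.burst_spikes <- function(m, onsets, dur, burst_ids = seq_along(onsets)) {
  if (!length(onsets))
    return(data.frame(electrode = character(), time = numeric(),
                      burst = integer()))
  els <- .module_electrodes(m)
  recs <- vector("list", length(els))
  for (e in seq_along(els)) {
    joins <- stats::runif(length(onsets)) < m$participation
    ns <- ifelse(joins, stats::rpois(length(onsets), m$spikesPerBurst), 0L)
    total <- sum(ns)
    if (!total) {
      recs[[e]] <- NULL
      next
    }
    off <- stats::runif(total, 0, m$burstDuration)
    recs[[e]] <- data.frame(
      electrode = els[e],
      time = rep(onsets, ns) + off,
      burst = rep(burst_ids, ns))
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) out <- data.frame(electrode = character(),
                                      time = numeric(), burst = integer())
  out[out$time < dur, , drop = FALSE]
}

.background_spikes <- function(m, dur) {
  els <- .module_electrodes(m)
  recs <- lapply(els, function(id) {
    n <- stats::rpois(1L, m$backgroundRate * dur)
    data.frame(electrode = rep(id, n), time = stats::runif(n, 0, dur),
               burst = rep(NA_integer_, n))
  })
  do.call(rbind, recs)
}

.assemble_trains <- function(m, spikes, dur) {
  lapply(.module_electrodes(m), function(id) {
    ts <- sort(unique(spikes$time[spikes$electrode == id]))
    SpikeTrain(id, ts, 0, dur, sort = FALSE)
  })
}

## full burst cascade over all modules; returns the burst table with
## provenance (id, module, onset, end, parent, delay, generation)
.burst_cascade <- function(config, maxBursts = 5e5) {
  dur <- config@duration
  recs <- list()
  nid <- 0L
  frontier <- list()
  for (m in config@modules) {
    rate <- m$burstRate / 60 * (1 - m$drivenFraction)
    n <- stats::rpois(1L, rate * dur)
    if (!n) next
    onsets <- sort(stats::runif(n, 0, dur))
    ids <- nid + seq_len(n)
    nid <- nid + n
    df <- data.frame(id = ids, module = m$label, onset = onsets,
                     parent = NA_integer_, delay = NA_real_, generation = 0L)
    recs[[length(recs) + 1L]] <- df
    frontier[[length(frontier) + 1L]] <- df
  }
  gen <- 0L
  while (length(frontier)) {
    fr <- do.call(rbind, frontier)
    frontier <- list()
    gen <- gen + 1L
    if (gen > 200L) stop("burst cascade did not terminate; check loop gains")
    for (cp in config@couplings) {
      src <- fr[fr$module == cp$source, , drop = FALSE]
      if (!nrow(src)) next
      if (!is.null(cp$active))
        src <- src[src$onset >= cp$active[1L] & src$onset < cp$active[2L], ,
                   drop = FALSE]
      if (!nrow(src)) next
      hit <- stats::runif(nrow(src)) < cp$p
      if (!any(hit)) next
      delays <- .rtrunc_norm_pos(sum(hit), cp$delayMean, cp$delaySd)
      onsets <- src$onset[hit] + delays
      keep <- onsets < dur
      if (!any(keep)) next
      n <- sum(keep)
      ids <- nid + seq_len(n)
      nid <- nid + n
      if (nid > maxBursts)
        stop("burst cascade exceeded ", maxBursts, " events")
      df <- data.frame(id = ids, module = cp$target, onset = onsets[keep],
                       parent = src$id[hit][keep], delay = delays[keep],
                       generation = gen)
      recs[[length(recs) + 1L]] <- df
      frontier[[length(frontier) + 1L]] <- df
    }
  }
  if (!length(recs))
    return(data.frame(id = integer(), module = character(), onset = numeric(),
                      parent = integer(), delay = numeric(),
                      generation = integer()))
  out <- do.call(rbind, recs)
  out <- out[order(out$id), ]
  rownames(out) <- NULL
  out
}

.suppression_factor <- function(config, power) {
  i <- match(power, config@suppression$power)
  if (is.na(i)) stop("no suppression factor configured for power ", power)
  config@suppression$factor[i]
}

#' Apply suppression epochs to a generated session plan
#'
#' Deletes the targeted module's bursts whose onset falls in an epoch with
#' probability \code{1 - factor} (the configured rate scaling for the
#' epoch's power density); every burst downstream in the trigger provenance
#' of a deleted burst is deleted with it, so suppressing a source module also
#' silences the activity it would have driven in coupled modules. Background
#' and evoked spikes of the targeted module inside the epoch are thinned by
#' the same factor. Ground-truth factors are recorded per epoch.
#'
#' @param plan output of [generateSession()] (run without a protocol).
#' @param protocol protocol data.frame (see [readProtocol()]); epochs of one
#'   module must not overlap.
#' @param config the [SimConfig-class] used to generate the plan (supplies
#'   the power-to-factor mapping).
#' @param seed integer seed for the deletion draws.
#' @return a plan of the same shape with suppressed activity removed and
#'   \code{groundTruth$epochs} filled in.
#' @export
applySuppression <- function(plan, protocol, config, seed) {
  set.seed(seed)
  gt <- plan$groundTruth
  bursts <- gt$bursts
  spikes <- gt$spikes
  protocol <- protocol[order(protocol$on), , drop = FALSE]
  for (m in unique(protocol$target)) {
    pm <- protocol[protocol$target == m, ]
    if (nrow(pm) > 1L && any(pm$on[-1L] < pm$off[-nrow(pm)]))
      stop("overlapping suppression epochs for module ", m)
  }
  protocol$factor <- vapply(protocol$power, .suppression_factor,
                            numeric(1L), config = config)
  deleted <- rep(FALSE, nrow(bursts))
  direct <- rep(FALSE, nrow(bursts))
  for (i in seq_len(nrow(protocol))) {
    sel <- bursts$module == protocol$target[i] &
      bursts$onset >= protocol$on[i] & bursts$onset < protocol$off[i]
    if (!any(sel)) next
    kill <- sel & (stats::runif(nrow(bursts)) >= protocol$factor[i])
    direct <- direct | kill
  }
  ## propagate deletions to descendants (children carry larger ids)
  deleted <- direct
  idx_of <- match(bursts$parent, bursts$id)
  ord <- order(bursts$id)
  for (j in ord) {
    p <- idx_of[j]
    if (!is.na(p) && deleted[p]) deleted[j] <- TRUE
  }
  bursts$suppressed <- deleted
  dead_ids <- bursts$id[deleted]
  keep <- !(spikes$burst %in% dead_ids)
  ## thin loose (background/evoked) spikes of the target module in-epoch
  mod_of_electrode <- gt$electrodeModule
  loose <- is.na(spikes$burst)
  for (i in seq_len(nrow(protocol))) {
    sel <- loose & mod_of_electrode[spikes$electrode] == protocol$target[i] &
      spikes$time >= protocol$on[i] & spikes$time < protocol$off[i]
    if (!any(sel)) next
    drop <- sel & (stats::runif(nrow(spikes)) >= protocol$factor[i])
    keep <- keep & !drop
  }
  spikes <- spikes[keep, , drop = FALSE]
  gt$bursts <- bursts
  gt$spikes <- spikes
  gt$epochs <- protocol
  trains <- list()
  for (m in config@modules)
    trains <- c(trains, .assemble_trains(m, spikes, config@duration))
  plan$session <- RecordingSession(trains)
  plan$groundTruth <- gt
  plan$protocol <- protocol
  plan
}

#' Generate a complete synthetic session
#'
#' Runs the full burst cascade over all modules and couplings, adds
#' background spikes, optionally applies a suppression protocol and injects
#' evoked responses to electrical-stimulation trials, and returns the spike
#' trains together with the module map and the generator's ground truth.
#' Identical \code{config} and \code{seed} reproduce the session exactly.
#'
#' @param config a [SimConfig-class].
#' @param seed integer seed fixing all randomness.
#' @param protocol optional suppression protocol (see [readProtocol()] and
#'   [buildSuppressionProtocol()]).
#' @param stimTimes optional vector of electrical-stimulation times (s);
#'   evoked responses follow \code{config@stimResponse}.
#' @return list with \code{session} ([RecordingSession-class]), \code{map}
#'   ([ModuleMap-class]), \code{protocol} (or NULL), \code{stimTimes}, and
#'   \code{groundTruth}: \code{bursts} (provenance table), \code{spikes}
#'   (per-spike category and burst id), \code{epochs}, \code{evoked}, and
#'   \code{electrodeModule}.
#' @export
generateSession <- function(config, seed, protocol = NULL, stimTimes = NULL) {
  validObject(config)
  set.seed(seed)
  dur <- config@duration
  bursts <- .burst_cascade(config)
  spike_recs <- list()
  for (m in config@modules) {
    mb <- bursts[bursts$module == m$label, , drop = FALSE]
    sp <- .burst_spikes(m, mb$onset, dur, burst_ids = mb$id)
    spike_recs[[length(spike_recs) + 1L]] <- sp
    spike_recs[[length(spike_recs) + 1L]] <- .background_spikes(m, dur)
  }
  evoked <- data.frame(stim = numeric(), module = character(),
                       delay = numeric(), responded = logical())
  if (!is.null(stimTimes) && length(config@stimResponse)) {
    stimTimes <- sort(stimTimes)
    for (resp in config@stimResponse) {
      m <- .find_module(config, resp$module)
      hits <- stats::runif(length(stimTimes)) < resp$probability
      delays <- rep(NA_real_, length(stimTimes))
      delays[hits] <- .rtrunc_norm_pos(sum(hits), resp$delayMean,
                                       resp$delaySd)
      evoked <- rbind(evoked, data.frame(stim = stimTimes,
                                         module = resp$module,
                                         delay = delays, responded = hits))
      if (any(hits)) {
        els <- .module_electrodes(m)
        base_t <- stimTimes[hits] + delays[hits]
        for (id in els) {
          tt <- base_t + stats::rnorm(length(base_t), 0, resp$jitterSd)
          tt <- tt[tt > 0 & tt < dur]
          spike_recs[[length(spike_recs) + 1L]] <-
            data.frame(electrode = rep(id, length(tt)), time = tt,
                       burst = rep(NA_integer_, length(tt)),
                       category = rep("evoked", length(tt)))
        }
      }
    }
  }
  spikes <- do.call(rbind, lapply(spike_recs, function(d) {
    if (is.null(d) || !nrow(d)) return(NULL)
    if (is.null(d$category))
      d$category <- ifelse(is.na(d$burst), "background", "burst")
    d
  }))
  if (is.null(spikes))
    spikes <- data.frame(electrode = character(), time = numeric(),
                         burst = integer(), category = character())
  bursts$end <- bursts$onset +
    vapply(bursts$module, function(l) .find_module(config, l)$burstDuration,
           numeric(1L))
  bursts$suppressed <- rep(FALSE, nrow(bursts))
  el_mod <- unlist(lapply(config@modules, function(m)
    stats::setNames(rep(m$label, m$nElectrodes), .module_electrodes(m))))
  gt <- list(bursts = bursts, spikes = spikes,
             epochs = NULL, evoked = evoked, electrodeModule = el_mod)
  trains <- list()
  for (m in config@modules)
    trains <- c(trains, .assemble_trains(m, spikes, dur))
  plan <- list(session = RecordingSession(trains),
               map = simModuleMap(config),
               protocol = NULL, stimTimes = stimTimes, groundTruth = gt)
  if (!is.null(protocol) && nrow(protocol))
    plan <- applySuppression(plan, protocol, config, seed = seed + 1L)
  plan
}

#' Build a blocked suppression protocol
#'
#' One trial occupies three equal windows: baseline, illumination, recovery.
#' Trials are laid out back to back, blocked by power density in the given
#' order.
#'
#' @param target module to suppress.
#' @param powers power-density levels (must exist in the config's
#'   suppression table when the protocol is applied).
#' @param nTrials trials per power level (default 5).
#' @param stimDuration illumination window length in seconds (default 30).
#' @param start time of the first trial's baseline window (default 0).
#' @return protocol data.frame (\code{target}, \code{power}, \code{on},
#'   \code{off}, \code{trial}).
#' @export
buildSuppressionProtocol <- function(target, powers, nTrials = 5,
                                     stimDuration = 30, start = 0) {
  k <- 0L
  rows <- list()
  for (p in powers) {
    for (tr in seq_len(nTrials)) {
      t0 <- start + k * 3 * stimDuration
      rows[[length(rows) + 1L]] <- data.frame(
        target = target, power = p, on = t0 + stimDuration,
        off = t0 + 2 * stimDuration, trial = tr)
      k <- k + 1L
    }
  }
  do.call(rbind, rows)
}

#' Default biphasic spike waveform template
#'
#' Negative-leading biphasic waveform of 1 ms total duration: a negative
#' half-sine lobe (60% of the duration, peak \code{-amplitude}) followed by a
#' smaller positive half-sine lobe (40%, peak \code{0.35 * amplitude}).
#'
#' @param samplingRate sampling rate in Hz.
#' @param amplitude peak magnitude of the negative lobe (microvolts).
#' @param durationS total template duration in seconds (default 0.001).
#' @return numeric vector of template samples.
#' @export
spikeTemplate <- function(samplingRate, amplitude, durationS = 0.001) {
  n <- max(2L, round(samplingRate * durationS))
  n_neg <- max(1L, round(0.6 * n))
  n_pos <- n - n_neg
  neg <- -amplitude * sin(pi * seq_len(n_neg) / (n_neg + 1))
  pos <- if (n_pos > 0) 0.35 * amplitude * sin(pi * seq_len(n_pos) /
                                                 (n_pos + 1)) else numeric()
  c(neg, pos)
}

#' Render noisy voltage traces from spike trains
#'
#' Gaussian background noise plus a spike waveform template inserted at every
#' spike time, one channel per train. Spikes closer together than the
#' template length superimpose additively (allowed; the overlap count is
#' reported). The injected spike times per channel are exported so detection
#' performance can be scored against ground truth.
#'
#' @param session a [RecordingSession-class] (or list of trains) supplying
#'   injection times.
#' @param samplingRate sampling rate in Hz (default 25000).
#' @param noiseSd Gaussian noise SD in microvolts (default 10).
#' @param amplitudeSD template peak amplitude in units of the noise SD
#'   (default 10).
#' @param template custom waveform (default [spikeTemplate()]).
#' @param seed integer seed.
#' @return list with \code{traces} (a [TraceBlock-class]), \code{injections}
#'   (named list of spike-time vectors) and \code{n_overlaps}.
#' @export
renderNoiseTraces <- function(session, samplingRate = 25000, noiseSd = 10,
                              amplitudeSD = 10, template = NULL, seed = 1) {
  set.seed(seed)
  if (is(session, "RecordingSession")) trains <- session@trains else
    trains <- session
  if (is.null(template))
    template <- spikeTemplate(samplingRate, amplitudeSD * noiseSd)
  dur <- trains[[1L]]@tStop - trains[[1L]]@tStart
  n <- round(dur * samplingRate)
  L <- length(template)
  overlaps <- 0L
  mats <- lapply(trains, function(tr) {
    x <- stats::rnorm(n, 0, noiseSd)
    idx <- round((tr@times - tr@tStart) * samplingRate) + 1L
    if (length(idx) > 1L)
      overlaps <<- overlaps + sum(diff(idx) < L)
    for (i in idx) {
      j <- i:min(i + L - 1L, n)
      x[j] <- x[j] + template[seq_along(j)]
    }
    x
  })
  traces <- TraceBlock(do.call(rbind, mats), samplingRate,
                       channelIds = vapply(trains, function(t) t@electrodeId,
                                           character(1L)))
  list(traces = traces,
       injections = lapply(trains, function(t) t@times),
       n_overlaps = overlaps)
}

## ---- preset study configurations -------------------------------------------

#' Two bursting modules with adjustable one-way coupling
#'
#' Two four-electrode modules plus a two-electrode unconnected control
#' network. Module \code{N1} drives \code{N2} with probability \code{p};
#' \code{p = 0} gives fully independent modules. Used for null and
#' coupling-strength studies of the correlation analysis.
#'
#' @param p coupling probability \code{N1 -> N2}.
#' @param duration session length (s), default 600.
#' @param burstRate intrinsic burst rate per module, events/min (default 10).
#' @param active optional active window for the coupling (see
#'   [simCoupling()]).
#' @return a [SimConfig-class].
#' @export
presetCoupledPair <- function(p, duration = 600, burstRate = 10,
                              active = NULL) {
  simConfig(
    modules = list(
      simModule("N1", burstRate = burstRate),
      simModule("N2", burstRate = burstRate),
      simModule("C1", nElectrodes = 2, burstRate = burstRate,
                control = TRUE)),
    couplings = if (p > 0)
      list(simCoupling("N1", "N2", p = p, active = active)) else list(),
    duration = duration)
}

#' Asymmetrically dependent module pair for influence studies
#'
#' Module \code{N1} has no intrinsic bursts: its activity is entirely driven
#' by \code{N2} (coupling probability 1). \code{N2} is driven back by
#' \code{N1} with probability 0.6, so in the stationary cascade 60% of its
#' bursts trace back to \code{N1} and 40% are intrinsic. Suppressing
#' \code{N2} should therefore silence \code{N1} (influence near 100%), while
#' suppressing \code{N1} should remove about 60% of \code{N2}'s activity.
#' Both modules burst at 40 events/min, the regime of a strongly
#' synchronized mature culture, which keeps the per-trial burst-count noise
#' in suppression windows small. A three-electrode unconnected control
#' network with the same bursting statistics is included, and the
#' suppression table maps the highest power to complete suppression.
#'
#' @param duration session length (s); the default 1850 accommodates a
#'   two-power, five-trial protocol of 60 s windows, comparable to a 30 min
#'   recording.
#' @param drivenFractionTarget driven fraction of the reciprocally driven
#'   module (default 0.6).
#' @return a [SimConfig-class].
#' @export
presetAsymmetricPair <- function(duration = 1850,
                                 drivenFractionTarget = 0.6) {
  d <- drivenFractionTarget
  simConfig(
    modules = list(
      simModule("N1", burstRate = 40, drivenFraction = 1),
      simModule("N2", burstRate = 40, drivenFraction = d),
      simModule("C1", nElectrodes = 3, burstRate = 40, control = TRUE)),
    couplings = list(
      simCoupling("N2", "N1", p = 1),
      simCoupling("N1", "N2", p = d)),
    duration = duration,
    suppression = data.frame(power = c(60, 243), factor = c(0.5, 0)))
}
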