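## Firing-rate change under targeted suppression epochs, suppression curves
## against illumination power density, the network-to-network influence
## statistic, and exact Mann-Whitney testing against control electrodes.
##
## The influence of module A on module B, I[A->B], is the magnitude of B's
## baseline firing-rate change (percent) at the power level that fully
## suppresses A; it is reported only when A's own suppression reaches the
## full-suppression criterion (>= 90% rate reduction by default).

.window_rate <- function(session, electrodes, a, b) {
  n <- sum(vapply(electrodes, function(id) {
    ts <- session@trains[[id]]@times
    sum(ts >= a & ts < b)
  }, numeric(1L)))
  n / (b - a)
}

#' Firing-rate change for one modulation epoch
#'
#' Computes pooled firing rates per module (member electrodes' spikes pooled,
#' counts over window length) in the baseline, stimulation and recovery
#' windows of one epoch, and the percent change
#' \code{100 * (during - baseline) / baseline}. The baseline window
#' immediately precedes the stimulation window and defaults to the same
#' duration; the recovery window follows it. A zero baseline rate leaves the
#' change undefined (NA).
#'
#' @param session a [RecordingSession-class].
#' @param epoch one epoch: a list or one-row data.frame with \code{on},
#'   \code{off} (s) and optionally \code{target}, \code{power}, \code{trial}.
#' @param map a [ModuleMap-class]; control electrodes form their own group
#'   under the control label.
#' @param electrodes restrict to these electrodes (default: all mapped ones).
#' @param baselineDuration,recoveryDuration window lengths in seconds
#'   (default: the stimulation window's length).
#' @return list with data.frames \code{perModule} and \code{perElectrode},
#'   each with baseline/during/recovery rates (Hz) and \code{pct_change}.
#' @export
rateChange <- function(session, epoch, map, electrodes = NULL,
                       baselineDuration = NULL, recoveryDuration = NULL) {
  on <- epoch$on
  off <- epoch$off
  if (is.null(on) || is.null(off) || off <= on)
    stop("epoch must provide on < off")
  stim_len <- off - on
  bl <- baselineDuration %||% stim_len
  rl <- recoveryDuration %||% stim_len
  if (on - bl < tStart(session) || off + rl > tStop(session))
    stop("epoch windows fall outside the recording")
  if (is.null(electrodes)) electrodes <- names(map@assignment)
  electrodes <- intersect(electrodes, electrodeIds(session))
  mod <- unname(map@assignment[electrodes])
  groups <- split(electrodes, mod)
  per_group <- function(ids) {
    c(baseline = .window_rate(session, ids, on - bl, on),
      during = .window_rate(session, ids, on, off),
      recovery = .window_rate(session, ids, off, off + rl))
  }
  gm <- t(vapply(groups, per_group, numeric(3L)))
  em <- t(vapply(stats::setNames(electrodes, electrodes),
                 function(id) per_group(id), numeric(3L)))
  pct <- function(m) ifelse(m[, "baseline"] > 0,
                            100 * (m[, "during"] - m[, "baseline"]) /
                              m[, "baseline"], NA_real_)
  perModule <- data.frame(module = rownames(gm),
                          baseline_hz = gm[, "baseline"],
                          during_hz = gm[, "during"],
                          recovery_hz = gm[, "recovery"],
                          pct_change = pct(gm), row.names = NULL)
  perElectrode <- data.frame(electrode_id = rownames(em),
                             module = unname(map@assignment[rownames(em)]),
                             baseline_hz = em[, "baseline"],
                             during_hz = em[, "during"],
                             recovery_hz = em[, "recovery"],
                             pct_change = pct(em), row.names = NULL)
  list(perModule = perModule, perElectrode = perElectrode)
}

#' Suppression curve: rate change against power density
#'
#' Runs [rateChange()] for every epoch of a protocol and summarizes the
#' per-module percent change by (observed module, power density) as mean and
#' SD over trials. Control electrodes appear as their own group.
#'
#' @param session a [RecordingSession-class].
#' @param protocol protocol data.frame (see [readProtocol()]); all epochs are
#'   expected to target the same module when the curve feeds [influence()].
#' @param map a [ModuleMap-class].
#' @param baselineDuration baseline window length (default: stim length).
#' @return data.frame with columns \code{module}, \code{power},
#'   \code{mean_change}, \code{sd_change}, \code{n_trials},
#'   \code{mean_recovery_change}; plus attribute \code{"trials"} holding the
#'   per-trial module table.
#' @export
suppressionCurve <- function(session, protocol, map, baselineDuration = NULL) {
  if (!nrow(protocol)) stop("empty protocol")
  rows <- lapply(seq_len(nrow(protocol)), function(i) {
    rc <- rateChange(session, protocol[i, ], map,
                     baselineDuration = baselineDuration)$perModule
    rc$power <- protocol$power[i]
    rc$trial <- protocol$trial[i]
    rc$target <- protocol$target[i]
    rc$recovery_change <- ifelse(rc$baseline_hz > 0,
                                 100 * (rc$recovery_hz - rc$baseline_hz) /
                                   rc$baseline_hz, NA_real_)
    rc
  })
  trials <- do.call(rbind, rows)
  key <- interaction(trials$module, trials$power, drop = TRUE)
  agg <- lapply(split(trials, key), function(d) {
    ok <- !is.na(d$pct_change)
    data.frame(module = d$module[1L], power = d$power[1L],
               mean_change = if (any(ok)) mean(d$pct_change[ok]) else NA_real_,
               sd_change = if (sum(ok) > 1L) stats::sd(d$pct_change[ok]) else
                 NA_real_,
               n_trials = sum(ok),
               mean_recovery_change =
                 if (any(!is.na(d$recovery_change)))
                   mean(d$recovery_change, na.rm = TRUE) else NA_real_)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$module, out$power), ]
  rownames(out) <- NULL
  attr(out, "trials") <- trials
  out
}

#' Network-to-network influence from a suppression experiment
#'
#' \code{I[source->target]} is the magnitude of the target module's mean
#' percent rate change at the source's maximum-suppression power level
#' (the highest power in the curve). It is defined only when the source
#' itself reaches the full-suppression criterion there (mean change at or
#' below \code{-fullSuppression} percent); otherwise the achieved suppression
#' is reported and the value is NA.
#'
#' @param curve output of [suppressionCurve()] for a protocol targeting
#'   \code{source}.
#' @param source,target module labels.
#' @param fullSuppression criterion in percent (default 90).
#' @return list with \code{source}, \code{target}, \code{value} (percent
#'   magnitude, NA when undefined), \code{signed_change} (the target's signed
#'   mean change), \code{achieved_suppression} (the source's mean change at
#'   max power), \code{power} and \code{defined}.
#' @export
influence <- function(curve, source, target, fullSuppression = 90) {
  pmax_ <- max(curve$power)
  src <- curve[curve$module == source & curve$power == pmax_, ]
  tgt <- curve[curve$module == target & curve$power == pmax_, ]
  if (!nrow(src) || !nrow(tgt))
    stop("source or target module missing from the curve")
  achieved <- src$mean_change[1L]
  defined <- is.finite(achieved) && achieved <= -fullSuppression
  signed <- tgt$mean_change[1L]
  list(source = source, target = target,
       value = if (defined) abs(signed) else NA_real_,
       signed_change = signed,
       achieved_suppression = achieved,
       power = pmax_, defined = defined)
}

#' Exact two-sided Mann-Whitney test
#'
#' Exact two-sided Mann-Whitney U p-value by exhaustive enumeration of all
#' \code{choose(n1 + n2, n1)} assignments of the (mid-)ranks to the first
#' group, doubling the smaller tail (capped at 1). Ties are handled by
#' mid-ranks in both the observed statistic and the enumerated null. For
#' larger samples (total > \code{exactLimit}) the normal approximation with
#' tie correction is used instead.
#'
#' Under complete separation with five observations per group the exact
#' p-value is 2/252, about 0.0079 -- the smallest attainable at this sample
#' size, and the resolution limit of any significance statement there.
#'
#' @param x,y numeric samples (at least 3 observations each).
#' @param exactLimit largest total sample size for exhaustive enumeration
#'   (default 20).
#' @return list with \code{statistic} (U for the first sample), \code{p.value}
#'   and \code{method}.
#' @export
mannWhitneyExact <- function(x, y, exactLimit = 20) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 3L || n2 < 3L) stop("need at least 3 observations per group")
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exactLimit) {
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_lo <- mean(u_all <= u_obs + eps)
    p_hi <- mean(u_all >= u_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    if (sig2 <= 0) return(list(statistic = u_obs, p.value = 1,
                               method = "normal approximation"))
    z <- (u_obs - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = u_obs, p.value = p, method = method)
}
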