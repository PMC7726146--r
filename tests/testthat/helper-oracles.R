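## Independent brute-force reference implementations used to cross-check the
## package's vectorized/sweep-based algorithms on small randomized instances.
## These deliberately use the most literal O(n^2)-style formulation.

## maximal runs of spikes with consecutive gaps <= isi, at least min_spikes
oracle_bursts <- function(times, isi, min_spikes) {
  out <- list()
  i <- 1L
  n <- length(times)
  while (i <= n) {
    j <- i
    while (j < n && times[j + 1L] - times[j] <= isi) j <- j + 1L
    if (j - i + 1L >= min_spikes)
      out[[length(out) + 1L]] <- c(start = times[i], end = times[j],
                                   n = j - i + 1L)
    i <- j + 1L
  }
  if (!length(out)) return(data.frame(start = numeric(), end = numeric(),
                                      n = numeric()))
  as.data.frame(do.call(rbind, out))
}

## connected components of the pairwise closed-interval overlap graph,
## keeping components that span >= 2 electrodes
oracle_sbes <- function(bursts) {
  n <- nrow(bursts)
  if (!n) return(data.frame(start = numeric(), end = numeric()))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- bursts$start[i] <= bursts$end[j] &&
      bursts$start[j] <= bursts$end[i]
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  recs <- list()
  for (k in unique(comp)) {
    idx <- which(comp == k)
    if (length(unique(bursts$electrode_id[idx])) < 2L) next
    recs[[length(recs) + 1L]] <- data.frame(
      start = min(bursts$start[idx]), end = max(bursts$end[idx]),
      n_electrodes = length(unique(bursts$electrode_id[idx])))
  }
  if (!length(recs)) return(data.frame(start = numeric(), end = numeric(),
                                       n_electrodes = integer()))
  out <- do.call(rbind, recs)
  out[order(out$start), , drop = FALSE]
}

## fraction of spikes inside any closed window
oracle_assoc <- function(times, starts, ends) {
  if (!length(times)) return(NA_real_)
  hits <- 0L
  for (t in times) {
    inside <- FALSE
    for (k in seq_along(starts))
      if (t >= starts[k] && t <= ends[k]) inside <- TRUE
    hits <- hits + inside
  }
  hits / length(times)
}

## per-module first-spike ordering within a closed window
oracle_propagation <- function(trains, members_by_module, start, end) {
  ft <- sapply(names(members_by_module), function(m) {
    best <- Inf
    for (id in members_by_module[[m]]) {
      ts <- trains[[id]]@times
      ts <- ts[ts >= start & ts <= end]
      if (length(ts)) best <- min(best, min(ts))
    }
    best
  })
  ft <- ft[is.finite(ft)]
  paste(names(sort(ft)), collapse = "->")
}

## percent rate change by direct window counting over pooled electrodes
oracle_rate_change <- function(trains, ids, on, off, bl) {
  count <- function(a, b) sum(sapply(ids, function(id) {
    ts <- trains[[id]]@times
    sum(ts >= a & ts < b)
  }))
  rb <- count(on - bl, on) / bl
  rd <- count(on, off) / (off - on)
  if (rb == 0) return(NA_real_)
  100 * (rd - rb) / rb
}

## PSTH counts by explicit per-trial window scan
oracle_psth <- function(times, stims, bin, window) {
  nb <- floor(window / bin + 1e-9)
  counts <- numeric(nb)
  for (s in stims) for (t in times) {
    dt <- t - s
    if (dt >= 0 && dt < nb * bin) {
      b <- floor(dt / bin) + 1L
      counts[b] <- counts[b] + 1
    }
  }
  counts
}

## exact two-sided Mann-Whitney p by enumerating group assignments and
## counting exceedance pairs directly (no rank-sum shortcut)
oracle_mw <- function(x, y) {
  u_of <- function(a, b) {
    u <- 0
    for (xi in a) for (yj in b) {
      if (xi > yj) u <- u + 1
      else if (xi == yj) u <- u + 0.5
    }
    u
  }
  pool <- c(x, y)
  n1 <- length(x)
  u_obs <- u_of(x, y)
  sets <- utils::combn(length(pool), n1)
  us <- apply(sets, 2L, function(idx) u_of(pool[idx], pool[-idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

## ---- random fixture builders ----------------------------------------------

random_train <- function(id = "ch1", n = 20, t_stop = 10) {
  SpikeTrain(id, sort(runif(n, 0, t_stop - 1e-6)), 0, t_stop)
}

random_session <- function(n_electrodes = 4, n = 30, t_stop = 10,
                           prefix = "ch") {
  RecordingSession(lapply(seq_len(n_electrodes), function(i)
    random_train(paste0(prefix, i), n = rpois(1, n), t_stop = t_stop)))
}

random_bursts <- function(n_bursts = 12, n_electrodes = 3, t_stop = 10) {
  starts <- runif(n_bursts, 0, t_stop)
  data.frame(electrode_id = sample(paste0("ch", seq_len(n_electrodes)),
                                   n_bursts, replace = TRUE),
             start = starts, end = starts + runif(n_bursts, 0.05, 0.6),
             n_spikes = rpois(n_bursts, 5) + 3L)
}
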