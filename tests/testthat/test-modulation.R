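make_epoch_session <- function(rates_by_window, dur = 90) {
  ## piecewise-constant regular trains: baseline [0,30), stim [30,60),
  ## recovery [60,90)
  mk <- function(id, r) {
    ts <- c()
    bounds <- c(0, 30, 60, 90)
    for (k in 1:3) {
      n <- round(r[k] * 30)
      if (n > 0) ts <- c(ts, seq(bounds[k], bounds[k + 1],
                                 length.out = n + 1)[-(n + 1)])
    }
    SpikeTrain(id, ts + 1e-4, 0, dur)
  }
  RecordingSession(mapply(mk, names(rates_by_window), rates_by_window,
                          SIMPLIFY = FALSE))
}

test_that("rate change computes pooled percent change per module", {
  map <- ModuleMap(list(N1 = c("a", "b"), N2 = "c"))
  ep <- list(on = 30, off = 60)
  ## identical baseline and stim rates -> 0%
  s <- make_epoch_session(list(a = c(5, 5, 5), b = c(5, 5, 5),
                               c = c(4, 4, 4)))
  rc <- rateChange(s, ep, map)
  expect_equal(rc$perModule$pct_change, c(0, 0), tolerance = 1e-6)
  ## full suppression -> -100%
  s2 <- make_epoch_session(list(a = c(5, 0, 5), b = c(5, 0, 5),
                                c = c(4, 4, 4)))
  rc2 <- rateChange(s2, ep, map)
  expect_equal(rc2$perModule$pct_change[rc2$perModule$module == "N1"], -100)
  expect_equal(rc2$perModule$pct_change[rc2$perModule$module == "N2"], 0,
               tolerance = 1e-6)
  ## zero baseline flagged undefined
  s3 <- make_epoch_session(list(a = c(0, 5, 0), b = c(0, 0, 0),
                                c = c(4, 4, 4)))
  rc3 <- rateChange(s3, ep, map)
  expect_true(is.na(rc3$perModule$pct_change[rc3$perModule$module == "N1"]))
  ## windows outside the recording are rejected
  expect_error(rateChange(s, list(on = 10, off = 60), map), "outside")
  ## randomized equivalence with direct window counting
  set.seed(17)
  for (rep in 1:50) {
    s <- random_session(n_electrodes = 3, n = 80, t_stop = 90)
    names(s@trains) <- c("a", "b", "c")
    for (i in 1:3) s@trains[[i]]@electrodeId <- c("a", "b", "c")[i]
    rc <- rateChange(s, ep, map)
    ref <- oracle_rate_change(s@trains, c("a", "b"), 30, 60, 30)
    got <- rc$perModule$pct_change[rc$perModule$module == "N1"]
    if (is.na(ref)) expect_true(is.na(got)) else expect_equal(got, ref)
  }
})

test_that("influence is invariant to uniform rate scaling", {
  map <- ModuleMap(list(N1 = c("a", "b"), N2 = "c"))
  ep <- list(on = 30, off = 60)
  s <- make_epoch_session(list(a = c(6, 2, 6), b = c(6, 2, 6),
                               c = c(4, 2, 4)))
  s2 <- make_epoch_session(list(a = 2 * c(6, 2, 6), b = 2 * c(6, 2, 6),
                                c = 2 * c(4, 2, 4)))
  rc <- rateChange(s, ep, map)$perModule
  rc2 <- rateChange(s2, ep, map)$perModule
  expect_equal(rc$pct_change, rc2$pct_change, tolerance = 1e-6)
})

test_that("suppression curves aggregate trials and feed the influence statistic", {
  map <- ModuleMap(list(N1 = c("a", "b"), N2 = "c"))
  ## five identical trials of -50% in N1
  mk <- function(seg) {
    ts <- c()
    for (k in seq_along(seg))
      if (seg[k] > 0)
        ts <- c(ts, seq((k - 1) * 30, k * 30,
                        length.out = seg[k] * 30 + 1)[-(seg[k] * 30 + 1)])
    ts + 1e-4
  }
  segs_a <- c(rbind(rep(8, 5), rep(4, 5), rep(8, 5)))  # b,s,r per trial
  s <- RecordingSession(list(
    SpikeTrain("a", mk(segs_a), 0, 450),
    SpikeTrain("b", mk(segs_a), 0, 450),
    SpikeTrain("c", mk(rep(6, 15)), 0, 450)))
  prot <- data.frame(target = "N1", power = 100,
                     on = (0:4) * 90 + 30, off = (0:4) * 90 + 60,
                     trial = 1:5)
  curve <- suppressionCurve(s, prot, map)
  n1 <- curve[curve$module == "N1", ]
  expect_equal(n1$mean_change, -50, tolerance = 1e-6)
  expect_equal(n1$sd_change, 0, tolerance = 1e-6)
  expect_equal(n1$n_trials, 5L)
  ## influence: target changed -62% at full source suppression -> I = 62
  curve2 <- data.frame(module = c("N1", "N2", "N1", "N2"),
                       power = c(30, 30, 243, 243),
                       mean_change = c(-40, -20, -97, -62),
                       sd_change = 1, n_trials = 5L,
                       mean_recovery_change = 0)
  i <- influence(curve2, "N1", "N2")
  expect_true(i$defined)
  expect_equal(i$value, 62)
  ## unmet criterion leaves the influence undefined but reports suppression
  curve3 <- curve2
  curve3$mean_change[3L] <- -70
  i3 <- influence(curve3, "N1", "N2")
  expect_false(i3$defined)
  expect_true(is.na(i3$value))
  expect_equal(i3$achieved_suppression, -70)
  ## unchanged target -> influence 0
  curve4 <- curve2
  curve4$mean_change[4L] <- 0
  expect_equal(influence(curve4, "N1", "N2")$value, 0)
})

test_that("exact Mann-Whitney matches enumeration, wilcox.test and the null", {
  ## complete separation at n = 5 per group: p = 2/252
  x <- 1:5
  y <- 6:10
  mw <- mannWhitneyExact(x, y)
  expect_equal(mw$p.value, 2 / 252)
  expect_equal(mw$statistic, 0)
  ## identical samples: p = 1
  expect_equal(mannWhitneyExact(rep(1, 5), rep(1, 5))$p.value, 1)
  expect_error(mannWhitneyExact(1:2, 1:5), "at least 3")
  ## equivalence with the pair-counting enumeration oracle for n1, n2 <= 6
  set.seed(18)
  for (rep in 1:40) {
    n1 <- sample(3:6, 1L)
    n2 <- sample(3:6, 1L)
    x <- round(rnorm(n1), 1)  # rounding induces occasional ties
    y <- round(rnorm(n2, 0.5), 1)
    expect_equal(mannWhitneyExact(x, y)$p.value, oracle_mw(x, y))
  }
  ## agreement with wilcox.test exact p for tie-free samples
  for (rep in 1:20) {
    x <- rnorm(5)
    y <- rnorm(5)
    expect_equal(mannWhitneyExact(x, y)$p.value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  ## type-I error at alpha = 0.01 stays within [0, 0.03] under the null
  set.seed(19)
  rej <- mean(replicate(1000, {
    mannWhitneyExact(rnorm(5), rnorm(5))$p.value < 0.01
  }))
  expect_lte(rej, 0.03)
})
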