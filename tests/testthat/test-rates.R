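test_that("binned rates use half-open bins and count/width normalization", {
  ## 10 spikes placed one per 100 ms bin -> each bin 10 Hz
  tr <- SpikeTrain("ch1", seq(0.05, 0.95, by = 0.1), 0, 1)
  h <- binRates(tr, 0.1)
  expect_equal(h@rates, rep(10, 10))
  ## empty train -> all-zero histogram
  h0 <- binRates(SpikeTrain("ch1", numeric(), 0, 1), 0.1)
  expect_equal(h0@rates, rep(0, 10))
  ## spike exactly on a bin edge belongs to the right-hand bin
  hb <- binRates(SpikeTrain("ch1", 0.1, 0, 1), 0.1)
  expect_equal(which(hb@rates > 0), 2L)
  expect_error(binRates(tr, 2), "duration")
  ## randomized equivalence with explicit interval counting
  set.seed(6)
  for (rep in 1:30) {
    tr <- random_train(n = 50, t_stop = 8)
    bw <- sample(c(0.1, 0.2, 0.5), 1L)
    h <- binRates(tr, bw)
    nb <- floor(8 / bw)
    brute <- vapply(seq_len(nb), function(i)
      sum(tr@times >= (i - 1) * bw & tr@times < i * bw), numeric(1L))
    expect_equal(h@rates, brute / bw)
    expect_equal(sum(h@rates) * bw, length(tr@times))
  }
})

test_that("Gaussian smoothing matches naive convolution and conserves counts", {
  tr <- SpikeTrain("ch1", seq(0.05, 9.95, by = 0.1), 0, 10)
  h <- binRates(tr, 0.1)
  ## kernel_bins = 1 is the identity
  expect_equal(smoothRates(h, 1)@rates, h@rates)
  expect_error(smoothRates(h, 4), "odd")
  ## a single spike in a central bin spreads into a symmetric 5-bin bump
  h1 <- binRates(SpikeTrain("ch1", 0.55, 0, 1), 0.1)
  s1 <- smoothRates(h1, 5)
  expect_equal(sum(s1@rates) * 0.1, 1)
  expect_equal(s1@rates[5], s1@rates[7])
  expect_equal(s1@rates[4], s1@rates[8])
  expect_gt(s1@rates[6], s1@rates[5])
  ## interior bins equal direct convolution with the explicit kernel
  set.seed(7)
  for (rep in 1:20) {
    x <- rpois(40, 3) / 0.1
    h <- new("RateHistogram", electrodeId = "ch1", binWidth = 0.1,
             rates = x, tStart = 0, smoothed = FALSE, kernelBins = 0L)
    sm <- smoothRates(h, 5)
    k <- gaussianKernel(5)
    ## bins whose whole kernel support is clear of the edge renormalization
    conv <- vapply(5:36, function(i) sum(x[(i - 2):(i + 2)] * k),
                   numeric(1L))
    expect_equal(sm@rates[5:36], conv, tolerance = 1e-12)
    ## count conservation under the renormalized edge policy
    expect_equal(sum(sm@rates), sum(x), tolerance = 1e-9)
  }
})

test_that("active-electrode filter is strictly greater than 0.05 Hz", {
  dur <- 600
  s <- RecordingSession(list(
    SpikeTrain("at_thr", seq_len(30) * 19.9, 0, dur),   # exactly 0.05 Hz
    SpikeTrain("above", seq_len(31) * 19.0, 0, dur),    # 31/600 Hz
    SpikeTrain("silent", numeric(), 0, dur)))
  expect_equal(activeFilter(s), "above")
})

test_that("Pearson matrices behave on exact and null cases", {
  mk <- function(x) new("RateHistogram", electrodeId = "h", binWidth = 0.1,
                        rates = x, tStart = 0, smoothed = FALSE,
                        kernelBins = 0L)
  a <- mk(c(1, 0, 1, 0))
  a@electrodeId <- "a"
  b <- mk(c(0, 1, 0, 1))
  b@electrodeId <- "b"
  m <- pearsonMatrix(list(a, b))
  expect_equal(m["a", "a"], 1)
  expect_equal(m["a", "b"], -1)
  expect_true(isSymmetric(m))
  ## zero-variance channel yields NA, not zero
  z <- mk(rep(2, 4))
  z@electrodeId <- "z"
  mz <- pearsonMatrix(list(a, z))
  expect_true(is.na(mz["a", "z"]))
  ## mismatched grids are rejected
  expect_error(pearsonMatrix(list(a, mk(c(1, 0, 1)))), "grid")
  ## two independent Poisson trains decorrelate
  set.seed(8)
  s <- RecordingSession(list(
    SpikeTrain("p1", sort(runif(2000, 0, 1000 - 1e-9)), 0, 1000),
    SpikeTrain("p2", sort(runif(2000, 0, 1000 - 1e-9)), 0, 1000)))
  mcc <- pearsonMatrix(sessionRates(s, binWidth = 0.1, smooth = TRUE))
  expect_lt(abs(mcc["p1", "p2"]), 0.1)
})

test_that("ccSummary means match explicit pair enumeration", {
  map <- ModuleMap(list(N1 = c("a", "b"), N2 = c("c", "d"), CTRL = "e"))
  ## constant matrix
  ids <- c("a", "b", "c", "d")
  m <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  diag(m) <- 1
  sm <- ccSummary(m, map)
  expect_equal(sm@intraOverall, 0.5)
  expect_equal(sm@interOverall, 0.5)
  ## block matrix: within 0.8, between 0
  m2 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  m2[1, 2] <- m2[2, 1] <- m2[3, 4] <- m2[4, 3] <- 0.8
  diag(m2) <- 1
  sm2 <- ccSummary(m2, map)
  expect_equal(sm2@intraOverall, 0.8)
  expect_equal(sm2@interOverall, 0)
  expect_equal(unname(sm2@intraModule[c("N1", "N2")]), c(0.8, 0.8))
  ## random symmetric matrices against brute-force loops, incl. control
  set.seed(9)
  ids5 <- c("a", "b", "c", "d", "e")
  for (rep in 1:20) {
    r <- matrix(runif(25, -1, 1), 5, 5, dimnames = list(ids5, ids5))
    r <- (r + t(r)) / 2
    diag(r) <- 1
    sm <- ccSummary(r, map)
    mods <- c(a = "N1", b = "N1", c = "N2", d = "N2", e = "CTRL")
    intra <- c()
    inter <- c()
    ctrl <- c()
    for (i in 1:4) for (j in (i + 1):5) {
      v <- r[ids5[i], ids5[j]]
      mi <- mods[ids5[i]]
      mj <- mods[ids5[j]]
      if (mi == "CTRL" || mj == "CTRL") ctrl <- c(ctrl, v)
      else if (mi == mj) intra <- c(intra, v)
      else inter <- c(inter, v)
    }
    expect_equal(sm@intraOverall, mean(intra))
    expect_equal(sm@interOverall, mean(inter))
    expect_equal(sm@control, mean(ctrl))
  }
  ## a module with a single active electrode is flagged
  m3 <- m[c("a", "c", "d"), c("a", "c", "d")]
  sm3 <- ccSummary(m3, map)
  expect_true("N1" %in% sm3@flagged)
  expect_true(is.na(sm3@intraModule[["N1"]]))
})
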