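test_that("burst detection groups spikes by the inter-spike threshold", {
  tr <- SpikeTrain("ch1", c(0, 0.1, 0.2, 1.0, 1.05, 1.1), 0, 2)
  b <- detectBursts(tr, 0.2, minSpikes = 3)
  expect_equal(nrow(b), 2L)
  expect_equal(b$start, c(0, 1.0))
  expect_equal(b$end, c(0.2, 1.1))
  expect_equal(b$n_spikes, c(3L, 3L))
  ## single spike / short runs below the minimum yield nothing
  expect_equal(nrow(detectBursts(SpikeTrain("ch1", 0.5, 0, 1), 0.2, 3)), 0L)
  expect_equal(nrow(detectBursts(SpikeTrain("ch1", c(0.5, 0.6), 0, 1),
                                 0.2, 3)), 0L)
  ## gaps exactly at the threshold stay within one burst
  tr2 <- SpikeTrain("ch1", c(0, 0.2, 0.4), 0, 1)
  b2 <- detectBursts(tr2, 0.2, 3)
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$end, 0.4)
  ## randomized equivalence with the exhaustive gap scan
  set.seed(10)
  for (rep in 1:100) {
    tr <- random_train(n = sample(3:40, 1L), t_stop = 5)
    isi <- runif(1, 0.05, 0.5)
    ms <- sample(2:4, 1L)
    got <- detectBursts(tr, isi, ms)
    ref <- oracle_bursts(tr@times, isi, ms)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref)) {
      expect_equal(got$start, ref$start)
      expect_equal(got$end, ref$end)
      expect_equal(got$n_spikes, as.integer(ref$n))
    }
  }
})

test_that("SBE detection merges overlapping bursts transitively", {
  b <- data.frame(electrode_id = c("ch1", "ch2"),
                  start = c(0, 0.1), end = c(0.2, 0.3),
                  n_spikes = c(3L, 3L))
  s <- detectSBEs(b)
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 0)
  expect_equal(s$end, 0.3)
  expect_setequal(s$electrodes[[1L]], c("ch1", "ch2"))
  ## disjoint bursts form no event
  b2 <- data.frame(electrode_id = c("ch1", "ch2"),
                   start = c(0, 0.5), end = c(0.2, 0.7),
                   n_spikes = c(3L, 3L))
  expect_equal(nrow(detectSBEs(b2)), 0L)
  ## chains merge transitively into one window
  b3 <- data.frame(electrode_id = c("ch1", "ch2", "ch3"),
                   start = c(0, 0.15, 0.3), end = c(0.2, 0.35, 0.5),
                   n_spikes = 3L)
  s3 <- detectSBEs(b3)
  expect_equal(nrow(s3), 1L)
  expect_equal(c(s3$start, s3$end), c(0, 0.5))
  ## touching endpoints count as simultaneous (closed intervals)
  b4 <- data.frame(electrode_id = c("ch1", "ch2"),
                   start = c(0, 0.2), end = c(0.2, 0.4), n_spikes = 3L)
  expect_equal(nrow(detectSBEs(b4)), 1L)
  ## a multi-burst cluster on one electrode is not an SBE
  b5 <- data.frame(electrode_id = c("ch1", "ch1"),
                   start = c(0, 0.1), end = c(0.2, 0.3), n_spikes = 3L)
  expect_equal(nrow(detectSBEs(b5)), 0L)
})

test_that("SBE detection equals the O(n^2) overlap-graph oracle", {
  set.seed(11)
  for (rep in 1:100) {
    b <- random_bursts(n_bursts = sample(2:50, 1L),
                       n_electrodes = sample(2:5, 1L))
    got <- detectSBEs(b)
    ref <- oracle_sbes(b)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref)) {
      expect_equal(got$start, ref$start)
      expect_equal(got$end, ref$end)
      expect_equal(got$n_electrodes, ref$n_electrodes)
    }
  }
})

test_that("SE classification requires two modules, with the single-spike extension", {
  map <- ModuleMap(list(N1 = c("ch1", "ch2"), N2 = c("ch3", "ch4")))
  sb <- data.frame(start = c(0, 1), end = c(0.3, 1.3),
                   n_electrodes = 2L)
  sb$electrodes <- list(c("ch1", "ch3"), c("ch1", "ch2"))
  sb$bursts <- list(1:2, 3:4)
  cl <- classifySEs(sb, map)
  expect_equal(cl$kind, c("SE", "SBE"))
  expect_equal(cl$modules[[1L]], c("N1", "N2"))
  ## single-spike rule promotes when another module fires inside the window
  s <- RecordingSession(list(
    SpikeTrain("ch1", c(1.0, 1.1, 1.25), 0, 2),
    SpikeTrain("ch2", c(1.05, 1.15, 1.3), 0, 2),
    SpikeTrain("ch3", 1.25, 0, 2),
    SpikeTrain("ch4", 0.2, 0, 2)))
  sb2 <- data.frame(start = 1.0, end = 1.3, n_electrodes = 2L)
  sb2$electrodes <- list(c("ch1", "ch2"))
  sb2$bursts <- list(1:2)
  off <- classifySEs(sb2, map, session = s, singleSpikeRule = FALSE)
  expect_equal(off$kind, "SBE")
  on <- classifySEs(sb2, map, session = s, singleSpikeRule = TRUE)
  expect_equal(on$kind, "SE")
  expect_setequal(on$electrodes[[1L]], c("ch1", "ch2", "ch3"))
  ## randomized: the promotion equals a spike-in-window membership scan
  set.seed(12)
  for (rep in 1:30) {
    s <- random_session(n_electrodes = 4, n = 15, t_stop = 5)
    sbw <- sort(runif(2, 0, 4))
    sb3 <- data.frame(start = sbw[1L], end = sbw[2L], n_electrodes = 2L)
    sb3$electrodes <- list(c("ch1", "ch2"))
    sb3$bursts <- list(1:2)
    got <- classifySEs(sb3, map, session = s, singleSpikeRule = TRUE)
    other_fired <- any(vapply(c("ch3", "ch4"), function(id) {
      ts <- spikeTimes(s, id)
      any(ts >= sbw[1L] & ts <= sbw[2L])
    }, logical(1L)))
    expect_equal(got$kind == "SE", other_fired)
  }
})

test_that("association degree equals the per-spike window test", {
  s <- RecordingSession(list(
    SpikeTrain("ch1", c(0.1, 0.2, 0.3, 0.4, 1.1, 1.2, 2.1, 2.2, 2.3, 2.4),
               0, 3)))
  ev <- data.frame(start = c(0.05, 1.05), end = c(0.45, 1.15),
                   n_electrodes = 2L, kind = "SE")
  ev$electrodes <- list("ch1", "ch1")
  ev$modules <- list("N1", "N1")
  a <- associationDegree(s, ev)
  expect_equal(a$degree, 0.5)  # 5 of 10 spikes inside
  ## no SEs -> degree 0; all inside -> 1
  a0 <- associationDegree(s, ev[0, ])
  expect_equal(a0$degree, 0)
  evall <- ev[1, ]
  evall$start <- 0
  evall$end <- 3
  expect_equal(associationDegree(s, evall)$degree, 1)
  ## zero-spike electrodes undefined
  s2 <- RecordingSession(list(SpikeTrain("ch1", 0.1, 0, 1),
                              SpikeTrain("ch2", numeric(), 0, 1)))
  ev2 <- ev[1, ]
  a2 <- associationDegree(s2, ev2)
  expect_true(is.na(a2$degree[a2$electrode_id == "ch2"]))
  ## randomized equivalence with the double loop
  set.seed(13)
  for (rep in 1:50) {
    s <- random_session(n_electrodes = 3, n = 25, t_stop = 10)
    st <- sort(runif(3, 0, 9))
    ev <- data.frame(start = st, end = st + runif(3, 0.1, 0.3),
                     n_electrodes = 2L, kind = "SE")
    ev$electrodes <- list("ch1", "ch1", "ch1")
    ev$modules <- list("N1", "N1", "N1")
    got <- associationDegree(s, ev)
    for (id in electrodeIds(s)) {
      ref <- oracle_assoc(spikeTimes(s, id), ev$start, ev$end)
      expect_equal(got$degree[got$electrode_id == id], ref)
    }
  }
})

test_that("association degree is monotone when SE windows are enlarged", {
  set.seed(14)
  s <- random_session(n_electrodes = 3, n = 40, t_stop = 10)
  st <- sort(runif(4, 0, 9))
  mk <- function(pad) {
    ev <- data.frame(start = pmax(st - pad, 0), end = st + 0.2 + pad,
                     n_electrodes = 2L, kind = "SE")
    ev$electrodes <- list("ch1", "ch1", "ch1", "ch1")
    ev
  }
  small <- associationDegree(s, mk(0))$degree
  large <- associationDegree(s, mk(0.3))$degree
  expect_true(all(large >= small))
})

test_that("propagation direction orders modules by first spike with tie handling", {
  map <- ModuleMap(list(N1 = "ch1", N2 = "ch2", N3 = "ch3"))
  s <- RecordingSession(list(
    SpikeTrain("ch1", c(2.05, 2.10, 2.15), 0, 3),
    SpikeTrain("ch2", c(2.02, 2.08, 2.14), 0, 3),
    SpikeTrain("ch3", c(2.00, 2.06, 2.12), 0, 3)))
  ev <- data.frame(start = 2.0, end = 2.2, n_electrodes = 3L, kind = "SE")
  ev$electrodes <- list(c("ch1", "ch2", "ch3"))
  ev$modules <- list(c("N1", "N2", "N3"))
  lab <- propagationLabels(ev, s, map)
  expect_equal(lab$sequence, "N3->N2->N1")
  expect_false(lab$ambiguous)
  ## two-module ordering
  s2 <- RecordingSession(list(SpikeTrain("ch1", c(1.00, 1.05), 0, 2),
                              SpikeTrain("ch2", c(1.03, 1.06), 0, 2)))
  ev2 <- data.frame(start = 1.0, end = 1.1, n_electrodes = 2L, kind = "SE")
  ev2$electrodes <- list(c("ch1", "ch2"))
  ev2$modules <- list(c("N1", "N2"))
  expect_equal(propagationLabels(ev2, s2, map)$sequence, "N1->N2")
  ## leads below the tolerance are ambiguous
  s3 <- RecordingSession(list(SpikeTrain("ch1", 1.0000, 0, 2),
                              SpikeTrain("ch2", 1.0004, 0, 2)))
  expect_true(propagationLabels(ev2, s3, map, tieTolerance = 0.001)$ambiguous)
  ## single-module events yield no label
  ev3 <- ev2
  ev3$kind <- "SBE"
  expect_equal(nrow(propagationLabels(ev3, s2, map)), 0L)
  ## randomized equivalence with the min-over-members oracle
  set.seed(15)
  map4 <- ModuleMap(list(N1 = c("ch1", "ch2"), N2 = c("ch3", "ch4")))
  for (rep in 1:50) {
    s <- random_session(n_electrodes = 4, n = 20, t_stop = 5)
    w <- sort(runif(2, 0, 5))
    ev <- data.frame(start = w[1L], end = w[2L], n_electrodes = 4L,
                     kind = "SE")
    ev$electrodes <- list(paste0("ch", 1:4))
    ev$modules <- list(c("N1", "N2"))
    lab <- propagationLabels(ev, s, map4, tieTolerance = 0)
    ref <- oracle_propagation(s@trains,
                              list(N1 = c("ch1", "ch2"),
                                   N2 = c("ch3", "ch4")), w[1L], w[2L])
    if (nrow(lab)) expect_equal(lab$sequence, ref)
    else expect_lt(nchar(ref), 7)  # fewer than two modules had spikes
  }
})

test_that("propagation proportions normalize over unambiguous labels", {
  lab <- data.frame(event = 1:10,
                    sequence = c(rep("A->B", 7), rep("B->A", 3)),
                    ambiguous = FALSE, n_modules = 2L)
  pp <- propagationProportions(lab)
  expect_equal(pp$proportion[pp$sequence == "A->B"], 0.7)
  expect_equal(pp$proportion[pp$sequence == "B->A"], 0.3)
  expect_equal(sum(pp$proportion), 1)
  lab$sequence <- "A->B"
  expect_equal(propagationProportions(lab)$proportion, 1)
  expect_error(propagationProportions(lab[lab$ambiguous, ]), "no unambiguous")
})

test_that("SE detection is invariant to electrode order and label permutation", {
  set.seed(16)
  cfg <- presetCoupledPair(p = 0.8, duration = 120)
  plan <- generateSession(cfg, seed = 21)
  ev1 <- sessionEvents(plan$session, plan$map)
  ## permute train order
  perm <- rev(seq_along(plan$session@trains))
  s2 <- RecordingSession(plan$session@trains[perm])
  ev2 <- sessionEvents(s2, plan$map)
  expect_equal(ev1$start, ev2$start)
  expect_equal(ev1$end, ev2$end)
  expect_equal(lapply(ev1$electrodes, sort), lapply(ev2$electrodes, sort))
  ## relabel modules: swap N1 and N2 in the map
  asg <- plan$map@assignment
  swapped <- ifelse(asg == "N1", "N2", ifelse(asg == "N2", "N1", asg))
  map2 <- ModuleMap(split(names(asg), swapped),
                    controlLabel = plan$map@controlLabel)
  ev3 <- classifySEs(detectSBEs(sessionBursts(plan$session)), map2)
  expect_equal(ev1$kind, ev3$kind)
})
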