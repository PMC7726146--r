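test_that("identical seeds reproduce sessions exactly", {
  cfg <- presetCoupledPair(p = 0.5, duration = 120)
  a <- generateSession(cfg, seed = 31)
  b <- generateSession(cfg, seed = 31)
  expect_identical(a$session, b$session)
  expect_identical(a$groundTruth$bursts, b$groundTruth$bursts)
  c <- generateSession(cfg, seed = 32)
  expect_false(identical(a$session, c$session))
  ## byte-identical written spike tables
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeSession(a$session, f1)
  writeSession(b$session, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("module burst generation matches its Poisson specification", {
  cfg <- simConfig(modules = list(simModule("N1", burstRate = 6)),
                   duration = 600)
  counts <- vapply(1:10, function(sd)
    nrow(simulateModuleBursts(cfg, "N1", seed = sd)$bursts), numeric(1L))
  expect_gt(mean(counts), 60 - 3 * sqrt(60 / 10))
  expect_lt(mean(counts), 60 + 3 * sqrt(60 / 10))
  ## null process: no bursts, no background -> empty trains
  cfg0 <- simConfig(modules = list(simModule("N1", burstRate = 0,
                                             backgroundRate = 0)),
                    duration = 100)
  out <- simulateModuleBursts(cfg0, "N1", seed = 1)
  expect_equal(nrow(out$bursts), 0L)
  expect_equal(nSpikes(out$session), 0L)
  ## full participation: every electrode appears in every burst
  cfgp <- simConfig(modules = list(
    simModule("N1", nElectrodes = 3, burstRate = 12, backgroundRate = 0,
              participation = 1, spikesPerBurst = 30)), duration = 200)
  plan <- generateSession(cfgp, seed = 2)
  b <- plan$groundTruth$bursts
  sp <- plan$groundTruth$spikes
  for (k in seq_len(nrow(b)))
    expect_equal(length(unique(sp$electrode[sp$burst == b$id[k]])), 3L)
})

test_that("coupling triggers target bursts with the configured probability", {
  base <- list(simModule("N1", burstRate = 30),
               simModule("N2", burstRate = 30, drivenFraction = 0.5))
  mk <- function(p) simConfig(base, list(simCoupling("N1", "N2", p = p)),
                              duration = 400)
  src <- data.frame(onset = seq(1, 399, by = 2))
  ## p = 1 with drivenFraction 1: every target burst has a source trigger
  cfg1 <- simConfig(list(simModule("N1", burstRate = 30),
                         simModule("N2", drivenFraction = 1)),
                    list(simCoupling("N1", "N2", p = 1)), duration = 400)
  out <- coupleModules(cfg1, src, "N1", "N2", seed = 3)
  expect_true(all(!is.na(out$triggered_by)))
  expect_equal(nrow(out), sum(src$onset + 0.01 < 400))
  ## p = 0: no triggered bursts at all
  out0 <- coupleModules(mk(0), src, "N1", "N2", seed = 3)
  expect_true(all(is.na(out0$triggered_by)))
  ## p = 0.9: triggered fraction near 0.9 with delays near the mean
  cfg9 <- simConfig(list(simModule("N1", burstRate = 30),
                         simModule("N2", drivenFraction = 1)),
                    list(simCoupling("N1", "N2", p = 0.9, delayMean = 0.03,
                                     delaySd = 0.005)), duration = 400)
  trig <- lapply(1:10, function(sd)
    coupleModules(cfg9, src, "N1", "N2", seed = sd))
  frac <- mean(vapply(trig, nrow, numeric(1L)) / nrow(src))
  expect_gt(frac, 0.85)
  expect_lt(frac, 0.95)
  delays <- unlist(lapply(trig, `[[`, "delay"))
  expect_true(all(delays > 0))
  expect_lt(abs(mean(delays) - 0.03), 0.005)
})

test_that("inter-module correlation rises monotonically with coupling", {
  ps <- c(0, 0.3, 0.6, 0.9)
  mean_inter <- vapply(ps, function(p) {
    vals <- vapply(1:5, function(sd) {
      plan <- generateSession(presetCoupledPair(p = p, duration = 300),
                              seed = 40 + sd)
      connectivity(plan$session, plan$map)$summary@interOverall
    }, numeric(1L))
    mean(vals)
  }, numeric(1L))
  expect_true(all(diff(mean_inter) > 0))
  expect_lt(abs(mean_inter[1L]), 0.05)
})

test_that("suppression deletes targeted activity and its downstream cascade", {
  cfg <- simConfig(
    modules = list(simModule("N1", burstRate = 30, drivenFraction = 0),
                   simModule("N2", burstRate = 30, drivenFraction = 1)),
    couplings = list(simCoupling("N1", "N2", p = 1)),
    duration = 300,
    suppression = data.frame(power = c(10, 99), factor = c(1, 0)))
  prot <- data.frame(target = "N1", power = 99, on = 100, off = 200,
                     trial = 1L)
  plan <- generateSession(cfg, seed = 5, protocol = prot)
  s <- plan$session
  n1 <- grep("^N1", electrodeIds(s), value = TRUE)
  n2 <- grep("^N2", electrodeIds(s), value = TRUE)
  in_epoch <- function(ids) sum(vapply(ids, function(id) {
    ts <- spikeTimes(s, id)
    sum(ts >= 100.5 & ts < 200)  # past the burst-length edge
  }, numeric(1L)))
  ## factor 0: target silenced apart from (zero-rate) background
  expect_equal(in_epoch(n1), 0)
  ## the fully driven downstream module falls to background level too
  bg_rate <- in_epoch(n2) / (99.5 * length(n2))
  expect_lt(bg_rate, 2 * 0.2 + 0.1)
  ## factor 1: identity
  prot1 <- data.frame(target = "N1", power = 10, on = 100, off = 200,
                      trial = 1L)
  plan1 <- generateSession(cfg, seed = 5, protocol = prot1)
  plan_none <- generateSession(cfg, seed = 5)
  expect_identical(plan1$session, plan_none$session)
  ## overlapping epochs for one module are rejected
  bad <- data.frame(target = "N1", power = 99, on = c(10, 50),
                    off = c(60, 90), trial = 1:2)
  expect_error(generateSession(cfg, seed = 5, protocol = bad), "overlap")
})

test_that("every generated spike is attributable to one category", {
  cfg <- presetCoupledPair(p = 0.7, duration = 200)
  stims <- seq(150, 195, by = 3)
  cfg@stimResponse <- list(simStimResponse("N2", probability = 0.8))
  plan <- generateSession(cfg, seed = 6, stimTimes = stims)
  sp <- plan$groundTruth$spikes
  expect_setequal(unique(sp$category),
                  c("burst", "background", "evoked"))
  expect_true(all(!is.na(sp$burst[sp$category == "burst"])))
  expect_true(all(is.na(sp$burst[sp$category != "burst"])))
  ## spike counts in the session equal category totals (up to boundary
  ## clipping and exact-duplicate removal, which are measure-zero)
  expect_equal(nSpikes(plan$session), nrow(sp))
})

test_that("rendered traces support detection scoring against injections", {
  ## noiseless single spike: exactly one detection at the injected time
  tr <- SpikeTrain("ch1", 0.5, 0, 1)
  rn <- renderNoiseTraces(RecordingSession(list(tr)), noiseSd = 1e-6,
                          amplitudeSD = 1e7, seed = 7)
  det <- detectSpikes(rn$traces@samples[1L, ], 25000, kSd = 6, noiseSD = 1)
  expect_equal(nSpikes(det), 1L)
  expect_lt(abs(det@times - 0.5), 2e-4)
  ## zero spikes: pure noise stays almost entirely below 6 sigma
  empty <- SpikeTrain("ch1", numeric(), 0, 60)
  rn0 <- renderNoiseTraces(RecordingSession(list(empty)), seed = 8)
  det0 <- detectSpikes(rn0$traces@samples[1L, ], 25000, kSd = 6)
  expect_lte(nSpikes(det0), 2)
  ## overlap flagging
  tr2 <- SpikeTrain("ch1", c(0.5, 0.5004), 0, 1)
  rn2 <- renderNoiseTraces(RecordingSession(list(tr2)), seed = 9)
  expect_equal(rn2$n_overlaps, 1L)
})
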