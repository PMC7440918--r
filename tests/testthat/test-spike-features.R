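test_that("spike detection ignores subthreshold traces", {
  dt <- 0.1
  expect_equal(nrow(detectSpikes(rep(-70, 5000), dt)), 0)
  # a ramp rising at 9 mV/ms never crosses the 10 mV/ms criterion
  ramp <- -70 + 9 * (seq_len(3000) - 1) * dt
  expect_equal(nrow(detectSpikes(ramp, dt)), 0)
})

test_that("spike threshold lands within one sample of the true crossing", {
  dt <- 0.1
  v <- rep(-50, 4000)
  v <- putSpike(v, dt, tThr = 220.0)
  sp <- detectSpikes(v, dt)
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$threshold_time - 220.0), dt + 1e-9)
  expect_lt(abs(sp$threshold_v - (-31)), 0.2)
  expect_equal(sp$peak_v, 64, tolerance = 0.01)
})

test_that("passive properties follow their defining formulas exactly", {
  # steady responses -78/-74/-70/-66 mV at -100/-50/0/+50 pA -> 80 MOhm
  lad <- flatLadder(c(-78, -74, -70, -66),
                    currents = c(-100, -50, 0, 50))
  pp <- passiveProperties(lad)
  expect_equal(pp$input_resistance, 80, tolerance = 1e-8)
  # sag forced by the ratio definition: steady -81.6 over peak -85
  dt <- 0.5; stepOnset <- 50; stepDuration <- 400
  ns <- round((stepOnset + stepDuration + 50) / dt)
  tt <- (seq_len(ns) - 1) * dt
  hyp <- rep(-70, ns)
  inStep <- tt >= stepOnset & tt < stepOnset + stepDuration
  hyp[inStep] <- -81.6
  hyp[tt >= stepOnset + 100 & tt < stepOnset + 110] <- -85
  lad2 <- SweepLadder("sag", c(-100, -50, 0),
                      rbind(hyp, rep(-75, ns), rep(-70, ns)), dt = dt,
                      stepOnset = stepOnset, stepDuration = stepDuration)
  expect_equal(passiveProperties(lad2)$sag, -81.6 / -85, tolerance = 1e-3)
})

test_that("membrane time constant is recovered from an RC relaxation", {
  dt <- 0.1; stepOnset <- 100
  ns <- 6000
  tt <- (seq_len(ns) - 1) * dt
  v <- rep(-70, ns)
  inStep <- tt >= stepOnset
  v[inStep] <- -70 - 12 * (1 - exp(-(tt[inStep] - stepOnset) / 15))
  lad <- SweepLadder("rc", c(-100, -50), rbind(v, rep(-70, ns)), dt = dt,
                     stepOnset = stepOnset, stepDuration = 400)
  pp <- passiveProperties(lad)
  expect_equal(as.numeric(pp$tau_membrane), 15, tolerance = 0.1)
})

test_that("rheobase-sweep features follow the waveform definitions", {
  spec <- defaultSubtypeSpecs()$ADP
  r <- coarseLadder(spec, seed = 2, noiseSd = 0)
  f <- rheobaseFeatures(r$ladder)
  expect_equal(unname(f["rheobase_current"]),
               unname(r$truth["rheobase_current"]))
  expect_equal(unname(f["adp_amplitude"]), 13.8, tolerance = 0.05)
  expect_equal(unname(f["adp_latency"]), 20, tolerance = 0.5)
  expect_equal(unname(f["spike_count_rheo"]),
               unname(r$truth["spike_count_rheo"]))
  # AHP trough -60 followed by a bump peaking at -46.2 gives 13.8 mV
  expect_equal(-46.2 - -60, 13.8)
})

test_that("half-width is measured at half amplitude by interpolation", {
  # symmetric construction: threshold -31, peak +64, level +16.5,
  # rising crossing 0.3 ms after threshold, falling crossing 1.3 ms
  dt <- 0.1
  v <- rep(-50, 4000)
  # rising crossing 0.3 ms after threshold; the fall duration is chosen
  # so the falling crossing of +16.5 mV sits exactly 1.0 ms later
  v <- putSpike(v, dt, tThr = 200, thr = -31, amp = 95, riseMs = 0.6,
                fallMs = 0.7 * (95 + 26) / 47.5, ahp = 26)
  sp <- detectSpikes(v, dt)
  expect_equal(sp$halfwidth, 1.00, tolerance = 0.02)
})

test_that("saturated-sweep rates follow the interval definitions", {
  # peaks with ISIs 5,6,7,...: fmax_init = 1/5 ms = 200 Hz
  dt <- 0.1
  v <- rep(-60, 9000)
  isis <- c(5, 6, 7, 8, 10, 14, 20, 30, 38, 40, 42, 40)
  tThrs <- 100 + c(0, cumsum(isis))
  for (tth in tThrs)
    v <- putSpike(v, dt, tth, thr = -31, amp = 60, riseMs = 0.3,
                  fallMs = 0.7, ahp = 15, recoverTo = -45.8,
                  recoverBy = 60)
  lad <- SweepLadder("sat", c(-100, 0, 100),
                     rbind(rep(-75, 9000), rep(-70, 9000), v), dt = dt,
                     stepOnset = 100, stepDuration = 780)
  f <- saturationFeatures(lad)
  expect_equal(unname(f["spike_count_sat"]), length(tThrs))
  expect_equal(unname(f["fmax_init"]), 200, tolerance = 1e-6)
  # last four ISIs 38,40,42,40 -> 25 Hz; adaptation = 25/200
  expect_equal(unname(f["fmax_ss"]), 25, tolerance = 1e-6)
  expect_equal(unname(f["adaptation_ratio"]), 0.125, tolerance = 1e-6)
})

test_that("feature extraction is complete, deterministic and errors on
           subthreshold ladders", {
  spec <- defaultSubtypeSpecs()$HFF
  r <- coarseLadder(spec, seed = 5, noiseSd = 0.2)
  f1 <- extractFeatures(r$ladder)
  f2 <- extractFeatures(r$ladder)
  expect_identical(f1, f2)
  expect_named(f1, featureRoster())
  expect_false(anyNA(f1))
  expect_equal(unname(f1["adaptation_ratio"]),
               unname(f1["fmax_ss"] / f1["fmax_init"]))
  expect_error(extractFeatures(flatLadder(seq(-75, -70, by = 1))),
               "no_rheobase")
})

test_that("noiseless extraction recovers generator truth within 2% or one
           sample", {
  slackFeatures <- c("ap_decay", "adp_latency")   # trough-timing metrics
  for (spec in defaultSubtypeSpecs()) {
    r <- coarseLadder(spec, seed = 7, noiseSd = 0)
    err <- recoveryError(extractFeatures(r$ladder), r$truth)
    expect_lt(max(abs(err[!names(err) %in% slackFeatures])), 0.02,
              label = sprintf("%s max relative error", spec@name))
    # timing metrics: within one sample of the realized knots
    f <- extractFeatures(r$ladder)
    expect_lt(abs(f["ap_decay"] - r$truth["ap_decay"]), 0.11)
    expect_lt(abs(f["first_spike_latency_sat"] -
                    r$truth["first_spike_latency_sat"]), 0.11)
  }
})

test_that("voltage translation shifts potentials and preserves shape
           metrics", {
  spec <- defaultSubtypeSpecs()$Delayed
  r <- coarseLadder(spec, seed = 9, noiseSd = 0)
  lad <- r$ladder
  shifted <- SweepLadder(cellId(lad), sweepCurrents(lad),
                         sweepVoltages(lad) + 5, dt = lad@dt,
                         stepOnset = lad@stepOnset,
                         stepDuration = lad@stepDuration,
                         capacitancePf = lad@capacitancePf)
  f0 <- extractFeatures(r$ladder)
  f5 <- extractFeatures(shifted)
  expect_equal(unname(f5["rmp"] - f0["rmp"]), 5, tolerance = 1e-6)
  expect_equal(unname(f5["ap_threshold"] - f0["ap_threshold"]), 5,
               tolerance = 0.25)
  for (f in c("ap_halfwidth", "first_spike_latency_rheo",
              "first_spike_latency_sat", "fmax_init", "fmax_ss",
              "spike_count_rheo", "spike_count_sat"))
    expect_equal(unname(f5[f]), unname(f0[f]), tolerance = 1e-3,
                 label = f)
})

test_that("appending post-step baseline does not change spike counts", {
  spec <- defaultSubtypeSpecs()$HFF
  lad <- coarseLadder(spec, seed = 4, noiseSd = 0)$ladder
  i <- which.max(vapply(vtaSst:::.spikesBySweep(lad), nrow, 0L))
  v <- sweepVoltages(lad)[i, ]
  n0 <- nrow(detectSpikes(v, lad@dt))
  expect_gt(n0, 0)
  vPad <- c(v, rep(v[length(v)], 2000))
  expect_equal(nrow(detectSpikes(vPad, lad@dt)), n0)
})

test_that("interval count equals spike count minus one on every sweep", {
  spec <- defaultSubtypeSpecs()$ADP
  lad <- coarseLadder(spec, seed = 6, noiseSd = 0.2)$ladder
  for (sp in vtaSst:::.spikesBySweep(lad))
    if (nrow(sp) > 0)
      expect_equal(length(diff(sp$peak_time)), nrow(sp) - 1L)
})
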