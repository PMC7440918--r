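# shared fixture builders (everything generated in code, no files)

# a flat-baseline ladder with given per-sweep baselines and no spikes
flatLadder <- function(baselines, currents = seq(-100, by = 10,
                                                 length.out = length(baselines)),
                       dt = 0.5, stepOnset = 50, stepDuration = 400) {
  ns <- round((stepOnset + stepDuration + 50) / dt)
  volt <- matrix(rep(baselines, each = ns), nrow = length(baselines),
                 byrow = TRUE)
  SweepLadder(cellId = "flat", currents = currents, voltage = volt,
              dt = dt, stepOnset = stepOnset, stepDuration = stepDuration)
}

# one linear-segment action potential written into a trace: slow ramp
# from rampFrom, quadratic approach hitting `thr` with slope 10 mV/ms at
# tThr, linear rise to the peak, linear fall to the trough, slow linear
# recovery (all times ms)
putSpike <- function(v, dt, tThr, thr = -31, amp = 95, riseMs = 0.6,
                     fallMs = 1.4, ahp = 26, recoverTo = -45,
                     recoverBy = 60, rampFrom = NULL) {
  tt <- (seq_along(v) - 1) * dt
  appStartV <- thr - 2.5                  # quadratic start (tApp 0.5 ms)
  if (is.null(rampFrom)) rampFrom <- v[max(1, round((tThr - 6) / dt))]
  rampT <- max((appStartV - rampFrom) / 8, 2 * dt)   # <= 8 mV/ms
  rmp <- tt >= tThr - 0.5 - rampT & tt < tThr - 0.5
  v[rmp] <- rampFrom + (appStartV - rampFrom) *
    (tt[rmp] - (tThr - 0.5 - rampT)) / rampT
  app <- tt >= tThr - 0.5 & tt <= tThr
  v[app] <- thr - 10 * (tThr - tt[app])^2 / (2 * 0.5)
  ris <- tt > tThr & tt <= tThr + riseMs
  v[ris] <- thr + amp * (tt[ris] - tThr) / riseMs
  fal <- tt > tThr + riseMs & tt <= tThr + riseMs + fallMs
  v[fal] <- (thr + amp) - (amp + ahp) * (tt[fal] - tThr - riseMs) / fallMs
  rec <- tt > tThr + riseMs + fallMs & tt <= tThr + riseMs + fallMs + recoverBy
  v[rec] <- (thr - ahp) + (recoverTo - thr + ahp) *
    (tt[rec] - tThr - riseMs - fallMs) / recoverBy
  v
}

# subtype specs rendered on a coarse current grid for speed
coarseLadder <- function(spec, seed = 1, noiseSd = 0) {
  synthTraceLadder(spec, seed = seed, noiseSd = noiseSd,
                   currents = seq(-100, 600, by = 20))
}

# relative (or absolute, for zero truth) extraction error
recoveryError <- function(extracted, truth) {
  ifelse(truth != 0, (extracted - truth) / truth, extracted - truth)
}
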