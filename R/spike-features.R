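#' The default electrophysiological feature roster
#'
#' Twenty-five features: five passive (resting potential, input
#' resistance, sag ratio, membrane time constant, capacitance), ten from
#' the rheobase sweep (the lowest current step that elicits a spike) and
#' ten from the saturated sweep (the step with the most spikes).
#'
#' @return character vector of 25 feature names.
#' @export
featureRoster <- function() {
  c("rmp", "input_resistance", "sag", "tau_membrane", "capacitance_pf",
    "rheobase_current", "ap_threshold", "ap_amplitude", "ap_halfwidth",
    "ahp_amplitude", "ap_decay", "adp_amplitude", "adp_latency",
    "first_spike_latency_rheo", "spike_count_rheo",
    "saturating_current", "first_spike_latency_sat", "fmax_init",
    "fmax_ss", "adaptation_ratio", "ap_halfwidth_sat", "spike_count_sat",
    "ap_amplitude_sat", "ahp_amplitude_sat", "isi_cv_sat")
}

# 3-point moving average; endpoints kept as-is
.smooth3 <- function(v) {
  n <- length(v)
  if (n < 3L) return(v)
  s <- v
  s[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  s
}

#' Detect action potentials in a voltage trace
#'
#' The spike threshold is the first sample at which the smoothed voltage
#' slope exceeds \code{slopeThreshold} (10 mV/ms by default) on the rise
#' to a peak. The slope is computed by central differences after 3-point
#' moving-average smoothing. Candidate events whose peak rises less than
#' \code{minAmplitude} above threshold are rejected (this keeps
#' afterdepolarization bumps from being double counted).
#'
#' @param voltage numeric trace, mV.
#' @param dt sampling interval, ms.
#' @param slopeThreshold threshold-crossing slope, mV/ms.
#' @param minAmplitude minimum peak height above threshold, mV.
#' @return data.frame with one row per spike: \code{threshold_time},
#'   \code{threshold_v}, \code{peak_time}, \code{peak_v}, \code{ahp_time},
#'   \code{ahp_v}, \code{halfwidth}, \code{decay_time} (times in ms from
#'   trace start). Zero rows for subthreshold traces.
#' @export
detectSpikes <- function(voltage, dt, slopeThreshold = 10,
                         minAmplitude = 20) {
  stopifnot(dt > 0)
  if (any(!is.finite(voltage))) .stopf("voltage trace must be finite")
  n <- length(voltage)
  empty <- data.frame(threshold_time = numeric(), threshold_v = numeric(),
                      peak_time = numeric(), peak_v = numeric(),
                      ahp_time = numeric(), ahp_v = numeric(),
                      halfwidth = numeric(), decay_time = numeric())
  if (n < 5L) return(empty)
  s <- .smooth3(voltage)
  slope <- c(0, (s[3:n] - s[1:(n - 2)]) / (2 * dt), 0)
  fast <- slope > slopeThreshold
  if (!any(fast)) return(empty)
  runs <- rle(fast)
  starts <- cumsum(c(1L, runs$lengths))[seq_along(runs$lengths)]
  thrIdx <- starts[runs$values]
  rows <- list()
  lastPeak <- 0L
  for (ti in thrIdx) {
    if (ti <= lastPeak) next   # run still on the rise of the previous AP
    # peak: the first local maximum of the smoothed trace after the
    # crossing that rises at least minAmplitude above it (a bounded
    # window-global max could skip to the next spike at short intervals)
    hi <- min(n, ti + ceiling(10 / dt))
    if (hi - ti < 3L) next
    sw <- s[ti:hi]
    lm <- which(diff(sign(diff(sw))) < 0) + 1L
    peakIdx <- NA_integer_
    for (j in lm) {
      cand <- ti + j - 1L
      lo <- max(1L, cand - 2L); up <- min(n, cand + 2L)
      cand <- lo + which.max(voltage[lo:up]) - 1L
      if (voltage[cand] - voltage[ti] >= minAmplitude) {
        peakIdx <- cand
        break
      }
    }
    if (is.na(peakIdx) || peakIdx >= n) next
    rows[[length(rows) + 1L]] <- c(ti, peakIdx)
    lastPeak <- peakIdx
  }
  if (!length(rows)) return(empty)
  idx <- do.call(rbind, rows)
  nev <- nrow(idx)
  out <- empty[seq_len(nev), ]
  for (k in seq_len(nev)) {
    ti <- idx[k, 1]; pi <- idx[k, 2]
    nextThr <- if (k < nev) idx[k + 1, 1] else n
    # AHP trough: most negative point between peak and next spike
    # (bounded 50 ms lookahead so post-step repolarization is not mistaken
    # for an AHP)
    hi <- min(nextThr, pi + ceiling(50 / dt), n)
    tr <- pi + which.min(voltage[pi:hi]) - 1L
    thrV <- voltage[ti]; peakV <- voltage[pi]
    level <- thrV + (peakV - thrV) / 2
    out$threshold_time[k] <- (ti - 1L) * dt
    out$threshold_v[k] <- thrV
    out$peak_time[k] <- (pi - 1L) * dt
    out$peak_v[k] <- peakV
    out$ahp_time[k] <- (tr - 1L) * dt
    out$ahp_v[k] <- voltage[tr]
    out$halfwidth[k] <- .halfwidth(voltage, dt, ti, pi, tr, level)
    out$decay_time[k] <- (tr - pi) * dt
  }
  out
}

# width at `level` between the rising crossing (threshold..peak) and the
# falling crossing (peak..trough), by linear interpolation
.halfwidth <- function(v, dt, ti, pi, tr, level) {
  riseSeg <- v[ti:pi]
  iUp <- which(riseSeg >= level)[1]
  tUp <- if (is.na(iUp) || iUp == 1L) (ti - 1L) * dt else {
    a <- riseSeg[iUp - 1L]; b <- riseSeg[iUp]
    (ti + iUp - 3L + (level - a) / (b - a)) * dt
  }
  fallSeg <- v[pi:tr]
  iDn <- which(fallSeg <= level)[1]
  tDn <- if (is.na(iDn) || iDn == 1L) (tr - 1L) * dt else {
    a <- fallSeg[iDn - 1L]; b <- fallSeg[iDn]
    (pi + iDn - 3L + (a - level) / (a - b)) * dt
  }
  tDn - tUp
}

# afterdepolarization bump after an AHP trough. Window runs from the
# trough to min(next spike threshold, trough + maxMs, step end). A bump
# registers only as an interior local maximum that rises at least minAdp
# above the trough AND declines again by at least minAdp before the
# window ends (prominence test on a ~1 ms smoothed segment); a monotone
# recovery toward the next spike is not a bump.
.adpAfter <- function(v, dt, troughIdx, windowEndIdx, minAdp = 0.5) {
  windowEndIdx <- min(windowEndIdx, length(v))
  none <- c(adp_amplitude = 0, adp_latency = 0)
  if (windowEndIdx - troughIdx < 10L) return(none)
  seg <- v[troughIdx:windowEndIdx]
  w <- min(9L, 2L * floor((length(seg) - 1L) / 4L) + 1L)
  sm <- as.numeric(stats::filter(seg, rep(1 / w, w), sides = 2))
  half <- (w - 1L) %/% 2L
  if (half > 0) {                     # pad the filter edges
    sm[seq_len(half)] <- sm[half + 1L]
    sm[(length(sm) - half + 1L):length(sm)] <- sm[length(sm) - half]
  }
  im <- which.max(sm)
  amp <- sm[im] - seg[1]            # referenced to the trough sample
  if (im <= 1L || im >= length(sm) || amp < minAdp) return(none)
  if (sm[im] - min(sm[im:length(sm)]) < minAdp) return(none)
  c(adp_amplitude = amp, adp_latency = (im - 1L) * dt)
}

# spike tables for every sweep of a ladder
.spikesBySweep <- function(ladder, slopeThreshold = 10, minAmplitude = 20) {
  lapply(seq_along(ladder@currents), function(i)
    detectSpikes(ladder@voltage[i, ], ladder@dt, slopeThreshold,
                 minAmplitude))
}

#' Passive membrane properties from a sweep ladder
#'
#' Resting membrane potential is the mean of per-sweep pre-step baselines.
#' Input resistance is the least-squares slope of the steady-state voltage
#' (mean of the last 50 ms of the step) against injected current over all
#' spike-free sweeps, converted to megaohms. Sag is the ratio of the
#' steady-state mean of the last 50 ms of the most hyperpolarizing
#' (-100 pA) sweep to the most negative voltage during that step, both as
#' absolute voltages (set \code{sagMode = "deflection"} for the
#' baseline-relative alternative). The membrane time constant comes from a
#' single-exponential fit of the -100 pA step onset (first 200 ms,
#' skipping 2 ms of capacitive transient).
#'
#' @param ladder a \linkS4class{SweepLadder}.
#' @param spikesBySweep optional precomputed output of
#'   \code{\link{detectSpikes}} per sweep.
#' @param sagMode \code{"absolute"} or \code{"deflection"}.
#' @return named list: \code{rmp}, \code{input_resistance} (MOhm),
#'   \code{sag}, \code{tau_membrane} (ms; \code{NA} with a
#'   \code{"tau_flagged"} attribute when the fit fails to converge).
#' @export
passiveProperties <- function(ladder, spikesBySweep = NULL,
                              sagMode = c("absolute", "deflection")) {
  sagMode <- match.arg(sagMode)
  if (is.null(spikesBySweep)) spikesBySweep <- .spikesBySweep(ladder)
  rmp <- mean(.sweepBaselines(ladder))
  nspk <- vapply(spikesBySweep, nrow, 0L)
  free <- which(nspk == 0L)
  if (length(free) < 2L)
    .stopf("feature error: fewer than 2 spike-free sweeps")
  tail50 <- .stepTailIdx(ladder)
  vss <- rowMeans(ladder@voltage[free, tail50, drop = FALSE])
  rin <- unname(coef(lm(vss ~ ladder@currents[free]))[2]) * 1000
  hyp <- which(ladder@currents < 0)
  if (!length(hyp)) .stopf("feature error: no hyperpolarizing sweep for sag")
  hyp <- hyp[which.min(ladder@currents[hyp])]
  stepIdx <- .stepIdx(ladder)
  vHyp <- ladder@voltage[hyp, ]
  vssHyp <- mean(vHyp[tail50])
  vPeak <- min(vHyp[stepIdx])
  sag <- if (sagMode == "absolute") vssHyp / vPeak
         else (vssHyp - rmp) / (vPeak - rmp)
  tau <- .fitTau(vHyp, ladder@dt, ladder@stepOnset)
  list(rmp = rmp, input_resistance = rin, sag = sag, tau_membrane = tau)
}

.fitTau <- function(v, dt, stepOnset, skipMs = 2, fitMs = 200) {
  i0 <- floor((stepOnset + skipMs) / dt) + 1L
  i1 <- min(floor((stepOnset + fitMs) / dt), length(v))
  tt <- (seq.int(i0, i1) - 1L) * dt - stepOnset
  vv <- v[i0:i1]
  st <- list(vinf = vv[length(vv)], v0 = vv[1], tau = 20)
  fit <- tryCatch(
    minpack.lm::nlsLM(vv ~ vinf + (v0 - vinf) * exp(-tt / tau), start = st,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || coef(fit)[["tau"]] <= 0) {
    out <- NA_real_
    attr(out, "tau_flagged") <- TRUE
    return(out)
  }
  unname(coef(fit)[["tau"]])
}

#' Features of the rheobase sweep
#'
#' Waveform metrics of the first action potential on the lowest current
#' step that elicits any spike: threshold voltage, amplitude
#' (threshold to peak), half-width at half amplitude, AHP amplitude
#' (threshold to trough), decay time (peak to trough), the
#' afterdepolarization bump (amplitude above the AHP trough and latency
#' from the trough; both 0 when no bump is present), first-spike latency
#' from step onset, and the spike count of that sweep.
#'
#' @param ladder a \linkS4class{SweepLadder}.
#' @param spikesBySweep per-sweep spike tables.
#' @return named numeric vector (the rheobase block of the roster).
#' @export
rheobaseFeatures <- function(ladder, spikesBySweep = NULL) {
  if (is.null(spikesBySweep)) spikesBySweep <- .spikesBySweep(ladder)
  nspk <- vapply(spikesBySweep, nrow, 0L)
  iRheo <- which(nspk >= 1L)[1]
  if (is.na(iRheo)) .stopf("feature error: no_rheobase")
  sp <- spikesBySweep[[iRheo]]
  ev <- sp[1, ]
  dt <- ladder@dt
  v <- ladder@voltage[iRheo, ]
  troughIdx <- round(ev$ahp_time / dt) + 1L
  stepEndIdx <- floor((ladder@stepOnset + ladder@stepDuration) / dt)
  windowEnd <- min(
    if (nrow(sp) > 1L) round(sp$threshold_time[2] / dt) + 1L else stepEndIdx,
    troughIdx + round(100 / dt), stepEndIdx)
  adp <- .adpAfter(v, dt, troughIdx, windowEnd)
  c(rheobase_current = ladder@currents[iRheo],
    ap_threshold = ev$threshold_v,
    ap_amplitude = ev$peak_v - ev$threshold_v,
    ap_halfwidth = ev$halfwidth,
    ahp_amplitude = ev$threshold_v - ev$ahp_v,
    ap_decay = ev$decay_time,
    adp,
    first_spike_latency_rheo = ev$threshold_time - ladder@stepOnset,
    spike_count_rheo = nrow(sp))
}

#' Features of the saturated sweep
#'
#' The saturated sweep is the one with the most spikes (ties broken toward
#' the lowest current). Interspike intervals are measured between spike
#' peaks. The initial maximal frequency is the inverse of the shortest of
#' the first two intervals (i.e. among the first three spikes); the
#' steady-state maximal frequency is the inverse of the mean of the last
#' four intervals (of all intervals when fewer than four are available);
#' the adaptation ratio is their quotient. Waveform metrics come from the
#' first spike of the sweep. Fields that need at least two spikes are
#' \code{NA} when the sweep has fewer.
#'
#' @inheritParams rheobaseFeatures
#' @return named numeric vector (the saturated block of the roster).
#' @export
saturationFeatures <- function(ladder, spikesBySweep = NULL) {
  if (is.null(spikesBySweep)) spikesBySweep <- .spikesBySweep(ladder)
  nspk <- vapply(spikesBySweep, nrow, 0L)
  if (!any(nspk >= 1L)) .stopf("feature error: no_rheobase")
  iSat <- which(nspk == max(nspk))[1]      # ties -> lowest current
  sp <- spikesBySweep[[iSat]]
  ev <- sp[1, ]
  isi <- diff(sp$peak_time)
  if (length(isi) >= 1L) {
    fi <- 1000 / min(isi[seq_len(min(2L, length(isi)))])
    lastFour <- utils::tail(isi, 4L)
    fs <- 1000 / mean(lastFour)
    ar <- fs / fi
  } else fi <- fs <- ar <- NA_real_
  cvv <- if (length(isi) >= 2L) sd(isi) / mean(isi) else 0
  c(saturating_current = ladder@currents[iSat],
    first_spike_latency_sat = ev$threshold_time - ladder@stepOnset,
    fmax_init = fi, fmax_ss = fs, adaptation_ratio = ar,
    ap_halfwidth_sat = ev$halfwidth,
    spike_count_sat = nrow(sp),
    ap_amplitude_sat = ev$peak_v - ev$threshold_v,
    ahp_amplitude_sat = ev$threshold_v - ev$ahp_v,
    isi_cv_sat = cvv)
}

#' Extract the full 25-feature vector from a sweep ladder
#'
#' Runs spike detection over every sweep, then assembles the passive,
#' rheobase and saturated feature blocks (see \code{\link{featureRoster}}).
#' Deterministic for a fixed input.
#'
#' @param ladder a \linkS4class{SweepLadder}; should pass
#'   \code{\link{validateLadder}}.
#' @param sagMode see \code{\link{passiveProperties}}.
#' @return named numeric vector of length 25.
#' @export
extractFeatures <- function(ladder, sagMode = "absolute") {
  spikes <- .spikesBySweep(ladder)
  pp <- passiveProperties(ladder, spikes, sagMode = sagMode)
  out <- c(rmp = pp$rmp, input_resistance = pp$input_resistance,
           sag = pp$sag, tau_membrane = as.numeric(pp$tau_membrane),
           capacitance_pf = ladder@capacitancePf,
           rheobaseFeatures(ladder, spikes),
           saturationFeatures(ladder, spikes))
  out[featureRoster()]
}

#' Build a FeatureMatrix from a list of ladders
#'
#' @param ladders list of \linkS4class{SweepLadder} objects.
#' @param trueLabels optional ground-truth subtype per cell.
#' @param ... passed to \code{\link{extractFeatures}}.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
extractFeatureMatrix <- function(ladders, trueLabels = character(), ...) {
  vals <- t(vapply(ladders, extractFeatures,
                   setNames(numeric(25), featureRoster()), ...))
  rownames(vals) <- vapply(ladders, cellId, "")
  new("FeatureMatrix", values = vals,
      ageGroup = vapply(ladders, function(l) l@ageGroup, ""),
      trueLabels = as.character(trueLabels))
}
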