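#' Built-in generative specifications for the three subtypes
#'
#' Returns \linkS4class{SubtypeSpec} objects for the afterdepolarizing
#' (ADP), high-frequency-firing (HFF) and Delayed subtypes. Population
#' means and SEMs follow the published summary table of the juvenile
#' cohort (cohort sizes 215/92/85); population SDs are reconstructed as
#' SEM x sqrt(n). Features that the summary table does not report
#' (membrane time constant, afterdepolarization latency, saturated-sweep
#' amplitude/AHP, interspike-interval CV) carry package defaults chosen as
#' typical for these cells and documented in the methods vignette.
#'
#' @return named list of three \linkS4class{SubtypeSpec} objects.
#' @export
defaultSubtypeSpecs <- function() {
  mk <- function(name, n, m, sem, tpl) {
    new("SubtypeSpec", name = name, n = as.integer(n),
        featureMeans = m[featureRoster()],
        featureSds = (sem * sqrt(n))[featureRoster()], template = tpl)
  }
  f <- function(...) {
    v <- c(...)
    setNames(as.numeric(v), names(v))[featureRoster()] -> out
    names(out) <- featureRoster()
    out
  }
  adpM <- f(rmp = -69.9, input_resistance = 783, sag = 0.963,
            tau_membrane = 15, capacitance_pf = 13.2,
            rheobase_current = 18.4, ap_threshold = -31.1,
            ap_amplitude = 95.2, ap_halfwidth = 1.01, ahp_amplitude = 26.3,
            ap_decay = 2.2, adp_amplitude = 13.8, adp_latency = 20,
            first_spike_latency_rheo = 218, spike_count_rheo = 2.1,
            saturating_current = 207, first_spike_latency_sat = 24.8,
            fmax_init = 108, fmax_ss = 25.6, adaptation_ratio = 0.28,
            ap_halfwidth_sat = 1.88, spike_count_sat = 21.6,
            ap_amplitude_sat = 90.2, ahp_amplitude_sat = 24.3,
            isi_cv_sat = 0.30)
  adpS <- f(rmp = 0.6, input_resistance = 24, sag = 0.002,
            tau_membrane = 0.5, capacitance_pf = 0.2,
            rheobase_current = 1.0, ap_threshold = 0.3, ap_amplitude = 0.6,
            ap_halfwidth = 0.01, ahp_amplitude = 0.5, ap_decay = 0.1,
            adp_amplitude = 0.5, adp_latency = 1,
            first_spike_latency_rheo = 10, spike_count_rheo = 0.1,
            saturating_current = 5, first_spike_latency_sat = 3.4,
            fmax_init = 3, fmax_ss = 1.1, adaptation_ratio = 0.02,
            ap_halfwidth_sat = 0.04, spike_count_sat = 0.9,
            ap_amplitude_sat = 0.8, ahp_amplitude_sat = 0.5,
            isi_cv_sat = 0.02)
  hffM <- f(rmp = -67.8, input_resistance = 835, sag = 0.952,
            tau_membrane = 12, capacitance_pf = 12.4,
            rheobase_current = 11.9, ap_threshold = -31.7,
            ap_amplitude = 94.0, ap_halfwidth = 0.90, ahp_amplitude = 35.7,
            ap_decay = 1.84, adp_amplitude = 0, adp_latency = 0,
            first_spike_latency_rheo = 182, spike_count_rheo = 3.9,
            saturating_current = 209, first_spike_latency_sat = 12.2,
            fmax_init = 129, fmax_ss = 42.9, adaptation_ratio = 0.32,
            ap_halfwidth_sat = 1.6, spike_count_sat = 39.1,
            ap_amplitude_sat = 89.0, ahp_amplitude_sat = 33.7,
            isi_cv_sat = 0.25)
  hffS <- f(rmp = 0.8, input_resistance = 37, sag = 0.002,
            tau_membrane = 0.5, capacitance_pf = 0.3,
            rheobase_current = 1.2, ap_threshold = 0.5, ap_amplitude = 0.8,
            ap_halfwidth = 0.02, ahp_amplitude = 0.9, ap_decay = 0.04,
            adp_amplitude = 0, adp_latency = 0,
            first_spike_latency_rheo = 14, spike_count_rheo = 0.2,
            saturating_current = 11, first_spike_latency_sat = 1.2,
            fmax_init = 5, fmax_ss = 3.7, adaptation_ratio = 0.02,
            ap_halfwidth_sat = 0.1, spike_count_sat = 3.1,
            ap_amplitude_sat = 0.9, ahp_amplitude_sat = 0.9,
            isi_cv_sat = 0.02)
  delM <- f(rmp = -64.9, input_resistance = 928, sag = 0.961,
            tau_membrane = 20, capacitance_pf = 15.0,
            rheobase_current = 40.8, ap_threshold = -25.6,
            ap_amplitude = 87.9, ap_halfwidth = 1.46, ahp_amplitude = 25.3,
            ap_decay = 7.9, adp_amplitude = 0, adp_latency = 0,
            first_spike_latency_rheo = 528, spike_count_rheo = 1.4,
            saturating_current = 242, first_spike_latency_sat = 279.0,
            fmax_init = 46, fmax_ss = 21.2, adaptation_ratio = 0.80,
            ap_halfwidth_sat = 2.5, spike_count_sat = 11.0,
            ap_amplitude_sat = 82.9, ahp_amplitude_sat = 23.3,
            isi_cv_sat = 0.15)
  delS <- f(rmp = 1.0, input_resistance = 42, sag = 0.003,
            tau_membrane = 0.8, capacitance_pf = 0.4,
            rheobase_current = 4.3, ap_threshold = 0.6, ap_amplitude = 0.8,
            ap_halfwidth = 0.04, ahp_amplitude = 1.5, ap_decay = 0.5,
            adp_amplitude = 0, adp_latency = 0,
            first_spike_latency_rheo = 25, spike_count_rheo = 0.1,
            saturating_current = 12, first_spike_latency_sat = 20.4,
            fmax_init = 15, fmax_ss = 1.4, adaptation_ratio = 0.04,
            ap_halfwidth_sat = 0.1, spike_count_sat = 0.8,
            ap_amplitude_sat = 0.9, ahp_amplitude_sat = 1.5,
            isi_cv_sat = 0.02)
  tpl <- function(m) list(
    rmp = m[["rmp"]], tau = m[["tau_membrane"]],
    rin = m[["input_resistance"]], sag = m[["sag"]],
    cm = m[["capacitance_pf"]], rheobase = m[["rheobase_current"]],
    thr = m[["ap_threshold"]], amp = m[["ap_amplitude"]],
    hw = m[["ap_halfwidth"]], ahp = m[["ahp_amplitude"]],
    decay = m[["ap_decay"]], adp_amp = m[["adp_amplitude"]],
    adp_lat = m[["adp_latency"]],
    lat_rheo = m[["first_spike_latency_rheo"]],
    lat_sat = m[["first_spike_latency_sat"]],
    n_rheo = max(1, round(m[["spike_count_rheo"]])),
    n_sat = max(1, round(m[["spike_count_sat"]])),
    sat_current = m[["saturating_current"]],
    fmax_init = m[["fmax_init"]], fmax_ss = m[["fmax_ss"]],
    amp_sat = m[["ap_amplitude_sat"]], ahp_sat = m[["ahp_amplitude_sat"]],
    hw_sat = m[["ap_halfwidth_sat"]], isi_init = 1000 / m[["fmax_init"]])
  list(ADP = mk("ADP", 215, adpM, adpS, tpl(adpM)),
       HFF = mk("HFF", 92, hffM, hffS, tpl(hffM)),
       Delayed = mk("Delayed", 85, delM, delS, tpl(delM)))
}

# physical bounds used when truncating feature draws
.featureBounds <- function() {
  lo <- setNames(rep(0, 25), featureRoster())
  lo[c("rmp", "ap_threshold")] <- -Inf
  hi <- setNames(rep(Inf, 25), featureRoster())
  hi["sag"] <- 1
  list(lower = lo, upper = hi)
}

#' Draw a synthetic feature table from subtype specifications
#'
#' Features are drawn independently per feature from truncated Gaussians
#' (latencies, counts, rates and widths bounded below by zero; sag bounded
#' above by one). The afterdepolarization amplitude and latency are forced
#' to zero for non-ADP subtypes. Spike counts are rounded to whole spikes
#' and the saturated count is kept at or above the rheobase count; the
#' adaptation ratio is recomputed as fmax_ss / fmax_init so the feature
#' identity holds exactly.
#'
#' @param specs list of \linkS4class{SubtypeSpec}.
#' @param seed integer RNG seed.
#' @return a \linkS4class{FeatureMatrix} with ground-truth labels.
#' @export
synthFeatureTable <- function(specs = defaultSubtypeSpecs(), seed = 1) {
  stopifnot(length(specs) > 0)
  for (s in specs) validObject(s)
  set.seed(seed)
  b <- .featureBounds()
  blocks <- lapply(specs, function(s) {
    v <- vapply(featureRoster(), function(f) {
      if (s@featureSds[[f]] == 0)
        rep(s@featureMeans[[f]], s@n)
      else
        .rtruncnorm(s@n, s@featureMeans[[f]], s@featureSds[[f]],
                    b$lower[[f]], b$upper[[f]])
    }, numeric(s@n))
    if (s@name != "ADP") v[, c("adp_amplitude", "adp_latency")] <- 0
    v[, "spike_count_rheo"] <- pmax(1, round(v[, "spike_count_rheo"]))
    v[, "spike_count_sat"] <- pmax(v[, "spike_count_rheo"],
                                   round(v[, "spike_count_sat"]))
    v[, "adaptation_ratio"] <- v[, "fmax_ss"] / v[, "fmax_init"]
    v
  })
  vals <- do.call(rbind, blocks)
  labels <- rep(vapply(specs, function(s) s@name, ""),
                vapply(specs, function(s) s@n, 0L))
  rownames(vals) <- sprintf("cell_%04d", seq_len(nrow(vals)))
  new("FeatureMatrix", values = vals,
      ageGroup = rep("juvenile", nrow(vals)), trueLabels = labels)
}

# interspike-interval schedule: first interval 1000/fmax_init ms, then an
# exponential approach toward a plateau solved so the mean of the last
# four intervals is exactly 1000/fmax_ss
.isiSchedule <- function(n, fmaxInit, fmaxSs) {
  if (n < 2L) return(numeric(0))
  isi1 <- 1000 / fmaxInit
  if (n == 2L) return(isi1)
  k <- seq_len(n - 1L)
  tk <- max(1, (n - 1) / 4)
  e <- exp(-(k - 1) / tk)
  target <- 1000 / fmaxSs
  eTail <- mean(utils::tail(e, min(4L, n - 1L)))
  a <- (target - isi1 * eTail) / (1 - eTail)
  a * (1 - e) + isi1 * e
}

# grid-snapped waveform knots for one action potential. The rise time and
# trough time are aligned to the sample grid so the rendered peak and
# trough hit their nominal voltages exactly; the half-width is preserved
# by compensating the fall-to-threshold time (clamped against the decay).
.spikeKnots <- function(hw, decay, dt) {
  decayG <- max(round(decay / dt) * dt, 4 * dt)
  tf1 <- min(1.4 * hw, 0.9 * decayG)
  tr <- max(round((2 * hw - tf1) / dt) * dt, 2 * dt)
  tf1 <- min(max(2 * hw - tr, 2 * dt), 0.9 * decayG)
  decayG <- max(decayG, tf1 + 2 * dt)
  list(tr = tr, tf1 = tf1, decay = decayG, hw = (tr + tf1) / 2)
}

# render one action potential into `v`, evaluating the closed-form
# template piecewise by sample time (quadratic approach, linear rise and
# biphasic fall, optional Gaussian afterdepolarization bump riding on a
# hold at the trough). Returns the updated trace and the index at which
# the waveform ends (trough or ADP-hold end).
.renderSpike <- function(v, dt, tThr, thr, amp, hw, ahp, decay,
                         adpAmp = 0, adpLat = 0, tAppMs = 0.5) {
  kn <- .spikeKnots(hw, decay, dt)
  tPk <- tThr + kn$tr
  tKnee <- tPk + kn$tf1
  tTrough <- tThr + kn$tr + kn$decay
  tEnd <- if (adpAmp > 0 && adpLat > 0) tTrough + 2 * adpLat else tTrough
  n <- length(v)
  i0 <- max(1L, round((tThr - tAppMs) / dt) + 1L)
  i1 <- min(n, round(tEnd / dt) + 1L)
  tt <- (seq.int(i0, i1) - 1) * dt
  troughV <- thr - ahp
  val <- numeric(length(tt))
  seg <- findInterval(tt, c(-Inf, tThr, tPk, tKnee, tTrough + dt / 2))
  val[seg == 1] <- thr - 10 * (tThr - tt[seg == 1])^2 / (2 * tAppMs)
  val[seg == 2] <- thr + amp * (tt[seg == 2] - tThr) / kn$tr
  val[seg == 3] <- thr + amp * (1 - (tt[seg == 3] - tPk) / kn$tf1)
  val[seg == 4] <- thr - ahp * (tt[seg == 4] - tKnee) /
    (kn$decay - kn$tf1)
  if (adpAmp > 0 && adpLat > 0) {
    # plateau sits delta above the trough so the trough stays a distinct
    # minimum under noise; the bump peaks at exactly troughV + adpAmp
    sig <- adpLat / 4
    tail0 <- exp(-8)
    delta <- min(1, adpAmp / 3)
    hold <- seg == 5
    th <- tt[hold] - tTrough
    val[hold] <- troughV + delta * pmin(1, th / 2) + (adpAmp - delta) *
      (exp(-(th - adpLat)^2 / (2 * sig^2)) - tail0) / (1 - tail0)
  }
  v[i0:i1] <- val
  list(v = v, endIdx = i1, troughV = troughV, spanMs = kn$tr + kn$decay)
}

#' Render a synthetic current-clamp sweep ladder with known truth
#'
#' Subthreshold sweeps are RC relaxations with the specified time constant
#' and input resistance (the most hyperpolarized sweep additionally
#' carries a slow sag relaxation); spiking sweeps place action potentials
#' according to a latency/interval schedule interpolated between the
#' rheobase and saturating current steps, each rendered as a smooth
#' closed-form template with exactly the specified threshold, amplitude,
#' half-width, AHP depth, decay time and optional afterdepolarization
#' bump. Gaussian noise of SD \code{noiseSd} mV is added on top. The
#' ground-truth feature vector implied by the realized (grid-aligned)
#' schedule is returned alongside.
#'
#' @param spec a \linkS4class{SubtypeSpec} (its \code{template} drives the
#'   rendering).
#' @param seed RNG seed for the additive noise.
#' @param noiseSd noise SD, mV (0 gives a deterministic trace).
#' @param currents injected-current ladder, pA.
#' @param dt sampling interval, ms.
#' @param stepOnset,stepDuration,postMs protocol timing, ms.
#' @param cellId identifier for the rendered cell.
#' @return list with elements \code{ladder} (\linkS4class{SweepLadder})
#'   and \code{truth} (named 25-feature vector).
#' @export
synthTraceLadder <- function(spec, seed = 1, noiseSd = 0.2,
                             currents = seq(-100, 600, by = 10), dt = 0.1,
                             stepOnset = 100, stepDuration = 800,
                             postMs = 100, cellId = spec@name) {
  validObject(spec)
  p <- spec@template
  if (!length(p)) .stopf("spec has no trace template")
  set.seed(seed)
  step <- diff(currents)[1]
  snap <- function(x) currents[which.min(abs(currents - x))]
  iRheo <- max(snap(p$rheobase), step)          # rheobase must be > 0 pA
  iSat <- max(snap(p$sat_current), iRheo)
  nS <- round((stepOnset + stepDuration + postMs) / dt)
  tms <- (seq_len(nS) - 1) * dt
  onIdx <- round(stepOnset / dt) + 1L
  offIdx <- round((stepOnset + stepDuration) / dt) + 1L
  tApp <- 0.5
  satIsi <- .isiSchedule(p$n_sat, p$fmax_init, p$fmax_ss)

  schedule <- function(I) {
    # threshold times (ms from trace start) for current step I
    if (I < iRheo) return(numeric(0))
    fr <- if (iSat > iRheo) min(1, (I - iRheo) / (iSat - iRheo)) else 1
    lat <- p$lat_rheo + fr * (p$lat_sat - p$lat_rheo)
    if (I >= iSat) {
      n <- p$n_sat; isis <- satIsi
    } else {
      n <- min(p$n_sat - 1L,
               max(p$n_rheo, floor(p$n_rheo + fr * (p$n_sat - p$n_rheo))))
      isis <- if (n >= 2L)
        rep((stepDuration - lat - 20) / (n - 1 + 0.5), n - 1L)
      else numeric(0)
    }
    tt <- stepOnset + lat + c(0, cumsum(isis))
    # truncate spikes whose waveform would overflow the step
    keep <- tt + 2 * p$hw + p$decay + 2 < stepOnset + stepDuration
    if (!all(keep)) .warnf("schedule overflow: truncating %d spike(s)",
                           sum(!keep))
    round(tt[keep] / dt) * dt                   # align to sample grid
  }

  useSat <- function(I) I >= iSat
  minI <- min(currents)
  renderSweep <- function(I) {
    v <- rep(p$rmp, nS)
    tThrs <- schedule(I)
    if (!length(tThrs)) {                       # subthreshold / hyperpol
      dss <- I * p$rin / 1000
      tIn <- tms[onIdx:offIdx] - stepOnset
      v[onIdx:offIdx] <- p$rmp + dss * (1 - exp(-tIn / p$tau))
      if (I == minI && I < 0 && p$sag < 1) {
        dpk <- (p$rmp + dss) / p$sag - p$rmp
        t1 <- 300; tauSag <- 80
        late <- tIn > t1
        v[onIdx:offIdx] <- p$rmp + dpk * (1 - exp(-tIn / p$tau)) +
          ifelse(late, (dss - dpk) * (1 - exp(-(tIn - t1) / tauSag)), 0)
      }
    } else {
      sat <- useSat(I)
      amp <- if (sat) p$amp_sat else p$amp
      hw <- if (sat) p$hw_sat else p$hw
      ahp <- if (sat) p$ahp_sat else p$ahp
      appDepth <- 10 * tApp / 2
      # linear pre-spike ramp from rest to the approach start
      tApp1 <- tThrs[1] - tApp
      ii <- onIdx:min(round(tApp1 / dt) + 1L, nS)
      v[ii] <- p$rmp + (p$thr - appDepth - p$rmp) *
        (tms[ii] - stepOnset) / (tApp1 - stepOnset)
      prevEnd <- NULL
      for (k in seq_along(tThrs)) {
        gap <- if (k < length(tThrs)) tThrs[k + 1] - tThrs[k] else Inf
        allowAdp <- p$adp_amp > 0 &&
          gap - (2 * hw + p$decay) > 2 * p$adp_lat + 5
        rs <- .renderSpike(v, dt, tThrs[k], p$thr, amp, hw, ahp, p$decay,
                           adpAmp = if (allowAdp) p$adp_amp else 0,
                           adpLat = p$adp_lat, tAppMs = tApp)
        v <- rs$v
        # recovery ramp toward the next approach start (slope < 10 mV/ms)
        from <- rs$endIdx
        toT <- if (k < length(tThrs)) tThrs[k + 1] - tApp
               else stepOnset + stepDuration
        to <- min(round(toT / dt) + 1L, offIdx)
        target <- if (k < length(tThrs)) p$thr - appDepth else p$thr - 6
        if (to > from) {
          ii <- from:to
          depth <- target - v[from]
          avail <- tms[to] - tms[from]
          kickT <- min(2, 0.25 * avail)
          delta <- 0.5 * kickT      # initial 0.5 mV/ms kick off the trough
          if (depth > delta && (depth - delta) / (avail - kickT) <= 8) {
            th <- tms[ii] - tms[from]
            v[ii] <- v[from] + ifelse(th <= kickT, 0.5 * th,
              delta + (depth - delta) * (th - kickT) / (avail - kickT))
          } else {
            v[ii] <- v[from] + depth * (tms[ii] - tms[from]) / avail
          }
        }
      }
    }
    # post-step relaxation back to rest
    if (offIdx < nS) {
      ii <- offIdx:nS
      v[ii] <- p$rmp + (v[offIdx] - p$rmp) *
        exp(-(tms[ii] - tms[offIdx]) / p$tau)
    }
    v
  }

  volt <- t(vapply(currents, renderSweep, numeric(nS)))
  if (noiseSd > 0)
    volt <- volt + matrix(rnorm(length(volt), 0, noiseSd), nrow(volt))
  ladder <- SweepLadder(cellId = cellId, currents = currents,
                        voltage = volt, dt = dt, stepOnset = stepOnset,
                        stepDuration = stepDuration,
                        capacitancePf = p$cm, ageGroup = "juvenile")
  # ground truth from the realized grid-aligned schedules
  thrSat <- schedule(iSat)
  thrRheo <- schedule(iRheo)
  isisSat <- diff(thrSat)
  fi <- if (length(isisSat))
    1000 / min(isisSat[seq_len(min(2, length(isisSat)))]) else NA_real_
  fs <- if (length(isisSat))
    1000 / mean(utils::tail(isisSat, 4)) else NA_real_
  knR <- .spikeKnots(p$hw, p$decay, dt)
  knS <- .spikeKnots(p$hw_sat, p$decay, dt)
  truth <- setNames(numeric(25), featureRoster())
  truth[] <- c(p$rmp, p$rin, p$sag, p$tau, p$cm,
               iRheo, p$thr, p$amp, knR$hw, p$ahp, knR$decay,
               if (p$adp_amp > 0) c(p$adp_amp, p$adp_lat) else c(0, 0),
               thrRheo[1] - stepOnset, length(thrRheo),
               iSat, thrSat[1] - stepOnset, fi, fs, fs / fi,
               knS$hw, length(thrSat), p$amp_sat, p$ahp_sat,
               if (length(isisSat) >= 2)
                 sd(isisSat) / mean(isisSat) else 0)
  list(ladder = ladder, truth = truth)
}

#' Simulate a photostimulation session
#'
#' Each presynaptic source occupies a disc-shaped patch of the scan grid
#' within which a laser flash triggers an action potential with
#' probability \code{pInside} per trial (\code{pOutside} elsewhere).
#' Connected sources contribute IPSCs at the virtual postsynaptic cell;
#' per-source amplitudes are drawn uniformly from \code{amplitudeRangePa}
#' and event amplitudes jitter around them.
#'
#' @param nSources number of ChR2-expressing source cells.
#' @param footprintRadiusPx disc radius, pixels.
#' @param connectionProb probability that a source is connected to the
#'   postsynaptic cell.
#' @param amplitudeRangePa IPSC amplitude range, pA.
#' @param trials trials per pixel.
#' @param rows,cols,pitch grid geometry.
#' @param pInside,pOutside per-trial spike probabilities.
#' @param noiseSdPa additive amplitude jitter, pA.
#' @param seed RNG seed.
#' @return list: \code{apGrids} (one \linkS4class{PhotostimGrid} per
#'   source), \code{ipscGrid} (\code{"ipsc"} grid at the postsynaptic
#'   cell), \code{truth} (source centers, radii, connectivity,
#'   amplitudes).
#' @export
synthPhotostimSession <- function(nSources, footprintRadiusPx = 1,
                                  connectionProb = 1,
                                  amplitudeRangePa = c(8, 218), trials = 3,
                                  rows = 32, cols = 32, pitch = 16,
                                  pInside = 0.95, pOutside = 0.01,
                                  noiseSdPa = 1, seed = 1) {
  set.seed(seed)
  centers <- if (nSources > 0)
    cbind(sample(seq(3, rows - 2), nSources, replace = TRUE),
          sample(seq(3, cols - 2), nSources, replace = TRUE))
  else matrix(0, 0, 2)
  connected <- runif(nSources) < connectionProb
  srcAmp <- runif(nSources, amplitudeRangePa[1], amplitudeRangePa[2])
  discMask <- function(ctr) {
    outer(seq_len(rows), seq_len(cols), function(i, j)
      (i - ctr[1])^2 + (j - ctr[2])^2 <= footprintRadiusPx^2)
  }
  apGrids <- lapply(seq_len(nSources), function(s) {
    m <- discMask(centers[s, ])
    pr <- ifelse(m, pInside, pOutside)
    vals <- array(rbinom(rows * cols * trials, 1, rep(pr, trials)),
                  dim = c(rows, cols, trials))
    new("PhotostimGrid", mode = "ap_success", values = vals, pitch = pitch)
  })
  ipsc <- array(0, dim = c(rows, cols, trials))
  for (s in seq_len(nSources)) {
    if (!connected[s]) next
    m <- discMask(centers[s, ])
    for (tr in seq_len(trials)) {
      fired <- m & matrix(runif(rows * cols) < pInside, rows)
      amp <- pmax(0, srcAmp[s] + rnorm(sum(fired), 0, noiseSdPa))
      cur <- ipsc[, , tr]
      cur[fired] <- pmax(cur[fired], amp)   # largest input dominates
      ipsc[, , tr] <- cur
    }
  }
  ipscGrid <- new("PhotostimGrid", mode = "ipsc", values = ipsc,
                  pitch = pitch)
  list(apGrids = apGrids, ipscGrid = ipscGrid,
       truth = list(centers = centers, radiusPx = footprintRadiusPx,
                    connected = connected, amplitudes = srcAmp))
}

#' Simulate a Patch-seq dataset and its reference atlas
#'
#' Counts follow cluster-structured negative binomials. A designated
#' subset of genes loads on a latent per-cell depth factor in the
#' reference (and is highly expressed everywhere, making it ubiquitous in
#' the Patch-seq cells), so the depth-correlated gene set used for PC1
#' normalization is recoverable. A configurable number of Patch-seq cells
#' is pushed below the total-read and alignment-rate QC floors.
#'
#' @param nCells Patch-seq cells.
#' @param nGenes genes shared by both datasets.
#' @param qcFailReads,qcFailAlign cells forced below the read floor /
#'   alignment floor.
#' @param nDepthGenes size of the designated depth-correlated gene set.
#' @param nRefCells,nRefClusters reference-atlas geometry.
#' @param seed RNG seed.
#' @return list: \code{patchseq} (\linkS4class{PatchSeqExperiment}),
#'   \code{reference} (SummarizedExperiment with \code{cluster} and
#'   \code{molecular_count} colData), \code{truth} (depth-gene names,
#'   cluster of each Patch-seq cell, designated QC failures).
#' @export
synthPatchseq <- function(nCells = 69, nGenes = 800, qcFailReads = 5,
                          qcFailAlign = 3, nDepthGenes = 150,
                          nRefCells = 500, nRefClusters = 4, seed = 1) {
  stopifnot(qcFailReads + qcFailAlign <= nCells,
            nDepthGenes <= nGenes)
  set.seed(seed)
  genes <- sprintf("gene_%04d", seq_len(nGenes))
  depthGenes <- genes[seq_len(nDepthGenes)]
  # cluster-specific mean profiles
  base <- exp(rnorm(nGenes, 1.0, 1.2))
  base[seq_len(nDepthGenes)] <- exp(rnorm(nDepthGenes, 3.0, 0.3))
  clustEff <- matrix(exp(rnorm(nGenes * nRefClusters, 0, 0.8)), nGenes)
  # reference cells
  refCl <- sort(rep_len(seq_len(nRefClusters), nRefCells))
  refDepth <- exp(rnorm(nRefCells, 0, 0.35))
  mu <- clustEff[, refCl] * base
  mu[seq_len(nDepthGenes), ] <-
    outer(base[seq_len(nDepthGenes)], refDepth)   # depth drives these only
  refCounts <- matrix(rnbinom(nGenes * nRefCells, mu = mu, size = 4),
                      nGenes, nRefCells,
                      dimnames = list(genes,
                                      sprintf("ref_%04d", seq_len(nRefCells))))
  reference <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = refCounts),
    colData = S4Vectors::DataFrame(
      cluster = paste0("cluster_", refCl),
      molecular_count = round(1500 + 800 * refDepth +
                                rnorm(nRefCells, 0, 30))))
  # patch-seq cells: drawn from the same cluster profiles
  psCl <- sample(seq_len(nRefClusters), nCells, replace = TRUE)
  psDepth <- exp(rnorm(nCells, 0, 0.35))
  muPs <- clustEff[, psCl] * base
  muPs[seq_len(nDepthGenes), ] <-
    outer(base[seq_len(nDepthGenes)], psDepth)
  psCounts <- matrix(rnbinom(nGenes * nCells, mu = muPs, size = 4),
                     nGenes, nCells,
                     dimnames = list(genes,
                                     sprintf("ps_%03d", seq_len(nCells))))
  psCounts[seq_len(nDepthGenes), ] <-
    psCounts[seq_len(nDepthGenes), , drop = FALSE] + 1L  # ubiquitous
  totalReads <- round(4e6 * exp(rnorm(nCells, 0, 0.5)))
  alignment <- pmin(0.98, pmax(0.51, rnorm(nCells, 0.8, 0.08)))
  failR <- seq_len(qcFailReads)
  failA <- qcFailReads + seq_len(qcFailAlign)
  totalReads[failR] <- round(runif(qcFailReads, 1e4, 75499))
  alignment[failA] <- runif(qcFailAlign, 0.2, 0.49)
  patchseq <- PatchSeqExperiment(psCounts, totalReads, alignment)
  list(patchseq = patchseq, reference = reference,
       truth = list(depthGenes = depthGenes,
                    cluster = paste0("cluster_", psCl),
                    lowReads = colnames(psCounts)[failR],
                    lowAlignment = colnames(psCounts)[failA]))
}
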