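#' Compute the optical footprint of a photostimulated cell
#'
#' A pixel belongs to the footprint when the laser spot evoked an action
#' potential in at least \code{minTrialsFraction} of the trials (2/3 by
#' default). The footprint area is the pixel count times the single-pixel
#' area (pitch squared; 256 um^2 at the default 16 um pitch).
#'
#' @param grid a \linkS4class{PhotostimGrid} in \code{"ap_success"} mode.
#' @param minTrialsFraction minimum fraction of successful trials.
#' @return a \linkS4class{PixelMap} of kind \code{"footprint"}.
#' @export
computeFootprint <- function(grid, minTrialsFraction = 2 / 3) {
  if (grid@mode != "ap_success")
    .stopf("footprints need an ap_success grid")
  succ <- apply(grid@values, c(1, 2), mean)
  mask <- succ >= minTrialsFraction - 1e-12
  d <- dim(mask)
  new("PixelMap", kind = "footprint", mask = mask,
      amplitude = matrix(NA_real_, d[1], d[2]),
      normalized = matrix(NA_real_, d[1], d[2]), pitch = grid@pitch)
}

#' Compute an inhibitory input map
#'
#' A pixel is active when an IPSC event (amplitude above the detection
#' threshold) occurred in at least \code{minTrialsFraction} of the
#' trials; its amplitude is the mean over event trials and the normalized
#' map divides by the maximum pixel amplitude. The detection threshold is
#' the larger of \code{floorPa} and \code{noiseMult} times the baseline
#' noise SD estimated from sub-floor samples.
#'
#' @param grid a \linkS4class{PhotostimGrid} in \code{"ipsc"} mode
#'   (amplitudes in pA, 0 = no event).
#' @param minTrialsFraction minimum fraction of event trials.
#' @param floorPa absolute amplitude floor, pA (the smallest evoked IPSC
#'   reported in these experiments is 8 pA, so 5 pA is conservative).
#' @param noiseMult multiplier on the baseline noise SD.
#' @return a \linkS4class{PixelMap} of kind \code{"input"}.
#' @export
computeInputMap <- function(grid, minTrialsFraction = 2 / 3, floorPa = 5,
                            noiseMult = 3) {
  if (grid@mode != "ipsc") .stopf("input maps need an ipsc grid")
  v <- grid@values
  sub <- v[v > 0 & v < floorPa]
  thr <- max(floorPa, if (length(sub) > 1) noiseMult * sd(sub) else 0)
  ev <- v > thr
  frac <- apply(ev, c(1, 2), mean)
  mask <- frac >= minTrialsFraction - 1e-12
  amp <- matrix(NA_real_, dim(v)[1], dim(v)[2])
  for (i in seq_len(dim(v)[1])) for (j in seq_len(dim(v)[2]))
    if (mask[i, j]) amp[i, j] <- mean(v[i, j, ev[i, j, ]])
  nrm <- matrix(NA_real_, dim(v)[1], dim(v)[2])
  if (any(mask)) nrm[mask] <- amp[mask] / max(amp[mask])
  new("PixelMap", kind = "input", mask = mask, amplitude = amp,
      normalized = nrm, pitch = grid@pitch)
}

#' Count discrete clusters of active pixels in a map
#'
#' Uses 4-connectivity on the grid; disjoint clusters indicate convergent
#' input from more than one presynaptic cell.
#'
#' @param map a \linkS4class{PixelMap}.
#' @return number of connected components.
#' @export
countClusters <- function(map) {
  max(.labelComponents(map@mask), 0L)
}

#' Summarize footprint and input-field sizes across cells
#'
#' @param footprints list of footprint \linkS4class{PixelMap}s.
#' @param inputs list of input \linkS4class{PixelMap}s.
#' @return list with per-group medians and IQRs of areas (um^2), the
#'   input/footprint ratio of medians, and the sample sizes. No attempt
#'   is made to infer the number of converging presynaptic cells.
#' @export
convergenceSummary <- function(footprints, inputs) {
  stopifnot(length(footprints) > 0, length(inputs) > 0)
  fa <- vapply(footprints, areaUm2, 0)
  ia <- vapply(inputs, areaUm2, 0)
  list(
    footprint = list(median = median(fa), iqr = unname(
      quantile(fa, 0.75) - quantile(fa, 0.25)), n = length(fa)),
    input = list(median = median(ia), iqr = unname(
      quantile(ia, 0.75) - quantile(ia, 0.25)), n = length(ia)),
    medianRatio = median(ia) / median(fa))
}

#' Nernst equilibrium potential
#'
#' \eqn{E = (RT / zF) \ln([X]_{out} / [X]_{in})}, returned in millivolts.
#'
#' @param valence ionic valence z (nonzero integer; -1 for chloride).
#' @param concIn,concOut intracellular and extracellular concentrations
#'   (any common unit, typically mM).
#' @param temperatureC temperature in degrees Celsius.
#' @return equilibrium potential, mV.
#' @examples
#' nernstPotential(-1, 145, 135, 24)  # ~ +1.8 mV for chloride
#' @export
nernstPotential <- function(valence, concIn, concOut, temperatureC = 24) {
  if (valence == 0) .stopf("valence must be nonzero")
  if (concIn <= 0 || concOut <= 0)
    .stopf("concentrations must be positive")
  R <- 8.314462618; F <- 96485.33212
  TK <- temperatureC + 273.15
  1000 * R * TK / (valence * F) * log(concOut / concIn)
}

# chloride ions contributed per formula unit
.chlorideStoichiometry <- c(
  NaCl = 1, KCl = 1, CaCl2 = 2, MgCl2 = 2, CsCl = 1, LiCl = 1, HCl = 1,
  choline_chloride = 1, TEA_Cl = 1, NH4Cl = 1)

#' Total chloride concentration of a solution recipe
#'
#' @param recipe named numeric vector or two-column data.frame
#'   (salt, mM) of chloride-bearing salts; salts without chloride may be
#'   omitted. Recognized salts: NaCl, KCl, CaCl2, MgCl2, CsCl, LiCl, HCl,
#'   choline_chloride, TEA_Cl, NH4Cl.
#' @return total chloride, mM.
#' @examples
#' solutionChloride(c(KCl = 140, NaCl = 4, CaCl2 = 0.5))  # 145 mM
#' @export
solutionChloride <- function(recipe) {
  if (is.data.frame(recipe))
    recipe <- setNames(recipe[[2]], recipe[[1]])
  if (!length(recipe)) return(0)
  unknown <- setdiff(names(recipe), names(.chlorideStoichiometry))
  if (length(unknown))
    .stopf("unknown salt(s): %s", paste(unknown, collapse = ", "))
  sum(recipe * .chlorideStoichiometry[names(recipe)])
}
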