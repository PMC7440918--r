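#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom stats aggregate coef cor cor.test lm median p.adjust prcomp
#'   quantile rbinom rnbinom rnorm runif sd setNames TukeyHSD aov var
NULL

#' SweepLadder: one cell's current-clamp step protocol
#'
#' Container for the voltage responses of a single neuron to a ladder of
#' square current steps (the standard protocol is 800 ms steps from -100 to
#' +600 pA in 10 pA increments, sampled at 10 kHz). Rows of the voltage
#' matrix are sweeps ordered by increasing injected current.
#'
#' @slot cellId single character identifier.
#' @slot dt sampling interval in ms (0.1 ms at 10 kHz).
#' @slot currents injected current per sweep, pA; strictly increasing with
#'   a constant increment.
#' @slot voltage sweeps x samples matrix of membrane voltage, mV.
#' @slot stepOnset time of current-step onset, ms from sweep start.
#' @slot stepDuration current-step duration, ms.
#' @slot capacitancePf amplifier-reported membrane capacitance, pF
#'   (\code{NA_real_} when absent).
#' @slot ageGroup \code{"juvenile"} or \code{"adult"}.
#' @slot location optional named list (nucleus, bregma, axis classes).
#'
#' @export
setClass("SweepLadder",
  representation(
    cellId       = "character",
    dt           = "numeric",
    currents     = "numeric",
    voltage      = "matrix",
    stepOnset    = "numeric",
    stepDuration = "numeric",
    capacitancePf = "numeric",
    ageGroup     = "character",
    location     = "list"
  ),
  prototype(
    dt = 0.1, stepOnset = 100, stepDuration = 800,
    capacitancePf = NA_real_, ageGroup = "juvenile", location = list()
  )
)

setValidity("SweepLadder", function(object) {
  msg <- character()
  if (length(object@cellId) != 1L) msg <- c(msg, "cellId must be length 1")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  nsw <- length(object@currents)
  if (nsw < 1L) msg <- c(msg, "ladder must contain at least one sweep")
  if (nrow(object@voltage) != nsw)
    msg <- c(msg, "voltage must have one row per sweep")
  if (nsw >= 2L) {
    dc <- diff(object@currents)
    if (any(dc <= 0)) msg <- c(msg, "currents must be strictly increasing")
    else if (max(dc) - min(dc) > 1e-6 * max(abs(dc)))
      msg <- c(msg, sprintf(
        "non-uniform current increment at sweep %d",
        which.max(abs(dc - dc[1])) + 1L))
  }
  needed <- (object@stepOnset + object@stepDuration) / object@dt
  if (ncol(object@voltage) < needed)
    msg <- c(msg, "traces shorter than step_onset + step_duration")
  if (anyNA(object@voltage) || any(!is.finite(object@voltage)))
    msg <- c(msg, "voltage traces must be finite")
  if (length(msg)) msg else TRUE
})

#' LadderQC: resting-potential quality report for a SweepLadder
#'
#' Records the mean and standard deviation of the per-sweep baseline
#' (resting membrane potential) and whether the cell passes the standard
#' exclusion rules: depolarized cells (RMP above -50 mV) and unstable cells
#' (baseline SD above 6 mV) are rejected.
#'
#' @slot cellId cell identifier.
#' @slot rmpMean mean of per-sweep baselines, mV.
#' @slot rmpSd standard deviation of per-sweep baselines, mV.
#' @slot passed TRUE iff no exclusion reason applies.
#' @slot reasons zero or more of \code{"rmp_depolarized"},
#'   \code{"rmp_unstable"}.
#' @export
setClass("LadderQC",
  representation(cellId = "character", rmpMean = "numeric",
                 rmpSd = "numeric", passed = "logical",
                 reasons = "character"))

setValidity("LadderQC", function(object) {
  if (object@passed != (length(object@reasons) == 0L))
    "passed must be TRUE exactly when reasons is empty" else TRUE
})

#' FeatureMatrix: cells x electrophysiological features
#'
#' @slot values numeric matrix, one row per cell, one named column per
#'   feature (the default roster has 25 features, see
#'   \code{\link{featureRoster}}).
#' @slot ageGroup character vector, per cell.
#' @slot trueLabels generator ground-truth subtype per cell for synthetic
#'   cohorts; length zero otherwise.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", ageGroup = "character",
                 trueLabels = "character"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "feature columns must be uniquely named")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "cells must be uniquely named")
  if (length(object@ageGroup) && length(object@ageGroup) != nrow(v))
    msg <- c(msg, "ageGroup must have one entry per cell")
  if (length(object@trueLabels) && length(object@trueLabels) != nrow(v))
    msg <- c(msg, "trueLabels must have one entry per cell")
  if (length(msg)) msg else TRUE
})

#' PreprocessReport: provenance of feature preprocessing
#'
#' @slot logFeatures features that were log-transformed.
#' @slot outlierIds cells discarded by the 5 x IQR rule.
#' @slot featureMin,featureRange per-feature min and range used for
#'   min-max scaling (on the transformed scale, outliers removed).
#' @slot droppedFeatures constant columns dropped before scaling.
#' @export
setClass("PreprocessReport",
  representation(logFeatures = "character", outlierIds = "character",
                 featureMin = "numeric", featureRange = "numeric",
                 droppedFeatures = "character"))

#' ClusterModel: PCA + Gaussian-mixture subtype model
#'
#' @slot nPcs number of principal components selected by cross-validated
#'   BIC.
#' @slot loadings features x nPcs orthonormal loading matrix.
#' @slot explainedVar fraction of total variance per retained component.
#' @slot center per-feature means removed before projection.
#' @slot gmm list with elements \code{K}, \code{weights}, \code{means}
#'   (nPcs x K), \code{covariances} (nPcs x nPcs x K).
#' @slot bicPca cross-validated BIC per candidate PCA order.
#' @slot bicGmm cross-validated BIC per candidate number of mixture
#'   components.
#' @slot labels integer cluster label per cell (1..K).
#' @slot clusterNames optional map from label to subtype name.
#' @slot seed RNG seed used for fold assignment.
#' @export
setClass("ClusterModel",
  representation(nPcs = "integer", loadings = "matrix",
                 explainedVar = "numeric", center = "numeric",
                 gmm = "list", bicPca = "numeric", bicGmm = "numeric",
                 labels = "integer", clusterNames = "character",
                 seed = "integer"))

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (length(object@gmm)) {
    w <- object@gmm$weights
    if (abs(sum(w) - 1) > 1e-6) msg <- c(msg, "mixture weights must sum to 1")
    K <- object@gmm$K
    if (length(object@labels) &&
        (min(object@labels) < 1L || max(object@labels) > K))
      msg <- c(msg, "labels must lie in 1..K")
  }
  if (ncol(object@loadings)) {
    g <- crossprod(object@loadings)
    if (max(abs(g - diag(ncol(g)))) > 1e-6)
      msg <- c(msg, "loadings must have orthonormal columns")
  }
  if (length(msg)) msg else TRUE
})

#' PhotostimGrid: trial-resolved photostimulation response grid
#'
#' A 32 x 32 scanning-laser session at 16 um pitch (510 x 510 um field,
#' 0.26 mm^2), three trials per pixel by default. In \code{"ap_success"}
#' mode values are 0/1 action-potential successes recorded in the
#' ChR2-expressing cell; in \code{"ipsc"} mode they are evoked IPSC
#' amplitudes in pA at a postsynaptic cell (0 = no event).
#'
#' @slot mode \code{"ap_success"} or \code{"ipsc"}.
#' @slot values rows x cols x trials numeric array.
#' @slot pitch pixel pitch, um.
#' @slot laserPowerUw laser power, uW.
#' @slot flashMs flash duration, ms.
#' @export
setClass("PhotostimGrid",
  representation(mode = "character", values = "array", pitch = "numeric",
                 laserPowerUw = "numeric", flashMs = "numeric"),
  prototype(pitch = 16, laserPowerUw = 9, flashMs = 4))

setValidity("PhotostimGrid", function(object) {
  msg <- character()
  if (!object@mode %in% c("ap_success", "ipsc"))
    msg <- c(msg, "mode must be 'ap_success' or 'ipsc'")
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a rows x cols x trials array")
  else if (dim(object@values)[3] < 1L) msg <- c(msg, "need at least 1 trial")
  if (object@pitch <= 0) msg <- c(msg, "pitch must be positive")
  if (object@mode == "ap_success" &&
      !all(object@values %in% c(0, 1)))
    msg <- c(msg, "ap_success values must be 0/1")
  if (length(msg)) msg else TRUE
})

#' PixelMap: footprint or input map derived from a PhotostimGrid
#'
#' @slot kind \code{"footprint"} (binary optical footprint) or
#'   \code{"input"} (IPSC input map).
#' @slot mask logical matrix of included pixels.
#' @slot amplitude mean event amplitude per included pixel, pA (input maps;
#'   all-NA for footprints).
#' @slot normalized amplitude / max amplitude, in [0, 1] (input maps).
#' @slot pitch pixel pitch, um.
#' @export
setClass("PixelMap",
  representation(kind = "character", mask = "matrix",
                 amplitude = "matrix", normalized = "matrix",
                 pitch = "numeric"))

setValidity("PixelMap", function(object) {
  msg <- character()
  if (!object@kind %in% c("footprint", "input"))
    msg <- c(msg, "kind must be 'footprint' or 'input'")
  if (object@kind == "input" && any(object@mask)) {
    nz <- object@normalized[object@mask]
    if (any(!is.na(nz) & (nz < 0 | nz > 1)))
      msg <- c(msg, "normalized amplitudes must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' PatchSeqExperiment: gene x cell counts with sequencing QC metadata
#'
#' A \linkS4class{SummarizedExperiment} whose \code{"counts"} assay holds
#' nonnegative integer gene-level counts and whose \code{colData} carries
#' the per-cell \code{total_reads} and \code{alignment_rate} used by
#' \code{\link{qcFilter}}.
#'
#' @export
setClass("PatchSeqExperiment", contains = "SummarizedExperiment")

setValidity("PatchSeqExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else if (any(SummarizedExperiment::assay(object, "counts") < 0))
    msg <- c(msg, "counts must be nonnegative")
  cd <- SummarizedExperiment::colData(object)
  for (f in c("total_reads", "alignment_rate"))
    if (!f %in% colnames(cd)) msg <- c(msg, paste("colData needs", f))
  if ("alignment_rate" %in% colnames(cd)) {
    ar <- cd$alignment_rate
    if (any(ar < 0 | ar > 1)) msg <- c(msg, "alignment_rate must be in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' SubtypeSpec: generative specification of one neuron subtype
#'
#' Holds the per-feature population mean and SD used to draw synthetic
#' feature tables, plus the closed-form trace-template parameters used to
#' render synthetic sweep ladders (resting potential, membrane time
#' constant, input resistance, rheobase, action-potential shape, optional
#' afterdepolarization bump, and the saturated-train schedule).
#'
#' @slot name subtype name (\code{"ADP"}, \code{"HFF"} or
#'   \code{"Delayed"}).
#' @slot n default number of cells.
#' @slot featureMeans,featureSds named numeric vectors over the feature
#'   roster.
#' @slot template named list of trace-template parameters.
#' @export
setClass("SubtypeSpec",
  representation(name = "character", n = "integer",
                 featureMeans = "numeric", featureSds = "numeric",
                 template = "list"))

setValidity("SubtypeSpec", function(object) {
  msg <- character()
  if (object@n < 1L) msg <- c(msg, "n must be positive")
  if (!identical(names(object@featureMeans), names(object@featureSds)))
    msg <- c(msg, "featureMeans and featureSds must align")
  if (any(object@featureSds < 0)) msg <- c(msg, "SDs must be nonnegative")
  tpl <- object@template
  if (length(tpl)) {
    if (!is.null(tpl$isi_init) && tpl$isi_init < 2)
      msg <- c(msg, "schedule would violate the 2 ms absolute refractory period")
  }
  if (length(msg)) msg else TRUE
})
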