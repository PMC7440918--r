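#' @rdname SweepLadder-class
#' @param object,x a \linkS4class{SweepLadder}.
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname SweepLadder-class
#' @export
setGeneric("sweepCurrents", function(x) standardGeneric("sweepCurrents"))

#' @rdname SweepLadder-class
#' @export
setGeneric("sweepVoltages", function(x) standardGeneric("sweepVoltages"))

#' @rdname PixelMap-class
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' @rdname PixelMap-class
#' @export
setGeneric("areaUm2", function(x) standardGeneric("areaUm2"))

#' @rdname ClusterModel-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

setMethod("cellId", "SweepLadder", function(x) x@cellId)
setMethod("sweepCurrents", "SweepLadder", function(x) x@currents)
setMethod("sweepVoltages", "SweepLadder", function(x) x@voltage)
setMethod("nPixels", "PixelMap", function(x) sum(x@mask))
setMethod("areaUm2", "PixelMap", function(x) sum(x@mask) * x@pitch^2)
setMethod("clusterLabels", "ClusterModel", function(x) x@labels)
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

setMethod("show", "SweepLadder", function(object) {
  cat(sprintf(
    "SweepLadder '%s': %d sweeps (%g..%g pA, step %g pA), dt %g ms\n",
    object@cellId, length(object@currents), min(object@currents),
    max(object@currents),
    if (length(object@currents) > 1) diff(object@currents)[1] else NA,
    object@dt))
  cat(sprintf("  step: onset %g ms, duration %g ms; %d samples/sweep\n",
              object@stepOnset, object@stepDuration, ncol(object@voltage)))
})

setMethod("show", "LadderQC", function(object) {
  cat(sprintf("LadderQC '%s': RMP %.1f +/- %.2f mV -> %s%s\n",
              object@cellId, object@rmpMean, object@rmpSd,
              if (object@passed) "PASS" else "FAIL",
              if (length(object@reasons))
                paste0(" (", paste(object@reasons, collapse = ", "), ")")
              else ""))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d cells x %d features%s\n",
              nrow(object@values), ncol(object@values),
              if (length(object@trueLabels)) " (with ground-truth labels)"
              else ""))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: %d PCs, K = %d components, %d cells\n",
              object@nPcs, object@gmm$K, length(object@labels)))
  if (length(object@clusterNames))
    cat("  clusters:", paste(object@clusterNames, collapse = ", "), "\n")
})

setMethod("show", "PhotostimGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("PhotostimGrid [%s]: %d x %d pixels, %d trials, pitch %g um\n",
              object@mode, d[1], d[2], d[3], object@pitch))
})

setMethod("show", "PixelMap", function(object) {
  cat(sprintf("%s map: %d pixels, area %g um^2\n",
              object@kind, nPixels(object), areaUm2(object)))
})
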