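#' Scale a sampled section count to a whole-structure estimate
#'
#' When counting covered \code{sampledPercent} percent of the structure,
#' the estimated total is \code{counted / sampledPercent * 100} (the
#' published formulas (counted/40) x 100 and (counted/9) x 100 are the
#' 40 percent immunostaining and 9 percent in-situ sampling cases).
#'
#' @param counted number of counted cells.
#' @param sampledPercent sampled fraction, percent (0 < x <= 100).
#' @return list: \code{total} (unrounded), \code{display} (rounded).
#' @export
scaleSectionCounts <- function(counted, sampledPercent) {
  if (sampledPercent <= 0 || sampledPercent > 100)
    .stopf("sampledPercent must lie in (0, 100]")
  total <- counted / sampledPercent * 100
  list(total = total, display = round(total))
}

#' Ratio of two marker-positive populations, in percent
#'
#' @param countA,countB cell counts (denominator must be positive).
#' @return 100 * countA / countB.
#' @export
markerRatio <- function(countA, countB) {
  if (countB <= 0) .stopf("denominator count must be positive")
  100 * countA / countB
}

#' Classify neurotransmitter co-expression of Sst-positive cells
#'
#' Each cell carries presence calls for the vesicular GABA transporter
#' (Slc32a1), the vesicular glutamate transporter 2 (Slc17a6) and the
#' dopamine transporter (Slc6a3). Categories: GABA (Slc32a1 only), Glu
#' (Slc17a6 only), GABA+Glu, DA (Slc6a3 only), other (all remaining
#' marker-positive combinations, including triple positives), none.
#'
#' @param calls data.frame with logical columns \code{Slc32a1},
#'   \code{Slc17a6}, \code{Slc6a3} (one row per Sst-positive cell).
#' @return list: \code{category} per cell, \code{proportions} (percent
#'   per category, summing to 100), \code{combinations} (full
#'   combination table).
#' @export
classifyCoexpression <- function(calls) {
  need <- c("Slc32a1", "Slc17a6", "Slc6a3")
  stopifnot(all(need %in% names(calls)))
  g <- as.logical(calls$Slc32a1)
  e <- as.logical(calls$Slc17a6)
  d <- as.logical(calls$Slc6a3)
  cat <- ifelse(g & !e & !d, "GABA",
         ifelse(!g & e & !d, "Glu",
         ifelse(g & e & !d, "GABA+Glu",
         ifelse(!g & !e & d, "DA",
         ifelse(!g & !e & !d, "none", "other")))))
  if (any(cat == "none")) .warnf("%d cell(s) express no marker",
                                 sum(cat == "none"))
  lev <- c("GABA", "Glu", "GABA+Glu", "DA", "other", "none")
  prop <- 100 * table(factor(cat, lev)) / length(cat)
  combos <- table(Slc32a1 = g, Slc17a6 = e, Slc6a3 = d)
  list(category = cat, proportions = prop, combinations = combos)
}

#' Rostro-caudal density profile of a marker
#'
#' @param records data.frame with columns \code{bregma} (mm) and one
#'   count column per marker.
#' @param marker name of the count column.
#' @return list: \code{series} (bregma-descending data.frame, i.e.
#'   rostral to caudal), \code{trendSign} (sign of the least-squares
#'   slope of count against caudal position).
#' @export
rostrocaudalProfile <- function(records, marker) {
  stopifnot(nrow(records) >= 2, marker %in% names(records))
  if (anyDuplicated(records$bregma)) {
    .warnf("duplicate bregma values averaged")
    records <- aggregate(records[marker],
                         by = list(bregma = records$bregma), FUN = mean)
  }
  ord <- order(records$bregma, decreasing = TRUE)
  series <- data.frame(bregma = records$bregma[ord],
                       count = records[[marker]][ord])
  # caudal position increases as bregma decreases
  slope <- unname(coef(lm(series$count ~ I(-series$bregma)))[2])
  list(series = series, trendSign = sign(round(slope, 10)))
}
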