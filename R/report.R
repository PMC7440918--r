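#' Per-cluster summary table with grand means
#'
#' Mean and SEM of every feature per cluster, plus an unweighted grand
#' mean row (the arithmetic mean of the cluster means, matching how
#' cross-subtype figures such as the 849 MOhm input resistance are
#' quoted); an n-weighted grand mean is available behind a flag.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param labels cluster label per cell (integer or name).
#' @param weighted use n-weighted grand means instead of unweighted.
#' @return list: \code{n} per cluster, \code{mean} and \code{sem}
#'   (clusters x features), \code{grandMean} (per feature). SEM is
#'   \code{NA} for clusters of fewer than two cells (flagged in
#'   \code{semFlag}).
#' @export
clusterSummary <- function(fm, labels, weighted = FALSE) {
  v <- featureValues(fm)
  stopifnot(length(labels) == nrow(v))
  labs <- sort(unique(labels))
  n <- vapply(labs, function(l) sum(labels == l), 0L)
  mean_ <- t(vapply(labs, function(l)
    colMeans(v[labels == l, , drop = FALSE]), numeric(ncol(v))))
  sem <- t(vapply(labs, function(l) {
    sub <- v[labels == l, , drop = FALSE]
    if (nrow(sub) < 2) rep(NA_real_, ncol(v))
    else apply(sub, 2, sd) / sqrt(nrow(sub))
  }, numeric(ncol(v))))
  rownames(mean_) <- rownames(sem) <- as.character(labs)
  grand <- if (weighted) colSums(mean_ * n) / sum(n) else colMeans(mean_)
  list(n = setNames(n, labs), mean = mean_, sem = sem,
       grandMean = grand, semFlag = n < 2)
}

#' One-way ANOVA with Tukey HSD posthoc comparisons
#'
#' @param values numeric response per cell.
#' @param labels group label per cell (at least two groups of n >= 2).
#' @return list: \code{F}, \code{p}, \code{tukey} (pairwise adjusted
#'   p-values; Tukey-Kramer for unequal group sizes). \code{F} and
#'   \code{p} are \code{NA} when the within-group variance vanishes with
#'   equal group means (F is 0/0).
#' @export
groupCompare <- function(values, labels) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) >= 2, all(table(labels) >= 2))
  fit <- aov(values ~ labels)
  tab <- summary(fit)[[1]]
  Fv <- tab[["F value"]][1]
  pv <- tab[["Pr(>F)"]][1]
  if (tab[["Mean Sq"]][2] == 0 && tab[["Mean Sq"]][1] == 0) {
    Fv <- NA_real_; pv <- NA_real_
  } else if (tab[["Mean Sq"]][2] == 0) {
    # zero within-group variance, unequal means: infinitely significant
    Fv <- Inf; pv <- 0
  }
  tk <- tryCatch(TukeyHSD(fit)$labels, error = function(e) NULL)
  list(F = Fv, p = pv, tukey = tk)
}
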