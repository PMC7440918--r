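#' @importFrom mclust Mclust mclustBIC dens estep estepV estepVVV nMclustParams
NULL

#' Preprocess a feature matrix for clustering
#'
#' Count-like and latency-like features are log-transformed (natural log;
#' \code{log(x + 1)} for counts and the afterdepolarization latency,
#' \code{log(x)} for strictly positive latencies). Cells with any
#' transformed value lying more than \code{iqrMult} interquartile ranges
#' from the feature median are discarded as outliers (a single pass, on
#' the transformed but unscaled values). Remaining columns are min-max
#' scaled to [0, 1]; constant columns are dropped with a warning.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param logFeatures features to log-transform.
#' @param countLike subset of \code{logFeatures} transformed as
#'   \code{log(x + 1)}.
#' @param iqrMult outlier multiplier (5 by default).
#' @return list with \code{scaled} (matrix in [0,1]) and \code{report}
#'   (\linkS4class{PreprocessReport}).
#' @export
preprocessFeatures <- function(fm,
    logFeatures = c("spike_count_rheo", "spike_count_sat",
                    "first_spike_latency_rheo", "first_spike_latency_sat",
                    "adp_latency"),
    countLike = c("spike_count_rheo", "spike_count_sat", "adp_latency"),
    iqrMult = 5) {
  v <- featureValues(fm)
  if (anyNA(v)) .stopf("missing values; impute before preprocessing")
  logFeatures <- intersect(logFeatures, colnames(v))
  for (f in logFeatures) {
    x <- v[, f]
    if (f %in% countLike || any(x <= 0)) v[, f] <- log1p(x)
    else v[, f] <- log(x)
  }
  out <- rep(FALSE, nrow(v))
  for (j in seq_len(ncol(v))) {
    med <- median(v[, j])
    iqr <- quantile(v[, j], 0.75) - quantile(v[, j], 0.25)
    if (iqr == 0) next
    out <- out | abs(v[, j] - med) > iqrMult * iqr
  }
  outlierIds <- rownames(v)[out]
  v <- v[!out, , drop = FALSE]
  mins <- apply(v, 2, min)
  rng <- apply(v, 2, max) - mins
  drop <- names(rng)[rng == 0]
  if (length(drop))
    .warnf("dropping constant feature(s): %s", paste(drop, collapse = ", "))
  keep <- setdiff(colnames(v), drop)
  scaled <- sweep(sweep(v[, keep, drop = FALSE], 2, mins[keep]), 2,
                  rng[keep], "/")
  report <- new("PreprocessReport", logFeatures = logFeatures,
                outlierIds = outlierIds, featureMin = mins[keep],
                featureRange = rng[keep], droppedFeatures = drop)
  list(scaled = scaled, report = report)
}

# apply a frozen preprocessing to new cells
.applyPreprocess <- function(fm, report,
    countLike = c("spike_count_rheo", "spike_count_sat", "adp_latency")) {
  v <- featureValues(fm)
  for (f in report@logFeatures) {
    x <- v[, f]
    if (f %in% countLike || any(x <= 0)) v[, f] <- log1p(x)
    else v[, f] <- log(x)
  }
  keep <- names(report@featureMin)
  if (!all(keep %in% colnames(v))) .stopf("schema error: feature mismatch")
  sweep(sweep(v[, keep, drop = FALSE], 2, report@featureMin), 2,
        report@featureRange, "/")
}

# maximum-likelihood probabilistic PCA of a centered covariance:
# returns the model covariance C = W W' + sigma2 I implied by k components
.ppcaCov <- function(S, k) {
  d <- ncol(S)
  eg <- eigen(S, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  sigma2 <- if (k < d) mean(lam[(k + 1):d]) else 0
  sigma2 <- max(sigma2, 1e-9)
  gain <- pmax(lam[seq_len(k)] - sigma2, 0)
  W <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(gain), k)
  tcrossprod(W) + diag(sigma2, d)
}

# Gaussian log-likelihood of rows of X under N(mu, C)
.mvnLoglik <- function(X, mu, C) {
  d <- ncol(X)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    C <- C + diag(1e-8, d)
    ch <- chol(C)
  }
  Xc <- sweep(X, 2, mu)
  z <- backsolve(ch, t(Xc), transpose = TRUE)
  -0.5 * nrow(X) * (d * log(2 * pi) + 2 * sum(log(diag(ch)))) -
    0.5 * sum(z^2)
}

# number of free parameters of a k-component PPCA model in d dimensions
.ppcaNpar <- function(d, k) d + d * k - k * (k - 1) / 2 + 1

#' Select the PCA order by cross-validated BIC
#'
#' For each candidate number of components k, a probabilistic PCA model is
#' fit on the training folds (closed-form maximum likelihood) and the
#' held-out log-likelihood is penalized with the model's parameter count
#' to give a per-fold BIC; fold-averaged BICs are minimized over k.
#' Deterministic given \code{seed} (which fixes the fold assignment).
#'
#' @param scaled numeric matrix (cells x features), e.g. the output of
#'   \code{\link{preprocessFeatures}}.
#' @param kmax largest candidate order (9 by default).
#' @param folds number of cross-validation folds.
#' @param seed RNG seed for fold assignment.
#' @return list: \code{nPcs} (argmin), \code{bic} (named curve over k).
#' @export
selectPcaOrder <- function(scaled, kmax = 9, folds = 5, seed = 1) {
  n <- nrow(scaled)
  stopifnot(n >= folds, ncol(scaled) >= kmax)
  set.seed(seed)
  foldId <- sample(rep_len(seq_len(folds), n))
  bic <- matrix(NA_real_, folds, kmax)
  for (f in seq_len(folds)) {
    tr <- scaled[foldId != f, , drop = FALSE]
    te <- scaled[foldId == f, , drop = FALSE]
    mu <- colMeans(tr)
    S <- crossprod(sweep(tr, 2, mu)) / nrow(tr)
    for (k in seq_len(kmax)) {
      C <- .ppcaCov(S, k)
      ll <- .mvnLoglik(te, mu, C)
      bic[f, k] <- -2 * ll + .ppcaNpar(ncol(scaled), k) * log(nrow(te))
    }
  }
  curve <- colMeans(bic)
  names(curve) <- seq_len(kmax)
  list(nPcs = unname(which.min(curve)), bic = curve)
}

#' Fit a Gaussian mixture in PC space with cross-validated BIC over K
#'
#' For every candidate number of components K, full-covariance Gaussian
#' mixtures are fit on the training folds (mclust, model "VVV", its
#' deterministic model-based hierarchical initialization) and the held-out
#' log-likelihood, penalized with the full-model parameter count, is
#' averaged over folds. The best K is refit on all data and cells receive
#' their maximum-responsibility labels.
#'
#' @param scores cells x nPcs matrix of principal-component scores.
#' @param krange candidate numbers of mixture components.
#' @param folds cross-validation folds.
#' @param seed RNG seed (fold assignment and mclust initialization).
#' @return list: \code{K}, \code{bic} (fold-averaged curve),
#'   \code{labels}, \code{gmm} (weights/means/covariances),
#'   \code{fit} (the mclust object).
#' @export
fitGmm <- function(scores, krange = 1:7, folds = 5, seed = 1) {
  scores <- as.matrix(scores)
  stopifnot(all(is.finite(scores)))
  set.seed(seed)
  n <- nrow(scores)
  foldId <- sample(rep_len(seq_len(folds), n))
  mname <- if (ncol(scores) > 1) "VVV" else "V"
  bic <- matrix(NA_real_, folds, length(krange))
  for (f in seq_len(folds)) {
    tr <- scores[foldId != f, , drop = FALSE]
    te <- scores[foldId == f, , drop = FALSE]
    for (i in seq_along(krange)) {
      K <- krange[i]
      fit <- tryCatch(
        mclust::Mclust(tr, G = K, modelNames = mname, verbose = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) next
      dens <- tryCatch(
        mclust::dens(data = te, modelName = fit$modelName,
                     parameters = fit$parameters),
        error = function(e) NULL)
      if (is.null(dens) || any(!is.finite(log(dens)))) next
      npar <- mclust::nMclustParams(mname, ncol(scores), K)
      bic[f, i] <- -2 * sum(log(dens)) + npar * log(nrow(te))
    }
  }
  curve <- colMeans(bic, na.rm = TRUE)
  names(curve) <- krange
  K <- krange[which.min(curve)]
  final <- mclust::Mclust(scores, G = K, modelNames = mname,
                          verbose = FALSE)
  if (is.null(final)) .stopf("final mixture fit failed at K = %d", K)
  pars <- final$parameters
  sig <- pars$variance$sigma
  if (is.null(sig)) {            # 1-d model: rebuild covariance array
    sig <- array(pars$variance$sigmasq, dim = c(1, 1, K))
  }
  list(K = K, bic = curve, labels = as.integer(final$classification),
       gmm = list(K = K, weights = pars$pro, means = as.matrix(pars$mean),
                  covariances = sig, modelName = final$modelName,
                  parameters = pars),
       fit = final)
}

#' Cluster cells end to end: preprocess, select PCA order, fit the GMM
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param kmaxPca,krange,folds,seed see \code{\link{selectPcaOrder}} and
#'   \code{\link{fitGmm}}.
#' @param ... passed to \code{\link{preprocessFeatures}}.
#' @return list: \code{model} (\linkS4class{ClusterModel}),
#'   \code{report} (\linkS4class{PreprocessReport}), \code{scores},
#'   \code{retained} (a \linkS4class{FeatureMatrix} of non-outlier cells).
#' @export
clusterCells <- function(fm, kmaxPca = 9, krange = 1:7, folds = 5,
                         seed = 1, ...) {
  pp <- preprocessFeatures(fm, ...)
  sel <- selectPcaOrder(pp$scaled, kmax = kmaxPca, folds = folds,
                        seed = seed)
  pc <- prcomp(pp$scaled, center = TRUE, scale. = FALSE)
  nPcs <- sel$nPcs
  loadings <- pc$rotation[, seq_len(nPcs), drop = FALSE]
  scores <- pc$x[, seq_len(nPcs), drop = FALSE]
  gm <- fitGmm(scores, krange = krange, folds = folds, seed = seed)
  keep <- setdiff(rownames(featureValues(fm)), pp$report@outlierIds)
  vals <- featureValues(fm)[keep, , drop = FALSE]
  retained <- new("FeatureMatrix", values = vals,
                  ageGroup = if (length(fm@ageGroup))
                    fm@ageGroup[match(keep, rownames(featureValues(fm)))]
                  else character(),
                  trueLabels = if (length(fm@trueLabels))
                    fm@trueLabels[match(keep, rownames(featureValues(fm)))]
                  else character())
  model <- new("ClusterModel", nPcs = as.integer(nPcs),
               loadings = loadings,
               explainedVar = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nPcs)],
               center = pc$center, gmm = gm$gmm, bicPca = sel$bic,
               bicGmm = gm$bic, labels = gm$labels,
               clusterNames = character(), seed = as.integer(seed))
  list(model = model, report = pp$report, scores = scores,
       retained = retained)
}

#' Label new cells under an existing subtype model
#'
#' In \code{"frozen"} mode the stored preprocessing (log transforms and
#' min-max ranges), centering and loadings are applied to the new cells
#' and each is assigned to the mixture component with the highest
#' responsibility. In \code{"refit"} mode the new cells are pooled with
#' the original cohort and the whole pipeline is re-run, returning labels
#' for all cells.
#'
#' @param model a \linkS4class{ClusterModel}.
#' @param report the \linkS4class{PreprocessReport} of the fitted cohort.
#' @param newFm new cells (same feature roster).
#' @param mode \code{"frozen"} or \code{"refit"}.
#' @param origFm original cohort, required for \code{"refit"}.
#' @param ... passed to \code{\link{clusterCells}} in refit mode.
#' @return frozen mode: named integer labels for the new cells.
#'   Refit mode: the \code{\link{clusterCells}} result for the pooled
#'   cohort.
#' @export
assignNewCells <- function(model, report, newFm,
                           mode = c("frozen", "refit"), origFm = NULL,
                           ...) {
  mode <- match.arg(mode)
  if (mode == "refit") {
    if (is.null(origFm)) .stopf("refit mode needs the original cohort")
    v <- rbind(featureValues(origFm), featureValues(newFm))
    rownames(v) <- make.unique(rownames(v), sep = "_")
    pooled <- new("FeatureMatrix", values = v,
                  ageGroup = c(origFm@ageGroup, newFm@ageGroup),
                  trueLabels = c(origFm@trueLabels, newFm@trueLabels))
    return(clusterCells(pooled, seed = model@seed, ...))
  }
  sc <- .applyPreprocess(newFm, report)
  proj <- sweep(sc, 2, model@center) %*% model@loadings
  es <- mclust::estep(data = proj, modelName = model@gmm$modelName,
                      parameters = model@gmm$parameters)
  setNames(max.col(es$z), rownames(featureValues(newFm)))
}

#' Name the clusters of a 3-component model by their hallmark features
#'
#' Each name has a hallmark feature: the afterdepolarization amplitude
#' (ADP), the initial maximal firing rate (HFF) and the saturated-sweep
#' first-spike latency (Delayed). Cluster means of the three hallmarks
#' are standardized and names are assigned by the bijective
#' cluster-to-name matching with the largest summed evidence; when a
#' single cluster greedily wins several criteria a warning notes the
#' ambiguity. Models with K other than 3 get generic names.
#'
#' @param model a \linkS4class{ClusterModel}.
#' @param features the retained \linkS4class{FeatureMatrix} (rows aligned
#'   with \code{clusterLabels(model)}).
#' @return the model with \code{clusterNames} filled (label k maps to
#'   \code{clusterNames[k]}).
#' @export
nameClusters <- function(model, features) {
  K <- model@gmm$K
  if (K != 3L) {
    model@clusterNames <- paste0("cluster_", seq_len(K))
    return(model)
  }
  v <- featureValues(features)
  lab <- clusterLabels(model)
  stopifnot(nrow(v) == length(lab))
  hallmark <- c(ADP = "adp_amplitude", HFF = "fmax_init",
                Delayed = "first_spike_latency_sat")
  m <- vapply(hallmark, function(f) vapply(seq_len(K), function(k)
    mean(v[lab == k, f]), 0), numeric(K))       # clusters x hallmarks
  z <- scale(m)                                  # comparable units
  z[is.nan(z)] <- 0
  # bijective assignment maximizing the summed hallmark evidence
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  score <- vapply(perms, function(p) sum(z[cbind(p, 1:3)]), 0)
  best <- perms[[which.max(score)]]              # best[j]: cluster of name j
  greedy <- apply(z, 2, which.max)
  if (anyDuplicated(greedy))
    .warnf("ambiguous naming: one cluster wins several criteria; %s",
           "using the best bijective match")
  nm <- character(K)
  nm[best] <- names(hallmark)
  model@clusterNames <- nm
  model
}
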