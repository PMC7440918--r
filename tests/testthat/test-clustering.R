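# small labelled Gaussian-blob feature matrix (d features, K blobs)
blobMatrix <- function(n = 60, d = 10, centers, sdWithin = 0.5, seed = 1) {
  set.seed(seed)
  K <- nrow(centers)
  lab <- rep_len(seq_len(K), n)
  v <- centers[lab, seq_len(d), drop = FALSE] +
    matrix(rnorm(n * d, 0, sdWithin), n)
  colnames(v) <- paste0("f", seq_len(d))
  rownames(v) <- paste0("c", seq_len(n))
  list(values = v, labels = lab)
}

test_that("min-max scaling and the 5-IQR outlier rule follow their
           definitions", {
  v <- cbind(a = c(2, 4, 6), b = c(1, 1.5, 2))
  rownames(v) <- paste0("c", 1:3)
  fm <- new("FeatureMatrix", values = v, ageGroup = character(),
            trueLabels = character())
  pp <- preprocessFeatures(fm, logFeatures = character())
  expect_equal(unname(pp$scaled[, "a"]), c(0, 0.5, 1))
  expect_equal(range(pp$scaled), c(0, 1))
  # median 10, IQR 2: a value of 21 violates |x - med| > 5 IQR
  x <- c(9, 9.5, 10, 10.5, 11, 21)
  v2 <- cbind(a = x, b = seq_along(x))
  rownames(v2) <- paste0("c", seq_along(x))
  fm2 <- new("FeatureMatrix", values = v2, ageGroup = character(),
             trueLabels = character())
  pp2 <- preprocessFeatures(fm2, logFeatures = character())
  expect_equal(pp2$report@outlierIds, "c6")
  expect_equal(nrow(pp2$scaled), 5)
})

test_that("an engineered cohort with ten violating cells reports ten
           outliers, and the pass is idempotent", {
  set.seed(42)
  n <- 120
  v <- cbind(a = rnorm(n, 10, 0.5), b = rnorm(n, 5, 0.2),
             c = rnorm(n, 0, 1))
  v[1:10, "a"] <- 40      # far beyond 5 IQR of a tight distribution
  rownames(v) <- sprintf("c%03d", seq_len(n))
  fm <- new("FeatureMatrix", values = v, ageGroup = character(),
            trueLabels = character())
  pp <- preprocessFeatures(fm, logFeatures = character())
  expect_equal(sort(pp$report@outlierIds), sprintf("c%03d", 1:10))
  # removing the outliers leaves a cohort with no new outliers
  fm2 <- new("FeatureMatrix",
             values = v[!rownames(v) %in% pp$report@outlierIds, ],
             ageGroup = character(), trueLabels = character())
  pp2 <- preprocessFeatures(fm2, logFeatures = character())
  expect_length(pp2$report@outlierIds, 0)
})

test_that("constant columns are dropped with a warning", {
  v <- cbind(a = c(1, 2, 3, 4), b = rep(7, 4))
  rownames(v) <- paste0("c", 1:4)
  fm <- new("FeatureMatrix", values = v, ageGroup = character(),
            trueLabels = character())
  expect_warning(pp <- preprocessFeatures(fm, logFeatures = character()),
                 "constant")
  expect_equal(colnames(pp$scaled), "a")
})

test_that("cross-validated BIC selects the generative PCA order", {
  set.seed(11)
  # rank-1 structure plus tiny isotropic noise
  z <- rnorm(80)
  load1 <- runif(12, 0.5, 1)
  x1 <- outer(z, load1) + matrix(rnorm(80 * 12, 0, 0.05), 80)
  expect_equal(selectPcaOrder(x1, kmax = 6, seed = 1)$nPcs, 1)
  # two-factor model (distinct loading supports): recovered in at least
  # 9 of 10 seeds
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    zz <- matrix(rnorm(120 * 2), 120)
    L <- rbind(c(runif(6, 0.6, 1), rep(0, 6)),
               c(rep(0, 6), runif(6, 0.6, 1)))
    x2 <- zz %*% L + matrix(rnorm(120 * 12, 0, 0.3), 120)
    hits <- hits + (selectPcaOrder(x2, kmax = 6, seed = s)$nPcs == 2)
  }
  expect_gte(hits, 9)
})

test_that("BIC curves equal an independent exhaustive enumeration", {
  # independent oracle: dense multivariate-normal log-likelihood and an
  # explicit loop over the same candidate set and folds
  dmvnorm_log <- function(X, mu, C) {
    d <- ncol(X)
    iC <- solve(C)
    ld <- determinant(C, logarithm = TRUE)$modulus
    Xc <- sweep(X, 2, mu)
    -0.5 * (d * log(2 * pi) + as.numeric(ld)) * nrow(X) -
      0.5 * sum((Xc %*% iC) * Xc)
  }
  set.seed(21)
  X <- matrix(rnorm(60 * 6), 60)
  X[, 1:3] <- X[, 1:3] + rnorm(60) %o% c(1, 1, 1)
  sel <- selectPcaOrder(X, kmax = 4, folds = 3, seed = 5)
  set.seed(5)
  foldId <- sample(rep_len(1:3, 60))
  oracle <- sapply(1:4, function(k) {
    mean(sapply(1:3, function(f) {
      tr <- X[foldId != f, ]; te <- X[foldId == f, , drop = FALSE]
      mu <- colMeans(tr)
      S <- crossprod(sweep(tr, 2, mu)) / nrow(tr)
      eg <- eigen(S, symmetric = TRUE)
      s2 <- max(mean(eg$values[(k + 1):6]), 1e-9)
      W <- eg$vectors[, 1:k, drop = FALSE] %*%
        diag(sqrt(pmax(eg$values[1:k] - s2, 0)), k)
      C <- tcrossprod(W) + diag(s2, 6)
      npar <- 6 + 6 * k - k * (k - 1) / 2 + 1
      -2 * dmvnorm_log(te, mu, C) + npar * log(nrow(te))
    }))
  })
  expect_equal(unname(sel$bic), oracle, tolerance = 1e-8)
  expect_equal(sel$nPcs, which.min(oracle))
})

test_that("mixture-order selection recovers constructed cluster counts", {
  set.seed(31)
  one <- matrix(rnorm(150 * 2), 150)
  expect_equal(fitGmm(one, krange = 1:4, seed = 2)$K, 1)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))   # >= 10x within-SD apart
  b <- blobMatrix(90, d = 2, centers = centers, sdWithin = 1, seed = 3)
  gm <- fitGmm(b$values, krange = 1:5, seed = 4)
  expect_equal(gm$K, 3)
  expect_equal(mclust::adjustedRandIndex(gm$labels, b$labels), 1)
})

test_that("GMM cross-validated BIC matches an independent held-out
           enumeration at the selected K", {
  dmvnorm <- function(X, mu, C) {
    iC <- solve(C)
    Xc <- sweep(X, 2, mu)
    exp(-0.5 * (ncol(X) * log(2 * pi) +
                  as.numeric(determinant(C)$modulus)) -
          0.5 * rowSums((Xc %*% iC) * Xc))
  }
  set.seed(41)
  centers <- rbind(c(0, 0), c(8, 8))
  b <- blobMatrix(80, d = 2, centers = centers, sdWithin = 1, seed = 6)
  gm <- fitGmm(b$values, krange = 1:3, folds = 4, seed = 7)
  set.seed(7)
  foldId <- sample(rep_len(1:4, 80))
  oracleBic <- sapply(1:3, function(K) {
    mean(sapply(1:4, function(f) {
      tr <- b$values[foldId != f, ]; te <- b$values[foldId == f, , drop = FALSE]
      fit <- mclust::Mclust(tr, G = K, modelNames = "VVV", verbose = FALSE)
      mix <- rowSums(sapply(seq_len(K), function(k)
        fit$parameters$pro[k] *
          dmvnorm(te, fit$parameters$mean[, k],
                  fit$parameters$variance$sigma[, , k])))
      -2 * sum(log(mix)) +
        mclust::nMclustParams("VVV", 2, K) * log(nrow(te))
    }))
  })
  expect_equal(unname(gm$bic), oracleBic, tolerance = 1e-6)
  expect_equal(gm$K, which.min(oracleBic))
})

test_that("labels are invariant to cell and feature permutations", {
  fm <- synthFeatureTable(lapply(defaultSubtypeSpecs(), function(s) {
    s@n <- 50L; s
  }), seed = 8)
  cc <- clusterCells(fm, seed = 3)
  v <- featureValues(fm)
  set.seed(9)
  pc <- sample(ncol(v)); pr <- sample(nrow(v))
  fm2 <- new("FeatureMatrix", values = v[pr, pc],
             ageGroup = fm@ageGroup[pr], trueLabels = fm@trueLabels[pr])
  cc2 <- clusterCells(fm2, seed = 3)
  common <- intersect(rownames(featureValues(cc$retained)),
                      rownames(featureValues(cc2$retained)))
  l1 <- clusterLabels(cc$model)[match(common,
          rownames(featureValues(cc$retained)))]
  l2 <- clusterLabels(cc2$model)[match(common,
          rownames(featureValues(cc2$retained)))]
  expect_equal(mclust::adjustedRandIndex(l1, l2), 1)
})

test_that("frozen-model assignment maps component means to themselves and
           generalizes to new cohorts", {
  fm <- synthFeatureTable(seed = 12)    # full published cohort sizes
  cc <- clusterCells(fm, seed = 5)
  model <- cc$model
  # an adult cohort drawn from the same subtype distributions
  adult <- synthFeatureTable(lapply(defaultSubtypeSpecs(), function(s) {
    s@n <- 30L; s
  }), seed = 13)
  lab <- assignNewCells(model, cc$report, adult)
  named <- suppressWarnings(nameClusters(model, cc$retained))
  agree <- mean(named@clusterNames[lab] == adult@trueLabels)
  expect_gte(agree, 0.9)
})

test_that("joint refit of juvenile plus adult cohorts keeps three
           clusters", {
  juv <- synthFeatureTable(lapply(defaultSubtypeSpecs(), function(s) {
    s@n <- 60L; s
  }), seed = 14)
  adult <- synthFeatureTable(lapply(defaultSubtypeSpecs(), function(s) {
    s@n <- 18L; s
  }), seed = 15)
  adult@ageGroup[] <- "adult"
  rf <- assignNewCells(clusterCells(juv, seed = 6)$model,
                       preprocessFeatures(juv)$report, adult,
                       mode = "refit", origFm = juv)
  expect_equal(rf$model@gmm$K, 3)
})

test_that("clusters are named by their hallmark electrophysiology", {
  fm <- synthFeatureTable(lapply(defaultSubtypeSpecs(), function(s) {
    s@n <- 60L; s
  }), seed = 16)
  cc <- clusterCells(fm, seed = 7)
  named <- suppressWarnings(nameClusters(cc$model, cc$retained))
  expect_setequal(named@clusterNames, c("ADP", "HFF", "Delayed"))
  # majority of each true subtype carries its own name
  map <- named@clusterNames[clusterLabels(cc$model)]
  for (s in c("ADP", "HFF", "Delayed"))
    expect_gt(mean(map[cc$retained@trueLabels == s] == s), 0.8)
  # the Delayed cluster is the one carrying ~279 ms latencies
  lat <- featureValues(cc$retained)[, "first_spike_latency_sat"]
  expect_equal(names(which.max(tapply(lat, map, mean))), "Delayed")
  # K = 2 models get generic names
  two <- fitGmm(matrix(c(rnorm(60), rnorm(60, 10)), ncol = 2), krange = 2,
                seed = 1)
  m2 <- new("ClusterModel", nPcs = 2L,
            loadings = diag(2), explainedVar = c(0.5, 0.5),
            center = c(0, 0), gmm = two$gmm, bicPca = numeric(),
            bicGmm = two$bic, labels = two$labels,
            clusterNames = character(), seed = 1L)
  fmAny <- new("FeatureMatrix",
               values = matrix(rnorm(120 * 25), 120,
                 dimnames = list(sprintf("c%03d", 1:120), featureRoster())),
               ageGroup = character(), trueLabels = character())
  expect_equal(nameClusters(m2, fmAny)@clusterNames,
               c("cluster_1", "cluster_2"))
})
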