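mkPse <- function(reads, align, nGenes = 5) {
  n <- length(reads)
  counts <- matrix(5L, nGenes, n,
                   dimnames = list(paste0("g", seq_len(nGenes)),
                                   paste0("c", seq_len(n))))
  PatchSeqExperiment(counts, reads, align)
}

test_that("read and alignment QC floors are strict inequalities", {
  ps <- mkPse(c(75499, 75500, 2e6, 2e6), c(0.9, 0.9, 0.50, 0.49))
  q <- qcFilter(ps)
  expect_equal(q$kept, c("c2", "c3"))
  expect_equal(q$discarded$reason[q$discarded$cell_id == "c1"],
               "low_reads")
  expect_equal(q$discarded$reason[q$discarded$cell_id == "c4"],
               "low_alignment")
})

test_that("the default synthetic cohort reproduces the 61-of-69 QC
           margin", {
  s <- synthPatchseq(seed = 2)
  q <- qcFilter(s$patchseq)
  expect_equal(length(q$kept), 61)
  expect_equal(sum(q$discarded$reason == "low_reads"), 5)
  expect_equal(sum(q$discarded$reason == "low_alignment"), 3)
})

test_that("raising either QC threshold never keeps more cells", {
  s <- synthPatchseq(seed = 4)
  base <- length(qcFilter(s$patchseq)$kept)
  for (mr in c(1e5, 5e5, 2e6))
    expect_lte(length(qcFilter(s$patchseq, minReads = mr)$kept), base)
  for (ma in c(0.6, 0.8, 0.95))
    expect_lte(length(qcFilter(s$patchseq, minAlignment = ma)$kept), base)
})

test_that("the normalizing gene set is the correlated-and-ubiquitous
           intersection", {
  # constructed reference: exactly 20 genes scale with molecular count,
  # verified by a brute-force per-gene correlation oracle
  set.seed(71)
  nRef <- 120; nGenes <- 60
  depth <- exp(rnorm(nRef, 0, 0.4))
  mu <- matrix(20, nGenes, nRef)
  mu[1:20, ] <- 20 * rep(depth, each = 20)
  refCounts <- matrix(rpois(nGenes * nRef, mu), nGenes,
                      dimnames = list(paste0("g", 1:nGenes),
                                      paste0("r", 1:nRef)))
  ref <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = refCounts),
    colData = S4Vectors::DataFrame(
      cluster = rep_len(c("a", "b"), nRef),
      molecular_count = round(1000 * depth)))
  psCounts <- matrix(rpois(nGenes * 30, 20) + 1L, nGenes,
                     dimnames = list(paste0("g", 1:nGenes),
                                     paste0("p", 1:30)))
  ps <- PatchSeqExperiment(psCounts, rep(1e6, 30), rep(0.9, 30))
  nf <- normalizationFactors(ps, ref)
  oracleP <- apply(refCounts, 1, function(x)
    cor.test(x, ref$molecular_count)$p.value)
  oracleSig <- names(which(p.adjust(oracleP, "BH") < 0.05))
  expect_setequal(nf$genes, oracleSig)
  expect_true(all(paste0("g", 1:20) %in% nf$genes))
  expect_lte(length(setdiff(nf$genes, paste0("g", 1:20))), 3)
  expect_true(all(nf$factors > 0))
})

test_that("count normalization divides columns exactly and keeps zeros", {
  counts <- matrix(c(4L, 6L, 0L, 8L), 2,
                   dimnames = list(c("g1", "g2"), c("c1", "c2")))
  ps <- PatchSeqExperiment(counts, c(1e6, 1e6), c(0.9, 0.9))
  out <- normalizeCounts(ps, c(c1 = 2, c2 = 1))
  expect_equal(out[, "c1"], c(g1 = 2, g2 = 3))
  expect_equal(out[, "c2"], c(g1 = 0, g2 = 8))
  expect_identical(out == 0, counts == 0)
  expect_equal(normalizeCounts(ps, c(c1 = 1, c2 = 1)), counts,
               ignore_attr = TRUE)
  expect_error(normalizeCounts(ps, c(c1 = 2)), "schema")
  # random matrix: column sums scale by exactly 1/factor
  s <- synthPatchseq(seed = 5, nCells = 20, qcFailReads = 0,
                     qcFailAlign = 0, nGenes = 200, nRefCells = 100)
  f <- setNames(runif(20, 0.6, 1.4), colnames(s$patchseq))
  nc <- normalizeCounts(s$patchseq, f)
  expect_equal(colSums(nc),
               colSums(SummarizedExperiment::assay(s$patchseq)) / f)
})

test_that("bootstrap mapping assigns centroids, rejects noise, and
           splits blended cells", {
  s <- synthPatchseq(seed = 6, nRefCells = 300)
  refX <- SummarizedExperiment::assay(s$reference)
  cl <- SummarizedExperiment::colData(s$reference)$cluster
  cent <- sapply(split(seq_along(cl), cl), function(ix)
    rowMeans(refX[, ix, drop = FALSE]))
  ba <- bootstrapAssign(cent, s$reference, nBoot = 300, seed = 7)
  for (k in colnames(ba$pvalues))
    expect_lt(ba$pvalues[k, k], 0.05)
  # pure-noise profiles stay unassigned
  set.seed(8)
  noise <- apply(refX[, 1:20], 2, sample)
  rownames(noise) <- rownames(refX)
  colnames(noise) <- paste0("noise", 1:20)
  ban <- bootstrapAssign(noise, s$reference, nBoot = 300, seed = 9)
  expect_gte(mean(vapply(ban$assignments, identical, TRUE,
                         "unassigned")), 0.9)
  # 50/50 centroid blends are frequently assigned to both parents
  blend <- sapply(1:3, function(i) (cent[, 1] + cent[, 2]) / 2)
  colnames(blend) <- paste0("blend", 1:3)
  bb <- bootstrapAssign(blend, s$reference, nBoot = 300, seed = 10)
  both <- vapply(bb$assignments, function(a)
    all(colnames(cent)[1:2] %in% a), TRUE)
  expect_gte(mean(both), 2 / 3)
})

test_that("cross-dataset means anchor the Sst gene at exactly 1000", {
  a <- c(Sst = 500, geneX = 50)
  b <- c(Sst = 1000, geneX = 77, geneY = 3)
  c3 <- c(Sst = 20, geneZ = 10)
  tab <- sstNormalizedMeans(list(A = a, B = b, C = c3))
  expect_equal(tab["Sst", ], data.frame(A = 1000, B = 1000, C = 1000,
                                        row.names = "Sst"))
  expect_equal(tab["geneX", "A"], 100)
  expect_equal(tab["geneX", "B"], 77)     # already on the anchor scale
  expect_true(is.na(tab["geneZ", "A"]))   # absent gene marked absent
  expect_error(sstNormalizedMeans(list(bad = c(Sst = 0, g = 1))), "Sst")
})
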