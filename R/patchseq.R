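#' Construct a PatchSeqExperiment
#'
#' @param counts gene x cell matrix of nonnegative integer counts.
#' @param totalReads per-cell total sequenced reads.
#' @param alignmentRate per-cell alignment rate in [0, 1].
#' @param ... further arguments to
#'   \code{\link[SummarizedExperiment]{SummarizedExperiment}}.
#' @return a \linkS4class{PatchSeqExperiment}.
#' @export
PatchSeqExperiment <- function(counts, totalReads, alignmentRate, ...) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(total_reads = totalReads,
                                   alignment_rate = alignmentRate),
    ...)
  new("PatchSeqExperiment", se)
}

#' Sequencing quality control for Patch-seq cells
#'
#' Cells with fewer than \code{minReads} total reads are discarded
#' (reason \code{"low_reads"}); of the remainder, cells whose alignment
#' rate is below \code{minAlignment} are discarded
#' (\code{"low_alignment"}). Both comparisons are strict, so a cell at
#' exactly the floor is kept.
#'
#' @param ds a \linkS4class{PatchSeqExperiment}.
#' @param minReads total-read floor (default 75500).
#' @param minAlignment alignment-rate floor (default 0.5).
#' @return list: \code{kept} (cell ids), \code{discarded} (data.frame of
#'   cell id and reason), \code{filtered} (the subsetted experiment).
#' @export
qcFilter <- function(ds, minReads = 75500, minAlignment = 0.5) {
  cd <- SummarizedExperiment::colData(ds)
  ids <- colnames(ds)
  lowR <- cd$total_reads < minReads
  lowA <- !lowR & cd$alignment_rate < minAlignment
  discarded <- data.frame(
    cell_id = ids[lowR | lowA],
    reason = c(rep("low_reads", sum(lowR)),
               rep("low_alignment", sum(lowA)))[
      order(c(which(lowR), which(lowA)))],
    stringsAsFactors = FALSE)
  keep <- !(lowR | lowA)
  list(kept = ids[keep], discarded = discarded,
       filtered = ds[, keep])
}

#' Depth-normalization factors from a reference dataset
#'
#' The normalizing gene set is the intersection of (a) genes whose
#' reference expression is significantly correlated with the per-cell
#' molecular count (Pearson, Benjamini-Hochberg adjusted, at
#' \code{alpha}) and (b) genes detected at least once in every Patch-seq
#' cell. Patch-seq expression restricted to that set is reduced to its
#' first principal component; scores are oriented to correlate positively
#' with per-cell total counts, rescaled to half-unit maximum amplitude,
#' and offset by +1 so every factor is positive.
#'
#' @param ds a QC-filtered \linkS4class{PatchSeqExperiment}.
#' @param ref reference \code{SummarizedExperiment} with \code{colData}
#'   columns \code{cluster} and \code{molecular_count}.
#' @param alpha significance level after multiplicity correction.
#' @return list: \code{genes} (the gene set), \code{pc1} (score per
#'   cell), \code{factors} (pc1 + 1, named per cell).
#' @export
normalizationFactors <- function(ds, ref, alpha = 0.05) {
  counts <- SummarizedExperiment::assay(ds, "counts")
  refX <- SummarizedExperiment::assay(ref, 1)
  shared <- intersect(rownames(counts), rownames(refX))
  if (!length(shared)) .stopf("no shared gene namespace")
  mc <- SummarizedExperiment::colData(ref)$molecular_count
  refX <- refX[shared, , drop = FALSE]
  # per-gene Pearson correlation with molecular count, BH-corrected
  p <- apply(refX, 1, function(x) {
    if (sd(x) == 0) return(NA_real_)
    cor.test(x, mc)$p.value
  })
  sigGenes <- shared[!is.na(p) & p.adjust(p, "BH") < alpha]
  ubiq <- rownames(counts)[rowSums(counts[, , drop = FALSE] >= 1) ==
                             ncol(counts)]
  genes <- intersect(sigGenes, ubiq)
  if (!length(genes)) .stopf("empty normalizing gene set")
  pc <- prcomp(t(counts[genes, , drop = FALSE]), center = TRUE,
               scale. = FALSE)
  sc <- pc$x[, 1]
  tot <- colSums(counts)
  if (cor(sc, tot) < 0) sc <- -sc
  sc <- sc / (2 * max(abs(sc)))
  factors <- sc + 1
  if (any(factors <= 0))
    .stopf("nonpositive factors for: %s",
           paste(colnames(counts)[factors <= 0], collapse = ", "))
  list(genes = genes, pc1 = sc, factors = setNames(factors,
                                                   colnames(counts)))
}

#' Divide each cell's counts by its normalization factor
#'
#' @param ds a \linkS4class{PatchSeqExperiment}.
#' @param factors output of \code{\link{normalizationFactors}} (or a
#'   named numeric vector covering all cells).
#' @return normalized gene x cell matrix (zeros stay zero).
#' @export
normalizeCounts <- function(ds, factors) {
  if (is.list(factors)) factors <- factors$factors
  counts <- SummarizedExperiment::assay(ds, "counts")
  if (!all(colnames(counts) %in% names(factors)))
    .stopf("schema error: factors missing for some cells")
  sweep(counts, 2, factors[colnames(counts)], "/")
}

#' Bootstrap assignment of cells to reference clusters
#'
#' Expression is first standardized per gene with the reference mean and
#' SD, which removes the baseline expression structure that every cell
#' shares. A cell is then scored against every cluster centroid by
#' Pearson correlation of the standardized profiles. The null
#' distribution re-scores the cell after randomly permuting gene
#' identities \code{nBoot} times (\code{null = "genes"}, the default,
#' the same family of null as gene-set bootstrap mappers); the p-value is
#' the fraction of null scores at least as large as the observed one.
#' \code{null = "labels"} instead recomputes centroids from random
#' permutations of the reference cell labels; note that this null is
#' concentrated near the grand-mean profile and is markedly
#' anticonservative, so it is not the default. A cell may be assigned to
#' several clusters (all with p below \code{alpha}) or to none
#' (\code{"unassigned"}).
#'
#' @param profiles gene x cell matrix of (normalized) expression.
#' @param ref reference \code{SummarizedExperiment} with a
#'   \code{cluster} colData column.
#' @param nBoot number of permutations (warning below 100).
#' @param alpha assignment threshold on the p-value.
#' @param seed RNG seed.
#' @param null \code{"genes"} or \code{"labels"}.
#' @return list: \code{pvalues} (cells x clusters matrix),
#'   \code{assignments} (named list of cluster sets per cell).
#' @export
bootstrapAssign <- function(profiles, ref, nBoot = 1000, alpha = 0.05,
                            seed = 1, null = c("genes", "labels")) {
  null <- match.arg(null)
  if (nBoot < 100) .warnf("nBoot = %d gives coarse p-values", nBoot)
  set.seed(seed)
  refX <- SummarizedExperiment::assay(ref, 1)
  shared <- intersect(rownames(profiles), rownames(refX))
  if (length(shared) < 50) .stopf("need at least 50 shared genes")
  X <- as.matrix(profiles[shared, , drop = FALSE])
  R <- as.matrix(refX[shared, , drop = FALSE])
  gm <- rowMeans(R)
  gs <- apply(R, 1, sd)
  keepG <- gs > 0
  X <- (X[keepG, , drop = FALSE] - gm[keepG]) / gs[keepG]
  R <- (R[keepG, , drop = FALSE] - gm[keepG]) / gs[keepG]
  cl <- as.character(SummarizedExperiment::colData(ref)$cluster)
  clusters <- sort(unique(cl))
  nK <- length(clusters)
  centroid <- function(lab) vapply(clusters, function(k)
    rowMeans(R[, lab == k, drop = FALSE]), numeric(nrow(R)))
  obsC <- centroid(cl)
  keepCl <- apply(obsC, 2, sd) > 0
  if (!all(keepCl)) .warnf("skipping degenerate cluster(s): %s",
                           paste(clusters[!keepCl], collapse = ", "))
  nullC <- if (null == "genes") {
    # permuting the cell's genes equals permuting the centroid's genes
    do.call(cbind, lapply(seq_len(nBoot), function(b)
      obsC[sample(nrow(obsC)), , drop = FALSE]))
  } else {
    do.call(cbind, lapply(seq_len(nBoot), function(b) centroid(sample(cl))))
  }
  obsS <- cor(X, obsC)                       # cells x clusters
  nullS <- cor(X, nullC)                     # cells x (nBoot*clusters)
  pv <- matrix(NA_real_, ncol(X), nK,
               dimnames = list(colnames(X), clusters))
  for (k in which(keepCl)) {
    nullK <- nullS[, seq(k, by = nK, length.out = nBoot), drop = FALSE]
    pv[, k] <- (rowSums(nullK >= obsS[, k]) + 1) / (nBoot + 1)
  }
  assignments <- lapply(seq_len(nrow(pv)), function(i) {
    hit <- clusters[which(pv[i, ] < alpha)]
    if (length(hit)) hit else "unassigned"
  })
  names(assignments) <- rownames(pv)
  list(pvalues = pv, assignments = assignments)
}

#' Align region-level mean expression on a fixed Sst anchor
#'
#' Each region's gene-mean vector is rescaled so its Sst value is exactly
#' 1000, allowing cross-dataset comparison of somatostatin-neuron
#' profiles; the output table is aligned on the union of genes with
#' absent genes marked NA.
#'
#' @param datasets named list of named gene-mean vectors.
#' @param anchorGene the anchor gene (default \code{"Sst"}).
#' @return data.frame, genes x datasets, on the anchor scale.
#' @export
sstNormalizedMeans <- function(datasets, anchorGene = "Sst") {
  stopifnot(length(datasets) > 0)
  scaled <- lapply(datasets, function(v) {
    if (!anchorGene %in% names(v) || v[[anchorGene]] <= 0)
      .stopf("every dataset needs %s > 0", anchorGene)
    v * 1000 / v[[anchorGene]]
  })
  genes <- Reduce(union, lapply(scaled, names))
  out <- vapply(scaled, function(v) v[genes], numeric(length(genes)))
  rownames(out) <- genes
  as.data.frame(out)
}
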