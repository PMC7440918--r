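#' Run the subtyping pipeline end to end
#'
#' Feature extraction (when ladders are supplied), preprocessing,
#' PCA-order selection, mixture fitting, cluster naming and the summary
#' table, with all artifacts written to \code{outDir}: features.csv,
#' labels.csv, model.json, summary.json and pipeline.log. Fully
#' reproducible from (inputs, config, seed).
#'
#' @param ladders list of \linkS4class{SweepLadder}s (alternative to
#'   \code{fm}).
#' @param fm a \linkS4class{FeatureMatrix} (skips extraction).
#' @param outDir artifact directory (created if needed).
#' @param seed RNG seed for the clustering stages.
#' @param config optional list; recognized entries: \code{stages}
#'   (subset of \code{c("extract","cluster","name","summary")}),
#'   \code{kmaxPca}, \code{krange}, \code{folds}. Unknown stages are a
#'   config error.
#' @return invisibly, a list with the model, report, summary and label
#'   table.
#' @export
runPipeline <- function(ladders = NULL, fm = NULL, outDir, seed = 1,
                        config = list()) {
  known <- c("extract", "cluster", "name", "summary")
  stages <- config$stages %||% known
  if (!all(stages %in% known))
    .stopf("config error: unknown stage(s): %s",
           paste(setdiff(stages, known), collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "pipeline.log")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logFile, append = TRUE)
  cat("", file = logFile)
  stage <- function(name, expr) {
    logLine("[%s] start", name)
    out <- tryCatch(force(expr), error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    logLine("[%s] done", name)
    out
  }
  if (is.null(fm)) {
    if (is.null(ladders)) .stopf("config error: no input provided")
    fm <- stage("extract", extractFeatureMatrix(ladders))
  }
  utils::write.csv(data.frame(cell_id = rownames(featureValues(fm)),
                              featureValues(fm), check.names = FALSE),
                   file.path(outDir, "features.csv"), row.names = FALSE)
  cc <- stage("cluster", clusterCells(
    fm, kmaxPca = config$kmaxPca %||% 9, krange = config$krange %||% 1:7,
    folds = config$folds %||% 5, seed = seed))
  model <- stage("name", nameClusters(cc$model, cc$retained))
  labs <- clusterLabels(model)
  labTab <- data.frame(
    cell_id = rownames(featureValues(cc$retained)),
    cluster = labs,
    subtype = if (length(model@clusterNames)) model@clusterNames[labs]
              else as.character(labs))
  utils::write.csv(labTab, file.path(outDir, "labels.csv"),
                   row.names = FALSE)
  summ <- stage("summary",
                clusterSummary(cc$retained, labTab$subtype))
  jsonlite::write_json(
    list(nPcs = model@nPcs, K = model@gmm$K,
         explainedVar = model@explainedVar,
         bicPca = as.list(model@bicPca), bicGmm = as.list(model@bicGmm),
         weights = model@gmm$weights,
         clusterNames = model@clusterNames, seed = seed),
    file.path(outDir, "model.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(n = as.list(summ$n),
         mean = as.data.frame(summ$mean),
         sem = as.data.frame(summ$sem),
         grandMean = as.list(summ$grandMean)),
    file.path(outDir, "summary.json"), digits = NA)
  logLine("pipeline complete: K=%d, nPcs=%d", model@gmm$K, model@nPcs)
  invisible(list(model = model, report = cc$report, summary = summ,
                 labels = labTab, retained = cc$retained))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
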