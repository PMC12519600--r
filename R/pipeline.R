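#' Assemble a pipeline configuration
#'
#' Defaults mirror the full study protocol: the eight-candidate imputation
#' suite scored by AUC, Tukey fences at 1.5 x IQR, the `log(aX + c)`
#' transform, 10-fold cross-validation with 100 repetitions over the keepX
#' grid {5, 10, 20, 40, 80, 120, 140, p}, up to 4 components, and a
#' relevance-network threshold of 0.23. `reps`, `grid`, `ncompMax` and the
#' candidate list can be scaled down for desk-scale runs.
#'
#' @param synth a [SynthConfig-class] used when no `input` path is given.
#' @param input optional CSV path read by [readCohortCsv()].
#' @param candidates imputation candidates (subset of
#'   [imputationMethods()]).
#' @param tieOrder tie-break order for equal AUCs.
#' @param imputeControl hyperparameters for [imputeTable()].
#' @param fenceMultiplier outlier fence multiplier.
#' @param transform `"log_scaled"`, `"log_shift"` or `"none"`.
#' @param folds,reps,grid,ncompMax,alpha cross-validation protocol.
#' @param threshold relevance-network similarity threshold.
#' @param topK number of top variables to report.
#' @param seed master seed; every stage seed derives from it.
#' @return a named list (class `"pipelineConfig"`).
#' @export
pipelineConfig <- function(synth = synthConfig(), input = NULL,
                           candidates = imputationMethods(),
                           tieOrder = candidates, imputeControl = list(),
                           fenceMultiplier = 1.5,
                           transform = "log_scaled",
                           folds = 10L, reps = 100L,
                           grid = c(5, 10, 20, 40, 80, 120, 140, 148),
                           ncompMax = 4L, alpha = 0.05,
                           threshold = 0.23, topK = 10L, seed = 1L) {
  structure(list(synth = synth, input = input, candidates = candidates,
                 tieOrder = tieOrder, imputeControl = imputeControl,
                 fenceMultiplier = fenceMultiplier, transform = transform,
                 folds = folds, reps = reps, grid = grid,
                 ncompMax = ncompMax, alpha = alpha, threshold = threshold,
                 topK = topK, seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Run the end-to-end biomarker-discovery pipeline
#'
#' Stages, in order: load or simulate the cohort; per-column
#' imputation-method selection by AUC; fence-based outlier detection with
#' uniform replacement; logarithmic transform; Table-1 style univariate
#' screen; cross-validated tuning of keepX, component count and prediction
#' distance; final sparse PLS-DA fit on the full preprocessed data;
#' loading ranking; relevance network with top-variable table. Identical
#' configuration (including seed) gives an identical report.
#'
#' @param config a list from [pipelineConfig()].
#' @return a list (class `"pipelineReport"`) with per-stage summaries plus
#'   the fitted objects (`model`, `cv`, `network`, `table`, `truth`).
#' @export
runPipeline <- function(config) {
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  truth <- NULL
  table <- stage("load", {
    if (!is.null(config$input)) readCohortCsv(config$input)
    else {
      sc <- simulateCohort(config$synth)
      truth <- sc$truth
      sc$table
    }
  })
  rawMissing <- missingRate(table)

  imp <- stage("impute", selectImputation(
    table, config$candidates, config$tieOrder,
    seed = child_seed(seed, "impute"), control = config$imputeControl))
  table <- imp$table

  out <- stage("outliers", treatOutliers(table, config$fenceMultiplier,
                                         seed = child_seed(seed, "outliers")))
  table <- out$table

  specs <- NULL
  if (config$transform != "none") {
    tr <- stage("transform", transformTable(table, config$transform))
    table <- tr$table
    specs <- tr$specs
  }

  screen <- stage("screen", univariateScreen(table))

  X <- cohortValues(table)
  y <- cohortOutcome(table)
  cv <- stage("tune", tuneSplsda(
    X, y, ncompMax = config$ncompMax, grid = config$grid,
    folds = config$folds, reps = config$reps, alpha = config$alpha,
    seed = child_seed(seed, "tune")))

  model <- stage("fit", fitSplsda(X, y, ncomp = cv@chosenNcomp,
                                  keepX = cv@chosenKeepX))

  loadings <- stage("rank", {
    L <- splsdaLoadings(model)
    do.call(rbind, lapply(seq_len(ncol(L)), function(h) {
      nz <- which(L[, h] != 0)
      d <- data.frame(component = h, variable = rownames(L)[nz],
                      loading = unname(L[nz, h]))
      d[order(-abs(d$loading), d$variable), ]
    }))
  })

  network <- stage("network", buildNetwork(
    similarityMatrix(model, X, y), config$threshold))
  top <- rankTopVariables(network, min(config$topK, length(networkNodes(network))))

  structure(list(
    seed = seed,
    missingRate = rawMissing,
    nImputedCells = as.integer(sum(imp$report$nImputed)),
    imputationSelected = table(factor(imp$report$selected,
                                      levels = c("none", config$candidates))),
    imputationReport = imp$report,
    outliersTreated = nrow(out$flagged),
    transform = config$transform,
    transformSpecs = specs,
    screen = screen,
    cv = cv,
    chosenNcomp = cv@chosenNcomp,
    chosenKeepX = cv@chosenKeepX,
    chosenDistance = cv@chosenDistance,
    model = model,
    loadings = loadings,
    variableCounts = list(entered = ncol(X),
                          perComponentKeepX = cv@chosenKeepX,
                          unionSelected = length(selectedVariables(model))),
    network = network,
    topVariables = top,
    table = table,
    truth = truth
  ), class = "pipelineReport")
}

#' @export
print.pipelineReport <- function(x, ...) {
  cat("Biomarker-discovery pipeline report\n")
  cat(sprintf("  raw missing rate: %.3f; imputed cells: %d; outliers treated: %d\n",
              x$missingRate, x$nImputedCells, x$outliersTreated))
  cat(sprintf("  transform: %s\n", x$transform))
  cat(sprintf("  chosen model: ncomp = %d, keepX = %s, distance = %s\n",
              x$chosenNcomp, paste(x$chosenKeepX, collapse = ", "),
              x$chosenDistance))
  cat(sprintf("  variables: %d entered, %d in final model\n",
              x$variableCounts$entered, x$variableCounts$unionSelected))
  cat("  top variables (similarity to case class):\n")
  print(x$topVariables, row.names = FALSE)
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Writes `report.json` (stage summaries, chosen model, ranked loadings,
#' top variables, edge list; deterministic for a fixed config and seed),
#' `loadings.tsv`, `ber_grid.tsv`, `edges.tsv`, `screen.tsv`,
#' `network.graphml` and, for synthetic runs, `cohort.csv` and
#' `truth.json`.
#'
#' @param report a list from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePipelineReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  utils::write.table(report$loadings, fp("loadings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$cv@berTable, fp("ber_grid.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeScreenTsv(report$screen, fp("screen.tsv"))
  writeEdgesTsv(report$network, fp("edges.tsv"))
  writeNetworkGraphML(report$network, fp("network.graphml"))
  if (!is.null(report$truth)) {
    writeCohortCsv(report$table, fp("cohort.csv"))
    writeTruthJson(report$truth, fp("truth.json"))
  }
  json <- list(
    seed = report$seed,
    missing_rate = report$missingRate,
    n_imputed_cells = report$nImputedCells,
    imputation_selected = as.list(report$imputationSelected),
    outliers_treated = report$outliersTreated,
    transform = report$transform,
    chosen = list(ncomp = report$chosenNcomp,
                  keepX = report$chosenKeepX,
                  distance = report$chosenDistance),
    variable_counts = report$variableCounts,
    ber_grid = report$cv@berTable,
    loadings = report$loadings,
    top_variables = report$topVariables,
    edges = networkEdges(report$network)
  )
  jsonlite::write_json(json, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
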