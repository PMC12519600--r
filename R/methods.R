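#' @rdname CohortTable-class
#' @param values numeric matrix with unique column names; NA marks missing.
#' @param outcome binary vector (0/1 or a two-level factor), one per row.
#' @param blocks optional block label per column; defaults to "predictor".
#' @return A validated [CohortTable-class] object.
#' @examples
#' x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("v", 1:4)))
#' ct <- cohortTable(x, outcome = rep(c(0, 1), 5))
#' dim(ct)
#' @export
cohortTable <- function(values, outcome, blocks = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
  if (is.character(outcome)) {
    outcome <- match(tolower(outcome), c("no", "yes")) - 1L
  }
  outcome <- as.integer(outcome)
  if (is.null(blocks)) blocks <- rep("predictor", ncol(values))
  new("CohortTable", values = values, blocks = as.character(blocks),
      outcome = outcome)
}

#' Accessors for CohortTable
#'
#' @param x a [CohortTable-class].
#' @return `cohortValues()` the numeric matrix; `cohortOutcome()` the 0/1
#'   vector; `cohortBlocks()` the block label per column;
#'   `missingRate()` the fraction of NA cells.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
cohortValues <- function(x) x@values

#' @rdname cohort-accessors
#' @export
cohortOutcome <- function(x) x@outcome

#' @rdname cohort-accessors
#' @export
cohortBlocks <- function(x) x@blocks

#' @rdname cohort-accessors
#' @export
missingRate <- function(x) mean(is.na(x@values))

#' @describeIn CohortTable-class dimensions of the feature matrix.
#' @export
setMethod("dim", "CohortTable", function(x) dim(x@values))

setMethod("show", "CohortTable", function(object) {
  v <- object@values
  n1 <- sum(object@outcome == 1L)
  cat(sprintf("CohortTable: %d samples x %d predictors\n", nrow(v), ncol(v)))
  cat(sprintf("  outcome: %d cases / %d controls\n", n1, nrow(v) - n1))
  cat(sprintf("  blocks: %s\n",
              paste(sprintf("%s(%d)", names(table(object@blocks)),
                            table(object@blocks)), collapse = ", ")))
  cat(sprintf("  missing cells: %d (%.2f%%)\n",
              sum(is.na(v)), 100 * mean(is.na(v))))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d informative columns (%d up, %d down in cases)\n",
              length(object@informative), sum(object@directions > 0),
              sum(object@directions < 0)))
  cat(sprintf("  missing cells: %d; outlier cells: %d; seed: %d\n",
              nrow(object@missingMask), nrow(object@outlierCells), object@seed))
})

#' Accessors for SyntheticTruth
#'
#' @param x a [SyntheticTruth-class].
#' @return `informativeColumns()` planted column indices;
#'   `effectDirections()` their +1/-1 signs; `missingMask()` and
#'   `outlierCells()` two-column (row, col) index matrices.
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
informativeColumns <- function(x) x@informative

#' @rdname truth-accessors
#' @export
effectDirections <- function(x) x@directions

#' @rdname truth-accessors
#' @export
missingMask <- function(x) x@missingMask

#' @rdname truth-accessors
#' @export
outlierCells <- function(x) x@outlierCells

setMethod("show", "SplsdaModel", function(object) {
  cat(sprintf("SplsdaModel: %d components over %d predictors (classes %s / %s)\n",
              object@ncomp, nrow(object@loadingsX),
              object@labels[1], object@labels[2]))
  cat(sprintf("  keepX: %s; NIPALS iterations: %s\n",
              paste(object@keepX, collapse = ", "),
              paste(object@iterations, collapse = ", ")))
  if (length(object@constantCols))
    cat(sprintf("  constant predictors kept with zero weight: %d\n",
                length(object@constantCols)))
})

#' Accessors for SplsdaModel
#'
#' @param x a fitted [SplsdaModel-class].
#' @param comp component index (for `loadings`-type accessors).
#' @return `splsdaLoadings()` the p x H sparse x-loading matrix;
#'   `splsdaScores()` the n x H training scores; `splsdaKeepX()` the
#'   per-component retained-variable counts; `selectedVariables()` the
#'   names of variables with a nonzero loading on at least one (or the
#'   given) component.
#' @name splsda-accessors
NULL

#' @rdname splsda-accessors
#' @export
splsdaLoadings <- function(x) x@loadingsX

#' @rdname splsda-accessors
#' @export
splsdaScores <- function(x) x@scores

#' @rdname splsda-accessors
#' @export
splsdaKeepX <- function(x) x@keepX

#' @rdname splsda-accessors
#' @export
selectedVariables <- function(x, comp = NULL) {
  L <- x@loadingsX
  nz <- if (is.null(comp)) rowSums(L != 0) > 0 else L[, comp] != 0
  rownames(L)[nz]
}

setMethod("show", "CvResult", function(object) {
  cat(sprintf("CvResult: %d-fold CV x %d repetitions over keepX grid {%s}\n",
              object@folds, object@reps,
              paste(object@grid, collapse = ", ")))
  cat(sprintf("  chosen: ncomp = %d, keepX = %s, distance = %s\n",
              object@chosenNcomp,
              paste(object@chosenKeepX, collapse = ", "),
              object@chosenDistance))
  i <- which(object@berTable$component == object@chosenNcomp &
             object@berTable$distance == object@chosenDistance &
             object@berTable$keepX == object@chosenKeepX[object@chosenNcomp])
  if (length(i))
    cat(sprintf("  BER at chosen model: %.3f (SD %.3f), AUC %.3f\n",
                object@berTable$berMean[i[1]], object@berTable$berSD[i[1]],
                object@berTable$aucMean[i[1]]))
})

setMethod("show", "RelevanceNetwork", function(object) {
  cat(sprintf("RelevanceNetwork: %d variables + 2 class nodes, |similarity| >= %.2f\n",
              length(object@nodes), object@threshold))
  cat(sprintf("  edges: %d (%d positive, %d negative)\n",
              nrow(object@edges), sum(object@edges$sign > 0),
              sum(object@edges$sign < 0)))
})

#' Accessors for RelevanceNetwork
#'
#' @param x a [RelevanceNetwork-class].
#' @return `networkEdges()` the thresholded edge data.frame;
#'   `networkNodes()` the variable node names.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
networkEdges <- function(x) x@edges

#' @rdname network-accessors
#' @export
networkNodes <- function(x) x@nodes
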