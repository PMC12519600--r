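#' Configuration for the synthetic cohort generator
#'
#' Holds the study-design parameters emulated by [generateCohort()]: cohort
#' size, number of predictors, case prevalence, the planted informative
#' features and their standardized effect size, block structure, within-block
#' correlation, and the missingness / outlier contamination rates.
#'
#' @slot nSamples number of participants.
#' @slot nFeatures number of predictor columns.
#' @slot prevalence fraction of cases (outcome = 1); class sizes are fixed at
#'   `ceiling(prevalence * nSamples)`, not sampled.
#' @slot nInformative number of truly discriminative columns.
#' @slot effectSize standardized (within-class SD units) mean difference per
#'   informative column.
#' @slot blockSpec data.frame with columns `block`, `n`, `location`, `scale`
#'   describing each predictor block; the `n` column must sum to `nFeatures`.
#' @slot withinBlockCorrelation correlation induced within a block through a
#'   shared latent factor, in [0, 1).
#' @slot missingRate target fraction of missing cells under MAR.
#' @slot outlierCellFraction fraction of cells displaced to extreme values.
#' @slot outlierMagnitude length-2 range of |z| displacements in column SDs.
#' @slot seed integer generator seed.
#'
#' @seealso [synthConfig()] for the validated constructor.
#' @export
setClass("SynthConfig", representation(
  nSamples = "integer",
  nFeatures = "integer",
  prevalence = "numeric",
  nInformative = "integer",
  effectSize = "numeric",
  blockSpec = "data.frame",
  withinBlockCorrelation = "numeric",
  missingRate = "numeric",
  outlierCellFraction = "numeric",
  outlierMagnitude = "numeric",
  seed = "integer"
))

setValidity("SynthConfig", function(object) {
  msg <- character()
  n <- object@nSamples
  p <- object@nFeatures
  if (n < 4L) msg <- c(msg, "nSamples: need at least 4 samples")
  if (object@nInformative > p)
    msg <- c(msg, "nInformative: exceeds nFeatures")
  if (object@prevalence <= 0 || object@prevalence >= 1)
    msg <- c(msg, "prevalence: must lie in (0, 1)")
  else {
    n1 <- ceiling(object@prevalence * n)
    if (n1 < 2L || n - n1 < 2L)
      msg <- c(msg, "prevalence: each class needs at least 2 samples")
  }
  if (object@missingRate < 0 || object@missingRate >= 0.5)
    msg <- c(msg, "missingRate: must lie in [0, 0.5)")
  if (object@withinBlockCorrelation < 0 || object@withinBlockCorrelation >= 1)
    msg <- c(msg, "withinBlockCorrelation: must lie in [0, 1)")
  if (object@outlierCellFraction < 0 || object@outlierCellFraction > 0.05)
    msg <- c(msg, "outlierCellFraction: must lie in [0, 0.05]")
  if (length(object@outlierMagnitude) != 2L ||
      object@outlierMagnitude[1] <= 0 ||
      diff(object@outlierMagnitude) < 0)
    msg <- c(msg, "outlierMagnitude: need 0 < lower <= upper")
  bs <- object@blockSpec
  need <- c("block", "n", "location", "scale")
  if (!all(need %in% names(bs)))
    msg <- c(msg, "blockSpec: needs columns block, n, location, scale")
  else if (sum(bs$n) != p)
    msg <- c(msg, sprintf("blockSpec: feature counts sum to %d, not nFeatures = %d",
                          sum(bs$n), p))
  if (length(msg)) msg else TRUE
})

#' Cohort feature table with binary endpoint
#'
#' An n-samples by p-predictors numeric matrix (NA marks missing cells)
#' together with a block label per column and a binary outcome per row
#' (1 = case, e.g. subclinical atherosclerotic plaque present; 0 = control).
#'
#' @slot values numeric matrix, one row per participant, unique column names.
#' @slot blocks character vector of block labels, one per column.
#' @slot outcome integer vector in {0, 1}, one per row, both classes present.
#'
#' @seealso [cohortTable()], [cohortValues()], [cohortOutcome()],
#'   [cohortBlocks()], [readCohortCsv()], [writeCohortCsv()]
#' @export
setClass("CohortTable", representation(
  values = "matrix",
  blocks = "character",
  outcome = "integer"
))

setValidity("CohortTable", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values: must be numeric")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "values: column names must exist and be unique")
  if (length(object@outcome) != nrow(v))
    msg <- c(msg, "outcome: length must equal row count")
  if (!all(object@outcome %in% c(0L, 1L)))
    msg <- c(msg, "outcome: values must be 0 or 1")
  else if (length(unique(object@outcome)) < 2L)
    msg <- c(msg, "outcome: both classes must be present (single class)")
  if (length(object@blocks) != ncol(v))
    msg <- c(msg, "blocks: one label per column required")
  if (length(msg)) msg else TRUE
})

#' Ground-truth manifest for a synthetic cohort
#'
#' Records everything the generator planted so recovery can be scored:
#' which columns carry signal and in which direction, which cells were
#' deleted (MAR mask) and which were displaced to outliers.
#'
#' @slot informative integer indices of planted discriminative columns.
#' @slot directions numeric +1/-1 per informative column (+1 = higher in cases).
#' @slot missingMask two-column integer matrix of (row, col) deleted cells.
#' @slot outlierCells two-column integer matrix of (row, col) displaced cells.
#' @slot seed the generator seed.
#' @export
setClass("SyntheticTruth", representation(
  informative = "integer",
  directions = "numeric",
  missingMask = "matrix",
  outlierCells = "matrix",
  seed = "integer"
))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (length(object@directions) != length(object@informative))
    msg <- c(msg, "directions: one sign per informative column")
  if (length(object@directions) && !all(object@directions %in% c(-1, 1)))
    msg <- c(msg, "directions: must be +1 or -1")
  if (nrow(object@missingMask) && nrow(object@outlierCells)) {
    key <- function(m) paste(m[, 1], m[, 2])
    if (length(intersect(key(object@missingMask), key(object@outlierCells))))
      msg <- c(msg, "missingMask and outlierCells must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted sparse PLS-DA model
#'
#' A sparse partial least squares discriminant analysis fit: per-component
#' soft-thresholded x-loadings (unit norm, `keepX[h]` nonzeros), y-loadings,
#' training scores, deflation and regression vectors, plus the training
#' scaling, class centroids and pooled within-class score covariance needed
#' for prediction.
#'
#' Sign convention: each component is oriented so that its score correlates
#' non-negatively with the case (second-level) dummy, so variables elevated
#' in cases load positive and case-depleted variables load negative.
#'
#' @slot xCenter,xScale training column means / SDs of the predictors.
#' @slot yCenter,yScale centering / scaling of the two-column class dummy.
#' @slot ncomp number of components H.
#' @slot keepX integer vector, retained variables per component.
#' @slot loadingsX p x H matrix of sparse x-loadings (columns unit norm).
#' @slot loadingsY 2 x H matrix of y-loadings.
#' @slot scores n x H training score matrix (mutually orthogonal columns).
#' @slot loadingsP p x H x-deflation vectors.
#' @slot regressionQ 2 x H y-regression vectors.
#' @slot labels the two class labels, control first.
#' @slot centroids 2 x H class centroids in score space.
#' @slot withinCov H x H pooled within-class score covariance.
#' @slot constantCols indices of zero-variance predictors (kept, zero weight).
#' @slot iterations NIPALS iteration count per component.
#' @export
setClass("SplsdaModel", representation(
  xCenter = "numeric", xScale = "numeric",
  yCenter = "numeric", yScale = "numeric",
  ncomp = "integer", keepX = "integer",
  loadingsX = "matrix", loadingsY = "matrix",
  scores = "matrix", loadingsP = "matrix", regressionQ = "matrix",
  labels = "character", centroids = "matrix", withinCov = "matrix",
  constantCols = "integer", iterations = "integer"
))

setValidity("SplsdaModel", function(object) {
  msg <- character()
  H <- object@ncomp
  if (ncol(object@loadingsX) != H || ncol(object@scores) != H)
    msg <- c(msg, "loadingsX / scores: one column per component required")
  if (length(object@keepX) != H)
    msg <- c(msg, "keepX: one entry per component required")
  nrm <- sqrt(colSums(object@loadingsX^2))
  if (any(abs(nrm - 1) > 1e-6))
    msg <- c(msg, "loadingsX: columns must have unit norm")
  if (length(object@labels) != 2L)
    msg <- c(msg, "labels: exactly two classes supported")
  if (length(msg)) msg else TRUE
})

#' Cross-validation tuning result
#'
#' Balanced error rate and AUC summaries over a keepX grid, component counts
#' and prediction distances, across repeated stratified folds, together with
#' the selected hyperparameters.
#'
#' @slot grid keepX candidates evaluated.
#' @slot reps,folds cross-validation protocol.
#' @slot berTable data.frame: component, keepX, distance, berMean, berSD,
#'   aucMean over repetitions.
#' @slot chosenKeepX selected keepX per component.
#' @slot chosenNcomp selected number of components.
#' @slot chosenDistance selected prediction distance.
#' @slot seed master seed of the protocol.
#' @export
setClass("CvResult", representation(
  grid = "integer", reps = "integer", folds = "integer",
  berTable = "data.frame",
  chosenKeepX = "integer", chosenNcomp = "integer",
  chosenDistance = "character", seed = "integer"
))

setValidity("CvResult", function(object) {
  msg <- character()
  if (length(object@chosenKeepX) && !all(object@chosenKeepX %in% object@grid))
    msg <- c(msg, "chosenKeepX: must come from the candidate grid")
  if (nrow(object@berTable) &&
      (any(object@berTable$berMean < 0) || any(object@berTable$berMean > 1)))
    msg <- c(msg, "berTable: BER means must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Thresholded relevance network
#'
#' Variable-to-class and variable-to-variable similarities derived from the
#' latent components of a sparse PLS-DA fit (sums over components of
#' correlation products with the component scores), with the edge list
#' thresholded at `|similarity| >= threshold`.
#'
#' @slot nodes selected predictor variables (nonzero loading on >= 1 comp).
#' @slot classNodes the two class node names, control first.
#' @slot varClass nodes x 2 signed similarity to each class.
#' @slot varVar symmetric nodes x nodes similarity matrix.
#' @slot pearsonClass plain Pearson correlation of each node with the case
#'   indicator, reported alongside the model-based similarity.
#' @slot threshold minimum |similarity| for an edge (default 0.23).
#' @slot edges data.frame: nodeA, nodeB, similarity, sign.
#' @export
setClass("RelevanceNetwork", representation(
  nodes = "character", classNodes = "character",
  varClass = "matrix", varVar = "matrix",
  pearsonClass = "numeric",
  threshold = "numeric", edges = "data.frame"
))

setValidity("RelevanceNetwork", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@varVar, t(object@varVar), tolerance = 1e-8)))
    msg <- c(msg, "varVar: must be symmetric")
  if (nrow(object@edges) &&
      any(abs(object@edges$similarity) < object@threshold - 1e-12))
    msg <- c(msg, "edges: every edge must meet the threshold")
  if (length(msg)) msg else TRUE
})
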