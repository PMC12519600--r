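#' Default predictor block layout
#'
#' Mirrors the measurement categories of an immune-aging cohort: T-cell
#' subset percentages, a 38-protein serum panel, PBMC gene expression,
#' vascular function, anthropometrics, wearable activity and food-frequency
#' items. `location` and `scale` are block-typical centres and SDs; each
#' column draws its own location/scale uniformly within +/- 50% of these.
#'
#' @return data.frame with columns block, n, location, scale (n sums to 148).
#' @export
defaultBlockSpec <- function() {
  data.frame(
    block = c("cellular_pct", "protein", "gene_expr", "vascular",
              "anthropometric", "activity", "nutrition"),
    n = c(30L, 38L, 20L, 15L, 10L, 10L, 25L),
    location = c(20, 500, 1, 100, 60, 8000, 3),
    scale = c(6, 150, 0.4, 15, 12, 2500, 1.2),
    stringsAsFactors = FALSE
  )
}

#' Construct a synthetic-cohort configuration
#'
#' Defaults emulate the study design the pipeline targets: 79 participants
#' of whom 29 are cases (prevalence 29/79), 148 numeric predictors in seven
#' blocks, 10 truly discriminative columns at a standardized effect of 1 SD,
#' 3.8% missing cells under MAR, and sporadic 4-8 SD outliers in 0.5% of
#' cells.
#'
#' @param nSamples,nFeatures,prevalence,nInformative,effectSize,blockSpec,withinBlockCorrelation,missingRate,outlierCellFraction,outlierMagnitude,seed
#'   see [SynthConfig-class].
#' @return a validated [SynthConfig-class].
#' @examples
#' cfg <- synthConfig(seed = 1)
#' cfg@nSamples
#' @export
synthConfig <- function(nSamples = 79L, nFeatures = 148L,
                        prevalence = 29 / 79, nInformative = 10L,
                        effectSize = 1.0, blockSpec = defaultBlockSpec(),
                        withinBlockCorrelation = 0.2,
                        missingRate = 0.038, outlierCellFraction = 0.005,
                        outlierMagnitude = c(4, 8), seed = 1L) {
  if (nFeatures != sum(blockSpec$n) && identical(blockSpec, defaultBlockSpec())) {
    # rescale the default layout proportionally (largest-remainder rounding)
    # when nFeatures is overridden; blocks rounded to zero are dropped
    raw <- blockSpec$n * nFeatures / sum(blockSpec$n)
    n <- floor(raw)
    rem <- nFeatures - sum(n)
    if (rem > 0) {
      bump <- order(raw - n, decreasing = TRUE)[seq_len(rem)]
      n[bump] <- n[bump] + 1L
    }
    blockSpec$n <- as.integer(n)
    blockSpec <- blockSpec[blockSpec$n > 0L, , drop = FALSE]
  }
  new("SynthConfig",
      nSamples = as.integer(nSamples), nFeatures = as.integer(nFeatures),
      prevalence = prevalence, nInformative = as.integer(nInformative),
      effectSize = effectSize, blockSpec = blockSpec,
      withinBlockCorrelation = withinBlockCorrelation,
      missingRate = missingRate, outlierCellFraction = outlierCellFraction,
      outlierMagnitude = as.numeric(outlierMagnitude),
      seed = as.integer(seed))
}

# Realistic leading names per block; remaining columns are numbered.
.block_names <- list(
  cellular_pct = c("CD4_naive_pct", "CD4_CM_pct", "CD4_EM_pct", "CD4_TEMRA_pct",
                   "CD8_naive_pct", "CD8_CM_pct", "CD8_EM_pct", "CD8_TEMRA_pct",
                   "DN_lymphocytes_pct", "Treg_pct"),
  protein = c("OPN", "IL18", "GDF15", "MMP12", "TenascinC", "TRAIL",
              "IFNg", "IL6", "IL15", "IL1RA", "FGF23", "Galectin3"),
  gene_expr = c("LMNB1_expr", "TP53_expr", "PRKAA1_expr", "FOXO3_expr",
                "SERPINE1_expr", "TNFSF10_expr"),
  vascular = c("SBP", "cSBP", "DBP", "cDBP", "vascular_age", "PWV", "Aix75"),
  anthropometric = c("age", "BMI", "body_fat_pct", "VAT_pct", "grip_strength"),
  activity = c("VO2peak", "daily_steps", "floors", "distance_km"),
  nutrition = c("cooked_fruit", "raw_vegetables", "whole_grain", "red_meat")
)

.make_column_names <- function(blockSpec) {
  unlist(lapply(seq_len(nrow(blockSpec)), function(b) {
    blk <- blockSpec$block[b]
    n <- blockSpec$n[b]
    nm <- .block_names[[blk]] %||% character()
    nm <- nm[seq_len(min(length(nm), n))]
    if (length(nm) < n)
      nm <- c(nm, sprintf("%s_%02d", blk, seq_len(n - length(nm))))
    nm
  }), use.names = FALSE)
}

#' Generate a complete synthetic cohort with ground truth
#'
#' Draws a complete (no missing cells, no outliers) feature table. Within
#' each block, columns share a latent factor inducing the configured
#' within-block correlation; the planted informative columns differ between
#' cases and controls by `effectSize` within-class SDs in the recorded
#' direction. Class sizes are fixed (`ceiling(prevalence * n)` cases), not
#' sampled. Identical configuration (including seed) gives identical output.
#'
#' @param config a [SynthConfig-class].
#' @return list with elements `table` ([CohortTable-class]) and `truth`
#'   ([SyntheticTruth-class]).
#' @examples
#' gc <- generateCohort(synthConfig(seed = 7))
#' dim(gc$table)
#' sum(cohortOutcome(gc$table))
#' @export
generateCohort <- function(config) {
  validObject(config)
  n <- config@nSamples
  p <- config@nFeatures
  bs <- config@blockSpec
  rho <- config@withinBlockCorrelation
  n1 <- as.integer(ceiling(config@prevalence * n))
  outcome <- c(rep(0L, n - n1), rep(1L, n1))

  with_seed(config@seed, {
    informative <- sort(sample.int(p, config@nInformative))
    directions <- sample(c(-1, 1), config@nInformative, replace = TRUE)
    dir_of <- numeric(p)
    dir_of[informative] <- directions

    blocks <- rep(bs$block, bs$n)
    X <- matrix(0.0, n, p)
    j0 <- 0L
    for (b in seq_len(nrow(bs))) {
      nb <- bs$n[b]
      latent <- rnorm(n)
      z <- sqrt(rho) * matrix(latent, n, nb) +
        sqrt(1 - rho) * matrix(rnorm(n * nb), n, nb)
      cols <- j0 + seq_len(nb)
      z <- z + outcome %o% (config@effectSize * dir_of[cols])
      loc <- runif(nb, 0.5 * bs$location[b], 1.5 * bs$location[b])
      scl <- runif(nb, 0.5 * bs$scale[b], 1.5 * bs$scale[b])
      v <- sweep(sweep(z, 2, scl, `*`), 2, loc, `+`)
      if (bs$block[b] == "cellular_pct") v <- pmin(pmax(v, 0), 100)
      X[, cols] <- v
      j0 <- j0 + nb
    }
    colnames(X) <- .make_column_names(bs)

    list(
      table = cohortTable(X, outcome, blocks),
      truth = new("SyntheticTruth",
                  informative = informative, directions = directions,
                  missingMask = matrix(integer(), 0, 2),
                  outlierCells = matrix(integer(), 0, 2),
                  seed = config@seed)
    )
  })
}

# First column of each block is the designated always-observed MAR driver.
.driver_columns <- function(blocks) {
  match(unique(blocks), blocks)
}

#' Delete cells missing-at-random
#'
#' Cells are deleted with probability `plogis(a + z)` where `z` is the
#' standardized value of the deleting column's block driver (the first
#' column of each block, itself never deleted) and the intercept `a` is
#' calibrated so the expected deletion rate equals `rate`. The probability
#' depends only on always-observed values, never on the deleted value
#' itself (MAR). The realized mask is appended to the truth manifest.
#'
#' @param table complete [CohortTable-class].
#' @param truth matching [SyntheticTruth-class].
#' @param rate target missing fraction in [0, 0.5).
#' @param seed integer seed.
#' @return list(table, truth) with NA cells and the recorded mask.
#' @export
injectMissingMAR <- function(table, truth, rate, seed) {
  if (rate < 0 || rate >= 0.5) stopf("rate = %g out of [0, 0.5)", rate)
  if (rate == 0) return(list(table = table, truth = truth))
  X <- table@values
  n <- nrow(X); p <- ncol(X)
  drivers <- .driver_columns(table@blocks)
  # per-column driver z-scores, recycled across the block's columns
  zdrv <- vapply(drivers, function(j) as.numeric(scale(X[, j])), numeric(n))
  colnames(zdrv) <- table@blocks[drivers]
  eligible <- setdiff(seq_len(p), drivers)
  z_all <- zdrv[, match(table@blocks[eligible], colnames(zdrv)), drop = FALSE]
  # calibrate the logistic intercept so that mean deletion prob = target rate
  # over *all* n*p cells (driver columns contribute zero deletions)
  target <- rate * (n * p) / (n * length(eligible))
  if (target >= 1) stopf("rate = %g infeasible with %d protected driver columns",
                         rate, length(drivers))
  a <- uniroot(function(a) mean(plogis(a + z_all)) - target,
               c(-30, 30), tol = 1e-10)$root
  with_seed(seed, {
    del <- matrix(runif(n * length(eligible)), n) < plogis(a + z_all)
    mask <- which(del, arr.ind = TRUE)
    mask <- cbind(row = as.integer(mask[, 1]),
                  col = as.integer(eligible[mask[, 2]]))
  })
  X[mask] <- NA_real_
  table@values <- X
  truth@missingMask <- rbind(truth@missingMask, mask)
  validObject(truth)
  list(table = table, truth = truth)
}

#' @importFrom stats plogis uniroot
NULL

#' Displace cells to extreme outliers
#'
#' A seeded uniform sample of observed cells (never cells already in the
#' missing mask) is displaced to `column mean +/- u * column SD`, with `u`
#' drawn uniformly from `magnitude` and mean/SD computed on the observed
#' cells before injection. Coordinates are recorded in the truth manifest.
#'
#' @param table [CohortTable-class].
#' @param truth matching [SyntheticTruth-class].
#' @param cellFraction fraction of cells to displace, in [0, 0.05].
#' @param magnitude length-2 positive range of |z| displacements.
#' @param seed integer seed.
#' @return list(table, truth).
#' @export
injectOutliers <- function(table, truth, cellFraction, magnitude = c(4, 8),
                           seed = 1L) {
  if (cellFraction < 0 || cellFraction > 0.05)
    stopf("cellFraction = %g out of [0, 0.05]", cellFraction)
  if (magnitude[1] <= 0) stopf("magnitude lower bound must be positive")
  if (cellFraction == 0) return(list(table = table, truth = truth))
  X <- table@values
  n <- nrow(X); p <- ncol(X)
  ncells <- round(cellFraction * n * p)
  if (ncells == 0) return(list(table = table, truth = truth))
  obs <- which(!is.na(X))
  mu <- colMeans(X, na.rm = TRUE)
  sdv <- apply(X, 2, sd, na.rm = TRUE)
  with_seed(seed, {
    pick <- sample(obs, ncells)
    u <- runif(ncells, magnitude[1], magnitude[2])
    sgn <- sample(c(-1, 1), ncells, replace = TRUE)
  })
  cols <- ((pick - 1L) %/% n) + 1L
  rows <- ((pick - 1L) %% n) + 1L
  X[cbind(rows, cols)] <- mu[cols] + sgn * u * sdv[cols]
  table@values <- X
  truth@outlierCells <- rbind(truth@outlierCells,
                              cbind(row = rows, col = cols))
  validObject(truth)
  list(table = table, truth = truth)
}

#' Simulate a full study cohort
#'
#' Convenience wrapper: [generateCohort()], then [injectMissingMAR()] at the
#' configured rate, then [injectOutliers()], with stage seeds derived
#' deterministically from the configuration seed.
#'
#' @param config a [SynthConfig-class].
#' @return list(table, truth).
#' @examples
#' sc <- simulateCohort(synthConfig(seed = 3))
#' missingRate(sc$table)
#' @export
simulateCohort <- function(config) {
  gc <- generateCohort(config)
  gc <- injectMissingMAR(gc$table, gc$truth, config@missingRate,
                         child_seed(config@seed, "mar"))
  injectOutliers(gc$table, gc$truth, config@outlierCellFraction,
                 config@outlierMagnitude, child_seed(config@seed, "outliers"))
}

#' Write / read a cohort as CSV
#'
#' The on-disk format is one header row, one row per participant, numeric
#' predictor columns with empty fields for missing cells, and a final
#' binary column `SAP`.
#'
#' @param table a [CohortTable-class].
#' @param path file path.
#' @param blocks optional block labels to attach on read (defaults to
#'   "predictor" for every column).
#' @return `readCohortCsv()` returns a [CohortTable-class];
#'   `writeCohortCsv()` returns `path` invisibly.
#' @export
writeCohortCsv <- function(table, path) {
  df <- as.data.frame(table@values)
  df$SAP <- table@outcome
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path, blocks = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"SAP" %in% names(df)) stopf("missing outcome column 'SAP' in %s", path)
  if (anyDuplicated(names(df))) stopf("duplicate column names in %s", path)
  out <- df$SAP
  if (is.character(out)) out <- match(tolower(out), c("no", "yes")) - 1L
  if (!all(out %in% c(0, 1))) stopf("outcome not binary in %s", path)
  if (length(unique(out)) < 2L) stopf("single class in %s", path)
  df$SAP <- NULL
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) {
    for (j in bad) {
      cell <- which(!grepl("^\\s*-?[0-9.eE+]*\\s*$", df[[j]]))[1]
      stopf("non-numeric cell at row %d, column '%s'", cell %||% 1L,
            names(df)[j])
    }
  }
  cohortTable(as.matrix(df), as.integer(out), blocks)
}

#' Write the ground-truth manifest as JSON
#'
#' Indices are written 0-based for language-neutral consumption.
#'
#' @param truth a [SyntheticTruth-class].
#' @param path file path.
#' @export
writeTruthJson <- function(truth, path) {
  jsonlite::write_json(list(
    informative_indices = truth@informative - 1L,
    effect_directions = truth@directions,
    missing_mask = unname(truth@missingMask - 1L),
    outlier_cells = unname(truth@outlierCells - 1L),
    generator_seed = truth@seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
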