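#' Detect outliers by quartile fences
#'
#' Q1 and Q3 are computed on the observed values by linear interpolation
#' between order statistics (R quantile type 7); the fences are
#' `Q1 - m * IQR` and `Q3 + m * IQR` with `m = fenceMultiplier`. Observed
#' cells strictly outside the fences are flagged; missing cells are never
#' flagged. Fewer than 4 observed values is a no-op with a warning.
#'
#' @param values numeric column, NA allowed.
#' @param fenceMultiplier positive fence multiplier, default 1.5 (Tukey).
#' @return list with `indices` (flagged positions in `values`) and
#'   `bounds` (lower, upper).
#' @examples
#' detectOutliers(c(1, 2, 3, 4, 100))  # bounds (-1, 7), index 5 flagged
#' @export
detectOutliers <- function(values, fenceMultiplier = 1.5) {
  if (fenceMultiplier <= 0) stopf("fenceMultiplier must be positive")
  obs <- which(!is.na(values))
  if (length(obs) < 4L) {
    warnf("fewer than 4 observed values; outlier detection skipped")
    return(list(indices = integer(), bounds = c(lower = -Inf, upper = Inf)))
  }
  q <- quantile(values[obs], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  bounds <- c(lower = q[1] - fenceMultiplier * iqr,
              upper = q[2] + fenceMultiplier * iqr)
  flag <- obs[values[obs] < bounds[1] | values[obs] > bounds[2]]
  list(indices = flag, bounds = bounds)
}

#' Replace flagged outliers with uniform draws inside the fences
#'
#' Each flagged cell is replaced by an independent Uniform(lower, upper)
#' draw; all other cells are returned bit-identical. After replacement no
#' observed value lies outside the bounds.
#'
#' @param values numeric column.
#' @param indices positions to replace (must be observed cells).
#' @param bounds length-2 finite (lower, upper) with lower < upper.
#' @param seed integer seed.
#' @return the column with replacements.
#' @export
replaceOutliers <- function(values, indices, bounds, seed = 1L) {
  if (!length(indices)) return(values)
  if (!all(is.finite(bounds)) || bounds[1] >= bounds[2])
    stopf("degenerate bounds [%g, %g]", bounds[1], bounds[2])
  if (anyNA(values[indices])) stopf("cannot replace missing cells")
  values[indices] <- with_seed(seed,
    runif(length(indices), bounds[1], bounds[2]))
  values
}

#' Fence-detect and replace outliers across a whole table
#'
#' Applies [detectOutliers()] and [replaceOutliers()] column by column with
#' per-column seeds derived from `seed`.
#'
#' @param table a [CohortTable-class].
#' @param fenceMultiplier fence multiplier, default 1.5.
#' @param seed integer seed.
#' @return list with `table` (treated [CohortTable-class]), `flagged`
#'   (data.frame row, col, original value) and `bounds` (p x 2 matrix).
#' @export
treatOutliers <- function(table, fenceMultiplier = 1.5, seed = 1L) {
  X <- table@values
  bounds <- matrix(NA_real_, ncol(X), 2,
                   dimnames = list(colnames(X), c("lower", "upper")))
  rows <- integer(); cols <- integer(); orig <- numeric()
  for (j in seq_len(ncol(X))) {
    det <- suppressWarnings(detectOutliers(X[, j], fenceMultiplier))
    bounds[j, ] <- det$bounds
    if (length(det$indices)) {
      rows <- c(rows, det$indices)
      cols <- c(cols, rep.int(j, length(det$indices)))
      orig <- c(orig, X[det$indices, j])
      X[, j] <- replaceOutliers(X[, j], det$indices, det$bounds,
                                child_seed(seed, sprintf("out_%d", j)))
    }
  }
  table@values <- X
  list(table = table,
       flagged = data.frame(row = rows, col = cols, value = orig),
       bounds = bounds)
}
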