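#' Fit and apply a logarithmic transform to a column
#'
#' Two variance-stabilising transforms for right-skewed biomarker data:
#' \describe{
#'   \item{`log_shift`}{`x -> log(x + 1e-5)`; requires all observed values
#'     `> -1e-5`.}
#'   \item{`log_scaled`}{`x -> log(a * x' + c)` where `x' = x - min(x)` if
#'     the column contains non-positive values (offset-based treatment of
#'     negatives) and `x' = x` otherwise, `c` is the smallest strictly
#'     positive value of `x'` and `a = 1/c` (so `a * c = 1`).}
#' }
#' Both are strictly increasing on their domain, so ranks are preserved
#' exactly. The returned spec reapplies the fitted transform to held-out
#' data via [applyTransform()].
#'
#' @param values numeric column (NA allowed; NA propagates).
#' @param kind `"log_shift"` or `"log_scaled"`.
#' @return list with `values` (transformed column) and `spec`
#'   (kind, offset, c, a).
#' @examples
#' fitApplyTransform(c(0, 2, 5), "log_scaled")$values  # log(2), log(3), log(4.5)
#' @export
fitApplyTransform <- function(values, kind = c("log_scaled", "log_shift")) {
  kind <- match.arg(kind)
  obs <- values[!is.na(values)]
  if (kind == "log_shift") {
    if (any(obs <= -1e-5))
      stopf("log_shift requires all values > -1e-5 (min = %g)", min(obs))
    spec <- list(kind = kind, offset = 0, c = 1e-5, a = 1)
    return(list(values = log(values + 1e-5), spec = spec))
  }
  offset <- if (min(obs) <= 0) -min(obs) else 0
  shifted <- obs + offset
  pos <- shifted[shifted > 0]
  if (!length(pos))
    stopf("log_scaled undefined: no positive value after offset (constant column)")
  cc <- min(pos)
  a <- 1 / cc
  spec <- list(kind = kind, offset = offset, c = cc, a = a)
  list(values = log(a * (values + offset) + cc), spec = spec)
}

#' @rdname fitApplyTransform
#' @param spec a spec returned by `fitApplyTransform()`.
#' @export
applyTransform <- function(values, spec) {
  if (spec$kind == "log_shift") return(log(values + 1e-5))
  log(spec$a * (values + spec$offset) + spec$c)
}

#' Transform every column of a table
#'
#' @param table a [CohortTable-class].
#' @param kind transform kind, see [fitApplyTransform()].
#' @return list with `table` (transformed) and `specs` (per-column specs).
#' @export
transformTable <- function(table, kind = "log_scaled") {
  X <- table@values
  specs <- vector("list", ncol(X))
  names(specs) <- colnames(X)
  for (j in seq_len(ncol(X))) {
    ft <- fitApplyTransform(X[, j], kind)
    X[, j] <- ft$values
    specs[[j]] <- ft$spec
  }
  table@values <- X
  list(table = table, specs = specs)
}
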