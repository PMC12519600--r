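#' Imputation method identifiers
#'
#' The candidate suite scored by [selectImputation()]: univariate mean and
#' median, k-nearest-neighbour row imputation, four chained-equation
#' variants differing in their per-column regressor (ordinary least squares,
#' ridge shrinkage, random forest, gradient boosting), and single-pass
#' stochastic regression on the complete predictor columns.
#'
#' @return character vector of the eight method ids.
#' @export
imputationMethods <- function() {
  c("mean", "median", "knn", "chained_linear", "chained_bayes_shrinkage",
    "chained_forest", "chained_boosted", "stochastic_regression")
}

# Pairwise row distances over mutually observed coordinates, scaled by the
# number of shared coordinates (root mean squared difference).
.row_distances <- function(X) {
  n <- nrow(X)
  obs <- !is.na(X)
  X0 <- X
  X0[!obs] <- 0
  # squared diffs restricted to shared coords via the masked cross products
  G <- tcrossprod(X0)
  S2 <- tcrossprod(X0^2, obs)
  shared <- tcrossprod(obs * 1)
  D2 <- S2 + t(S2) - 2 * G
  D2 <- D2 / pmax(shared, 1)
  D2[shared == 0] <- Inf
  D2[D2 < 0] <- 0
  sqrt(D2)
}

.impute_knn <- function(X, k) {
  D <- .row_distances(X)
  diag(D) <- Inf
  out <- X
  for (j in which(colSums(is.na(X)) > 0)) {
    donors <- which(!is.na(X[, j]))
    for (i in which(is.na(X[, j]))) {
      ord <- donors[order(D[i, donors])]
      use <- ord[seq_len(min(k, length(ord)))]
      out[i, j] <- mean(X[use, j])
    }
  }
  out
}

.chained_regressors <- list(
  chained_linear = function(xobs, yobs, xmis, seed, control) {
    fit <- stats::lm.fit(cbind(1, xobs), yobs)
    b <- fit$coefficients
    b[is.na(b)] <- 0
    drop(cbind(1, xmis) %*% b)
  },
  chained_bayes_shrinkage = function(xobs, yobs, xmis, seed, control) {
    if (ncol(xobs) < 2L)  # glmnet needs >= 2 predictors
      return(.chained_regressors$chained_linear(xobs, yobs, xmis, seed, control))
    fit <- glmnet::glmnet(xobs, yobs, alpha = 0,
                          lambda = control$ridgeLambda %||% 1.0)
    drop(predict(fit, xmis))
  },
  chained_forest = function(xobs, yobs, xmis, seed, control) {
    fit <- ranger::ranger(
      x = xobs, y = yobs, num.trees = control$numTrees %||% 100L,
      seed = seed, num.threads = 1L)
    predict(fit, data.frame(xmis, check.names = FALSE),
            num.threads = 1L)$predictions
  },
  chained_boosted = function(xobs, yobs, xmis, seed, control) {
    fit <- with_seed(seed, xgboost::xgb.train(
      params = list(max_depth = 3L, eta = 0.3,
                    objective = "reg:squarederror", nthread = 1L),
      data = xgboost::xgb.DMatrix(xobs, label = yobs, nthread = 1L),
      nrounds = control$nrounds %||% 50L, verbose = 0))
    predict(fit, xgboost::xgb.DMatrix(xmis, nthread = 1L))
  }
)

# One chained-equation run: initialize missing cells to column means, then
# for `sweeps` full sweeps, in order of increasing per-column missingness,
# refit the designated regressor of each incomplete column on all other
# columns and overwrite its missing cells with the predictions. Only the
# final completed dataset is returned (a `sweeps` attribute records the
# executed sweep count).
.impute_chained <- function(X, method, sweeps, seed, control) {
  reg <- .chained_regressors[[method]]
  miss <- is.na(X)
  nmiss <- colSums(miss)
  todo <- order(nmiss)[nmiss[order(nmiss)] > 0]
  cur <- X
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(nmiss > 0)) cur[miss[, j], j] <- mu[j]
  ran <- 0L
  for (s in seq_len(sweeps)) {
    for (j in todo) {
      rows <- !miss[, j]
      pred <- reg(cur[rows, -j, drop = FALSE], cur[rows, j],
                  cur[!rows, -j, drop = FALSE],
                  child_seed(seed, sprintf("%s_%d_%d", method, s, j)), control)
      cur[!rows, j] <- pred
    }
    ran <- ran + 1L
  }
  attr(cur, "sweeps") <- ran
  cur
}

.impute_stochastic <- function(X, seed) {
  miss <- is.na(X)
  complete <- which(colSums(miss) == 0)
  out <- X
  for (j in which(colSums(miss) > 0)) {
    rows <- !miss[, j]
    preds <- setdiff(complete, j)
    mis_rows <- which(!rows)
    s <- child_seed(seed, sprintf("stoch_%d", j))
    if (length(preds)) {
      fit <- stats::lm.fit(cbind(1, X[rows, preds, drop = FALSE]), X[rows, j])
      b <- fit$coefficients
      b[is.na(b)] <- 0
      mu <- drop(cbind(1, X[mis_rows, preds, drop = FALSE]) %*% b)
      sigma <- sqrt(sum(fit$residuals^2) / max(1, fit$df.residual))
    } else {
      mu <- rep(mean(X[rows, j]), length(mis_rows))
      sigma <- sd(X[rows, j])
    }
    out[mis_rows, j] <- mu + with_seed(s, rnorm(length(mis_rows), 0, sigma))
  }
  out
}

#' Complete a whole table under one imputation method
#'
#' Observed cells are never altered. The chained methods run
#' `control$sweeps` (default 10) full sweeps and return only the final
#' completed dataset; the executed sweep count is attached as attribute
#' `"sweeps"` on the returned matrix.
#'
#' @param table a [CohortTable-class] (possibly with NA cells).
#' @param method one of [imputationMethods()].
#' @param seed integer seed (used by the stochastic and tree regressors).
#' @param control list of hyperparameters: `k` (kNN neighbours, default 5),
#'   `sweeps` (chained sweeps, default 10), `ridgeLambda` (default 1.0),
#'   `numTrees` (default 100), `nrounds` (default 50).
#' @return completed numeric matrix with the input dimnames.
#' @export
imputeTable <- function(table, method, seed = 1L, control = list()) {
  method <- match.arg(method, imputationMethods())
  X <- table@values
  if (any(colSums(!is.na(X)) == 0)) stopf("all-missing column cannot be imputed")
  if (!anyNA(X)) return(X)
  k <- control$k %||% 5L
  sweeps <- control$sweeps %||% 10L
  if (sweeps < 1L) stopf("sweeps must be >= 1")
  out <- switch(method,
    mean = {
      mu <- colMeans(X, na.rm = TRUE)
      for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
      X
    },
    median = {
      md <- apply(X, 2, median, na.rm = TRUE)
      for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- md[j]
      X
    },
    knn = .impute_knn(X, k),
    stochastic_regression = .impute_stochastic(X, seed),
    .impute_chained(X, method, sweeps, seed, control)
  )
  dimnames(out) <- dimnames(X)
  out
}

#' Complete a single column under one candidate method
#'
#' For the multivariate methods the whole-table machinery runs and the
#' requested column is extracted, since chained equations condition each
#' column on all others.
#'
#' @param table a [CohortTable-class].
#' @param column column name or index.
#' @param method one of [imputationMethods()].
#' @inheritParams imputeTable
#' @return the completed numeric column.
#' @export
imputeColumn <- function(table, column, method, seed = 1L, control = list()) {
  j <- if (is.character(column)) match(column, colnames(table@values)) else column
  if (is.na(j)) stopf("unknown column '%s'", column)
  imputeTable(table, method, seed, control)[, j]
}

# Rank AUC with half-credit ties: P(score_pos > score_neg) + 0.5 P(tie).
.rank_auc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Discriminative AUC of a completed column
#'
#' Fits an unpenalized univariate logistic regression of the binary outcome
#' on the column and returns the AUC of the fitted probabilities, which
#' equals the rank AUC of the column oriented by the fitted slope's sign
#' (ties contribute one half). A constant column returns 0.5 with a
#' `"constant"` attribute; perfect separation still yields a well-defined
#' AUC from the ranking.
#'
#' @param values completed numeric column (no NA).
#' @param outcome binary 0/1 vector.
#' @return AUC in [0.5, 1].
#' @examples
#' predictorAUC(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))  # 0.75
#' @export
predictorAUC <- function(values, outcome) {
  if (anyNA(values)) stopf("predictorAUC requires a completed column")
  if (length(unique(outcome)) < 2L) stopf("both classes must be present")
  if (length(unique(values)) < 2L) {
    return(structure(0.5, constant = TRUE))
  }
  slope <- suppressWarnings(
    coef(stats::glm(outcome ~ values, family = stats::binomial()))[2]
  )
  if (is.na(slope) || slope == 0) return(0.5)
  auc <- .rank_auc(sign(slope) * values, outcome)
  max(auc, 1 - auc)
}

#' Per-column imputation-method selection by AUC
#'
#' Every candidate method completes the table; each column with missing
#' cells is then scored by [predictorAUC()] against the outcome under every
#' candidate, and the column version from the highest-AUC method is kept
#' (exact ties go to the earlier method in `tieOrder`). Columns without
#' missing cells pass through untouched and are reported as `"none"`.
#'
#' @param table a [CohortTable-class].
#' @param candidates subset of [imputationMethods()].
#' @param tieOrder tie-break preference order; defaults to `candidates`.
#' @param seed integer seed.
#' @param control hyperparameters, see [imputeTable()].
#' @return list with `table` (completed [CohortTable-class]) and `report`
#'   (data.frame: column, nImputed, selected, plus one AUC column per
#'   candidate; attribute `"tieOrder"`).
#' @export
selectImputation <- function(table, candidates = imputationMethods(),
                             tieOrder = candidates, seed = 1L,
                             control = list()) {
  if (!length(candidates)) stopf("empty candidate list")
  candidates <- match.arg(candidates, imputationMethods(), several.ok = TRUE)
  X <- table@values
  y <- table@outcome
  nmiss <- colSums(is.na(X))
  completedBy <- lapply(candidates, function(m)
    imputeTable(table, m, child_seed(seed, m), control))
  names(completedBy) <- candidates

  aucs <- matrix(NA_real_, ncol(X), length(candidates),
                 dimnames = list(colnames(X), candidates))
  selected <- rep("none", ncol(X))
  out <- X
  for (j in which(nmiss > 0)) {
    aucs[j, ] <- vapply(candidates, function(m)
      as.numeric(predictorAUC(completedBy[[m]][, j], y)), numeric(1))
    best <- max(aucs[j, ])
    winners <- candidates[aucs[j, ] >= best - 1e-12]
    pick <- tieOrder[tieOrder %in% winners][1]
    selected[j] <- pick
    out[, j] <- completedBy[[pick]][, j]
  }
  table@values <- out
  report <- data.frame(column = colnames(X), nImputed = nmiss,
                       selected = selected, aucs,
                       row.names = NULL, check.names = FALSE)
  attr(report, "tieOrder") <- tieOrder
  list(table = table, report = report)
}
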