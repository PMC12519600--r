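#' Soft-thresholded unit loading with exactly k nonzeros
#'
#' The lasso-style selection step of sparse PLS: threshold at the
#' (k+1)-th largest absolute entry (`lambda = 0` when `k = length(w)`),
#' `u_i = sign(w_i) * max(|w_i| - lambda, 0)`, then scale to unit length.
#' Exactly `k` entries survive when there are no ties at the threshold.
#'
#' @param w numeric vector, not all zero.
#' @param k number of entries to retain, `1 <= k <= length(w)`.
#' @return unit-norm numeric vector with `k` nonzeros (generic data).
#' @examples
#' sparseLoading(c(3, -2, 1), 2)  # (2, -1, 0) / sqrt(5)
#' @export
sparseLoading <- function(w, k) {
  p <- length(w)
  if (k < 1 || k > p) stopf("k = %d out of range [1, %d]", k, p)
  if (all(w == 0)) stopf("w must be nonzero")
  aw <- abs(w)
  lambda <- if (k == p) 0 else sort(aw, decreasing = TRUE)[k + 1]
  u <- sign(w) * pmax(aw - lambda, 0)
  u / sqrt(sum(u^2))
}

# Center/scale helper: constant columns get scale 1 (-> all-zero column)
# and are flagged so they carry zero weight but keep their index.
.scale_train <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  constant <- which(sdv == 0 | is.na(sdv))
  sdv[constant] <- 1
  list(X = sweep(sweep(X, 2, mu, `-`), 2, sdv, `/`),
       center = mu, scale = sdv, constant = as.integer(constant))
}

#' Fit a sparse PLS-DA model
#'
#' Predictors are centered and unit-variance scaled; the two-class outcome
#' becomes a centered/scaled one-hot dummy matrix. Each component solves a
#' penalised SVD of `M = t(X_h) %*% Y_h` by alternating
#' `u <- sparseLoading(M v, keepX[h])` and `v <- t(M) u / ||t(M) u||` from
#' an SVD start until the loading change falls below 1e-9 (at most 500
#' iterations), then scores, deflation and regression vectors are
#' `t = X u`, `p = t(X) t / (t't)`, `q = t(Y) t / (t't)` with deflation
#' `X - t p'`, `Y - t q'`. Every component is sign-oriented so its score
#' correlates non-negatively with the case dummy: case-enriched variables
#' load positive, case-depleted ones negative.
#'
#' @param X numeric predictor matrix, no missing values.
#' @param y binary outcome (0/1 vector or two-level factor).
#' @param ncomp number of components H, `H <= min(n - 1, p)`.
#' @param keepX retained variables per component (recycled to length H);
#'   default keeps all.
#' @return a [SplsdaModel-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("v", 1:10)))
#' y <- rep(0:1, each = 10)
#' X[, 1] <- X[, 1] + 2 * y
#' fit <- fitSplsda(X, y, ncomp = 2, keepX = c(3, 3))
#' selectedVariables(fit, comp = 1)
#' @export
fitSplsda <- function(X, y, ncomp = 2, keepX = ncol(X)) {
  X <- as.matrix(X)
  if (anyNA(X)) stopf("X contains missing values; impute first")
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  yf <- factor(y)
  if (nlevels(yf) != 2L) stopf("outcome must have exactly two classes")
  labels <- levels(yf)
  H <- as.integer(ncomp)
  if (H < 1L || H > min(n - 1L, p))
    stopf("ncomp = %d out of range [1, %d]", H, min(n - 1L, p))
  keepX <- as.integer(rep_len(keepX, H))
  if (any(keepX < 1L | keepX > p)) stopf("keepX out of range [1, %d]", p)

  sc <- .scale_train(X)
  Xh <- sc$X
  Yd <- cbind(as.numeric(yf == labels[1]), as.numeric(yf == labels[2]))
  colnames(Yd) <- labels
  ysc <- .scale_train(Yd)
  Yh <- ysc$X
  caseDummy <- Yh[, 2]

  U <- matrix(0, p, H, dimnames = list(colnames(X), NULL))
  V <- matrix(0, 2, H, dimnames = list(labels, NULL))
  Tm <- matrix(0, n, H)
  P <- matrix(0, p, H, dimnames = list(colnames(X), NULL))
  Q <- matrix(0, 2, H, dimnames = list(labels, NULL))
  iters <- integer(H)

  for (h in seq_len(H)) {
    M <- crossprod(Xh, Yh)
    if (all(abs(M) < .Machine$double.eps))
      stopf("degenerate component %d: X and Y are uncorrelated after deflation", h)
    v <- svd(M, nu = 0, nv = 1)$v[, 1]
    u <- rep(0, p)
    it <- 0L
    repeat {
      it <- it + 1L
      unew <- sparseLoading(drop(M %*% v), keepX[h])
      vn <- drop(crossprod(M, unew))
      v <- vn / sqrt(sum(vn^2))
      delta <- max(abs(unew - u))
      u <- unew
      if (delta < 1e-9 || it >= 500L) break
    }
    if (it >= 500L)
      warnf("component %d did not converge within 500 iterations", h)
    tvec <- drop(Xh %*% u)
    tt <- sum(tvec^2)
    ph <- drop(crossprod(Xh, tvec)) / tt
    qh <- drop(crossprod(Yh, tvec)) / tt
    # orient so the score correlates non-negatively with the case dummy
    if (sum(tvec * caseDummy) < 0) {
      u <- -u; v <- -v; tvec <- -tvec; ph <- -ph; qh <- -qh
    }
    U[, h] <- u; V[, h] <- v; Tm[, h] <- tvec; P[, h] <- ph; Q[, h] <- qh
    iters[h] <- it
    Xh <- Xh - tcrossprod(tvec, ph)
    Yh <- Yh - tcrossprod(tvec, qh)
  }

  centroids <- rbind(colMeans(Tm[yf == labels[1], , drop = FALSE]),
                     colMeans(Tm[yf == labels[2], , drop = FALSE]))
  rownames(centroids) <- labels
  pool <- matrix(0, H, H)
  for (g in labels) {
    Tg <- Tm[yf == g, , drop = FALSE]
    pool <- pool + crossprod(scale(Tg, scale = FALSE))
  }
  pool <- pool / (n - 2)

  new("SplsdaModel",
      xCenter = sc$center, xScale = sc$scale,
      yCenter = ysc$center, yScale = ysc$scale,
      ncomp = H, keepX = keepX,
      loadingsX = U, loadingsY = V, scores = Tm,
      loadingsP = P, regressionQ = Q,
      labels = labels, centroids = centroids, withinCov = pool,
      constantCols = sc$constant, iterations = iters)
}

#' Project new samples into the component space
#'
#' Applies the training centering/scaling, then iterates
#' `t_h = X u_h`, `X <- X - t_h p_h'` with the training loadings.
#'
#' @param model a fitted [SplsdaModel-class].
#' @param Xnew matrix with the training columns (checked by name when both
#'   are named), no missing values.
#' @return n x H score matrix.
#' @export
projectSamples <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (anyNA(Xnew)) stopf("Xnew contains missing values; impute first")
  pn <- rownames(model@loadingsX)
  if (ncol(Xnew) != length(pn)) stopf("column mismatch: expected %d predictors",
                                      length(pn))
  if (!is.null(colnames(Xnew)) && !identical(colnames(Xnew), pn))
    stopf("column names do not match the training predictors")
  Xs <- sweep(sweep(Xnew, 2, model@xCenter, `-`), 2, model@xScale, `/`)
  H <- model@ncomp
  Tm <- matrix(0, nrow(Xnew), H)
  for (h in seq_len(H)) {
    Tm[, h] <- drop(Xs %*% model@loadingsX[, h])
    Xs <- Xs - tcrossprod(Tm[, h], model@loadingsP[, h])
  }
  Tm
}

# Class predictions from scores using components 1..h for every h <= H.
# Returns list(class = n x H character matrix, dummy = n x 2 de-scaled
# predicted dummy at full H, caseScore = n x H cumulative case-dummy score).
.predict_components <- function(model, Tm, distance) {
  n <- nrow(Tm); H <- model@ncomp
  labels <- model@labels
  cls <- matrix(NA_character_, n, H)
  Yhat_s <- matrix(0, n, 2)
  caseScore <- matrix(0, n, H)
  for (h in seq_len(H)) {
    Yhat_s <- Yhat_s + tcrossprod(Tm[, h], model@regressionQ[, h])
    Yhat <- sweep(sweep(Yhat_s, 2, model@yScale, `*`), 2, model@yCenter, `+`)
    caseScore[, h] <- Yhat[, 2]
    if (distance == "max") {
      cls[, h] <- labels[max.col(Yhat, ties.method = "first")]
    } else {
      C <- model@centroids[, seq_len(h), drop = FALSE]
      Th <- Tm[, seq_len(h), drop = FALSE]
      if (distance == "mahalanobis") {
        W <- model@withinCov[seq_len(h), seq_len(h), drop = FALSE]
        Winv <- tryCatch(solve(W), error = function(e) NULL)
        if (is.null(Winv) || !all(is.finite(Winv))) {
          warnf("singular score covariance; falling back to centroid distance")
          Winv <- diag(h)
        }
      } else {
        Winv <- diag(h)
      }
      d <- sapply(seq_len(nrow(C)), function(k) {
        Dk <- sweep(Th, 2, C[k, ], `-`)
        rowSums((Dk %*% Winv) * Dk)
      })
      d <- matrix(d, nrow = n)
      cls[, h] <- labels[max.col(-d, ties.method = "first")]
    }
  }
  list(class = cls, dummy = Yhat, caseScore = caseScore)
}

#' Predict class membership for new samples
#'
#' Three prediction rules: `"max"` assigns the class whose predicted
#' (de-scaled) dummy value is largest; `"centroid"` the nearest training
#' class centroid in score space (Euclidean); `"mahalanobis"` the nearest
#' centroid under the pooled within-class training score covariance
#' (falls back to centroid with a warning when singular).
#'
#' @param object a fitted [SplsdaModel-class].
#' @param Xnew predictor matrix matching the training columns.
#' @param distance `"max"`, `"centroid"` or `"mahalanobis"`.
#' @return list: `class` (predicted label per sample, at the full number of
#'   components), `classByComp` (n x H matrix using components 1..h),
#'   `dummy` (predicted dummy values), `scores` (projected scores).
#' @export
setMethod("predict", "SplsdaModel", function(object, Xnew,
    distance = c("max", "centroid", "mahalanobis")) {
  distance <- match.arg(distance)
  Tm <- projectSamples(object, Xnew)
  pr <- .predict_components(object, Tm, distance)
  list(class = pr$class[, object@ncomp], classByComp = pr$class,
       dummy = pr$dummy, scores = Tm)
})

#' Balanced error rate
#'
#' Mean over classes of the within-class misclassification rate; immune to
#' class imbalance.
#'
#' @param yTrue true labels (every class in `yTrue` defines the average).
#' @param yPred predicted labels of the same length.
#' @return BER in [0, 1].
#' @examples
#' balancedErrorRate(rep(c(0, 1), c(10, 10)),
#'                   c(rep(0, 8), rep(1, 2), rep(1, 6), rep(0, 4)))  # 0.3
#' @export
balancedErrorRate <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stopf("length mismatch")
  classes <- unique(yTrue)
  if (length(classes) < 2L) stopf("a true class is absent from yTrue")
  mean(vapply(classes, function(k)
    mean(yPred[yTrue == k] != k), numeric(1)))
}

#' Area under the ROC curve
#'
#' The probability that a random positive outranks a random negative,
#' ties counting one half (rank formulation).
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels, both classes present.
#' @return AUC in [0, 1].
#' @examples
#' rocAUC(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))  # 0.75
#' @export
rocAUC <- function(scores, labels) {
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  .rank_auc(scores, labels)
}
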