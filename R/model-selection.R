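#' Stratified fold assignment
#'
#' Within each class, indices are shuffled (seeded) and dealt round-robin
#' over the k folds, so per-class fold counts differ by at most one.
#'
#' @param outcome binary outcome vector (each class with >= 2 members).
#' @param k number of folds, `2 <= k <= length(outcome)`.
#' @param seed integer seed.
#' @return integer fold label in 1..k per sample.
#' @export
stratifiedFolds <- function(outcome, k, seed = 1L) {
  n <- length(outcome)
  if (k < 2L || k > n) stopf("k = %d out of range [2, %d]", k, n)
  fold <- integer(n)
  with_seed(seed, {
    off <- 0L
    for (g in unique(outcome)) {
      idx <- which(outcome == g)
      idx <- idx[sample.int(length(idx))]
      # continue the round-robin across classes so total fold sizes also
      # balance (and k = n yields leave-one-out)
      fold[idx] <- ((off + seq_along(idx) - 1L) %% k) + 1L
      off <- off + length(idx)
    }
  })
  fold
}

#' Repeated stratified cross-validated error of a sparse PLS-DA model
#'
#' Per repetition: a fresh stratified fold split, a fit on the training
#' folds only (column scaling refit inside [fitSplsda()], so held-out rows
#' never leak into the preprocessing), prediction of the held-out fold
#' under the given distance, and BER / AUC from the pooled out-of-fold
#' predictions of that repetition. Results are reported for every
#' component count 1..ncomp from the same fits.
#'
#' @param X completed predictor matrix.
#' @param y binary outcome.
#' @param ncomp number of components fitted.
#' @param keepX retained variables per component.
#' @param folds number of folds (default 10).
#' @param reps number of repetitions (default 100, the full protocol).
#' @param distance prediction distance, see [predict,SplsdaModel-method].
#' @param seed master seed; repetition r uses a child seed of (seed, r), so
#'   the first repetitions of two runs with the same master seed coincide.
#' @return list: `ber` and `auc`, reps x ncomp matrices.
#' @export
cvError <- function(X, y, ncomp = 2, keepX = ncol(X), folds = 10L,
                    reps = 100L, distance = "max", seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X)) stopf("X contains missing values; impute first")
  y <- as.character(y)
  n <- nrow(X)
  ber <- matrix(NA_real_, reps, ncomp)
  auc <- matrix(NA_real_, reps, ncomp)
  for (r in seq_len(reps)) {
    fold <- stratifiedFolds(y, folds, child_seed(seed, sprintf("rep_%d", r)))
    predCls <- matrix(NA_character_, n, ncomp)
    caseScore <- matrix(NA_real_, n, ncomp)
    for (f in sort(unique(fold))) {
      test <- fold == f
      if (length(unique(y[!test])) < 2L) {
        warnf("training fold lost a class; refolding")
        fold <- stratifiedFolds(y, folds,
                                child_seed(seed, sprintf("refold_%d_%d", r, f)))
        test <- fold == f
      }
      fit <- fitSplsda(X[!test, , drop = FALSE], y[!test], ncomp, keepX)
      Tm <- projectSamples(fit, X[test, , drop = FALSE])
      pr <- .predict_components(fit, Tm, distance)
      predCls[test, ] <- pr$class
      caseScore[test, ] <- pr$caseScore
    }
    for (h in seq_len(ncomp)) {
      ber[r, h] <- balancedErrorRate(y, predCls[, h])
      auc[r, h] <- .rank_auc(caseScore[, h], as.integer(y == sort(unique(y))[2]))
    }
  }
  list(ber = ber, auc = auc)
}

#' Tune keepX per component by the one-sided t-test rule
#'
#' Sequentially per component (earlier components fixed at their chosen
#' values): every candidate is cross-validated on identical fold splits,
#' the candidate with the lowest mean BER is the benchmark, and the chosen
#' keepX is the smallest candidate whose paired one-sided t-test against
#' the benchmark is non-significant at `alpha` — i.e. the most parsimonious
#' model not demonstrably worse than the best.
#'
#' @inheritParams cvError
#' @param grid ascending keepX candidates (>= 1; values capped at ncol(X)).
#' @param alpha significance level of the paired t-test, default 0.05.
#' @return list: `keepX` (chosen per component), `ber` and `auc`
#'   (data.frames of per-candidate summaries per component).
#' @export
tuneKeepX <- function(X, y, ncomp = 2, grid = c(5, 10, 20, 40, 80, 120, 140,
                                                ncol(X)),
                      folds = 10L, reps = 10L, distance = "max",
                      alpha = 0.05, seed = 1L) {
  grid <- sort(unique(pmin(as.integer(grid), ncol(X))))
  if (length(grid) < 1L) stopf("empty keepX grid")
  chosen <- integer(0)
  summaries <- list()
  for (h in seq_len(ncomp)) {
    berMat <- sapply(grid, function(k) {
      cvError(X, y, ncomp = h, keepX = c(chosen, k), folds = folds,
              reps = reps, distance = distance,
              seed = child_seed(seed, sprintf("comp_%d", h)))$ber[, h]
    })
    berMat <- matrix(berMat, nrow = reps)
    means <- colMeans(berMat)
    best <- which.min(means)
    pick <- grid[best]
    for (i in seq_along(grid)) {
      if (i == best) { pick <- min(pick, grid[i]); break }
      d <- berMat[, i] - berMat[, best]
      if (sd(d) == 0 || reps < 2L) { pick <- grid[i]; break }
      p <- stats::t.test(d, alternative = "greater")$p.value
      if (p >= alpha) { pick <- grid[i]; break }
    }
    chosen <- c(chosen, pick)
    summaries[[h]] <- data.frame(component = h, keepX = grid,
                                 berMean = means,
                                 berSD = apply(berMat, 2, sd))
  }
  list(keepX = chosen, summary = do.call(rbind, summaries))
}

#' Choose the component count and prediction distance
#'
#' Picks the (ncomp, distance) pair minimising mean BER; ties resolve to
#' fewer components, then to the distance order max < centroid <
#' mahalanobis.
#'
#' @param berMeans matrix of mean BER, components in rows, the three
#'   distances in columns (named "max", "centroid", "mahalanobis").
#' @return list: `ncomp`, `distance`.
#' @export
chooseNcomp <- function(berMeans) {
  distOrder <- c("max", "centroid", "mahalanobis")
  berMeans <- berMeans[, distOrder, drop = FALSE]
  cand <- expand.grid(comp = seq_len(nrow(berMeans)),
                      dist = seq_along(distOrder))
  cand$ber <- berMeans[as.matrix(cand)]
  cand <- cand[order(cand$ber, cand$comp, cand$dist), ]
  list(ncomp = as.integer(cand$comp[1]), distance = distOrder[cand$dist[1]])
}

#' Full sparse PLS-DA tuning protocol
#'
#' Stage 1 cross-validates a dense (all variables kept) model at up to
#' `ncompMax` components under all three prediction distances and selects
#' (ncomp, distance) by [chooseNcomp()]; stage 2 tunes keepX per component
#' by [tuneKeepX()] under the selected distance. The defaults mirror the
#' 10-fold x 100-repetition protocol; `reps` can be lowered for desk-scale
#' runs.
#'
#' @inheritParams tuneKeepX
#' @param ncompMax maximum number of components considered (default 4).
#' @return a [CvResult-class].
#' @export
tuneSplsda <- function(X, y, ncompMax = 4L, grid = c(5, 10, 20, 40, 80, 120,
                                                     140, ncol(X)),
                       folds = 10L, reps = 100L, alpha = 0.05, seed = 1L) {
  X <- as.matrix(X)
  ncompMax <- min(ncompMax, nrow(X) - 1L, ncol(X))
  distances <- c("max", "centroid", "mahalanobis")
  dense <- lapply(distances, function(d)
    cvError(X, y, ncomp = ncompMax, keepX = ncol(X), folds = folds,
            reps = reps, distance = d, seed = child_seed(seed, "ncomp")))
  names(dense) <- distances
  berMeans <- sapply(dense, function(z) colMeans(z$ber))
  berMeans <- matrix(berMeans, nrow = ncompMax,
                     dimnames = list(NULL, distances))
  sel <- chooseNcomp(berMeans)

  tk <- tuneKeepX(X, y, ncomp = sel$ncomp, grid = grid, folds = folds,
                  reps = reps, distance = sel$distance, alpha = alpha,
                  seed = child_seed(seed, "keepx"))

  denseTab <- do.call(rbind, lapply(distances, function(d) {
    data.frame(component = seq_len(ncompMax), keepX = ncol(X), distance = d,
               berMean = colMeans(dense[[d]]$ber),
               berSD = apply(dense[[d]]$ber, 2, sd),
               aucMean = colMeans(dense[[d]]$auc))
  }))
  keepTab <- data.frame(component = tk$summary$component,
                        keepX = tk$summary$keepX, distance = sel$distance,
                        berMean = tk$summary$berMean,
                        berSD = tk$summary$berSD, aucMean = NA_real_)
  new("CvResult",
      grid = sort(unique(pmin(as.integer(grid), ncol(X)))),
      reps = as.integer(reps), folds = as.integer(folds),
      berTable = rbind(denseTab, keepTab),
      chosenKeepX = as.integer(tk$keepX),
      chosenNcomp = as.integer(sel$ncomp),
      chosenDistance = sel$distance, seed = as.integer(seed))
}
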