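test_that("sparse loading reproduces the soft-threshold hand example", {
  expect_equal(sparseLoading(c(3, -2, 1), 2), c(2, -1, 0) / sqrt(5))
  w <- c(1.5, -0.2, 3, 0.7)
  expect_equal(sparseLoading(w, 4), w / sqrt(sum(w^2)))
  expect_equal(sparseLoading(w, 1), c(0, 0, 1, 0))
  expect_error(sparseLoading(w, 0), "out of range")
  expect_error(sparseLoading(w, 5), "out of range")
  expect_error(sparseLoading(c(0, 0), 1), "nonzero")
})

test_that("dense fits match the successive-SVD oracle up to sign", {
  set.seed(50)
  for (i in 1:5) {
    n <- sample(20:50, 1); p <- sample(5:30, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c(0, 1), length.out = n)
    H <- 2
    fit <- fitSplsda(X, y, ncomp = H, keepX = p)
    U <- dense_pls_oracle(X, y, H)
    for (h in 1:H)
      expect_lt(sign_invariant_diff(splsdaLoadings(fit)[, h], U[, h]), 1e-8)
  }
})

test_that("loadings agree with an independent sPLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(51)
  X <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(NULL, paste0("v", 1:12)))
  y <- rep(c(0, 1), each = 20)
  X[, 3] <- X[, 3] + 1.5 * y
  mine <- splsdaLoadings(fitSplsda(X, y, ncomp = 2, keepX = c(4, 4)))
  ref <- mixOmics::splsda(X, factor(y), ncomp = 2,
                          keepX = c(4, 4))$loadings$X
  for (h in 1:2)
    expect_lt(sign_invariant_diff(mine[, h], ref[, h]), 1e-8)
})

test_that("exact keepX sparsity and score orthogonality hold", {
  set.seed(52)
  for (i in 1:20) {
    n <- sample(15:40, 1); p <- sample(6:25, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c(0, 1), length.out = n)
    # keepX < p on the second component: a keepX = 1 first component can
    # deflate its selected column to exactly zero, a structural (non-generic)
    # zero weight that full-density later components would surface
    k <- c(sample(seq_len(p), 1), sample(seq_len(p - 1), 1))
    fit <- fitSplsda(X, y, ncomp = 2, keepX = k)
    expect_identical(colSums(splsdaLoadings(fit) != 0), as.numeric(k))
    Tm <- splsdaScores(fit)
    expect_lt(abs(crossprod(Tm[, 1], Tm[, 2])),
              1e-8 * sqrt(sum(Tm[, 1]^2) * sum(Tm[, 2]^2)))
    expect_equal(unname(sqrt(colSums(splsdaLoadings(fit)^2))), c(1, 1))
  }
})

test_that("case-elevated variables load positive under the sign convention", {
  gc <- small_cohort(n = 40, p = 10, nInformative = 2, effect = 2, seed = 53)
  X <- cohortValues(gc$table); y <- cohortOutcome(gc$table)
  fit <- fitSplsda(X, y, ncomp = 1, keepX = 10)
  inf <- informativeColumns(gc$truth)
  expect_identical(sign(splsdaLoadings(fit)[inf, 1]),
                   setNames(effectDirections(gc$truth),
                            colnames(X)[inf]))
})

test_that("a single strong feature is isolated by keepX = 1", {
  hits <- sapply(1:5, function(s) {
    gc <- small_cohort(n = 40, p = 12, nInformative = 1, effect = 2, seed = s)
    fit <- fitSplsda(cohortValues(gc$table), cohortOutcome(gc$table),
                     ncomp = 1, keepX = 1)
    which(splsdaLoadings(fit)[, 1] != 0) == informativeColumns(gc$truth)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("constant columns are kept with zero weight and flagged", {
  set.seed(54)
  X <- matrix(rnorm(30 * 6), 30, 6)
  X[, 4] <- 7
  y <- rep(c(0, 1), 15)
  fit <- fitSplsda(X, y, ncomp = 2, keepX = 6)
  expect_identical(fit@constantCols, 4L)
  expect_true(all(splsdaLoadings(fit)[4, ] == 0))
})

test_that("projection reproduces training scores and checks its inputs", {
  gc <- small_cohort(n = 30, p = 8, seed = 55)
  X <- cohortValues(gc$table)
  fit <- fitSplsda(X, cohortOutcome(gc$table), ncomp = 2, keepX = c(4, 4))
  expect_lt(max(abs(projectSamples(fit, X) - splsdaScores(fit))), 1e-10)
  Xna <- X; Xna[1, 1] <- NA
  expect_error(projectSamples(fit, Xna), "missing")
  expect_error(projectSamples(fit, X[, 1:5]), "mismatch")
  dup <- X[c(3, 3), ]
  sc <- projectSamples(fit, dup)
  expect_identical(sc[1, ], sc[2, ])
})

test_that("well-separated classes are recovered by all three distances", {
  gc <- small_cohort(n = 40, p = 10, nInformative = 3, effect = 3, seed = 56)
  X <- cohortValues(gc$table); y <- as.character(cohortOutcome(gc$table))
  fit <- fitSplsda(X, y, ncomp = 2, keepX = 10)
  for (d in c("max", "centroid", "mahalanobis")) {
    pr <- predict(fit, X, distance = d)
    expect_identical(pr$class, y)
  }
})

test_that("an identity score covariance makes mahalanobis match centroid", {
  gc <- small_cohort(n = 30, p = 8, seed = 57)
  X <- cohortValues(gc$table); y <- cohortOutcome(gc$table)
  fit <- fitSplsda(X, y, ncomp = 2, keepX = 8)
  fit@withinCov <- diag(2)
  expect_identical(predict(fit, X, "mahalanobis")$class,
                   predict(fit, X, "centroid")$class)
})

test_that("the one-component centroid rule splits at the midpoint", {
  # training scores approximately {-1,-1,+1,+1} with labels {0,0,1,1}:
  # any positive projected score must classify as the case class
  X <- matrix(c(-1, -1.0001, 1, 1.0001), 4, 1,
              dimnames = list(NULL, "v1"))
  y <- c(0, 0, 1, 1)
  fit <- fitSplsda(X, y, ncomp = 1, keepX = 1)
  Xnew <- matrix(c(0.5, -0.5), 2, 1, dimnames = list(NULL, "v1"))
  expect_identical(predict(fit, Xnew, "centroid")$class, c("1", "0"))
})

test_that("scores are invariant to positive rescaling of a predictor", {
  gc <- small_cohort(n = 30, p = 8, seed = 58)
  X <- cohortValues(gc$table); y <- cohortOutcome(gc$table)
  f1 <- fitSplsda(X, y, ncomp = 2, keepX = c(3, 3))
  X2 <- X; X2[, 2] <- X2[, 2] * 37
  f2 <- fitSplsda(X2, y, ncomp = 2, keepX = c(3, 3))
  expect_equal(splsdaScores(f1), splsdaScores(f2), tolerance = 1e-10)
})

test_that("balanced error rate equals per-class arithmetic", {
  expect_equal(balancedErrorRate(rep(c(0, 1), c(5, 5)), rep(c(0, 1), c(5, 5))), 0)
  yt <- rep(c("a", "b"), c(10, 10))
  yp <- c(rep("a", 8), rep("b", 2), rep("b", 6), rep("a", 4))
  expect_equal(balancedErrorRate(yt, yp), 0.3)
  yt2 <- rep(c(0, 1), c(50, 29))
  expect_equal(balancedErrorRate(yt2, rep(0, 79)), 0.5)
  expect_error(balancedErrorRate(rep(1, 5), rep(1, 5)), "absent")
})

test_that("rocAUC counts pairs with half-credit ties and is antisymmetric", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(rocAUC(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(59)
  s <- rnorm(20); l <- rep(c(0, 1), 10)
  expect_equal(rocAUC(s, l) + rocAUC(-s, l), 1)
  expect_error(rocAUC(1:5, rep(1, 5)), "both classes")
})

test_that("invalid fits are rejected", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0, 1), 5)
  expect_error(fitSplsda(X, y, ncomp = 5), "ncomp")
  expect_error(fitSplsda(X, rep(1, 10), 1), "two classes")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fitSplsda(Xna, y, 1), "missing")
  expect_error(fitSplsda(X, y, 1, keepX = 3), "keepX")
})
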