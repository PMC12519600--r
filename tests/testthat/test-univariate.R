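test_that("Kruskal-Wallis statistic matches the rank-sum hand computation", {
  # groups {1..5} vs {6..10}: rank sums 15 and 40, no ties,
  # H = 12/(10*11) * (15^2/5 + 40^2/5) - 3*11 = 6.8182
  # alphaNormality = 1 forces the rank route regardless of Shapiro-Wilk
  res <- testGroupDifference(1:10, rep(c("a", "b"), each = 5),
                             alphaNormality = 1)
  expect_identical(res$routedTest, "kruskal_wallis")
  expect_equal(res$statistic, 6.8182, tolerance = 1e-4)
})

test_that("identical groups give a null statistic and p of one", {
  res <- testGroupDifference(rep(c(1, 1, 1), 2), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$pValue, 1)
})

test_that("the ANOVA route on two groups equals the squared pooled t", {
  set.seed(20)
  x <- rnorm(40)
  g <- rep(c("a", "b"), each = 20)
  res <- testGroupDifference(x, g)
  expect_identical(res$routedTest, "anova")
  tt <- t.test(x[g == "a"], x[g == "b"], var.equal = TRUE)$statistic
  expect_equal(res$statistic, unname(tt^2), tolerance = 1e-10)
})

test_that("routing follows the per-group Shapiro-Wilk decision", {
  set.seed(21)
  x <- c(rnorm(20), rexp(20)^3)  # second group grossly non-normal
  g <- rep(c("a", "b"), each = 20)
  res <- testGroupDifference(x, g)
  expect_identical(res$routedTest, "kruskal_wallis")
  expect_true(any(res$normalityP < 0.05))
  expect_error(testGroupDifference(c(1, 2, 1, 2), c("a", "a", "a", "b")),
               "fewer than 3")
})

test_that("the statistic is invariant under strictly monotone transforms", {
  set.seed(22)
  x <- rexp(30)
  g <- rep(c("a", "b", "c"), each = 10)
  h1 <- kruskal.test(x, factor(g))$statistic
  h2 <- kruskal.test(exp(x) + 5, factor(g))$statistic
  expect_equal(h1, h2)
})

test_that("null p-values give nominal type-I error at the 5% level", {
  set.seed(23)
  rej <- mean(replicate(1000, {
    testGroupDifference(rnorm(30), rep(c("a", "b"), each = 15))$pValue < 0.05
  }))
  se2 <- 2 * sqrt(0.05 * 0.95 / 1000)
  expect_gte(rej, 0.05 - se2)
  expect_lte(rej, 0.05 + se2)
})

test_that("Dunn z matches the hand rank computation on a balanced toy", {
  # values 1..15 in three groups of 5: mean ranks 3, 8, 13; no ties;
  # V0 = 15*16/12 = 20; z(a,b) = (3-8)/sqrt(20*(2/5)) = -1.76777
  out <- posthocPairwise(1:15, rep(c("a", "b", "c"), each = 5), "dunn")
  z_ab <- out$statistic[out$groupA == "a" & out$groupB == "b"]
  expect_equal(z_ab, -5 / sqrt(20 * 2 / 5), tolerance = 1e-10)
})

test_that("three identical groups yield adjusted p of one in both families", {
  # three copies of the same sample: every rank mean and group mean ties
  x <- rep(c(1, 2, 3, 4, 5), 3)
  g <- rep(c("a", "b", "c"), each = 5)
  expect_true(all(posthocPairwise(x, g, "dunn")$pAdjusted == 1))
  expect_true(all(posthocPairwise(x, g, "tukey")$pAdjusted > 0.999))
  xc <- rep(1, 15)  # fully constant: tie correction absorbs the variance
  expect_true(all(posthocPairwise(xc, g, "dunn")$pAdjusted == 1))
})

test_that("two groups fall back to the omnibus comparison, flagged", {
  out <- posthocPairwise(1:10, rep(c("a", "b"), each = 5), "dunn")
  expect_identical(nrow(out), 1L)
  expect_true(attr(out, "degenerate"))
  om <- testGroupDifference(1:10, rep(c("a", "b"), each = 5))
  expect_equal(out$pAdjusted, om$pValue)
})

test_that("logistic slope matches the closed-form MLE on a saturated toy", {
  # x = -1: 3 cases / 10; x = +1: 7 cases / 10. The MLE reproduces the
  # empirical log-odds exactly: intercept 0, slope log(7/3).
  x <- rep(c(-1, 1), each = 10)
  y <- c(rep(1, 3), rep(0, 7), rep(1, 7), rep(0, 3))
  fit <- univariateLogistic(x, y)
  expect_equal(fit$slope, log(7 / 3), tolerance = 1e-6)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_equal(fit$oddsRatio, 7 / 3, tolerance = 1e-5)
  expect_false(fit$separation)
})

test_that("label permutation drives the slope toward zero", {
  gc <- small_cohort(n = 79, p = 4, nInformative = 1, effect = 1, seed = 30)
  x <- cohortValues(gc$table)[, informativeColumns(gc$truth)[1]]
  y <- cohortOutcome(gc$table)
  set.seed(31)
  small <- mean(replicate(50, {
    fit <- univariateLogistic(x, sample(y))
    abs(fit$slope * sd(x)) < 0.5
  }))
  expect_gte(small, 0.9)
})

test_that("perfect separation is flagged and the slope capped", {
  y <- rep(c(0, 1), each = 10)
  fit <- univariateLogistic(as.numeric(y), y)
  expect_true(fit$separation)
  expect_lte(abs(fit$slope * sd(as.numeric(y))), 20 + 1e-9)
  expect_equal(fit$auc, 1)
})

test_that("the screen reports one row per variable with group summaries", {
  sc <- small_cohort(n = 30, p = 6, seed = 32)
  scr <- univariateScreen(sc$table)
  expect_identical(nrow(scr), 6L)
  expect_true(all(c("meanControls", "meanCases", "pValue", "auc") %in%
                  names(scr)))
  expect_true(all(scr$test %in% c("anova", "kruskal_wallis")))
  f <- tempfile(fileext = ".tsv")
  writeScreenTsv(scr, f)
  expect_identical(nrow(read.delim(f)), 6L)
})
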