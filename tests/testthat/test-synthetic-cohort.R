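test_that("default configuration reproduces the study dimensions", {
  gc <- generateCohort(synthConfig(seed = 1))
  expect_identical(dim(gc$table), c(79L, 148L))
  expect_identical(sum(cohortOutcome(gc$table)), 29L)
  expect_false(anyNA(cohortValues(gc$table)))
  expect_identical(anyDuplicated(colnames(cohortValues(gc$table))), 0L)
  pct <- cohortValues(gc$table)[, cohortBlocks(gc$table) == "cellular_pct"]
  expect_true(all(pct >= 0 & pct <= 100))
})

test_that("generation is deterministic in the seed and varies across seeds", {
  a <- generateCohort(synthConfig(seed = 1))
  b <- generateCohort(synthConfig(seed = 1))
  c <- generateCohort(synthConfig(seed = 2))
  expect_identical(cohortValues(a$table), cohortValues(b$table))
  expect_identical(informativeColumns(a$truth), informativeColumns(b$truth))
  expect_false(identical(cohortValues(a$table), cohortValues(c$table)))
})

test_that("zero effect size produces no systematic group differences", {
  # pooled over seeds: block latents can tilt a whole block by chance in a
  # single draw, so the fraction is assessed in aggregate
  frac_small <- sapply(1:20, function(s) {
    gc <- generateCohort(synthConfig(effectSize = 0, seed = s))
    X <- cohortValues(gc$table)
    y <- cohortOutcome(gc$table)
    d <- apply(X, 2, function(v) {
      sp <- sqrt((var(v[y == 0]) + var(v[y == 1])) / 2)
      abs(mean(v[y == 1]) - mean(v[y == 0])) / sp
    })
    mean(d < 0.5)
  })
  expect_gte(mean(frac_small), 0.9)
})

test_that("planted columns carry more signal than background columns", {
  exceed <- sapply(1:5, function(s) {
    gc <- generateCohort(synthConfig(seed = s))
    X <- cohortValues(gc$table)
    y <- cohortOutcome(gc$table)
    tt <- apply(X, 2, function(v)
      abs(t.test(v[y == 1], v[y == 0])$statistic))
    inf <- informativeColumns(gc$truth)
    min(sapply(tt[inf], function(ti) mean(ti > tt[-inf])))
  })
  expect_gte(median(exceed), 0.9)
})

test_that("effect directions match the recorded signs", {
  gc <- generateCohort(synthConfig(effectSize = 2, seed = 3))
  X <- cohortValues(gc$table)
  y <- cohortOutcome(gc$table)
  inf <- informativeColumns(gc$truth)
  diffs <- apply(X[, inf, drop = FALSE], 2, function(v)
    mean(v[y == 1]) - mean(v[y == 0]))
  expect_identical(unname(sign(diffs)), effectDirections(gc$truth))
})

test_that("MAR deletion hits the target rate and records the mask", {
  gc <- generateCohort(synthConfig(seed = 5))
  im <- injectMissingMAR(gc$table, gc$truth, 0.038, seed = 99)
  rate <- missingRate(im$table)
  expect_gte(rate, 0.030)
  expect_lte(rate, 0.046)
  expect_identical(nrow(missingMask(im$truth)),
                   sum(is.na(cohortValues(im$table))))
  expect_true(all(is.na(cohortValues(im$table)[missingMask(im$truth)])))
})

test_that("zero rate leaves the table untouched and bad rates error", {
  gc <- generateCohort(synthConfig(seed = 5))
  im <- injectMissingMAR(gc$table, gc$truth, 0, seed = 1)
  expect_identical(cohortValues(im$table), cohortValues(gc$table))
  expect_error(injectMissingMAR(gc$table, gc$truth, 0.6, 1), "out of")
})

test_that("missingness depends on the block driver (MAR mechanism)", {
  # empirically: deletion rate in the top driver tercile at least twice the
  # bottom tercile, pooled over seeds, at rate 0.1
  ratios <- sapply(1:5, function(s) {
    gc <- generateCohort(synthConfig(seed = s))
    im <- injectMissingMAR(gc$table, gc$truth, 0.1, seed = s + 50)
    X <- cohortValues(im$table)
    blocks <- cohortBlocks(im$table)
    drv <- match(unique(blocks), blocks)
    rates <- sapply(seq_along(drv), function(b) {
      d <- X[, drv[b]]
      cols <- setdiff(which(blocks == blocks[drv[b]]), drv[b])
      cut3 <- cut(d, quantile(d, c(0, 1/3, 2/3, 1)), include.lowest = TRUE)
      tapply(rowMeans(is.na(X[, cols, drop = FALSE])), cut3, mean)
    })
    sum(rates[3, ]) / sum(rates[1, ])
  })
  expect_gte(median(ratios), 2)
})

test_that("missingness is unrelated to the deleted values themselves", {
  r <- sapply(1:5, function(s) {
    gc <- generateCohort(synthConfig(seed = s))
    im <- injectMissingMAR(gc$table, gc$truth, 0.1, seed = s)
    full <- cohortValues(gc$table)
    Xna <- cohortValues(im$table)
    # point-biserial correlation of the missing indicator with the hidden
    # true value, per column with deletions, standardized within column
    rs <- sapply(which(colSums(is.na(Xna)) > 2), function(j) {
      cor(scale(full[, j]), is.na(Xna[, j]))
    })
    abs(mean(rs))
  })
  expect_lt(median(r), 0.1)
})

test_that("driver columns are never deleted", {
  gc <- generateCohort(synthConfig(seed = 6))
  im <- injectMissingMAR(gc$table, gc$truth, 0.2, seed = 2)
  blocks <- cohortBlocks(im$table)
  drv <- match(unique(blocks), blocks)
  expect_false(anyNA(cohortValues(im$table)[, drv]))
})

test_that("injected outliers are extreme and recorded, disjoint from the mask", {
  gc <- generateCohort(synthConfig(seed = 7))
  pre <- cohortValues(gc$table)
  mu <- colMeans(pre); sdv <- apply(pre, 2, sd)
  io <- injectOutliers(gc$table, gc$truth, 0.005, c(4, 8), seed = 3)
  cells <- outlierCells(io$truth)
  expect_equal(nrow(cells), round(0.005 * 79 * 148))
  z <- abs(cohortValues(io$table)[cells] - mu[cells[, 2]]) / sdv[cells[, 2]]
  expect_true(all(z >= 4 - 1e-9))
  untouched <- cohortValues(io$table)
  untouched[cells] <- pre[cells]
  expect_identical(untouched, pre)
  # zero fraction is the identity
  io0 <- injectOutliers(gc$table, gc$truth, 0, c(4, 8), seed = 3)
  expect_identical(cohortValues(io0$table), pre)
  expect_error(injectOutliers(gc$table, gc$truth, 0.005, c(0, 8), 1),
               "positive")
})

test_that("cohort CSV round-trips values and missing mask", {
  sc <- small_cohort(missingRate = 0.1, seed = 9)
  f <- tempfile(fileext = ".csv")
  writeCohortCsv(sc$table, f)
  back <- readCohortCsv(f)
  expect_equal(cohortValues(back), cohortValues(sc$table))
  expect_identical(cohortOutcome(back), cohortOutcome(sc$table))
  expect_identical(is.na(cohortValues(back)), is.na(cohortValues(sc$table)))
  # empty fields come back as missing, not zero
  expect_gt(sum(is.na(cohortValues(back))), 0)
})

test_that("reader rejects a single-class cohort", {
  sc <- small_cohort(seed = 9)
  df <- as.data.frame(cohortValues(sc$table))
  df$SAP <- 0
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, na = "")
  expect_error(readCohortCsv(f), "single class")
})

test_that("truth manifest serializes with 0-based indices", {
  sc <- small_cohort(missingRate = 0.1, seed = 2)
  f <- tempfile(fileext = ".json")
  writeTruthJson(sc$truth, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(as.integer(j$informative_indices),
                   informativeColumns(sc$truth) - 1L)
  expect_identical(as.integer(j$generator_seed), 2L)
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(synthConfig(nInformative = 500), "nInformative")
  expect_error(synthConfig(prevalence = 1.2), "prevalence")
  expect_error(synthConfig(missingRate = 0.7), "missingRate")
  bs <- defaultBlockSpec(); bs$n[1] <- 31L
  expect_error(synthConfig(blockSpec = bs), "blockSpec")
})
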