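#' Normality-routed group difference test
#'
#' Shapiro-Wilk is run within each group; if every group is compatible with
#' normality at `alphaNormality` the omnibus test is one-way ANOVA,
#' otherwise Kruskal-Wallis. Missing values are excluded pairwise. A group
#' with constant values is treated as non-normal.
#'
#' @param values numeric vector (NA allowed).
#' @param groups grouping vector (>= 2 groups, each with >= 3 observations).
#' @param alphaNormality Shapiro-Wilk routing threshold, default 0.05.
#' @return list: `routedTest` ("anova" or "kruskal_wallis"), `statistic`
#'   (F or H), `pValue`, `normalityP` (per group), `groupSummary`
#'   (data.frame group, n, mean, sd).
#' @export
testGroupDifference <- function(values, groups, alphaNormality = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2L) stopf("need at least 2 groups")
  ns <- table(groups)
  if (any(ns < 3L))
    stopf("group '%s' has fewer than 3 observations",
          names(ns)[which(ns < 3L)[1]])
  normP <- vapply(levels(groups), function(g) {
    x <- values[groups == g]
    if (length(unique(x)) < 3L) return(0)  # constant/degenerate: non-normal
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  summ <- data.frame(group = levels(groups), n = as.integer(ns),
                     mean = tapply(values, groups, mean),
                     sd = tapply(values, groups, sd), row.names = NULL)
  if (all(normP >= alphaNormality)) {
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1]]
    res <- list(routedTest = "anova", statistic = tab$`F value`[1],
                pValue = tab$`Pr(>F)`[1])
  } else {
    if (length(unique(values)) == 1L) {
      res <- list(routedTest = "kruskal_wallis", statistic = 0, pValue = 1)
    } else {
      kw <- stats::kruskal.test(values, groups)
      res <- list(routedTest = "kruskal_wallis",
                  statistic = unname(kw$statistic), pValue = kw$p.value)
    }
  }
  c(res, list(normalityP = normP, groupSummary = summ))
}

#' Post-hoc pairwise comparisons
#'
#' Dunn's rank-based z tests (tie-corrected, Holm-adjusted by default) or
#' Tukey's honestly-significant-difference test on group means. With only
#' two groups the omnibus comparison is returned unchanged and flagged.
#'
#' @param values numeric vector.
#' @param groups grouping vector.
#' @param family `"dunn"` or `"tukey"`.
#' @param adjustment p-adjustment for Dunn (any [stats::p.adjust()] method),
#'   default `"holm"`; Tukey uses its native familywise adjustment.
#' @return data.frame: groupA, groupB, statistic, pAdjusted; attribute
#'   `"degenerate"` is TRUE when only two groups were supplied.
#' @export
posthocPairwise <- function(values, groups, family = c("dunn", "tukey"),
                            adjustment = "holm") {
  family <- match.arg(family)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  lev <- levels(groups)
  if (nlevels(groups) < 3L) {
    om <- testGroupDifference(values, groups)
    out <- data.frame(groupA = lev[1], groupB = lev[2],
                      statistic = om$statistic, pAdjusted = om$pValue)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (family == "tukey") {
    fit <- stats::aov(values ~ groups)
    tk <- stats::TukeyHSD(fit)$groups
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    out <- data.frame(groupA = vapply(pairs, `[`, "", 2),
                      groupB = vapply(pairs, `[`, "", 1),
                      statistic = tk[, "diff"], pAdjusted = tk[, "p adj"],
                      row.names = NULL)
  } else {
    N <- length(values)
    r <- rank(values)
    tie <- table(values)
    tieCorr <- sum(tie^3 - tie) / (12 * (N - 1))
    v0 <- N * (N + 1) / 12 - tieCorr
    rbar <- tapply(r, groups, mean)
    ns <- table(groups)
    cmb <- utils::combn(lev, 2)
    z <- apply(cmb, 2, function(ab) {
      if (v0 <= 0) return(0)  # all values tied: no evidence of difference
      (rbar[ab[1]] - rbar[ab[2]]) /
        sqrt(v0 * (1 / ns[ab[1]] + 1 / ns[ab[2]]))
    })
    p <- 2 * stats::pnorm(-abs(z))
    out <- data.frame(groupA = cmb[1, ], groupB = cmb[2, ], statistic = z,
                      pAdjusted = stats::p.adjust(p, adjustment),
                      row.names = NULL)
  }
  attr(out, "degenerate") <- FALSE
  out
}

#' Univariate logistic association with the outcome
#'
#' Unpenalized maximum-likelihood fit (IRLS, tolerance 1e-8, up to 100
#' iterations) of `outcome ~ values`, with Wald p-value and the rank AUC of
#' the fitted direction. Perfect separation is flagged and the slope capped
#' at +/- 20 on the standardized (per-SD) scale.
#'
#' @param values numeric predictor (NA dropped with matching outcome).
#' @param outcome binary 0/1 vector.
#' @return list: slope, intercept, oddsRatio, pValue, auc, separation.
#' @export
univariateLogistic <- function(values, outcome) {
  keep <- !is.na(values)
  values <- values[keep]; outcome <- outcome[keep]
  if (length(unique(outcome)) < 2L) stopf("both classes must be present")
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcome ~ values, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- unname(coef(fit))
  sdv <- sd(values)
  # separation shows either as the 0/1 fitted-probability warning or as a
  # silently diverged slope; both are flagged and capped on the per-SD scale
  separation <- is.finite(sdv) && sdv > 0 &&
    (warned || abs(b[2] * sdv) > 20) && abs(b[2] * sdv) > 20
  if (separation) b[2] <- sign(b[2]) * 20 / sdv
  p <- summary(fit)$coefficients["values", "Pr(>|z|)"]
  list(slope = b[2], intercept = b[1], oddsRatio = exp(b[2]), pValue = p,
       auc = as.numeric(predictorAUC(values, outcome)),
       separation = separation)
}

#' Table-1 style univariate screen
#'
#' For every predictor column: normality-routed group test against the
#' outcome plus univariate logistic association.
#'
#' @param table a completed [CohortTable-class].
#' @param alphaNormality Shapiro-Wilk routing threshold.
#' @return data.frame, one row per variable: group means +/- SD, routed
#'   test, statistic, p-value, odds ratio, logistic p, AUC.
#' @export
univariateScreen <- function(table, alphaNormality = 0.05) {
  X <- table@values
  y <- table@outcome
  rows <- lapply(seq_len(ncol(X)), function(j) {
    gt <- testGroupDifference(X[, j], y, alphaNormality)
    lf <- univariateLogistic(X[, j], y)
    s <- gt$groupSummary
    data.frame(
      variable = colnames(X)[j],
      meanControls = s$mean[s$group == "0"], sdControls = s$sd[s$group == "0"],
      meanCases = s$mean[s$group == "1"], sdCases = s$sd[s$group == "1"],
      test = gt$routedTest, statistic = gt$statistic, pValue = gt$pValue,
      oddsRatio = lf$oddsRatio, pLogistic = lf$pValue, auc = lf$auc)
  })
  do.call(rbind, rows)
}

#' @rdname univariateScreen
#' @param screen data.frame from `univariateScreen()`.
#' @param path output TSV path.
#' @export
writeScreenTsv <- function(screen, path) {
  utils::write.table(screen, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
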