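# Small cohort for fast unit tests.
small_cohort <- function(n = 24, p = 8, nInformative = 2, effect = 2,
                         seed = 1, missingRate = 0, outlierFraction = 0) {
  # two blocks only, so few columns are reserved as always-observed MAR
  # drivers even at very small p
  bs <- data.frame(block = c("protein", "gene_expr"),
                   n = c(ceiling(p / 2), floor(p / 2)),
                   location = c(500, 1), scale = c(150, 0.4))
  bs <- bs[bs$n > 0, ]
  cfg <- synthConfig(nSamples = n, nFeatures = p, prevalence = 1 / 3,
                     nInformative = nInformative, effectSize = effect,
                     blockSpec = bs, missingRate = missingRate,
                     outlierCellFraction = outlierFraction, seed = seed)
  if (missingRate > 0 || outlierFraction > 0) simulateCohort(cfg)
  else generateCohort(cfg)
}

# Independent dense PLS-DA oracle: successive rank-1 SVDs of t(X) %*% Y
# with the same regression-mode deflation, no sparsity, no sign convention.
dense_pls_oracle <- function(X, y, H) {
  Xh <- scale(X)
  yf <- factor(y)
  Yh <- scale(cbind(yf == levels(yf)[1], yf == levels(yf)[2]) * 1)
  U <- matrix(0, ncol(X), H)
  for (h in seq_len(H)) {
    u <- svd(crossprod(Xh, Yh))$u[, 1]
    tv <- drop(Xh %*% u)
    ph <- drop(crossprod(Xh, tv)) / sum(tv^2)
    qh <- drop(crossprod(Yh, tv)) / sum(tv^2)
    U[, h] <- u
    Xh <- Xh - tcrossprod(tv, ph)
    Yh <- Yh - tcrossprod(tv, qh)
  }
  U
}

# Brute-force AUC by exhaustive pair counting (ties count one half).
pair_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Maximum absolute difference between two vectors up to a global sign flip.
sign_invariant_diff <- function(a, b) {
  min(max(abs(a - b)), max(abs(a + b)))
}
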