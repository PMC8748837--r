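# Independent oracles used to freeze or cross-check expected values.
# These are deliberately written as plain enumerations, independent of the
# vectorized implementations in the package.

# AUROC by brute force over all positive-negative pairs (ties count 1/2).
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Hyperbolic-weighted tau by explicit pair enumeration with additive
# weights w(r) = 1/(1+r) on 0-based midranks, symmetrized over which vector
# supplies the weights.
hwt_oracle <- function(a, b) {
  n <- length(a)
  one <- function(ref) {
    r <- rank(-ref, ties.method = "average") - 1
    w <- 1 / (1 + r)
    num <- da <- db <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        wij <- w[i] + w[j]
        sa <- sign(a[i] - a[j])
        sb <- sign(b[i] - b[j])
        num <- num + sa * sb * wij
        da <- da + sa * sa * wij
        db <- db + sb * sb * wij
      }
    }
    num / sqrt(da * db)
  }
  (one(a) + one(b)) / 2
}

# Exact one-sided Mann-Whitney p-value (x stochastically smaller) by
# enumeration of all group assignments of the pooled values.
mw_oracle <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  rk <- rank(pooled)
  U_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  combos <- combn(length(pooled), m)
  U_perm <- apply(combos, 2, function(idx) sum(rk[idx]) - m * (m + 1) / 2)
  mean(U_perm <= U_obs)
}

# One-way ANOVA p-value for a single feature via stats::lm / anova.
anova_p_oracle <- function(x, y) {
  fit <- stats::anova(stats::lm(x ~ factor(y)))
  fit[["Pr(>F)"]][1]
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
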