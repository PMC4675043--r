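# Independent oracles: brute-force per-pair implementations of the GRM
# estimators and direct single-SNP samplers.  These deliberately avoid the
# package's matrix formulation so they can vouch for it.

# Per-pair loop G4: for each pair, copy the scores at SNPs called in both and
# compute sum((x_i - 2p)(x_j - 2p)) / (2 * sum(p(1-p))) over that copy.
oracle_G4 <- function(X, D, p) {
  n <- nrow(X)
  G <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      use <- !is.na(X[i, ]) & !is.na(X[j, ])
      if (any(use)) {
        num <- sum((X[i, use] - 2 * p[use]) * (X[j, use] - 2 * p[use]))
        G[i, j] <- G[j, i] <- num / (2 * sum(p[use] * (1 - p[use])))
      }
    }
  }
  G
}

# Direct-formula G5 diagonal over SNPs called with depth >= 2.
oracle_G5_diag <- function(X, D, p) {
  vapply(seq_len(nrow(X)), function(i) {
    use <- !is.na(X[i, ]) & D[i, ] >= 2
    if (!any(use)) return(NA_real_)
    K <- 0.5^D[i, use]
    S <- (X[i, use] - 2 * p[use])^2
    sum((S - 8 * p[use] * (1 - p[use]) * K) / (1 - 2 * K)) /
      (2 * sum(p[use] * (1 - p[use])))
  }, numeric(1))
}

# Random score/depth instance with arbitrary missingness for oracle checks.
random_instance <- function(n, m, p_missing = 0.3) {
  D <- matrix(rpois(n * m, 3), n, m)
  D[matrix(runif(n * m) < p_missing, n, m)] <- 0L
  true_g <- matrix(rbinom(n * m, 2, 0.4), n, m)
  X <- matrix(NA_real_, n, m)
  for (c in which(D > 0)) {
    ref <- rbinom(1, D[c], true_g[c] / 2)
    X[c] <- if (ref == D[c]) 2 else if (ref == 0) 0 else 1
  }
  p <- runif(m, 0.05, 0.95)
  list(X = X, D = D, p = p)
}

# Sample an observed score for one individual with true dosage g (0/1/2)
# sequenced to exact depth k: reads ~ Binomial(k, g/2).
sample_observed_score <- function(g, k) {
  ref <- rbinom(length(g), k, g / 2)
  ifelse(ref == k, 2, ifelse(ref == 0, 0, 1))
}

# Draw true genotype dosages for individuals with inbreeding F at frequency p.
sample_inbred_dosage <- function(n, p, F) {
  probs <- c(p^2 + p * (1 - p) * F,        # AA
             2 * p * (1 - p) * (1 - F),    # AB
             (1 - p)^2 + p * (1 - p) * F)  # BB
  sample(c(2, 1, 0), n, replace = TRUE, prob = probs)
}

# Draw (parent dosage, offspring dosage) pairs: the offspring gets one
# parental allele (reference w.p. g/2) and one population allele.
sample_parent_offspring <- function(n, p) {
  g_par <- rbinom(n, 2, p)
  g_off <- rbinom(n, 1, g_par / 2) + rbinom(n, 1, p)
  cbind(parent = g_par, offspring = g_off)
}
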