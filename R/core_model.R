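# Single-SNP probability model and method-of-moments estimators.
#
# The model: a biallelic SNP with alleles A (reference) and B is sequenced to
# depth k in one individual.  Reads are drawn at random, without error, from
# the individual's two alleles, so a true heterozygote is observed as a given
# homozygote with probability K = 1/2^k; true homozygotes are always observed
# correctly.  Depth 0 means the genotype is missing.

# Depths beyond this contribute K that underflows to 0 anyway; capping avoids
# needless 2^k overflow for pathological inputs.
.K_DEPTH_CAP <- 64L

#' Heterozygote-miscall probability at a given read depth
#'
#' Under random, error-free allele reads a true heterozygote sequenced to
#' depth `k` is observed as a specific homozygote with probability
#' `K = 1/2^k`.  `K` is the depth factor used throughout the self-relatedness
#' adjustment; at `k = 1`, `K = 1/2` (a heterozygote is always read as one
#' homozygote or the other) and `K -> 0` as depth grows.
#'
#' @param k Integer vector of read depths, each `>= 0`.
#' @return Numeric vector of the same length: `1/2^k` for `k >= 1`, `NA` for
#'   `k = 0` (no reads, genotype missing).  Depths above 64 are capped; `K`
#'   is exactly 0 in double precision from `k = 1075` but already below
#'   `.Machine$double.eps` at the cap.
#' @examples
#' depth_to_K(c(1, 2, 8))
#' @export
depth_to_K <- function(k) {
  if (length(k) == 0L) return(numeric(0))
  if (anyNA(k) || !is.numeric(k)) {
    stop("`k` must be a non-missing numeric vector of depths", call. = FALSE)
  }
  if (any(k < 0) || any(k != trunc(k))) {
    stop("read depths must be non-negative integers", call. = FALSE)
  }
  kk <- pmin(k, .K_DEPTH_CAP)
  K <- 0.5^kk
  K[k == 0] <- NA_real_
  K
}

#' Call a genotype from reference and alternate read counts
#'
#' Error-free calling: any mixture of both alleles is a heterozygote, reads of
#' a single allele give the corresponding homozygote, and zero total depth is
#' a missing genotype.  The score `x` counts reference alleles in the
#' observed genotype (2 = hom ref, 1 = het, 0 = hom alt).
#'
#' @param ref,alt Non-negative integer vectors (recycled to a common length)
#'   of reference and alternate read counts.
#' @return A list with components `x` (score, `NA` when missing) and `k`
#'   (total depth `ref + alt`).
#' @examples
#' call_genotype(c(3, 1, 0), c(0, 1, 0))
#' @export
call_genotype <- function(ref, alt) {
  if (anyNA(ref) || anyNA(alt) || any(ref < 0) || any(alt < 0) ||
      any(ref != trunc(ref)) || any(alt != trunc(alt))) {
    stop("read counts must be non-missing, non-negative integers",
         call. = FALSE)
  }
  k <- ref + alt
  x <- ifelse(ref > 0 & alt > 0, 1,
         ifelse(ref > 0, 2, ifelse(alt > 0, 0, NA_real_)))
  list(x = x, k = k)
}

#' Observed-genotype probabilities under depth-dependent miscalling
#'
#' Probabilities of the three observed genotypes (AA*, AB*, BB*) for an
#' individual with inbreeding coefficient `F` at a SNP with reference allele
#' frequency `p`, when a true heterozygote is read as either homozygote with
#' probability `K` each:
#' \deqn{P(AA^*) = p^2 + p(1-p)F + 2p(1-p)(1-F)K}
#' \deqn{P(AB^*) = 2p(1-p)(1-F)(1-2K)}
#' \deqn{P(BB^*) = (1-p)^2 + p(1-p)F + 2p(1-p)(1-F)K}
#'
#' @param p Reference allele frequency, strictly in (0, 1).
#' @param F Inbreeding coefficient in \[0, 1\].
#' @param K Depth factor in \[0, 1/2\].
#' @return A 3-column matrix (`pAA`, `pAB`, `pBB`); rows sum to 1.  Arguments
#'   are recycled to a common length.
#' @examples
#' observed_genotype_probs(0.5, F = 0, K = 0.5)  # depth 1: no observed hets
#' @export
observed_genotype_probs <- function(p, F = 0, K = 0) {
  n <- max(length(p), length(F), length(K))
  p <- rep_len(p, n); F <- rep_len(F, n); K <- rep_len(K, n)
  if (any(p <= 0 | p >= 1)) stop("`p` must lie strictly in (0, 1)", call. = FALSE)
  if (any(F < 0 | F > 1)) stop("`F` must lie in [0, 1]", call. = FALSE)
  if (any(K < 0 | K > 0.5)) stop("`K` must lie in [0, 1/2]", call. = FALSE)
  q <- 1 - p
  het0 <- 2 * p * q * (1 - F)          # true heterozygote probability
  pAA <- p^2 + p * q * F + het0 * K
  pAB <- het0 * (1 - 2 * K)
  pBB <- q^2 + p * q * F + het0 * K
  cbind(pAA = pAA, pAB = pAB, pBB = pBB)
}

#' Centred score cross-product for a pair of observations
#'
#' The moment quantity `S = (x_i - 2p)(x_i' - 2p)` underlying all the
#' relatedness estimators; with `i = i'` it is the squared centred score.
#'
#' @param x_i,x_i2 Observed genotype scores (0, 1, 2 or `NA`).
#' @param p Reference allele frequency in (0, 1).
#' @return `S`, `NA` wherever either score is missing.
#' @export
pair_S <- function(x_i, x_i2, p) {
  if (any(p <= 0 | p >= 1, na.rm = TRUE)) {
    stop("`p` must lie strictly in (0, 1)", call. = FALSE)
  }
  (x_i - 2 * p) * (x_i2 - 2 * p)
}

#' Single-SNP estimate of relatedness (2 * coancestry)
#'
#' `S / (2p(1-p))`.  Its expectation is `2 * theta` whatever the read depth:
#' the depth factor cancels from the expectation of the cross-product of two
#' different individuals' scores, which is the key unbiasedness property of
#' the co-called estimators.
#'
#' @inheritParams pair_S
#' @return Unclipped estimate of twice the coancestry; single-SNP values
#'   routinely fall outside \[0, 1\].
#' @export
single_snp_relatedness <- function(x_i, x_i2, p) {
  pair_S(x_i, x_i2, p) / (2 * p * (1 - p))
}

#' Depth-adjusted self cross-product for one SNP
#'
#' The per-SNP term of the corrected diagonal,
#' `(S_ii - 8p(1-p)K) / (1 - 2K)`, whose expectation is `2p(1-p)(1+F)` for
#' every admissible `K < 1/2`.  At `K = 1/2` (depth 1) the observation
#' carries no information about `F` and the SNP must be excluded.
#'
#' @param S_ii Squared centred score for the individual, from [pair_S()].
#' @param p Reference allele frequency in (0, 1).
#' @param K Depth factor, `0 <= K < 1/2`.
#' @return Adjusted term; `NA` propagates from `S_ii`.
#' @export
adjusted_self_S <- function(S_ii, p, K) {
  if (any(p <= 0 | p >= 1)) stop("`p` must lie strictly in (0, 1)", call. = FALSE)
  if (any(K < 0 | K >= 0.5, na.rm = TRUE)) {
    stop("`K` must lie in [0, 1/2); depth-1 SNPs (K = 1/2) carry no self-relatedness information and must be excluded",
         call. = FALSE)
  }
  (S_ii - 8 * p * (1 - p) * K) / (1 - 2 * K)
}

#' Single-SNP inbreeding estimate
#'
#' `F_hat = (S_ii - 2p(1-p)(1+2K)) / (2p(1-p)(1-2K))`.  Returned unclipped:
#' single-SNP values can be far outside \[0, 1\] and only average to `F`.
#'
#' @inheritParams adjusted_self_S
#' @export
single_snp_inbreeding <- function(S_ii, p, K) {
  if (any(K < 0 | K >= 0.5, na.rm = TRUE)) {
    stop("`K` must lie in [0, 1/2); at K = 1/2 the expectation of S_ii does not depend on F",
         call. = FALSE)
  }
  v <- 2 * p * (1 - p)
  (S_ii - v * (1 + 2 * K)) / (v * (1 - 2 * K))
}

#' Closed-form expectations of the moment quantities
#'
#' Test oracles: `E(S_ii) = 2p(1-p)(1 + F + 2K - 2FK)` (depth-dependent
#' unless `F = 1`) and `E(S_ii') = 4p(1-p) * theta` (depth-independent).
#'
#' @inheritParams observed_genotype_probs
#' @param theta Coancestry between the two individuals (pair mode only).
#' @param mode `"self"` or `"pair"`.
#' @export
expected_S <- function(p, F = 0, theta = 0, K = 0, mode = c("self", "pair")) {
  mode <- match.arg(mode)
  v <- 2 * p * (1 - p)
  if (mode == "self") v * (1 + F + 2 * K - 2 * F * K) else 2 * v * theta
}
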