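# Whole-panel genomic relationship matrices from GBS scores and depths.
#
# Four estimators are built from the same centred-score machinery:
#   G1 - classical GRM, missing scores naively imputed to the mean (2p),
#        one shared denominator 2*sum_j p_j(1-p_j); biased at low depth.
#   G3 - one read sampled per cell (the k = 1, K = 1/2 model), combined with
#        per-pair denominators; diagonal carries no inbreeding information.
#   G4 - per-pair denominators restricted to co-called SNPs; unbiased
#        off-diagonals, diagonal still depth-inflated.
#   G5 - G4 plus the depth-adjusted diagonal; the fully corrected estimator
#        ("kinship using GBS with depth adjustment").

#' Estimate allele frequencies from total read counts
#'
#' Pools all reads over individuals: `p_j = sum_i ref_ij / sum_i depth_ij`.
#' Equal weight per read (not per genotyped individual), matching the use of
#' raw allelic depths as the frequency source.
#'
#' @param counts A [gbs_counts] object.
#' @return An object of class `allele_freqs`: list with `p` (named numeric,
#'   `NaN` for SNPs with zero total depth), `monomorphic` (logical: zero
#'   depth or all reads one allele; such SNPs must be excluded downstream)
#'   and `source = "read_counts"`.
#' @export
estimate_allele_frequencies <- function(counts) {
  stopifnot(inherits(counts, "gbs_counts"))
  tot_ref <- colSums(counts$ref)
  tot <- tot_ref + colSums(counts$alt)
  p <- tot_ref / tot                      # NaN where tot == 0
  mono <- tot == 0 | p <= 0 | p >= 1
  structure(list(p = p, monomorphic = unname(mono), source = "read_counts"),
            class = "allele_freqs")
}

#' Wrap externally supplied allele frequencies
#'
#' @param p Numeric vector of reference allele frequencies, each strictly in
#'   (0, 1).
#' @return An `allele_freqs` object with `source = "external"`.
#' @export
allele_freqs <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop("external allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(p = p, monomorphic = rep(FALSE, length(p)),
                 source = "external"), class = "allele_freqs")
}

.freq_vector <- function(freqs, n_snps) {
  p <- if (inherits(freqs, "allele_freqs")) freqs$p else freqs
  if (length(p) != n_snps) {
    stop("allele frequencies are not aligned with the SNP columns", call. = FALSE)
  }
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop("all SNPs used in estimation must be polymorphic with p strictly in (0, 1); drop monomorphic SNPs first",
         call. = FALSE)
  }
  as.numeric(p)
}

#' Centre genotype scores
#'
#' `Z_ij = x_ij - 2 p_j` where called; missing cells are set to 0 so that a
#' SNP missing in either individual contributes nothing to `Z Z'`.
#'
#' @param scores A [gbs_scores] object.
#' @param freqs An `allele_freqs` object or plain numeric vector aligned with
#'   the SNP columns.
#' @return Numeric matrix `Z` of the same dimensions as `scores$X`.
#' @export
center_scores <- function(scores, freqs) {
  stopifnot(inherits(scores, "gbs_scores"))
  p <- .freq_vector(freqs, ncol(scores$X))
  Z <- sweep(scores$X, 2, 2 * p)
  Z[is.na(Z)] <- 0
  Z
}

.new_grm <- function(G, method, diagonal_valid, n_snps_used = NULL) {
  G <- (G + t(G)) / 2   # enforce exact symmetry against FP round-off
  structure(list(G = G, method = method, diagonal_valid = diagonal_valid,
                 n_snps_used = n_snps_used), class = "gbs_grm")
}

#' @export
print.gbs_grm <- function(x, ...) {
  off <- x$G[upper.tri(x$G)]
  cat(sprintf("<gbs_grm %s> %d individuals; mean diag %.3f%s; mean off-diag %.3f (%d missing cells)\n",
              x$method, nrow(x$G), mean(diag(x$G), na.rm = TRUE),
              if (x$diagonal_valid) "" else " [diagonal not valid]",
              mean(off, na.rm = TRUE), sum(is.na(off))))
  invisible(x)
}

#' Classical GRM with naive mean imputation (G1)
#'
#' `G1 = Z Z' / (2 sum_j p_j (1 - p_j))` with missing scores replaced by
#' their expectation 2p (i.e. zero after centring).  The single shared
#' denominator assumes every SNP informs every pair, so under low-depth GBS
#' data G1 is downwardly biased for related pairs and its diagonal is
#' inflated; it is provided as the baseline the corrected estimators are
#' judged against.
#'
#' @inheritParams center_scores
#' @return A `gbs_grm` object (`method = "G1"`).
#' @export
compute_G1 <- function(scores, freqs) {
  p <- .freq_vector(freqs, ncol(scores$X))
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic: zero denominator", call. = FALSE)
  Z <- center_scores(scores, p)
  .new_grm(tcrossprod(Z) / denom, "G1", diagonal_valid = TRUE)
}

# Shared machinery for the per-pair (co-called) denominator 2 * P0 P1' and
# pair SNP counts.  block_rows trades peak memory for a blocked loop over
# individual rows; results agree to floating-point rounding.
.pair_denominator <- function(called, p, block_rows = NULL) {
  P0 <- sweep(called, 2, p, `*`)
  P1 <- sweep(called, 2, 1 - p, `*`)
  n <- nrow(called)
  if (is.null(block_rows) || block_rows >= n) {
    den <- 2 * tcrossprod(P0, P1)
  } else {
    den <- matrix(0, n, n)
    idx <- split(seq_len(n), ceiling(seq_len(n) / block_rows))
    for (rows in idx) den[rows, ] <- 2 * tcrossprod(P0[rows, , drop = FALSE], P1)
  }
  # P0 P1' is symmetric (each term is p_j(1-p_j) * called_i * called_i');
  # symmetrise to kill FP asymmetry from the two different factor orders.
  (den + t(den)) / 2
}

#' Co-called-SNP GRM (G4)
#'
#' Numerator `Z Z'` with missing cells zeroed; denominator `2 P0 P1'` where
#' `P0` holds `p_j` and `P1` holds `1 - p_j`, both zeroed at missing cells,
#' so each element of the GRM is computed over exactly the SNPs called in
#' both individuals.  Off-diagonals are unbiased at any depth; the diagonal
#' is still inflated by depth (use [compute_G5()]).
#'
#' @inheritParams center_scores
#' @param block_rows Optional row-block size for a lower-memory denominator
#'   computation; agrees with the dense default to floating-point rounding.
#' @return A `gbs_grm` object (`method = "G4"`, `diagonal_valid = FALSE`)
#'   with `n_snps_used` the per-pair co-called SNP counts.  Pairs with no
#'   co-called SNPs get `NA` with a warning.
#' @export
compute_G4 <- function(scores, freqs, block_rows = NULL) {
  stopifnot(inherits(scores, "gbs_scores"))
  p <- .freq_vector(freqs, ncol(scores$X))
  Z <- center_scores(scores, p)
  called <- (scores$D > 0) * 1
  num <- tcrossprod(Z)
  den <- .pair_denominator(called, p, block_rows)
  n_used <- tcrossprod(called)
  G <- num / den
  if (any(n_used == 0)) {
    warning(sprintf("%d cell(s) have no co-called SNPs; set to NA",
                    sum(n_used == 0)), call. = FALSE)
    G[n_used == 0] <- NA_real_
  }
  dimnames(G) <- dimnames(n_used) <- list(rownames(scores$X), rownames(scores$X))
  .new_grm(G, "G4", diagonal_valid = FALSE, n_snps_used = n_used)
}

#' Depth-adjust the diagonal of a co-called GRM (G4 -> G5)
#'
#' Replaces diagonal element `i` by
#' `sum_j (S_iij - 8 p_j (1-p_j) K_ij) / (1 - 2 K_ij) / (2 sum_j p_j (1-p_j))`,
#' both sums over SNPs called in individual `i` with depth >= 2 (`K < 1/2`;
#' depth-1 observations carry no information about inbreeding and would put
#' a zero in the first sum's denominator).  The result estimates `1 + F_i`
#' without depth bias.  Off-diagonals are copied from G4 unchanged.
#'
#' @param G4 A `gbs_grm` produced by [compute_G4()].
#' @inheritParams center_scores
#' @param denominator `"matched"` (default) sums `2 p_j (1-p_j)` over the
#'   same depth->=2 SNP set as the numerator; `"all"` sums over every SNP
#'   called in the individual (either reading of the formula's unstated
#'   index set).
#' @return A `gbs_grm` object (`method = "G5"`, `diagonal_valid = TRUE`).
#'   Individuals with no depth->=2 SNPs get an `NA` diagonal.
#' @export
adjust_diagonal <- function(G4, scores, freqs,
                            denominator = c("matched", "all")) {
  stopifnot(inherits(G4, "gbs_grm"), inherits(scores, "gbs_scores"))
  denominator <- match.arg(denominator)
  p <- .freq_vector(freqs, ncol(scores$X))
  X <- scores$X; D <- scores$D
  n <- nrow(X)
  pq <- p * (1 - p)
  diag_new <- rep(NA_real_, n)
  Kmat <- matrix(depth_to_K(as.vector(pmin(D, .K_DEPTH_CAP))), n, ncol(X))
  for (i in seq_len(n)) {
    use <- !is.na(X[i, ]) & D[i, ] >= 2
    if (!any(use)) next
    S <- (X[i, use] - 2 * p[use])^2
    K <- Kmat[i, use]
    num <- sum((S - 8 * pq[use] * K) / (1 - 2 * K))
    den_set <- if (denominator == "matched") use else !is.na(X[i, ])
    diag_new[i] <- num / (2 * sum(pq[den_set]))
  }
  G <- G4$G
  diag(G) <- diag_new
  if (anyNA(diag_new)) {
    warning(sprintf("%d individual(s) have no SNPs with depth >= 2; diagonal set to NA",
                    sum(is.na(diag_new))), call. = FALSE)
  }
  .new_grm(G, "G5", diagonal_valid = TRUE, n_snps_used = G4$n_snps_used)
}

#' Fully depth-corrected GRM (G5, "KGD")
#'
#' Convenience wrapper: [compute_G4()] followed by [adjust_diagonal()].
#'
#' @inheritParams compute_G4
#' @inheritParams adjust_diagonal
#' @return A `gbs_grm` object (`method = "G5"`).
#' @export
compute_G5 <- function(scores, freqs, block_rows = NULL,
                       denominator = c("matched", "all")) {
  adjust_diagonal(compute_G4(scores, freqs, block_rows), scores, freqs,
                  denominator = match.arg(denominator))
}

#' Sampled-allele GRM (G3)
#'
#' Discards all but one read per cell: for each called cell one read is
#' drawn (reference with probability `ref/(ref+alt)`), giving a score of 2
#' or 0 — exactly the depth-1, `K = 1/2` model.  Scores are combined with
#' the per-pair co-called denominator of G4.  More robust to read-clustering
#' model violations but never uses full information, so it is noisier than
#' G5; its diagonal carries no inbreeding information and is flagged
#' invalid.
#'
#' @param counts A [gbs_counts] object.
#' @inheritParams center_scores
#' @param seed Integer seed for the read sampling (required, for
#'   reproducibility).
#' @return A `gbs_grm` object (`method = "G3"`, `diagonal_valid = FALSE`).
#' @export
compute_G3 <- function(counts, freqs, seed) {
  stopifnot(inherits(counts, "gbs_counts"))
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required for G3 (one read is sampled per cell)", call. = FALSE)
  }
  set.seed(seed)
  depth <- counts$ref + counts$alt
  p_ref_read <- counts$ref / ifelse(depth == 0, 1, depth)
  draw <- matrix(stats::rbinom(length(depth), 1, as.vector(p_ref_read)),
                 nrow(depth), ncol(depth))
  X <- ifelse(depth == 0, NA_real_, 2 * draw)
  dimnames(X) <- dimnames(depth)
  sampled <- gbs_scores(X, (depth > 0) * 1)
  g <- compute_G4(sampled, freqs)
  .new_grm(g$G, "G3", diagonal_valid = FALSE, n_snps_used = g$n_snps_used)
}

#' Summarise a GRM over relationship groups
#'
#' @param grm A `gbs_grm` object.
#' @param groups A data frame with columns `group`, `id1`, `id2` (ids present
#'   in the GRM); rows with `id1 == id2` read the diagonal.  Typically from
#'   [relationship_groups()].
#' @return A data frame `(group, mean, sd, n_pairs, n_missing)`; missing GRM
#'   cells are skipped and counted.  Empty groups are dropped with a warning.
#' @export
summarize_grm <- function(grm, groups) {
  stopifnot(inherits(grm, "gbs_grm"))
  ids <- rownames(grm$G)
  bad <- !(groups$id1 %in% ids) | !(groups$id2 %in% ids)
  if (any(bad)) stop("group pair lists reference unknown individual ids", call. = FALSE)
  i1 <- match(groups$id1, ids); i2 <- match(groups$id2, ids)
  vals <- grm$G[cbind(i1, i2)]
  out <- do.call(rbind, lapply(split(seq_along(vals), groups$group), function(idx) {
    v <- vals[idx]
    data.frame(group = groups$group[idx[1]],
               mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v[!is.na(v)]),
               n_pairs = sum(!is.na(v)),
               n_missing = sum(is.na(v)))
  }))
  empty <- setdiff(unique(groups$group), out$group)
  if (length(empty)) warning("empty group(s) omitted: ",
                             paste(empty, collapse = ", "), call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Eigenvalue report for a GRM
#'
#' The co-called construction does not guarantee positive semi-definiteness;
#' no repair is applied, but this report flags how far a matrix is from PSD.
#'
#' @param grm A `gbs_grm` with no missing cells.
#' @return List with `min_eigenvalue`, `n_negative` and `eigenvalues`.
#' @export
grm_eigen_report <- function(grm) {
  stopifnot(inherits(grm, "gbs_grm"))
  if (anyNA(grm$G)) stop("eigen report requires a complete GRM", call. = FALSE)
  ev <- eigen(grm$G, symmetric = TRUE, only.values = TRUE)$values
  list(min_eigenvalue = min(ev), n_negative = sum(ev < 0), eigenvalues = ev)
}
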