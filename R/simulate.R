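# Pedigreed genotype and GBS read simulator, and the three simulation
# experiments used to characterise the estimators:
#   1. method comparison at mean depths 1, 2, 8 (G1/G3/G4/G5 vs true-genotype
#      "Chip" baseline) on the default 100-family design;
#   2. fixed total sequencing effort (n_snps * depth = 10,000 reads) swept
#      over mean depth 0.25-20, G5 only;
#   3. allele-frequency x SNP-count grid at depth 2, G5 only.
#
# The stated world: 100 sire-dam pairs of unrelated, non-inbred parents, two
# full-sib offspring per pair (400 individuals), 10,000 unlinked SNPs with
# allele frequencies ~ Uniform(0,1), per-cell depths ~ Poisson(d), reads
# drawn with replacement from the individual's two alleles.

# One user seed is split into independent per-stage seeds so stages
# (genotypes, depths/reads, G3 sampling) can be re-run in isolation.
split_seed <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(as.integer(seed))
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

#' Build the default simulation pedigree
#'
#' `n_families` sire-dam pairs of unrelated founders, each with
#' `n_offspring` full-sib offspring.
#'
#' @param n_families Number of unrelated parent pairs (default 100).
#' @param n_offspring Full-sib offspring per pair (default 2).
#' @return A data frame `(id, sire, dam, generation)`; founders have `NA`
#'   parents.  Default design: 400 individuals.
#' @export
sim_pedigree <- function(n_families = 100, n_offspring = 2) {
  sires <- sprintf("S%03d", seq_len(n_families))
  dams <- sprintf("D%03d", seq_len(n_families))
  off <- as.vector(t(outer(seq_len(n_families), seq_len(n_offspring),
                           function(f, o) sprintf("O%03d_%d", f, o))))
  data.frame(
    id = c(sires, dams, off),
    sire = c(rep(NA_character_, 2 * n_families), rep(sires, each = n_offspring)),
    dam = c(rep(NA_character_, 2 * n_families), rep(dams, each = n_offspring)),
    generation = c(rep(0L, 2 * n_families),
                   rep(1L, n_families * n_offspring)),
    stringsAsFactors = FALSE)
}

#' Derive relationship-group pair lists from a pedigree
#'
#' Groups: `self` (every individual with itself), `full_sib` (distinct pairs
#' sharing both parents), `parent_offspring`, and `between_parents` (all
#' distinct pairs of recorded parents, unrelated under the default design).
#'
#' @param pedigree A pedigree data frame (`id`, `sire`, `dam`).
#' @return A data frame `(group, id1, id2)` usable with [summarize_grm()].
#' @export
relationship_groups <- function(pedigree) {
  ped <- pedigree
  self <- data.frame(group = "self", id1 = ped$id, id2 = ped$id)
  kids <- ped[!is.na(ped$sire) | !is.na(ped$dam), ]
  po <- rbind(
    data.frame(group = "parent_offspring", id1 = kids$id, id2 = kids$sire),
    data.frame(group = "parent_offspring", id1 = kids$id, id2 = kids$dam))
  po <- po[!is.na(po$id2), ]
  fam <- paste(kids$sire, kids$dam, sep = "|")
  fs <- do.call(rbind, lapply(split(kids$id, fam), function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(ids, 2)
    data.frame(group = "full_sib", id1 = cmb[1, ], id2 = cmb[2, ])
  }))
  parents <- unique(c(ped$sire, ped$dam))
  parents <- parents[!is.na(parents)]
  bp <- NULL
  if (length(parents) >= 2) {
    cmb <- utils::combn(parents, 2)
    bp <- data.frame(group = "between_parents", id1 = cmb[1, ], id2 = cmb[2, ])
  }
  out <- rbind(self, fs, po, bp)
  rownames(out) <- NULL
  out
}

#' Draw allele frequencies for a simulated SNP panel
#'
#' @param n_snps Number of SNPs.
#' @param freq_model `"uniform01"` (Uniform(0,1), the default design),
#'   `"uniform_0.1_0.5"` (used in the fixed-effort sweep so no SNP is lost
#'   to monomorphism), or a single numeric in (0, 1) for a common fixed
#'   frequency (the frequency-grid design).
#' @param seed Optional integer seed.
#' @return Numeric vector of reference allele frequencies.
#' @export
sim_allele_freqs <- function(n_snps, freq_model = "uniform01", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(freq_model)) {
    stopifnot(length(freq_model) == 1, freq_model > 0, freq_model < 1)
    return(rep(freq_model, n_snps))
  }
  switch(match.arg(freq_model, c("uniform01", "uniform_0.1_0.5")),
         uniform01 = stats::runif(n_snps),
         uniform_0.1_0.5 = stats::runif(n_snps, 0.1, 0.5))
}

#' Simulate unlinked genotypes down a two-generation pedigree
#'
#' Founders receive two alleles i.i.d. Bernoulli(`p_j`); each offspring
#' receives one uniformly chosen allele from each parent, independently per
#' SNP (unlinked loci).
#'
#' @param pedigree From [sim_pedigree()] (two generations; founders first).
#' @param p Reference allele frequencies, length = number of SNPs.
#' @param seed Optional integer seed.
#' @return Integer matrix of reference-allele dosages (0/1/2), individuals x
#'   SNPs, rows named by pedigree id.
#' @export
simulate_genotypes <- function(pedigree, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(p)
  ped <- pedigree
  if (any(ped$id %in% ped$sire & !is.na(ped$sire) & ped$id %in% ped$dam)) {
    stop("pedigree loops are not supported", call. = FALSE)
  }
  n <- nrow(ped)
  G <- matrix(0L, n, m, dimnames = list(ped$id, paste0("snp", seq_len(m))))
  founder <- is.na(ped$sire) & is.na(ped$dam)
  nf <- sum(founder)
  G[founder, ] <- matrix(stats::rbinom(nf * m, 2L, rep(p, each = nf)), nf, m)
  kids <- which(!founder)
  if (length(kids)) {
    si <- match(ped$sire[kids], ped$id)
    di <- match(ped$dam[kids], ped$id)
    if (anyNA(si) || anyNA(di)) {
      stop("offspring sire/dam must be present in the pedigree", call. = FALSE)
    }
    nk <- length(kids)
    # transmitted allele is reference w.p. (parental dosage)/2
    from_sire <- matrix(stats::rbinom(nk * m, 1L, G[si, , drop = FALSE] / 2), nk, m)
    from_dam <- matrix(stats::rbinom(nk * m, 1L, G[di, , drop = FALSE] / 2), nk, m)
    G[kids, ] <- from_sire + from_dam
  }
  G
}

#' Simulate GBS reads over a genotype matrix
#'
#' Per-cell depth `k_ij ~ Poisson(d_i)`; each read is independently one of
#' the individual's two alleles (reference with probability dosage/2), i.e.
#' random reads with replacement.  Homozygotes always yield their own
#' allele.
#'
#' @param genotypes Dosage matrix (0/1/2) from [simulate_genotypes()].
#' @param mean_depth Poisson mean depth: a scalar, or one value per
#'   individual (recycled across SNPs) for depth heterogeneity.
#' @param seed Optional integer seed.
#' @return A [gbs_counts] object.
#' @export
simulate_gbs <- function(genotypes, mean_depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes); m <- ncol(genotypes)
  if (any(mean_depth <= 0)) stop("`mean_depth` must be positive", call. = FALSE)
  lam <- if (length(mean_depth) == 1) rep(mean_depth, n) else mean_depth
  if (length(lam) != n) stop("`mean_depth` must be scalar or one per individual", call. = FALSE)
  k <- matrix(stats::rpois(n * m, rep(lam, m)), n, m)
  ref <- matrix(stats::rbinom(n * m, as.vector(k), as.vector(genotypes) / 2), n, m)
  dimnames(ref) <- dimnames(genotypes)
  gbs_counts(ref, k - ref)
}

#' Identify SNPs monomorphic in the genotypes or the reads
#'
#' A SNP is dropped if its minor allele frequency is zero either in the true
#' genotypes or in the observed GBS reads (no SNP can be used for estimation
#' once all observed reads agree).
#'
#' @param genotypes Dosage matrix, or `NULL` to filter on reads only.
#' @param counts A [gbs_counts] object.
#' @return Integer vector of surviving SNP column indices.
#' @export
drop_monomorphic <- function(genotypes, counts) {
  stopifnot(inherits(counts, "gbs_counts"))
  tot_ref <- colSums(counts$ref); tot_alt <- colSums(counts$alt)
  keep <- tot_ref > 0 & tot_alt > 0
  if (!is.null(genotypes)) {
    d <- colSums(genotypes)
    keep <- keep & d > 0 & d < 2 * nrow(genotypes)
  }
  if (!any(keep)) stop("all SNPs are monomorphic", call. = FALSE)
  unname(which(keep))
}

#' Simulate a complete GBS panel
#'
#' One call running the whole stated design: pedigree, allele frequencies,
#' genotypes, reads, monomorphic-SNP removal and read-based frequency
#' re-estimation.
#'
#' @inheritParams sim_pedigree
#' @param n_snps SNPs simulated before monomorphic removal (default 10,000).
#' @param freq_model See [sim_allele_freqs()].
#' @param mean_depth Poisson mean depth (scalar or per individual).
#' @param seed Integer seed (split into independent per-stage streams).
#' @param use_true_freqs If `TRUE` the returned `freqs` are the simulated
#'   truth (restricted to kept SNPs) instead of read-count estimates.
#' @return List: `pedigree`, `groups`, `p_true`, `genotypes`, `counts`,
#'   `scores`, `freqs` (all restricted to kept SNPs), `kept` (SNP indices).
#' @export
sim_gbs_panel <- function(n_families = 100, n_offspring = 2, n_snps = 10000,
                          freq_model = "uniform01", mean_depth = 8,
                          seed = NULL, use_true_freqs = FALSE) {
  s <- split_seed(seed, 3)
  ped <- sim_pedigree(n_families, n_offspring)
  p_true <- sim_allele_freqs(n_snps, freq_model, seed = s[[1]])
  geno <- simulate_genotypes(ped, p_true, seed = s[[2]])
  counts <- simulate_gbs(geno, mean_depth, seed = s[[3]])
  kept <- drop_monomorphic(geno, counts)
  counts <- gbs_counts(counts$ref[, kept, drop = FALSE],
                       counts$alt[, kept, drop = FALSE])
  geno <- geno[, kept, drop = FALSE]
  freqs <- if (use_true_freqs) allele_freqs(p_true[kept])
           else estimate_allele_frequencies(counts)
  list(pedigree = ped, groups = relationship_groups(ped),
       p_true = p_true[kept], genotypes = geno, counts = counts,
       scores = score_genotypes(counts), freqs = freqs, kept = kept)
}

# "Chip" baseline: G1 on the true genotypes (complete, infinite depth),
# with frequencies estimated from the genotypes themselves.
.chip_grm <- function(genotypes) {
  X <- genotypes
  storage.mode(X) <- "double"
  scr <- gbs_scores(X, matrix(1, nrow(X), ncol(X), dimnames = dimnames(X)))
  p <- colMeans(X) / 2
  compute_G1(scr, p)
}

#' Experiment 1: method comparison across depths
#'
#' Runs the default design at each depth and summarises relationship-group
#' means and standard deviations for the true-genotype baseline (`Chip`,
#' G1 on actual genotypes) and the GBS estimators G1, G3, G4, G5.
#'
#' @param depths Mean depths to simulate (default `c(1, 2, 8)`).
#' @inheritParams sim_gbs_panel
#' @return A data frame `(depth, method, group, mean, sd, n_pairs,
#'   n_missing)`.
#' @export
experiment_method_comparison <- function(depths = c(1, 2, 8),
                                         n_families = 100, n_snps = 10000,
                                         freq_model = "uniform01",
                                         seed = NULL) {
  seeds <- split_seed(seed, 2 * length(depths))
  out <- list()
  for (di in seq_along(depths)) {
    d <- depths[di]
    panel <- sim_gbs_panel(n_families = n_families, n_snps = n_snps,
                           freq_model = freq_model, mean_depth = d,
                           seed = seeds[[2 * di - 1]])
    grms <- list(
      Chip = .chip_grm(panel$genotypes),
      G1 = compute_G1(panel$scores, panel$freqs),
      G3 = compute_G3(panel$counts, panel$freqs, seed = seeds[[2 * di]]),
      G4 = compute_G4(panel$scores, panel$freqs),
      G5 = compute_G5(panel$scores, panel$freqs))
    for (meth in names(grms)) {
      tab <- summarize_grm(grms[[meth]], panel$groups)
      tab$depth <- d; tab$method <- meth
      out[[length(out) + 1L]] <- tab
    }
  }
  res <- do.call(rbind, out)
  res[, c("depth", "method", "group", "mean", "sd", "n_pairs", "n_missing")]
}

#' Experiment 2: fixed total sequencing effort
#'
#' Total effort (SNPs x mean depth) is held at `total_effort` reads while
#' mean depth sweeps `depths`; allele frequencies are Uniform(0.1, 0.5) so
#' that no SNP is lost.  G5 only.  Non-integer SNP counts are rounded to
#' nearest and the realised effort recorded.
#'
#' @param total_effort Reads spanning a SNP (default 10,000).
#' @param depths Mean-depth grid (default `c(0.25, 0.5, 1, 2, 4, 8, 12, 20)`).
#' @inheritParams sim_gbs_panel
#' @return A data frame `(depth, n_snps, realized_effort,
#'   mean_called_per_snp, group, mean, sd, n_pairs, n_missing)`;
#'   `mean_called_per_snp` counts parents (founders) with depth >= 1,
#'   averaged over SNPs.
#' @export
experiment_fixed_effort <- function(total_effort = 10000,
                                    depths = c(0.25, 0.5, 1, 2, 4, 8, 12, 20),
                                    n_families = 100, seed = NULL) {
  seeds <- split_seed(seed, length(depths))
  out <- list()
  for (di in seq_along(depths)) {
    d <- depths[di]
    m <- as.integer(round(total_effort / d))
    panel <- sim_gbs_panel(n_families = n_families, n_snps = m,
                           freq_model = "uniform_0.1_0.5", mean_depth = d,
                           seed = seeds[[di]])
    is_parent <- panel$pedigree$generation == 0
    called_per_snp <- mean(colSums(panel$scores$D[is_parent, , drop = FALSE] > 0))
    tab <- summarize_grm(compute_G5(panel$scores, panel$freqs), panel$groups)
    tab$depth <- d; tab$n_snps <- m; tab$realized_effort <- m * d
    tab$mean_called_per_snp <- called_per_snp
    out[[length(out) + 1L]] <- tab
  }
  res <- do.call(rbind, out)
  res[, c("depth", "n_snps", "realized_effort", "mean_called_per_snp",
          "group", "mean", "sd", "n_pairs", "n_missing")]
}

#' Experiment 3: allele-frequency by SNP-count grid
#'
#' All SNPs share one allele frequency per run; mean depth fixed (default 2,
#' near-optimal for pair relatedness).  G5 only.
#'
#' @param freqs Common allele frequencies to test.
#' @param n_snps_grid SNP counts to test.
#' @param mean_depth Poisson mean depth (default 2).
#' @inheritParams sim_gbs_panel
#' @return A data frame `(freq, n_snps, group, mean, sd, n_pairs,
#'   n_missing)`.
#' @export
experiment_freq_grid <- function(freqs = c(0.01, 0.05, 0.1, 0.2, 0.5),
                                 n_snps_grid = c(1000, 10000, 50000),
                                 mean_depth = 2, n_families = 100,
                                 seed = NULL) {
  grid <- expand.grid(freq = freqs, n_snps = n_snps_grid)
  seeds <- split_seed(seed, nrow(grid))
  out <- list()
  for (gi in seq_len(nrow(grid))) {
    panel <- sim_gbs_panel(n_families = n_families,
                           n_snps = grid$n_snps[gi],
                           freq_model = grid$freq[gi],
                           mean_depth = mean_depth, seed = seeds[[gi]])
    tab <- summarize_grm(compute_G5(panel$scores, panel$freqs), panel$groups)
    tab$freq <- grid$freq[gi]; tab$n_snps <- grid$n_snps[gi]
    out[[length(out) + 1L]] <- tab
  }
  res <- do.call(rbind, out)
  res[, c("freq", "n_snps", "group", "mean", "sd", "n_pairs", "n_missing")]
}
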