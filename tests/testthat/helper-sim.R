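# Shared simulation fixtures built in code.

# Small complete-data score fixture with known values.
toy_scores <- function() {
  X <- rbind(c(2, 1, 0, 2),
             c(1, 1, 2, 0),
             c(0, 2, 1, 1))
  D <- matrix(5, 3, 4)
  gbs_scores(X, D)
}

# A GBS panel contaminated with duplicated-region SNPs: a fraction of SNPs
# come from collapsed genome duplications with a fixed difference between
# copies, so every individual is truly heterozygous there and the apparent
# depth is doubled.  Per-individual mean depths are log-uniform on
# [depth_lo, depth_hi] to give the self-relatedness-vs-depth diagnostic
# something to regress on.
sim_contaminated_panel <- function(n_families = 50, n_snps = 2000,
                                   prop_dup = 0.1, depth_lo = 1,
                                   depth_hi = 8, seed = 1) {
  set.seed(seed)
  ped <- sim_pedigree(n_families)
  n <- nrow(ped)
  d_i <- exp(runif(n, log(depth_lo), log(depth_hi)))
  p <- sim_allele_freqs(n_snps, "uniform_0.1_0.5")
  geno <- simulate_genotypes(ped, p)
  n_dup <- round(prop_dup * n_snps)
  dup <- seq_len(n_dup)
  geno[, dup] <- 1L
  ct <- simulate_gbs(geno[, dup, drop = FALSE], 2 * d_i)
  cl <- simulate_gbs(geno[, -dup, drop = FALSE], d_i)
  ref <- cbind(ct$ref, cl$ref); alt <- cbind(ct$alt, cl$alt)
  colnames(ref) <- colnames(alt) <- paste0("snp", seq_len(n_snps))
  counts <- gbs_counts(ref, alt)
  kept <- drop_monomorphic(NULL, counts)
  counts <- gbs_counts(counts$ref[, kept, drop = FALSE],
                       counts$alt[, kept, drop = FALSE])
  list(pedigree = ped, counts = counts, scores = score_genotypes(counts),
       freqs = estimate_allele_frequencies(counts),
       is_dup = kept <= n_dup, mean_depth_i = d_i)
}

# Filter a counts object to given columns and re-estimate frequencies,
# dropping SNPs left monomorphic (the post-filter re-estimation policy).
refit_panel <- function(counts, keep) {
  cc <- gbs_counts(counts$ref[, keep, drop = FALSE],
                   counts$alt[, keep, drop = FALSE])
  fr <- estimate_allele_frequencies(cc)
  poly <- !fr$monomorphic
  cc <- gbs_counts(cc$ref[, poly, drop = FALSE], cc$alt[, poly, drop = FALSE])
  list(counts = cc, scores = score_genotypes(cc),
       freqs = estimate_allele_frequencies(cc))
}
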