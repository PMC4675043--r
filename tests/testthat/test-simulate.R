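test_that("sim_pedigree builds the default two-generation design", {
  ped <- sim_pedigree()
  expect_equal(nrow(ped), 400)
  expect_equal(sum(is.na(ped$sire) & is.na(ped$dam)), 200)
  groups <- relationship_groups(ped)
  tab <- table(groups$group)
  expect_equal(as.integer(tab[c("self", "full_sib", "parent_offspring",
                                "between_parents")]),
               c(400L, 100L, 400L, 19900L))
  # offspring's recorded parents are in the panel
  kids <- ped[!is.na(ped$sire), ]
  expect_true(all(kids$sire %in% ped$id) && all(kids$dam %in% ped$id))
})

test_that("simulate_genotypes follows Mendelian transmission", {
  ped <- sim_pedigree(n_families = 2)
  # p = 1 - eps: parents essentially always hom ref
  g <- simulate_genotypes(ped, rep(0.999999, 5), seed = 1)
  expect_true(all(g == 2))
  # AA x BB cross gives AB always
  ped2 <- data.frame(id = c("s", "d", "o1", "o2"),
                     sire = c(NA, NA, "s", "s"), dam = c(NA, NA, "d", "d"),
                     generation = c(0L, 0L, 1L, 1L))
  g2 <- simulate_genotypes(ped2, rep(0.5, 50), seed = 2)
  g2[1, ] <- 2L; g2[2, ] <- 0L     # force parent genotypes, redo offspring
  set.seed(3)
  kid <- rbinom(50, 1, g2[1, ] / 2) + rbinom(50, 1, g2[2, ] / 2)
  expect_true(all(kid == 1))
  # founder population frequency matches p within binomial error
  ped3 <- sim_pedigree(n_families = 50)  # 100 founders = 200 alleles/SNP
  m <- 2000
  g3 <- simulate_genotypes(ped3, rep(0.3, m), seed = 4)
  founders <- g3[1:100, ]
  phat <- mean(founders) / 2
  se <- sqrt(0.3 * 0.7 / (200 * m))
  expect_lt(abs(phat - 0.3), 3 * se)
})

test_that("simulate_gbs draws Poisson depths and random allele reads", {
  g <- matrix(2L, 10, 1000)           # all hom ref
  cc <- simulate_gbs(g, mean_depth = 2, seed = 1)
  expect_true(all(cc$alt == 0))
  # depth-0 mass at d = 1 is about exp(-1)
  g2 <- matrix(1L, 20, 2000)
  cc2 <- simulate_gbs(g2, mean_depth = 1, seed = 2)
  n_cells <- length(cc2$ref)
  p0 <- mean(cc2$ref + cc2$alt == 0)
  se <- sqrt(exp(-1) * (1 - exp(-1)) / n_cells)
  expect_lt(abs(p0 - exp(-1)), 3 * se)
  # heterozygotes yield each allele with probability 1/2
  called <- cc2$ref + cc2$alt > 0
  ref_frac <- sum(cc2$ref[called]) / sum((cc2$ref + cc2$alt)[called])
  expect_lt(abs(ref_frac - 0.5), 3 * sqrt(0.25 / sum(cc2$ref + cc2$alt)))
  # per-individual mean depths are honoured
  cc3 <- simulate_gbs(matrix(1L, 2, 5000), mean_depth = c(1, 6), seed = 3)
  d <- rowMeans(cc3$ref + cc3$alt)
  expect_lt(abs(d[1] - 1), 3 * sqrt(1 / 5000))
  expect_lt(abs(d[2] - 6), 3 * sqrt(6 / 5000))
  expect_error(simulate_gbs(g, mean_depth = 0), "positive")
})

test_that("drop_monomorphic removes SNPs fixed in genotypes or reads", {
  geno <- cbind(c(2L, 1L), c(2L, 2L), c(1L, 1L))
  ref <- cbind(c(2L, 1L), c(3L, 1L), c(1L, 1L))
  alt <- cbind(c(0L, 1L), c(0L, 0L), c(0L, 0L))
  counts <- gbs_counts(ref, alt)
  # SNP2 fixed in genotypes; SNP3 polymorphic in genotypes but only ref reads
  expect_identical(drop_monomorphic(geno, counts), 1L)
  expect_identical(drop_monomorphic(NULL, counts), 1L)
  mono <- gbs_counts(cbind(c(2L, 2L)), cbind(c(0L, 0L)))
  expect_error(drop_monomorphic(NULL, mono), "monomorphic")
  # the 0.1-0.5 frequency design retains every SNP
  panel <- sim_gbs_panel(n_families = 50, n_snps = 500,
                         freq_model = "uniform_0.1_0.5", mean_depth = 2,
                         seed = 5)
  expect_equal(length(panel$kept), 500)
})

test_that("call and co-call rates match the Poisson zero mass", {
  panel <- sim_gbs_panel(n_families = 25, n_snps = 3000, mean_depth = 2,
                         freq_model = "uniform_0.1_0.5", seed = 6)
  rates <- sample_and_cocall_rates(panel$scores)
  m <- ncol(panel$scores$D)
  target <- 1 - exp(-2)
  se <- sqrt(target * (1 - target) / m)
  expect_lt(abs(mean(rates$call_rate) - target), 3 * se)
  # co-call for two independent individuals ~ (1 - e^-d)^2
  off <- rates$cocall[upper.tri(rates$cocall)]
  expect_lt(abs(mean(off) - target^2), 3 * se)
  expect_equal(diag(rates$cocall), rates$call_rate)
})

test_that("panels are reproducible by seed", {
  a <- sim_gbs_panel(n_families = 5, n_snps = 100, mean_depth = 2, seed = 7)
  b <- sim_gbs_panel(n_families = 5, n_snps = 100, mean_depth = 2, seed = 7)
  c <- sim_gbs_panel(n_families = 5, n_snps = 100, mean_depth = 2, seed = 8)
  expect_identical(a$counts, b$counts)
  expect_identical(a$p_true, b$p_true)
  expect_false(identical(a$counts, c$counts))
})

test_that("method comparison reproduces the depth-bias fingerprints", {
  res <- experiment_method_comparison(depths = c(1, 8), n_families = 25,
                                      n_snps = 1200, seed = 9)
  pick <- function(m, g, d) res$mean[res$method == m & res$group == g &
                                       res$depth == d]
  pick_sd <- function(m, g, d) res$sd[res$method == m & res$group == g &
                                        res$depth == d]
  # all runs estimate allele frequencies in-sample, which attenuates
  # estimates by up to ~ 2 * (max row-mean relatedness) = 5/n for this
  # design (n = 100 individuals); allow that known bias on top of 3 SE
  atten <- 5 / 100
  # true-genotype baseline recovers truth up to the attenuation
  expect_lt(abs(pick("Chip", "full_sib", 8) - 0.5),
            atten + 3 * pick_sd("Chip", "full_sib", 8) / sqrt(25))
  # naive G1 at depth 1: strong downward bias for related pairs
  expect_lt(pick("G1", "full_sib", 1), 0.4)
  # G4 removes the denominator inflation only: self estimates exceed G1's
  expect_gt(pick("G4", "self", 1), pick("G1", "self", 1))
  # G5 recovers truth at both depths
  for (d in c(1, 8)) {
    expect_lt(abs(pick("G5", "self", d) - 1),
              atten + 3 * pick_sd("G5", "self", d) / sqrt(100))
    expect_lt(abs(pick("G5", "full_sib", d) - 0.5),
              atten + 3 * pick_sd("G5", "full_sib", d) / sqrt(25))
  }
  # G3 is unbiased but noisier than G5 for pairs
  expect_lt(abs(pick("G3", "full_sib", 8) - 0.5),
            atten + 3 * pick_sd("G3", "full_sib", 8) / sqrt(25))
  expect_gt(pick_sd("G3", "full_sib", 8), pick_sd("G5", "full_sib", 8))
})

test_that("freq-grid sds fall with frequency and SNP count", {
  res <- experiment_freq_grid(freqs = c(0.05, 0.5),
                              n_snps_grid = c(1000, 4000),
                              n_families = 50, seed = 10)
  po_sd <- function(f, m) res$sd[res$group == "parent_offspring" &
                                   res$freq == f & res$n_snps == m]
  expect_lt(po_sd(0.5, 1000), po_sd(0.05, 1000))
  expect_lt(po_sd(0.5, 4000), po_sd(0.5, 1000))
  # independent SNPs: quadrupling the panel roughly halves the sd
  expect_gt(po_sd(0.5, 1000) / po_sd(0.5, 4000), 1.4)
  expect_lt(po_sd(0.5, 1000) / po_sd(0.5, 4000), 2.9)
  # between-parents sd nearly frequency-independent
  bp_sd <- function(f, m) res$sd[res$group == "between_parents" &
                                   res$freq == f & res$n_snps == m]
  expect_lt(bp_sd(0.05, 1000) / bp_sd(0.5, 1000), 2)
  expect_gt(bp_sd(0.05, 1000) / bp_sd(0.5, 1000), 0.5)
})

test_that("fixed-effort bookkeeping rounds SNP counts and logs realised effort", {
  res <- experiment_fixed_effort(total_effort = 1000, depths = c(0.8, 4),
                                 n_families = 10, seed = 11)
  expect_equal(unique(res$n_snps[res$depth == 0.8]), 1250L)
  expect_equal(unique(res$realized_effort[res$depth == 0.8]), 1000)
  expect_equal(unique(res$n_snps[res$depth == 4]), 250L)
})
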