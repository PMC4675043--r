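# Per-SNP / per-sample QC, the Hardy-Weinberg "fin plot", SNP filters, the
# self-relatedness-vs-depth diagnostic and pedigree parentage verification.
#
# The fin plot scatters per-SNP Hardy-Weinberg disequilibrium (observed
# reference-homozygote frequency minus its expectation p^2) against MAF.
# Algebraically every SNP falls between -MAF^2 (maximal heterozygosity, e.g.
# collapsed duplicated regions) and MAF - MAF^2 (maximal homozygosity, e.g.
# depth-1 calls), giving the fin shape.  Filtering SNPs with disequilibrium
# below about -0.05 removes non-Mendelian (duplicated-region) SNPs.

#' Hardy-Weinberg disequilibrium for one SNP
#'
#' `hw_dis = obs - p_hat^2` where `obs` is the observed frequency of the
#' reference-allele homozygote among called individuals and
#' `p_hat = (2 n_AA + n_AB) / (2 n_called)` is the genotype-call-based
#' reference allele frequency.  Using the call-based frequency makes the
#' bounds `[-maf^2, maf - maf^2]` exact.
#'
#' @param x Vector of genotype scores (0/1/2, `NA` = missing) for one SNP.
#' @return The disequilibrium, or `NA` if no individual is called.
#' @examples
#' hw_disequilibrium(c(1, 1, 1, 1))  # all het: -0.25
#' @export
hw_disequilibrium <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  p_hat <- mean(x) / 2
  mean(x == 2) - p_hat^2
}

#' Per-SNP diagnostics table
#'
#' @param scores A [gbs_scores] object.
#' @return Data frame with one row per SNP: `snp_id`, `call_rate`
#'   (proportion of individuals with depth >= 1), `p_hat` (call-based
#'   reference allele frequency), `maf` (folded, <= 0.5), `mean_depth`, and
#'   `hw_dis`.
#' @export
snp_diagnostics <- function(scores) {
  stopifnot(inherits(scores, "gbs_scores"))
  X <- scores$X; D <- scores$D
  n_called <- colSums(!is.na(X))
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  obs_hom <- colMeans(X == 2, na.rm = TRUE)
  data.frame(snp_id = colnames(X),
             call_rate = n_called / nrow(X),
             p_hat = ifelse(n_called > 0, p_hat, NA_real_),
             maf = ifelse(n_called > 0, pmin(p_hat, 1 - p_hat), NA_real_),
             mean_depth = colMeans(D),
             hw_dis = ifelse(n_called > 0, obs_hom - p_hat^2, NA_real_),
             stringsAsFactors = FALSE)
}

#' Fin-plot coordinates with boundary curves
#'
#' @inheritParams snp_diagnostics
#' @return The [snp_diagnostics()] table plus boundary columns
#'   `lower = -maf^2` and `upper = maf - maf^2`; every SNP's `hw_dis` lies
#'   in `[lower, upper]`.
#' @export
fin_plot_data <- function(scores) {
  d <- snp_diagnostics(scores)
  d$lower <- -d$maf^2
  d$upper <- d$maf - d$maf^2
  d
}

#' Draw a fin plot
#'
#' Hardy-Weinberg disequilibrium against MAF, points shaded from grey (low
#' mean SNP depth) to blue (high), with the `-maf^2` and `maf - maf^2`
#' boundary curves and an optional filter threshold line.
#'
#' @param fin A table from [fin_plot_data()].
#' @param file Optional output path; extension selects the device (`.pdf`
#'   default, `.png` supported).
#' @param hw_dis_min Optional horizontal threshold line to draw.
#' @return Invisibly, `file` (or `NULL` when drawing to the active device).
#' @export
plot_fin <- function(fin, file = NULL, hw_dis_min = NULL) {
  if (!is.null(file)) {
    if (grepl("\\.png$", file)) grDevices::png(file, 900, 700)
    else grDevices::pdf(file, 7, 5.5)
    on.exit(grDevices::dev.off())
  }
  ok <- !is.na(fin$maf)
  fin <- fin[ok, ]
  dep <- log1p(fin$mean_depth)
  shade <- (dep - min(dep)) / max(1e-9, diff(range(dep)))
  cols <- grDevices::rgb(0.55 * (1 - shade), 0.55 * (1 - shade),
                         0.55 + 0.45 * shade)
  plot(fin$maf, fin$hw_dis, pch = 16, cex = 0.4, col = cols,
       xlab = "MAF", ylab = "Hardy-Weinberg disequilibrium",
       main = "Fin plot", xlim = c(0, 0.5))
  mg <- seq(0, 0.5, length.out = 200)
  graphics::lines(mg, mg - mg^2, lty = 2)
  graphics::lines(mg, -mg^2, lty = 2)
  if (!is.null(hw_dis_min)) graphics::abline(h = hw_dis_min, col = "red")
  invisible(file)
}

#' Filter SNPs on QC statistics
#'
#' A SNP is kept iff it passes every enabled criterion (conjunctive, so the
#' kept set is order-independent).  The removal report attributes each
#' dropped SNP to the first failing criterion in the order `call_rate`,
#' `maf_min`, `maf_max`, `hw_dis`.
#'
#' @param diag A table from [snp_diagnostics()] or [fin_plot_data()].
#' @param hw_dis_min Drop SNPs with `hw_dis` strictly below this (default
#'   -0.05, the empirically chosen duplicated-region cut-off); `NULL`
#'   disables.
#' @param maf_min Drop SNPs with `maf` strictly below this; `NULL` disables.
#' @param maf_max Drop SNPs with `maf >=` this (e.g. 0.48); `NULL` disables.
#' @param call_rate_min Drop SNPs with `call_rate` strictly below this;
#'   `NULL` disables.
#' @return List: `kept` (SNP ids), `keep` (logical vector aligned with
#'   `diag`), `report` (removals per criterion, first-fail attribution).
#' @export
apply_filters <- function(diag, hw_dis_min = -0.05, maf_min = NULL,
                          maf_max = NULL, call_rate_min = NULL) {
  n <- nrow(diag)
  fails <- list(
    call_rate = if (!is.null(call_rate_min)) diag$call_rate < call_rate_min,
    maf_min = if (!is.null(maf_min)) diag$maf < maf_min,
    maf_max = if (!is.null(maf_max)) diag$maf >= maf_max,
    hw_dis = if (!is.null(hw_dis_min)) diag$hw_dis < hw_dis_min)
  fails <- fails[!vapply(fails, is.null, logical(1))]
  fails <- lapply(fails, function(f) !is.na(f) & f)
  if (!length(fails)) {
    return(list(kept = diag$snp_id, keep = rep(TRUE, n),
                report = data.frame(criterion = character(0),
                                    n_removed = integer(0))))
  }
  keep <- rep(TRUE, n)
  for (f in fails) keep <- keep & !f
  if (!any(keep)) stop("all SNPs removed by the filters", call. = FALSE)
  attributed <- rep(FALSE, n)
  report <- data.frame(criterion = names(fails),
                       n_removed = NA_integer_, stringsAsFactors = FALSE)
  for (ci in seq_along(fails)) {
    first_fail <- fails[[ci]] & !attributed
    report$n_removed[ci] <- sum(first_fail)
    attributed <- attributed | first_fail
  }
  list(kept = diag$snp_id[keep], keep = keep, report = report)
}

#' Regression diagnostic: self-relatedness against log sample depth
#'
#' Under a correctly specified model the depth-adjusted diagonal is
#' unrelated to an individual's mean sequencing depth; a positive slope is
#' the signature of non-Mendelian (e.g. duplicated-region) SNPs.
#'
#' @param grm A `gbs_grm` with a valid diagonal (G5).
#' @param sample_mean_depths Per-individual mean depth, aligned with the GRM
#'   rows.
#' @return List with `slope` and `correlation` of `diag(G)` on
#'   `log(mean depth)`; `correlation` is `NA` when depth is constant.
#' @export
self_relatedness_depth_check <- function(grm, sample_mean_depths) {
  stopifnot(inherits(grm, "gbs_grm"))
  if (!isTRUE(grm$diagonal_valid)) {
    warning("GRM diagonal is not depth-corrected; diagnostic reflects raw diagonals",
            call. = FALSE)
  }
  y <- diag(grm$G)
  x <- log(sample_mean_depths)
  ok <- !is.na(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (stats::var(x) == 0) {
    return(list(slope = if (stats::var(y) == 0) 0 else NA_real_,
                correlation = NA_real_))
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  list(slope = unname(fit$coefficients[2]),
       correlation = if (stats::var(y) == 0) NA_real_ else stats::cor(x, y))
}

#' Verify recorded parentage against estimated relatedness
#'
#' Flags recorded offspring whose estimated relatedness with either recorded
#' parent falls below `threshold` (default 0.25, half the expected
#' parent-offspring relatedness of 0.5) — the signature of a pedigree
#' recording or sample-tracking error.
#'
#' @param grm A `gbs_grm` object.
#' @param pedigree Data frame (`id`, `sire`, `dam`).
#' @param threshold Relatedness below which a parent link is rejected.
#' @return Data frame `(id, sire, dam, sire_relatedness, dam_relatedness,
#'   flagged)`, one row per recorded offspring.  Parents absent from the GRM
#'   are skipped for that link with a warning.
#' @export
verify_parentage <- function(grm, pedigree, threshold = 0.25) {
  stopifnot(inherits(grm, "gbs_grm"))
  ids <- rownames(grm$G)
  kids <- pedigree[(!is.na(pedigree$sire) | !is.na(pedigree$dam)) &
                     pedigree$id %in% ids, ]
  rel_to <- function(kid, par) {
    if (is.na(par)) return(NA_real_)
    if (!(par %in% ids)) {
      warning(sprintf("parent '%s' absent from the GRM; check skipped", par),
              call. = FALSE)
      return(NA_real_)
    }
    grm$G[kid, par]
  }
  sire_rel <- mapply(rel_to, kids$id, kids$sire)
  dam_rel <- mapply(rel_to, kids$id, kids$dam)
  flagged <- (!is.na(sire_rel) & sire_rel < threshold) |
             (!is.na(dam_rel) & dam_rel < threshold)
  data.frame(id = kids$id, sire = kids$sire, dam = kids$dam,
             sire_relatedness = unname(sire_rel),
             dam_relatedness = unname(dam_rel),
             flagged = flagged, row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample call rates and pairwise co-call rates
#'
#' Call rate of an individual: proportion of SNPs with depth >= 1.  Co-call
#' rate of a pair: proportion of SNPs with depth >= 1 in both; the co-call
#' matrix diagonal equals the call rate.
#'
#' @param depths Individuals x SNPs depth matrix (or a [gbs_scores] /
#'   [gbs_counts] object).
#' @return List with `call_rate` (named vector) and `cocall` (symmetric
#'   matrix).
#' @export
sample_and_cocall_rates <- function(depths) {
  if (inherits(depths, "gbs_scores")) depths <- depths$D
  if (inherits(depths, "gbs_counts")) depths <- depths$ref + depths$alt
  called <- (depths > 0) * 1
  m <- ncol(called)
  list(call_rate = rowSums(called) / m, cocall = tcrossprod(called) / m)
}
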