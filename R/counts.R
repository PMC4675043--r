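# Containers for GBS allele-count data and called genotype scores.
# Orientation everywhere: rows = individuals, columns = SNPs.

#' Construct an allele-count matrix pair
#'
#' The raw GBS observable: aligned individuals x SNPs matrices of reference
#' and alternate read counts.  Depth 0 (both counts zero) is the single
#' representation of a missing genotype.
#'
#' @param ref,alt Non-negative integer matrices of identical dimensions.
#'   Row names (individual ids) and column names (SNP ids) are taken from
#'   `ref` and must match `alt` when both are named; unnamed inputs get
#'   `ind1..n` / `snp1..m`.
#' @return An object of class `gbs_counts`: a list with elements `ref` and
#'   `alt`.
#' @export
gbs_counts <- function(ref, alt) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (!identical(dim(ref), dim(alt))) {
    stop("`ref` and `alt` must have identical dimensions", call. = FALSE)
  }
  if (anyNA(ref) || anyNA(alt) || any(ref < 0) || any(alt < 0)) {
    stop("read counts must be non-missing and non-negative", call. = FALSE)
  }
  if (any(ref != trunc(ref)) || any(alt != trunc(alt))) {
    stop("read counts must be integers", call. = FALSE)
  }
  ids <- rownames(ref); snps <- colnames(ref)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(ref)))
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(ref)))
  if (!is.null(rownames(alt)) && !identical(rownames(alt), ids)) {
    stop("row names of `ref` and `alt` disagree", call. = FALSE)
  }
  if (!is.null(colnames(alt)) && !identical(colnames(alt), snps)) {
    stop("column names of `ref` and `alt` disagree", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate individual ids", call. = FALSE)
  if (anyDuplicated(snps)) stop("duplicate SNP ids", call. = FALSE)
  storage.mode(ref) <- storage.mode(alt) <- "integer"
  dimnames(ref) <- dimnames(alt) <- list(ids, snps)
  structure(list(ref = ref, alt = alt), class = "gbs_counts")
}

#' @export
print.gbs_counts <- function(x, ...) {
  cat(sprintf("<gbs_counts> %d individuals x %d SNPs; mean depth %.2f; %.1f%% cells missing\n",
              nrow(x$ref), ncol(x$ref), mean(x$ref + x$alt),
              100 * mean(x$ref + x$alt == 0)))
  invisible(x)
}

#' Call genotype scores and depths from allele counts
#'
#' Applies the error-free calling rule of [call_genotype()] to a whole count
#' matrix.
#'
#' @param counts A [gbs_counts] object.
#' @return An object of class `gbs_scores`: list with `X` (scores, `NA`
#'   exactly where depth is 0) and `D` (depths), both individuals x SNPs.
#' @export
score_genotypes <- function(counts) {
  stopifnot(inherits(counts, "gbs_counts"))
  D <- counts$ref + counts$alt
  X <- matrix(NA_real_, nrow(D), ncol(D), dimnames = dimnames(D))
  X[counts$ref > 0 & counts$alt > 0] <- 1
  X[counts$ref > 0 & counts$alt == 0] <- 2
  X[counts$ref == 0 & counts$alt > 0] <- 0
  structure(list(X = X, D = D), class = "gbs_scores")
}

#' Construct a score/depth container directly
#'
#' For callers that already hold scores and depths (e.g. tests and oracles).
#' Enforces the invariant that scores are missing exactly where depth is 0.
#'
#' @param X Score matrix (0/1/2/`NA`).
#' @param D Depth matrix (non-negative integers), same dimensions.
#' @return A `gbs_scores` object.
#' @export
gbs_scores <- function(X, D) {
  X <- as.matrix(X); D <- as.matrix(D)
  if (!identical(dim(X), dim(D))) stop("X and D dimensions differ", call. = FALSE)
  if (anyNA(D) || any(D < 0)) stop("depths must be non-missing and >= 0", call. = FALSE)
  if (any(is.na(X) != (D == 0))) {
    stop("scores must be missing exactly where depth is 0", call. = FALSE)
  }
  if (any(!is.na(X) & !(X %in% c(0, 1, 2)))) {
    stop("scores must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (is.null(rownames(X))) rownames(X) <- paste0("ind", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("snp", seq_len(ncol(X)))
  dimnames(D) <- dimnames(X)
  structure(list(X = X, D = D), class = "gbs_scores")
}

#' @export
print.gbs_scores <- function(x, ...) {
  cat(sprintf("<gbs_scores> %d individuals x %d SNPs; call rate %.3f\n",
              nrow(x$X), ncol(x$X), mean(!is.na(x$X))))
  invisible(x)
}
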