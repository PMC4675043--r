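# Readers and writers: count matrices (wide and long), VCF allelic depths,
# pedigrees and relatedness matrices.  Depth 0 is the single missingness
# encoding in count files; GRM files serialise missing cells as empty
# fields.

.read_table <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.sep_for <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' Read GBS allele counts
#'
#' Three layouts are supported:
#' \describe{
#'   \item{`wide`}{two aligned tables (`path` = `c(ref, alt)`), rows =
#'     individuals, first column = individual id, remaining headers = SNP
#'     ids.}
#'   \item{`long`}{one table with columns `individual`, `snp`, `ref_count`,
#'     `alt_count`; absent combinations are depth 0.}
#'   \item{`vcf_ad`}{a VCF with a per-sample `AD` field; biallelic SNP
#'     records only (multiallelic records are skipped with a message);
#'     requires the VariantAnnotation package.}
#' }
#' Separator is inferred from the extension (`.csv` comma, otherwise tab).
#'
#' @param path File path (length 2 for `wide`: ref then alt).
#' @param format One of `"wide"`, `"long"`, `"vcf_ad"`.
#' @return A [gbs_counts] object (individuals x SNPs).
#' @export
read_counts <- function(path, format = c("wide", "long", "vcf_ad")) {
  format <- match.arg(format)
  switch(format,
    wide = {
      if (length(path) != 2) stop("wide format needs c(ref_path, alt_path)", call. = FALSE)
      tabs <- lapply(path, function(p) {
        tb <- .read_table(p, .sep_for(p))
        ids <- as.character(tb[[1]])
        if (anyDuplicated(ids)) stop("duplicate individual ids in ", p, call. = FALSE)
        m <- as.matrix(tb[, -1, drop = FALSE])
        if (anyNA(m) || any(m < 0)) stop("negative or missing counts in ", p, call. = FALSE)
        rownames(m) <- ids
        m
      })
      if (!identical(dimnames(tabs[[1]]), dimnames(tabs[[2]]))) {
        stop("ref and alt tables must share identical individual and SNP ids",
             call. = FALSE)
      }
      gbs_counts(tabs[[1]], tabs[[2]])
    },
    long = {
      tb <- .read_table(path, .sep_for(path))
      need <- c("individual", "snp", "ref_count", "alt_count")
      if (!all(need %in% names(tb))) {
        stop("long format needs columns: ", paste(need, collapse = ", "),
             call. = FALSE)
      }
      if (anyDuplicated(tb[, c("individual", "snp")])) {
        stop("duplicate (individual, snp) rows", call. = FALSE)
      }
      ids <- unique(tb$individual); snps <- unique(tb$snp)
      ref <- matrix(0L, length(ids), length(snps), dimnames = list(ids, snps))
      alt <- ref
      ref[cbind(match(tb$individual, ids), match(tb$snp, snps))] <- tb$ref_count
      alt[cbind(match(tb$individual, ids), match(tb$snp, snps))] <- tb$alt_count
      gbs_counts(ref, alt)
    },
    vcf_ad = .read_vcf_ad(path))
}

.read_vcf_ad <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF allelic depths requires the VariantAnnotation package",
         call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF has no per-sample AD field", call. = FALSE)
  n_alt <- lengths(VariantAnnotation::alt(vcf))
  biallelic <- n_alt == 1
  if (any(!biallelic)) {
    message(sum(!biallelic), " multiallelic record(s) skipped")
  }
  ad <- ad[biallelic, , drop = FALSE]
  take <- function(slot) {
    m <- apply(ad, c(1, 2), function(v) {
      v <- v[[1]]
      if (length(v) < 2 || anyNA(v)) 0L else as.integer(v[slot])
    })
    t(m)  # VCF is SNPs x samples; we use individuals x SNPs
  }
  gbs_counts(take(1), take(2))
}

#' Write GBS allele counts
#'
#' Inverse of [read_counts()] for the `wide` and `long` layouts.
#'
#' @param counts A [gbs_counts] object.
#' @param path Output path(s): length 2 (ref, alt) for `wide`, length 1 for
#'   `long`.
#' @param format `"wide"` or `"long"` (long omits depth-0 cells).
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path, format = c("wide", "long")) {
  format <- match.arg(format)
  stopifnot(inherits(counts, "gbs_counts"))
  if (format == "wide") {
    if (length(path) != 2) stop("wide format needs c(ref_path, alt_path)", call. = FALSE)
    for (i in 1:2) {
      m <- if (i == 1) counts$ref else counts$alt
      df <- data.frame(individual = rownames(m), m, check.names = FALSE)
      utils::write.table(df, path[i], sep = .sep_for(path[i]),
                         row.names = FALSE, quote = FALSE)
    }
  } else {
    depth <- counts$ref + counts$alt
    idx <- which(depth > 0, arr.ind = TRUE)
    df <- data.frame(individual = rownames(depth)[idx[, 1]],
                     snp = colnames(depth)[idx[, 2]],
                     ref_count = counts$ref[idx], alt_count = counts$alt[idx])
    df <- df[order(match(df$individual, rownames(depth)),
                   match(df$snp, colnames(depth))), ]
    utils::write.table(df, path, sep = .sep_for(path), row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

# full-precision decimal rendering so long_tsv round-trips bit-exactly
.num17 <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write a relatedness matrix
#'
#' `square_csv`: ids in the header row and first column, values at full
#' precision, missing cells empty.  `long_tsv`: columns `id1`, `id2`,
#' `method`, `n_snps_used`, `relatedness` over the lower triangle including
#' the diagonal; round-trips bit-exactly.
#'
#' @param grm A `gbs_grm` object.
#' @param path Output file.
#' @param format `"square_csv"` or `"long_tsv"`.
#' @return Invisibly, `path`.
#' @export
write_grm <- function(grm, path, format = c("square_csv", "long_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(grm, "gbs_grm"))
  G <- grm$G; ids <- rownames(G)
  if (format == "square_csv") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste(c("id", ids), collapse = ","), con)
    for (i in seq_along(ids)) {
      writeLines(paste(c(ids[i], .num17(G[i, ])), collapse = ","), con)
    }
  } else {
    idx <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
    n_used <- if (is.null(grm$n_snps_used)) NA_integer_ else grm$n_snps_used[idx]
    df <- data.frame(id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
                     method = grm$method, n_snps_used = n_used,
                     relatedness = .num17(G[idx]))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a relatedness matrix written by [write_grm()]
#'
#' @param path Input file.
#' @param format `"square_csv"` or `"long_tsv"`.
#' @param method For `square_csv` (which does not store it), the method
#'   label to attach.
#' @return A `gbs_grm` object.  `diagonal_valid` is set from the method
#'   (`FALSE` for G3/G4).
#' @export
read_grm <- function(path, format = c("square_csv", "long_tsv"),
                     method = "G5") {
  format <- match.arg(format)
  if (format == "square_csv") {
    tb <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tb[[1]])
    G <- as.matrix(tb[, -1, drop = FALSE])
    storage.mode(G) <- "double"
    dimnames(G) <- list(ids, ids)
    n_used <- NULL
  } else {
    tb <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c(id1 = "character", id2 = "character"))
    method <- tb$method[1]
    ids <- unique(c(tb$id1, tb$id2))
    G <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    i1 <- match(tb$id1, ids); i2 <- match(tb$id2, ids)
    G[cbind(i1, i2)] <- tb$relatedness
    G[cbind(i2, i1)] <- tb$relatedness
    n_used <- NULL
    if (!all(is.na(tb$n_snps_used))) {
      n_used <- matrix(NA_real_, length(ids), length(ids),
                       dimnames = list(ids, ids))
      n_used[cbind(i1, i2)] <- tb$n_snps_used
      n_used[cbind(i2, i1)] <- tb$n_snps_used
    }
  }
  structure(list(G = G, method = method,
                 diagonal_valid = !(method %in% c("G3", "G4")),
                 n_snps_used = n_used), class = "gbs_grm")
}

#' Read a pedigree file
#'
#' CSV/TSV with columns `id`, `sire`, `dam`; empty fields mean unknown
#' parent.
#'
#' @param path Input file.
#' @return Data frame (`id`, `sire`, `dam`) with `NA` for unknown parents.
#' @export
read_pedigree <- function(path) {
  tb <- .read_table(path, .sep_for(path))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(tb))) {
    stop("pedigree needs columns id, sire, dam", call. = FALSE)
  }
  for (col in need) {
    tb[[col]] <- as.character(tb[[col]])
    tb[[col]][tb[[col]] == ""] <- NA_character_
  }
  if (anyDuplicated(tb$id)) stop("duplicate pedigree ids", call. = FALSE)
  tb[, c("id", "sire", "dam")]
}
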