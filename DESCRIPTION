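Package: gbsrelate
Title: Depth-Adjusted Genomic Relatedness from Genotyping-by-Sequencing
    Allele Counts
Version: 0.1.0
Authors@R:
    person("gbsrelate", "developers", email = "gbsrelate@example.org",
           role = c("aut", "cre"))
Description: Method-of-moments estimation of genomic relatedness (kinship)
    matrices from genotyping-by-sequencing (GBS) reference/alternate allele
    read counts, including very low and zero read depths.  Off-diagonal
    relatedness is estimated from SNPs co-called in both individuals and the
    diagonal (self-relatedness, 1 + F) is corrected for the per-observation
    probability 1/2^k that a heterozygote is read as a homozygote at depth k.
    Includes a pedigreed GBS read simulator (Poisson depths, random allele
    reads), Hardy-Weinberg disequilibrium 'fin plot' diagnostics and SNP
    filters, pedigree parentage verification, and readers/writers for count
    matrices, VCF allelic depths and relatedness matrices, plus a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite
Config/testthat/edition: 3
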