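---
title: "Depth-adjusted relatedness estimation from GBS allele counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-adjusted relatedness estimation from GBS allele counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsrelate)
```

## The model

A biallelic SNP with reference allele A (frequency $p$) and alternate
allele B is sequenced to depth $k$ in one individual.  Reads are assumed to
be drawn at random, without error, from the individual's two allele copies.
A true homozygote is therefore always observed correctly, while a true
heterozygote is observed as a specific homozygote with probability
$K = 1/2^k$ and as a heterozygote with probability $1 - 2K$.  At $k = 1$,
$K = 1/2$: a heterozygote is always miscalled.  At $k = \infty$, $K = 0$.
Depth 0 means the genotype is missing; depth 0 in the count matrices is the
single representation of missingness everywhere in this package.

For an individual with inbreeding coefficient $F$ the observed genotype
probabilities are

$$P(\mathrm{AA}^*) = p^2 + p(1-p)F + 2p(1-p)(1-F)K,$$
$$P(\mathrm{AB}^*) = 2p(1-p)(1-F)(1-2K),$$
$$P(\mathrm{BB}^*) = (1-p)^2 + p(1-p)F + 2p(1-p)(1-F)K.$$

Writing $x$ for the observed score (number of A alleles: 0, 1, 2) and
$S_{ii'} = (x_i - 2p)(x_{i'} - 2p)$, the two moment identities that drive
everything are

$$E(S_{ii'}) = 4p(1-p)\,\theta_{ii'} \qquad\text{(two individuals)},$$
$$E(S_{ii}) = 2p(1-p)\,(1 + F_i + 2K_i - 2F_iK_i) \qquad\text{(self)}.$$

The pair expectation does not involve $K$: relatedness between two
individuals can be estimated without bias at *any* depth, provided each SNP
only enters a pair's estimate when it is called in both individuals.  The
self expectation does involve $K$, interpolating between $2p(1-p)(1+F)$ at
infinite depth and $4p(1-p)$ at depth 1 — at depth 1 the observation
carries no information about $F$ at all, which is why depth-1 SNPs are
excluded from the diagonal correction (and why a sampled-allele estimator
can never estimate inbreeding).

## The estimators

`compute_G1` is the classical GRM $\mathbf{G}_1 = \mathbf{ZZ}'/\,
2\sum_j p_j(1-p_j)$ with missing centred scores set to 0 (naive mean
imputation) and one shared denominator.  It is the baseline: at low depth
its diagonal is inflated by miscalled heterozygotes and its off-diagonals
are shrunk because the denominator counts SNPs that never contributed to
the numerator.

`compute_G4` keeps the zeroed numerator but divides element-wise by
$2\,\mathbf{P}_0\mathbf{P}_1'$, where $\mathbf{P}_0$ ($\mathbf{P}_1$) holds
$p_j$ ($1-p_j$) zeroed at missing cells, so each cell's denominator sums
over exactly the co-called SNPs.  Off-diagonals are unbiased at any depth;
the diagonal is still depth-inflated and flagged `diagonal_valid = FALSE`.
A `block_rows` argument computes the denominator in row blocks when the
dense $n \times m$ intermediates would not fit in memory.

`adjust_diagonal` (or the wrapper `compute_G5`) replaces diagonal $i$ by

$$\sum_{j}\frac{S_{iij} - 8p_j(1-p_j)K_{ij}}{1-2K_{ij}} \Big/\,
 2\sum_{j} p_j(1-p_j),$$

both sums over SNPs called in individual $i$ with depth $\ge 2$.  Each term
has expectation $2p_j(1-p_j)(1+F_i)$ for every admissible $K < 1/2$ (an
algebraic identity the unit tests verify to machine precision on a
$(p, F, K)$ grid), so the diagonal estimates $1 + F_i$ without depth bias.
G5 off-diagonals are copied bit-for-bit from G4.

`compute_G3` discards all but one read per cell (sampled-allele estimator,
the $k = 1$, $K = 1/2$ model) and combines the resulting 0/2 scores with
the per-pair denominators.  It is more robust to read-clustering model
violations but strictly noisier; its diagonal is ignored.

### Numerical and design choices

- **Index set of the G5 sums.** The source formulation writes both sums
  without explicit index sets (and its prose condition on $K$ contains an
  evident sign typo: $K = 1/2^k \le 1/2$ always, and the stated motivation —
  a zero denominator at $K = 1/2$ — forces the exclusion of depth-1
  observations).  We sum numerator *and* denominator over the same
  depth-$\ge 2$ SNP set, by the same argument that motivates the per-pair
  denominators of G4: a denominator must only count SNPs whose terms are in
  the numerator.  The alternative reading (denominator over all SNPs called
  in the individual) is available via `denominator = "all"`; with complete
  depth-$\ge 2$ data the two coincide.
- **$K$ from total depth.** $K$ is computed as $1/2^k$ from the cell's
  total read count.  Depths are capped at 64 before exponentiation; beyond
  that $K$ is below double precision anyway.  Models with "clustered"
  allele reads would change $K(k)$ for $k \ge 2$ but not the pair
  estimators, which is why only the random-reads form is implemented.
- **No clipping.** Single-SNP estimates of $2\theta$ and $F$ routinely fall
  outside $[0, 1]$; clipping would destroy the method-of-moments
  unbiasedness, so nothing is clipped anywhere.
- **Missing cells stay missing.** Pairs with zero co-called SNPs get `NA`
  (with a warning), never 0 — imputing would silently reintroduce the bias
  the construction removes.  Likewise individuals with no depth-$\ge 2$
  SNPs get an `NA` diagonal.
- **No PSD repair.** The per-pair denominators do not guarantee a positive
  semi-definite matrix.  No repair is applied; `grm_eigen_report` tells you
  how far from PSD a result is so downstream users (e.g. GBLUP) can decide.
- **Allele frequencies.** By default $p_j$ is estimated from the pooled
  read counts (every read weighted equally), and re-estimated after any SNP
  filtering.  Externally supplied frequencies are accepted via
  `allele_freqs()`; monomorphic SNPs are always excluded before estimation.

## The simulator and what a green test establishes

`sim_gbs_panel` generates the stated world used throughout testing: 100
sire-dam pairs of unrelated, non-inbred founders and two full-sib offspring
per pair (400 individuals); 10,000 unlinked SNPs with frequencies drawn
Uniform(0, 1); founder alleles i.i.d. Bernoulli($p_j$); each offspring
inherits one uniformly chosen allele per parent, independently per SNP;
per-cell depths Poisson($d$); reads drawn with replacement from the
individual's two alleles; SNPs monomorphic in the genotypes or in the reads
removed.  Defaults mirror that design exactly; the three experiment drivers
vary depth (1, 2, 8), hold total effort at 10,000 reads while sweeping
depth 0.25–20 over 500–40,000 SNPs (frequencies Uniform(0.1, 0.5) so no
SNP is lost), and sweep a common allele frequency against panel size at
depth 2.  One user seed is split into independent per-stage streams so any
stage can be reproduced in isolation; runs are bit-reproducible given
(seed, configuration).  The default replicate count is 1, matching the
single-run design of the experiments the package reproduces.

What the simulator does *not* emulate: linkage (SNPs are independent, so
realised relatedness has almost no variation around its pedigree
expectation), sequencing error, allele-read clustering, multi-generation
pedigrees, and real site-frequency spectra.  A green parameter-recovery
test therefore establishes correctness of the estimators *under the model's
own assumptions* — it says nothing about robustness to error or
non-Mendelian inheritance, which is exactly the gap the QC tooling below
addresses on real data.

### Finite-panel attenuation with in-sample frequencies

The unbiasedness results are derived for *known* allele frequencies.  When
$p$ is estimated from the same panel, centring at $2\hat p$ attenuates a
pair's expected estimate by approximately
$\bar r_i + \bar r_{i'} - \bar{\bar r}$, where $\bar r_i$ is individual
$i$'s mean relatedness to the panel (self included) and $\bar{\bar r}$ the
panel-wide mean.  In the default design this is at most $5/n \approx 0.0125$
and the observed full-sib mean at depth 8 is ≈ 0.4956 rather than 0.5000.
The acceptance tests therefore assert strict 3-SE unbiasedness using the
true simulated frequencies, and allow the additional, theoretically bounded
$5/n$ when frequencies are re-estimated (the default pipeline).  At very
low depth ($d \lesssim 0.5$) frequency estimates themselves are poor and
deviations grow; a `use_true_freqs` flag isolates that component, which
reduces the residual bias by one to two orders of magnitude.

## QC diagnostics

Per-SNP Hardy-Weinberg disequilibrium is `obs − p̂²`, where `obs` is the
observed frequency of the reference-allele homozygote among *called*
individuals and `p̂` the genotype-call-based frequency — with that choice
the bounds $[-\mathrm{MAF}^2,\ \mathrm{MAF} - \mathrm{MAF}^2]$ hold exactly
(the "fin" shape when plotted against MAF).  Two failure modes live on the
two edges: SNPs called mostly at depth 1 appear maximally homozygous (upper
edge), and SNPs from collapsed genome duplications with a fixed difference
between copies appear maximally heterozygous with roughly doubled depth
(lower edge).  The latter violate diploid Mendelian inheritance and drag
the G5 diagonal into a spurious dependence on sample depth;
`self_relatedness_depth_check` regresses `diag(G5)` on log mean depth to
detect this, and `apply_filters` with the default `hw_dis_min = -0.05`
(chosen empirically in the source study; −0.10 performed only marginally
worse) removes it.  Filters are conjunctive, so the kept set is
order-independent; the removal report attributes each SNP to the first
failing criterion in the order call rate, MAF-min, MAF-max, HW.  The
reference-allele orientation of the disequilibrium statistic follows the
input's reference designation; MAF is always folded.  No significance test
is attached to the disequilibrium — filtering is on the raw statistic.

`verify_parentage` flags recorded offspring whose estimated relatedness to
a recorded parent falls below a threshold (default 0.25, halfway between
the expected 0.5 of a true parent-offspring pair and the ~0 of an unrelated
one); the threshold is configurable, not hard-coded.

## Known limitations

- Strictly biallelic; multiallelic VCF records are skipped, not decomposed.
- Sequencing error is not modelled: a single stray read turns a homozygote
  into an apparent heterozygote.  Low-MAF filtering upstream mitigates
  this.
- Allele-frequency estimation weights reads, not individuals; with very
  unequal depths a depth-aware weighting might do better.
- Relatedness is estimated marker-by-marker with no linkage information;
  the estimators target IBS-based expectations of pedigree relatedness.
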