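---
title: "Analysing chromatin reorganization between two cellular states"
author: "tadir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing chromatin reorganization between two cellular states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadir)
```

# Scope and data model

`tadir` starts where alignment pipelines stop: from deduplicated,
quality-filtered Hi-C *valid pairs* in the text `.pairs` convention
(readID, chrom1, pos1, chrom2, pos2, strand1, strand2; 1-based
positions). Alignment, chimeric-read rescue, duplicate marking and
mapping-quality filters are deliberately out of scope. Internally all
bins are 0-based half-open, and every exported interval follows the BED
convention. Strands are parsed and carried but enter no statistic — all
analyses implemented here are strand-free.

Three resolutions appear throughout, following common practice for
in situ Hi-C libraries of modest depth: **500 kb** for genome-level
visualization and replicate QC, **40 kb** for domain calling, and
**5 kb** for differential bin-pair testing.

# Read classification and QC

A pair is *trans* when its ends map to different chromosomes, *self*
when it maps to one chromosome with separation below a cutoff, and
*cis* otherwise. Hi-C libraries contain a large fraction of
self-ligation and re-ligation products that carry no spatial
information; in practice these dominate short separations, and
typical libraries show roughly 40–60% self, 20–30% cis and 10–20%
trans pairs among uniquely mapped reads. The separation cutoff
defaults to **20 kb**. There is no universally agreed definition of
the "self" category (same fragment, same bin, or a separation
threshold are all in circulation); a pure separation cutoff was chosen
because it is reproducible on data that no longer carries fragment
annotations, and because it makes the synthetic generator's
classification exactly invertible. The cutoff is a parameter
everywhere it is used.

Replicate agreement is summarized by the Pearson correlation of
`log2(count + 1)` over 500 kb bin pairs where at least one replicate is
non-zero, computed on raw (unbalanced) counts. The log transform is a
choice: correlations on raw counts are dominated by the near-diagonal
heavy tail, and the literature rarely states which transform produced a
reported correlation. Raw versus balanced input matters little at this
resolution; raw is the default because balancing weights are themselves
replicate-dependent.

# Matrix balancing

`ice_normalize()` implements iterative correction under the standard
multiplicative-bias model `E[counts[i,j]] = t_ij · b_i · b_j`: each pass
divides the working matrix by the outer product of the square roots of
its mean-normalized row sums, accumulating per-bin weights, until the
coefficient of variation of non-masked row sums falls below `tol`
(default 1e-5, capped at 200 iterations; non-convergence is flagged on
the result rather than silently returned). All-zero rows are masked and
receive `NA` weights. On matrices generated with planted log-normal
biases the weights recover the biases up to a global scale factor.

# TAD calling

## Directionality index

For bin *i* with upstream contact sum *A* (bins in `(i−w, i)`),
downstream sum *B* (bins in `(i, i+w)`) and `E = (A+B)/2`:

$$\mathrm{DI}_i = \mathrm{sign}(B-A)\left(\frac{(A-E)^2}{E} +
  \frac{(B-E)^2}{E}\right)$$

with DI = 0 when `A = B`, a masked value when `A + B = 0`, and windows
truncated at chromosome ends. Defaults are 40 kb bins and a 2 Mb
window on each side — the classical parameterization for domain calling
at this scale. DI is computed on raw counts by default; the caller may
pass a balanced matrix instead, and which one a given study used is
often unstated, so the choice is recorded with the track. An exact
property used in testing: reversing the bin order of a chromosome
reverses and sign-flips the DI track.

## Bias states and domain inference

The genome-wide DI track is modelled with a 3-state hidden Markov model
with a **single Gaussian emission per state**, trained by
Baum–Welch on all chromosomes jointly (masked bins split the track
into independent training sequences) and decoded with Viterbi. The
single-Gaussian emission is a deliberate simplification of the
mixture emissions used by the original domain-calling literature:
the downstream rule consumes only the run structure of the three
states, which well-separated Gaussians capture; the recovery tests in
`tests/testthat/` quantify exactly what this simplification achieves on
synthetic tracks (≥ 98% state recovery at ±5σ separation, ≥ 80%
boundary recovery end-to-end). States are relabeled after fitting so
that the highest emission mean is downstream-biased and the lowest
upstream-biased, making the procedure invariant to EM label switching.
A constant DI track short-circuits to all no-bias states, and an EM
step that decreases the log-likelihood raises an error carrying the
last iterate.

A domain opens at the first bin of a run of at least *k*
downstream-biased states and closes at the end of the next run of at
least *k* upstream-biased states; intervening no-bias bins are
interior, and unpaired runs yield nothing. *k* = 2 interprets
"consecutive" minimally and is exposed as a parameter. By
construction the output is sorted, non-overlapping and cannot cross
chromosome ends.

## Overlap statistics

`max_overlap_pairs()` finds, for every domain of one set, the maximally
overlapping domain of the other, with deterministic tie-breaking
(larger fraction of the partner covered, then leftmost partner), flags
reciprocal pairs, and reports counts of overlapped and reciprocal
domains. Any positive overlap counts as "overlapped" — no minimum
fraction is imposed, since none is standard. The 2-D histogram of
reciprocal overlap fractions over `[0,1]²` is the conventional summary:
conserved architecture concentrates mass near (1, 1).

# Differential interactions

The differential pipeline is a self-contained re-implementation of the
negative-binomial quasi-likelihood approach for Hi-C bin pairs; it
reproduces the statistical skeleton (abundance filter, MA-plot loess
offsets, QL F-test, BH selection) without depending on the packages
that popularized it, and its acceptance is through error-rate
properties on planted truth rather than value-matching any specific
implementation.

* **Filter.** `logCPM = log2((y + 0.5)/(N + 1) · 10⁶)` with prior count
  0.5 and library size + 1 (stated exactly so the filter is testable in
  closed form); a bin pair is kept when its sample-mean logCPM exceeds
  0.
* **Offsets.** Per sample, the deviation `M = logCPM − logCPM_ref`
  (reference = row mean across samples) is smoothed against abundance
  `A` by a robust local-quadratic loess (span 0.3, symmetric family),
  followed by a second pass that excludes rows with residuals beyond
  2 MAD and refits. The second pass matters: genuinely differential
  rows otherwise drag the trend and bias the surrounding null rows,
  inflating the false discovery rate when changes are predominantly
  one-directional. Offsets are reported on the log2 count scale and
  include each sample's depth relative to the geometric-mean library
  size.
* **Dispersion.** Per-row moment estimates
  `(s² − m)/m²` (pooled within-condition variance against the grand
  mean) are smoothed into an abundance trend by a running median in
  average-logCPM order. Because a pooled variance on `df` degrees of
  freedom is chi-square, its median sits at `qchisq(0.5, df)/df` of its
  mean; the trend inverts this relation so it is median-unbiased for
  the true dispersion. With two replicates per condition the raw
  per-row values are individually almost uninformative, so the final
  per-row dispersion defaults to the trend alone (`shrink_weight = 1`);
  the mixing weight is exposed for designs with more replicates.
* **Test.** Per bin pair, a negative-binomial log-linear model with a
  condition effect and the per-cell offsets is fitted by Fisher scoring
  at the trended dispersion. Significance comes from a deviance-ratio
  quasi-likelihood F-statistic: the residual deviance over its
  replication degrees of freedom is moderated across rows by
  empirical-Bayes variance squeezing, and the drop in deviance between
  the common-mean and per-condition fits is divided by the moderated
  quasi-dispersion, with F degrees of freedom `(1, df_resid +
  df_prior)`. Rows with non-finite fits are flagged and forced to
  `p = 1`.
* **Selection.** Benjamini–Hochberg over all tested pairs; `q < 0.05`
  pairs become DIRs, labelled *up* when the log2 fold change is
  positive in the second condition level. The direction convention
  treats the differentiated state as the second level, so "up" means
  enriched after differentiation. Only intra-chromosomal pairs are
  tested.
* **Gene association.** A gene is associated with a DIR when its
  interval, padded by `pad` bp (default 0), overlaps or touches either
  5 kb anchor. The padded interval is treated as closed, so a gene
  exactly `pad` bp from an anchor still associates.

Under the simulation conditions used for validation (≈5000 bin pairs,
NB dispersion 0.05, two replicates per condition, 250 planted 4-fold
pairs at baseline mean ≈50), the pipeline's measured operating point is
a mean false discovery proportion of ≈0.06 at the nominal 0.05
threshold with sensitivity ≈0.95 (see `scripts/acceptance.R` and
`tests/testthat/test-acceptance.R`, which recompute both numbers from
scratch). The small excess over the nominal level reflects the
chi-square approximation of the deviance ratio at four observations per
row and residual trend-estimation noise.

# Promoter–promoter coherence

Published promoter-interactome analyses rarely document their
interaction-calling rule in enough detail to re-derive; the rule here
is an explicit design choice, kept simple and config-exposed. Candidate
pairs are bin pairs at least 2 bins apart whose anchors each contain at
least one promoter (default window ± 2 kb around the TSS, clipped to
chromosome bounds); the observed count is compared with the matrix-wide
mean count at that separation (the empirical distance-decay
expectation) by an upper-tail Poisson test, `P(X ≥ obs | λ = exp)`,
with BH control over candidates and expansion of significant bin pairs
to all gene-level combinations.

Coherence classification uses the thresholds FPKM < 1 (suppressed) and
FPKM > 2 (activated); a pair is **G1** when both genes are suppressed,
**G2** when both are activated, **incoherent** when the two genes sit on
opposite sides, and **intermediate** otherwise. The `[1, 2]` gap is kept
as an explicit intermediate class rather than forced into either group;
where different threshold variants circulate (an activated threshold of
1 is sometimes quoted), the explicitly stated Results-level values
(1 and 2) are used. Pair identity across conditions is the unordered
gene-id pair, not bin coordinates, so transition tables count the same
biological pair even when promoters move between bins at the analysis
resolution.

Enrichment of coherent status is tested by permuting the gene→FPKM
assignment genome-wide (`p = (1 + #{null ≥ obs})/(1 + n_perm)`), which
preserves the interaction graph and the marginal expression
distribution while breaking their association. Expression shifts
between transition classes (e.g. genes of pairs moving G1→G2 versus
staying G1→G1) use a two-sided Mann–Whitney test — exact for combined
n ≤ 20 without ties, normal approximation with tie correction
otherwise. Whether the post-differentiation FPKM or the FPKM change is
compared is flag-selectable; the default is the post-differentiation
value.

# The synthetic generator

The generator exists to make every pipeline stage testable against
known truth. For cis bins `i ≤ j` the expected count is

$$E[i,j] = s\,(|i-j|+1)^{-\alpha}\,(1 + \beta\,
  \mathbf{1}[i,j \text{ same TAD}])\; b_i b_j$$

with counts drawn negative-binomially (`variance = mean + φ·mean²`;
Poisson at φ = 0). Planted TAD sizes follow an exponential law with a
floor, rounded to bins — a one-parameter law giving realistically
variable domains. Bin biases default to 1, with log-normal biases
available so ICE can be tested for parameter recovery. Pairs files add
self reads (separation below the cutoff) and uniform trans reads around
the cis reads implied by a contact matrix, making read classification
invertible; requested composition is met up to rounding. Expression
tables draw suppressed genes from `uniform(0, 0.9)` and activated genes
from `2 + lognormal(1, 0.5)` — cleanly separated from the 1 and 2
thresholds with a dead zone in `[1, 2]` — so planted coherence groups
classify back exactly.

Default study conditions used by the tests and the acceptance script:

* TAD recovery: one 20 Mb chromosome at 40 kb bins, mean domain size
  880 kb (floor 200 kb), depth `s = 100`, decay `α = 1`, enrichment
  `β = 2`, dispersion `φ = 0.05` — giving an in-TAD mean bin-pair count
  above 10. Domain sizes around 0.9 Mb mirror what genome-wide human
  TAD catalogues typically average.
* Differential testing: one 1.3 Mb chromosome at 5 kb bins with anchor
  separations up to 20 bins (≈5000 pairs), log-normal bin biases
  (sdlog 0.4) so abundance varies continuously across pairs, depth
  chosen to put baseline means near 50, `φ = 0.05`, 250 planted 4-fold
  pairs, two replicates per condition with matched depths.
* Read composition: 50% self, 35% cis, 15% trans.

Real library depths vary widely between experiments; the defaults
above are chosen for desk-scale runtime at full statistical validity,
not for fidelity to any particular library, and all of them are
ordinary function arguments.

What the generator does **not** emulate: restriction-fragment
structure, read-level sequences, interchromosomal structure beyond
uniform noise, copy-number or mappability artefacts, and the
band-matrix correlation structure real Hi-C matrices inherit from
polymer behaviour. Passing tests on synthetic data therefore
demonstrate correctness of the implemented statistics under the stated
model, not robustness to every artefact of real libraries.

# Numerical choices and degenerate inputs

* ICE: tolerance 1e-5 on the row-sum coefficient of variation,
  maximum 200 iterations, all-zero matrices return fully masked
  weights without iterating.
* HMM: emission standard deviations floored at 1e-3 of the data SD;
  EM stops on a relative log-likelihood change below 1e-6; sequences
  shorter than 2 bins inform decoding but not training.
* GLM fitting: Fisher scoring with step clamping at ±5 on the log
  scale; empty groups are driven to the small-mean boundary and
  flagged rather than erroring.
* Mann–Whitney: all-tied inputs return `p = 1` with the midpoint
  statistic.
* Loess offsets: constant deviations bypass the smoother; smoother
  failure falls back to a constant median-M offset with a warning.
* Ties in maximal overlap are broken deterministically (partner
  fraction, then leftmost), making every reported table reproducible.

# Known limitations

* The promoter-pair caller conditions on the empirical distance-decay
  of the same matrix it tests, which is slightly conservative for
  matrices dominated by enriched structure.
* The QL F-test is mildly anti-conservative at two replicates per
  condition (measured ≈0.06 empirical FDR at the 0.05 target under the
  validation conditions); with more replicates the deviance
  approximation sharpens.
* TAD calling reports a single non-overlapping segmentation; nested or
  hierarchical domains, insulation-score or corner-score callers, and
  A/B compartment analysis are out of scope.
* Only intra-chromosomal structure is modelled and tested;
  interchromosomal matrices are not constructed.

# Session info

```{r}
sessionInfo()
```
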