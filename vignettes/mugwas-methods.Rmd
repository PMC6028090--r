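---
title: "u-statistics for genetically structured GWAS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{u-statistics for genetically structured GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-SNP case/control GWAS ("ssGWAS") scores each variant under a fixed
genetic model — usually additive allele dosage — and tests it in isolation.
Both choices are assumptions of convenience: real loci are rarely exactly
additive, and risk at a locus often depends on the joint configuration of
several nearby variants on the same haplotype (cis-epistasis, of which
compound heterozygosity is the textbook case: one disabled copy from each
parent, at two different sites of the same gene). A misspecified model costs
power for true effects and, across millions of tests, occasionally
manufactures extreme statistics for null ones.

`mugwas` implements an association scan that replaces both assumptions with
weaker, ordinal ones:

* **heterodominance** — a SNP's effect is taken to be merely *monotonic* in
  minor-allele count (aa ≤ aA ≤ AA), never forced to be recessive, additive,
  or dominant;
* **diplotype windows** — neighboring SNPs within an LD block are combined
  into a joint ordinal feature ("diplotype", unphased) rather than tested
  independently or summed.

## Pairwise orderings and the Λ operator

All information is carried by *n × n pairwise ordering matrices*: for
subjects *i*, *j*, a cell states whether *i* carries lower (`<`), equal
(`=`), or higher (`>`) genetic risk than *j*, or whether the comparison is
undecided (`?`, e.g. missing genotypes). For one SNP with polarity +1
(minor allele treated as the risk allele) the matrix is just the monotonic
comparison of dosages.

Orderings of neighboring SNPs are combined with a logical AND, `lambda2()`:
agreement or partial information propagates (`<` with `=` or `?` stays
`<`), conflict cancels (`<` with `>` becomes `?`). A window of SNPs is
aggregated by first forming the consecutive-pair matrices
I(k, k+1) = Λ(S(k), S(k+1)) — a disease locus should be in LD with *both*
its neighbors, so it is adjacent pairs that carry the signal — and then
combining the I's element-wise with the multiset extension
`lambda_multi()`: undecided if both directions occur, otherwise the
direction present, otherwise `=` if present, otherwise undecided.

Two remarks on that rule. First, folding `lambda2()` sequentially is *not*
associative (Λ(Λ(<,>),=) = `=` but Λ(<,Λ(>,=)) = `?`): an interleaved `=`
can mask a conflict. The multiset rule is the unique permutation-invariant
resolution, and the package defines the aggregation by it. Second, because
pairing precedes aggregation, the same set of tag SNPs arranged differently
yields different matrices — window enumeration over all offsets therefore
adds resolution rather than redundancy.

Diagonal cells are `=` by convention and excluded from all counts;
self-comparisons carry no information.

## u-scores, the score test, and polarity regularization

From a window's ordering matrix W, each subject's u-score is the number of
subjects with lower risk minus the number with higher risk (oriented so
higher score = higher risk; the opposite orientation only flips the sign of
the statistic). The scores sum to zero by antisymmetry. The test statistic
is T = Σ u over cases; under the permutation null of drawing the m cases
from n subjects without replacement,

  Var(T) = m(n−m) / (n(n−1)) · Σᵢ uᵢ²,

and Z = T/√Var(T) is referred to the standard normal (two-sided). An exact
enumeration over all case/control relabelings is available for n ≤ 20. No
continuity correction is applied in the normal path: at study sizes the
correction is negligible, and at nominal thresholds it would make the scan
conservative; the vanishing-variance case (monomorphic window) is flagged
`non_informative` with p = 1. p-values are floored at the smallest positive
double and flagged when floored.

Since it is unknown a priori whether a minor allele is deleterious,
irrelevant, or protective, the scan applies every polarity vector over
{−1, 0, +1} to each window (zero drops the SNP; a global sign flip only
transposes W, so those duplicates are skipped). This enumeration creates
many highly dependent candidates per center SNP, and the most significant
one is *not* automatically the best: a candidate can reach a small p-value
on a small, unusual subset of decidable pairs. The package scores each
candidate by the pair (s = −log₁₀ p, µIC), where the information content
µIC is the fraction of subject pairs whose ordering is decided, and selects
the candidate with the highest bivariate dominance score: the number of
candidates it weakly dominates on both axes minus the number that weakly
dominate it. Ties break to higher µIC, then shorter window, then the
lexicographically smallest polarity. This regularizes without any tuned
cutoff. The selection inflates the per-center null distribution relative to
a single test — measured at roughly 6–7× the nominal 0.05 rejection rate
under the default study conditions — which is deliberately left
uncorrected: the study-wide threshold below absorbs it.

## Adaptive genome-wide significance (aGWS)

Because allele counts are bounded, the best attainable p-value of a SNP
depends on its MAF; a chromosome's null quantile-rank (QR) curve — sorted
s-values against normalized rank (i − 0.5)/N — is therefore a *convex*
curve, a mixture over MAF strata, not the straight line of classical QQ
intuition. Chromosomes that carry true association (or systematic
differences between non-randomized cohorts) bend concave at the top and
throw outliers above any convex fit.

`agws_cutoff()` fits, per chromosome, a non-decreasing convex function by
least squares (a piecewise-linear hinge basis with non-negative slope
increments, solved as NNLS — the solution coincides with the
shape-constrained QP projection when knots are placed at the data), with
the top 1% of ranks excluded from the fit and covered by linear
continuation of the last segment (the "projection"). The half of
chromosomes with the fewest points rising more than `tol` (default 0.5
s-units) above their fit is taken as the null reference — ties break to
the smaller apex — and the adaptive cutoff is the median of their apexes
(fitted value at the top rank). Half that cutoff, aGWS/2, is the threshold
for calling a result in an independent cohort "supportive" in
`replication_check()`, which reports same-SNP, same-gene (user-supplied
BED intervals), and flanking-window tiers.

Parameters with no principled default are exposed and logged: trim
fraction (0.01), outlier tolerance (0.5), minimum results per chromosome
(10). With fewer than four usable chromosomes the estimate is refused
rather than extrapolated.

## QC ahead of the scan

`filter_snps()` removes SNPs with sample MAF below 0.01 or call rate below
0.9 (both logged, both configurable); `prune_adjacent_ld()` drops SNPs
whose dosage r² with the previously retained neighbor exceeds 0.95 —
near-duplicate neighbors add candidates without adding information.
`insert_block_spacers()` places `max_window − 1` all-missing spacer SNPs
between LD blocks so no window spans a recombination hotspot; spacers are
never tested and never contribute. Block boundaries are user-supplied
(BED); the package does not infer them. Windows are also clipped at
chromosome ends. The minor allele is defined per dataset by sample
frequency with deterministic tie-breaks (ALT for VCF, second-listed allele
for PLINK text, the coded allele for TSV).

## The synthetic cohort generator

`generate_cohort()` emulates the data structure the method is built for,
not any particular population:

* **LD blocks** — per block, a pool of H = 12 haplotypes from a star
  genealogy (an all-major ancestral haplotype; each SNP's minor allele
  placed on `round(maf·H)` random pool members, maf ~ Uniform(0.05, 0.5)).
  Each subject draws two pool haplotypes per block, independently across
  blocks: within-block LD, between-block independence. A dozen common
  haplotypes per block is typical of real chip data; smaller pools give
  stronger LD.
* **Study conditions** — defaults are 500 cases / 500 controls, 100 blocks
  × 10 SNPs = 1,000 SNPs on 10 chromosomes, 0.5% missing calls (post-QC
  chip quality), penetrance 0.3 for carriers vs 0.1 for non-carriers when
  a risk locus is implanted.
* **Risk models** — monotonic single-locus models (dominant, recessive,
  additive) and two-SNP cis models within one block: `compound_het`
  (minor allele present at both targets — the unphased proxy for one
  disabled copy from each parent) and `cis_epistatic_and` (minor at A and
  major present at B). Case/control status is drawn by penetrance and
  sampled to exact quotas; the truth record suffices to recompute carrier
  status exactly.

What the generator does *not* emulate: population structure and admixture,
realistic recombination maps or coalescent genealogies, genotyping batch
effects, phased compound heterozygosity (the unphased proxy is used
because the pipeline consumes unphased genotypes). Tests passing on these
cohorts show the machinery is correct and calibrated under the stated
conditions; they do not show robustness to stratification, which is
explicitly out of scope.

## Numerical and design choices

* The scan collapses subjects to genotype-profile classes per retained SNP
  set (the ordering of a pair depends only on the two profiles), groups
  candidates that share a retained set and sign pattern, and memoizes the
  Λ-chain per distinct comparison signature; the compiled core makes the
  full enumeration (≈ 3,000 candidates per center at `max_window = 6`)
  practical on one core (~30 s for 1,000 subjects × 1,000 SNPs). An
  explicit ordering-matrix route in R defines the reference semantics and
  the two are tested against each other exactly.
* `max_window` defaults to 6 SNPs; windows of length 1 make the windowed
  scan contain the single-SNP scan as a special case.
* Candidate p-values use `s` on the −log₁₀ scale throughout; exact ties in
  the dominance selection are resolved deterministically so results are
  byte-reproducible under a fixed configuration and seed.
* Replicate counts in the test harnesses (e.g. 19 seeds for the power
  comparison, 20 for type-I calibration, 1,000 SNPs per cohort) are the
  package's standing study sizes, chosen to give stable medians and
  binomial bands on a single core. Because the windowed scan's candidate
  set contains every single-SNP candidate, its locus s-value never falls
  below the single-SNP scan's in practice, but frequently equals it; the
  median comparison between the two scans therefore carries probability
  atoms at ties, and small replicate counts can land the median exactly on
  one.

## Worked sizes for the shipped checks

The automated checks generate all data themselves: operator tables are
verified exhaustively; u-score and antisymmetry invariants on 1,000 random
matrices; the exact permutation test against full enumeration at n ≤ 12;
trend-test similarity on 200 additively simulated SNPs at n = 1,000
(Spearman ρ ≥ 0.95); type-I calibration on 20 × 1,000 null SNPs; the
compound-heterozygote power comparison on 11 seeded cohorts of 1,000 SNPs;
convex fits against a frozen quadratic-programming oracle; and permuted-
phenotype runs demanding ~0 study-wide hits. The same quantities are
recomputed end-to-end by `scripts/acceptance.R`.

## Known limitations

* **The adaptive cutoff is an envelope estimate, not an FWER guarantee.**
  On desk-scale panels (hundreds of results per chromosome) the median
  apex of the least-outlying chromosomes sits *below* the global null
  maximum: for any trim fraction t, the linear projection caps a
  chromosome's apex near −log₁₀(t) + 1/ln 10, while the largest of
  N·n_chrom null results grows like log₁₀ of the panel size, and the
  fewest-outlier selection (ties to the smaller apex) draws the cutoff
  from the lower half of the apex distribution. Consequently a permuted-
  phenotype run on a small synthetic panel retains a handful to a few
  dozen results above aGWS rather than zero; on such panels the cutoff
  ranks loci usefully but should not be read as "nothing above this is
  noise". The shipped checks assert the zero-exceedance validation anyway
  and record the measured counts.
* No covariates, no quantitative phenotypes, no stratification correction:
  the score test conditions only on the case/control split.
* LD information enters only through immediate neighbors and user-supplied
  block boundaries; long-range LD is not modeled.
* The exact test is limited to n ≤ 20 (enumeration); beyond that the
  normal approximation is used unconditionally.
* The aGWS construction assumes enough chromosomes (≥ 4 with ≥ 10 results)
  to estimate a null envelope; small targeted panels should use a fixed
  threshold instead.
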