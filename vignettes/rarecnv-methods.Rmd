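---
title: "Methods: rare and common CNV case-control association with rarecnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare and common CNV case-control association with rarecnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecnv)
```

## The problem

Copy-number variants (CNVs) called from SNP-array intensities are noisy:
different callers disagree, short calls are unreliable, and some genomic
contexts (segmental duplications) generate artifacts wholesale. `rarecnv`
implements a complete case-control association workflow for discrete CNV
call tables produced by two independent callers (for example a hidden-Markov
caller and a mixture-model caller run on the same arrays): consensus and
quality control, frequency stratification, and association at four levels —
individual loci for common variants, genes, genome-wide burden, and gene
sets for rare variants — each with a permutation-based null that respects
the observed carrier structure. A targeted-sequencing module estimates
integer copy number from read-depth ratios, the standard orthogonal check
when an array locus looks suspicious. The package was built around a cohort
of 189 cases and 380 controls that survive quality control, and its
synthetic-data generator reproduces that cohort's statistical shape so every
stage is testable without access to genotype data.

## Coordinates and input formats

All internal coordinates are 1-based and inclusive at both ends; the length
of a call is `end - start + 1`. BED input (genes, segmental duplications,
known-CNV references, the `bed_like` call dialect) is converted at the
boundary from 0-based half-open, and converted back on writing, so
`bed_like -> internal -> bed_like` is byte-identity for well-formed rows.
Chromosome names are never rewritten and are compared string-exactly, which
keeps the package assembly-agnostic. A CNV call stores an integer copy
number different from the diploid 2; deletion versus duplication status is
always derived from the copy number, never stored, so the two can never
disagree. Malformed rows fail the whole read by default with line numbers
named — silently skipping rows would corrupt carrier counts downstream — and
a permissive flag downgrades this to skip-and-warn.

## Consensus and quality control

A primary-caller call is kept when the same sample has a secondary-caller
call of the same direction overlapping at least 10% of it. The denominator
of the overlap fraction is the primary call, and kept calls retain primary
boundaries, so downstream coordinates have a single source. Direction must
agree because a one-copy and a three-copy call at the same locus are
contradictory evidence, not confirmation. Call-level filters then require a
log-odds confidence strictly above 2, at least 5 markers, and a length
between 4 kb and 1 Mb (boundaries inclusive, mirroring the "less than"
wording of each rule). Sample-level filters remove a sample, with all its
calls, when it has more than 110 calls, more than 7.5 Mb of total CNV
length, a median copy-number variance above 2, or an LRR standard deviation
above 0.4; call counts and total lengths are recomputed from the surviving
calls, while the two array-quality metrics are input metadata. Finally,
rare calls with more than half their bases inside the union of segmental
duplication regions are removed. This last filter runs after
stratification, since it applies to the rare stratum only. The call-level
filters are pure intersections of keeps, so their order cannot change the
result; the QC report nevertheless attributes removals in cascade order.

## Regions, the maximum-stack rule, and strata

A CNV region is a connected component of the interval-overlap graph of
calls on one chromosome; merely adjacent calls (no shared base) stay
separate. The carrier frequency of a region is taken at the locus within
the region where the most *distinct samples* stack — a sample's overlapping
calls are unioned before the sweep, so no sample counts twice — divided by
the cohort size. The leftmost maximal-depth interval breaks ties, for
determinism. Regions strictly above 1% are common; a region at exactly 1%
is rare. Deletions and duplications are pooled by default when stacking; a
per-direction mode restricts region construction to one direction, because
gene-level counting conventions in the field are ambiguous on this point.

## Exact inference and permutation nulls

Carrier tables (case carriers / non-carriers versus control carriers /
non-carriers) are tested with the exact two-sided Fisher test — the sum of
hypergeometric probabilities no larger than the observed table's, with a
relative tolerance of 1e-7 — and effect sizes are conditional
maximum-likelihood odds ratios under the noncentral hypergeometric
likelihood, with the exact conditional confidence interval. Both are
computed by `stats::fisher.test`, which implements exactly this
construction; the test suite verifies it against an independent
full-enumeration oracle on every table with up to 25 subjects. A table with
no carriers anywhere is reported as p = 1; a zero cell yields an infinite
(or zero) odds-ratio estimate with a finite one-sided bound.

Genome-wide significance uses the permutation min-p construction:
case/control labels are shuffled with the carrier structure fixed, the full
battery of tests is recomputed, and the minimum p per permutation forms the
null. The empirical p of test *i* is `(1 + #{perm: min_p <= p_obs_i}) /
(n_perm + 1)`; the add-one form is never zero and slightly conservative.
This controls the family-wise error rate across the battery. Because
permutations only move carriers between groups, each battery reduces to a
lookup table indexed by (total carriers, case carriers), which makes
thousands of permutations cheap. Under very sparse carrier tables the
smallest attainable per-gene p is bounded away from zero (two carriers both
in cases give p ≈ 0.11 at this cohort size), so the min-p procedure is
conservative there — its type-I error falls below the nominal level rather
than above, which the calibration tests reflect.

The locus scan for common CNVs tests the breakpoint-bounded elementary
intervals of the stacked calls, collapses consecutive intervals with
identical carrier sets into one test, and excludes edge loci — a first or
last locus of a region whose carrier set is a strict subset of its inner
neighbour's — as boundary-truncation artifacts: such a locus differs from
its neighbour only because some calls' estimated endpoints fall short, not
because any sample's variant differs there.

The burden analysis compares four per-sample aggregates (call count, genes
hit, mean call length, total call length) across the strata all /
deletions-only / duplications-only. Zero-call samples contribute zeros to
the count and total-length means but are excluded from the mean-length
mean, which would otherwise average an empty set. The one-sided p for
excess burden in cases compares the observed case:control ratio of means
with its label-permutation distribution.

## Gene sets and the local FDR

A sample carries a gene set when at least one of its rare calls overlaps at
least one member gene (one shared base suffices; one count per sample per
set). Sets are size-filtered to 5–700 genes, counted against the provided
annotation, because tiny sets carry no signal and huge ones are
catch-alls. Each set's statistic is the signed root of the likelihood-ratio
(G) statistic of its carrier table, positive when cases carry more; it is
defined for zero cells through the `0·log 0 = 0` convention, antisymmetric
under group swap, and approximately standard normal under the null.

The per-set local false discovery rate follows the empirical-Bayes
density-ratio idea with both distributions taken from the data: the null is
the pool of statistics across label permutations, and for each observed
statistic the ratio of the expected number of null sets at least as extreme
(in the same direction, scaled to one battery) to the number of observed
sets at least as extreme is formed. The local FDR is that ratio times the
null proportion `p0` (the median ratio capped at 1, close to 1 when most
sets are null), truncated to `[0, 1]`, and finally monotonized so that a
set never receives a better local FDR than a more extreme one. Counting
exceedances was chosen over smoothing two separate binned densities after
direct comparison: a polynomial density fit cannot follow the permutation
null's sharply light tail, and systematically overstates the local FDR of
an isolated extreme set — the permutation pool itself is the best available
statement of how rare such values are under the null. Sets whose signal is
driven by one gene are visible through the `top_gene` annotation (the
member gene carried by most samples), and a gene-exclusion mode reruns the
analysis with all calls overlapping a named gene removed, which is the
direct diagnostic for a single-gene-driven pathway hit.

## Depth-ratio copy-number estimation

For targeted sequencing, the depth ratio is the region read count divided
by region length and by the sample's total reads, scaled by 1e9 for
readability. Ratios of exactly zero are assigned copy number 0 before any
clustering — no template DNA yields no reads. The remaining ratios are
split by exact one-dimensional partitioning (dynamic programming minimizing
the within-cluster sum of squares over sorted values), which is
deterministic and optimal — there is no random initialization to converge
badly on 62 samples. Clusters map to copy numbers 1, 2, … in increasing
ratio order; an optional anchor sample of known copy number 2 relabels the
clusters, guarding against the classic mis-assignment in which software
assumes the most common state is diploid while the population in fact
segregates a high-frequency deletion allele. Cluster concordance between
two assignments is counted after exhaustive label matching, since cluster
labels are arbitrary.

## The synthetic cohort generator

The generator defines the study conditions the tests run under. Per
sample, the background call count is Poisson with mean 4.8 (controls) or
5.17 (cases); calls are deletions with probability 0.60 (one-copy 90%,
zero-copy 10%; duplications three-copy 90%, four-copy 10%); positions are
uniform over a 22-chromosome, 2.87-Gb genome; and lengths are log-normal
(`meanlog = 10.764`, `sdlog = 1`) truncated to the 4 kb–1 Mb QC window,
giving a mean near 77 kb. The annotation places 20,000 genes of about
20 kb median length uniformly, which reproduces a genes-hit-per-sample rate
near 3.3, and draws gene sets of 5–100 members. The secondary caller is a
degraded copy of the primary calls: Gaussian boundary jitter (SD 500 bp),
false-negative dropouts and Poisson false-positive additions (5% each by
default). Marker counts scale with length (about one per 500 bp) and
confidences are gamma-distributed, so a realistic minority of background
calls fails each call-level filter; the per-sample array-quality metrics
are drawn comfortably below the exclusion thresholds because the 189/380
cohort the generator emulates is a *post*-QC cohort.

Planted effects are additive carrier events, not rate shifts, so true
carrier status is unambiguous and recorded exactly in a truth table. A
planted gene effect with penetrance `p` is realized as a deterministic
carrier count `round(p * n_group)` over randomly chosen samples: the
worked example of five case carriers and no control carriers then
reproduces exactly, and recovery scoring never conflates planting noise
with detection failure. Planted pathway effects add per-gene Bernoulli
carrier calls across a set's members.

What the generator does not emulate: linkage between variants, recurrent
breakpoints at hotspots, population stratification, batch effects, or any
correlation between call quality and genomic context. Passing tests on
synthetic cohorts therefore demonstrate that the statistical machinery is
correct and calibrated under the assumed sampling model, not that the QC
thresholds are optimal for any particular array platform.

## Problem sizes and numerical choices

The test suite runs the calibration studies at the sizes a desk check
supports, chosen as the package's own trade-off between statistical
resolution and turnaround: 20 null cohorts for the gene-level FWER check
and 200 for the burden type-I check at 500 permutations each, 50 planted
replicates at 1,000 permutations for the pathway recovery study, and full
enumeration of all 2×2 tables with up to 25 subjects for the exact-test
oracle. Ties in permutation comparisons are resolved conservatively (a
permuted statistic equal to the observed one counts against the
hypothesis, with a 1e-12 relative guard for floating point). The
common/rare threshold sits at exactly 1% with "equal means rare"; the QC
inequalities are strict or inclusive following the wording of each rule,
and both conventions are pinned by boundary tests. Carrier percentages are
reported with the combined-cohort denominator (the convention of the
result tables this package mirrors) alongside within-group percentages,
since both conventions appear in the literature.

## Known limitations

Stratified or covariate-adjusted permutation is not implemented; labels
are exchangeable under the null only in unstructured cohorts. The
gene-set analysis treats genes as exchangeable units — no topology, no
gene length correction beyond what carrier counting implies. The depth
module assumes a single target region per sample table and integer copy
numbers up to the requested cluster count. The DGV-style false-positive
flag compares frequencies only; it cannot distinguish a genuine association
at a polymorphic locus from an artifact.
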