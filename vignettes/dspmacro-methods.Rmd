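---
title: "Spatial macrophage signatures from DSP data: models, parameters and design choices"
author: "dspmacro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial macrophage signatures from DSP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dspmacro)
options(dspmacro.verbose = FALSE)
```

## Scope

`dspmacro` analyzes digital spatial profiling (DSP) experiments in which each
region of interest of a lymphoid-tissue section is segmented by
immunofluorescence masks into cell-type areas of interest (AOIs) — CD68
(macrophages), CD3 (T cells), CD20 (B cells) — across spatial compartments
(germinal center, interfollicular region, light zone, dark zone) of reactive
lymphoid tissue (RLT) and DLBCL tumors. The pipeline derives signed,
significance-weighted macrophage signatures from spatial contrasts and
evaluates their prognostic value in bulk survival cohorts. Because real DSP
and cohort data cannot ship with a package, every stage is exercised on a
synthetic generator with recorded ground truth; this vignette documents the
models, the tunable parameters, and the design decisions that were genuinely
open.

## Preprocessing model

**AOI quality control.** An AOI is dropped when `raw_reads < 10,000`,
`saturation < 0.5`, or the fraction of target genes with nonzero counts is
below 0.05. All three comparisons are strict, so an AOI exactly at a
threshold is retained. The 5%-of-genes rule counts raw nonzero genes (not
genes above the LOQ); this is the simplest reading and it is configurable
via `qc_thresholds()`.

**Limit of quantitation.** The per-AOI LOQ is the platform convention
`geomean(neg + eps) * geoSD(neg + eps)^2` over the negative probes, with a
pseudo-count `eps = 0.5` guarding zero probe counts and the n−1 denominator
on the log scale. A gene is kept when its count exceeds the LOQ in at least
5% of AOIs (a `>=` comparison on the fraction, so the boundary case is
retained).

**Q3 normalization.** Each AOI is divided by its third quartile — computed
with type-7 linear interpolation over the retained genes, fixed for
determinism so that independent oracles agree to machine precision — and
multiplied by the geometric mean of all AOIs' third quartiles. Two exact
consequences are tested: every post-normalization Q3 equals that geometric
mean, and renormalizing a normalized matrix changes nothing.

**Log transform and batch harmonization.** Expression is `log2(x + 1)`.
Batch effects are removed per gene by least squares on
`[preserved design | batch indicators]`, subtracting only the fitted batch
terms relative to the first batch; the preserved design defaults to mask,
tissue and region. Internal collinearity of the preserved labels (tissue is
implied by region = NONE) is projected out, but a batch that is inseparable
from a preserved label is an error rather than a silent confounded fit. We
subtract reference-coded batch terms (rather than the sum-to-zero coding some
implementations use, which differs only by a per-gene constant) because the
package's contracts state exact restoration of a planted balanced shift.

**PCA outliers.** AOIs whose PC1 or PC2 coordinate lies more than 4 median
absolute deviations from the median are flagged. No published rule exists for
this step, so the flags are strictly advisory: `preprocess_dsp()` reports
them and removes nothing by default. On data with strong biological cluster
structure (e.g. whole masks separating on PC1) a MAD rule can flag an entire
biological group, which is exactly why silent removal would be wrong.

## Differential expression

Duplicate cores — AOIs sharing patient, mask, region and tissue — are
technical replicates and are collapsed by per-gene averaging on the log2
scale. This replaces the generalized-least-squares treatment of replicate
correlation with a deterministic, slightly conservative reduction; the
package deliberately prefers the reproducible choice.

For a two-group contrast the per-gene statistics are the mean difference
(log2FC), the pooled residual variance `s²` on `df = n_A + n_B − 2` degrees
of freedom, and a moderated t statistic. The empirical-Bayes prior
`(d0, s0²)` of the scaled inverse-chi-square variance prior is estimated by
matching the first two moments of `log s²` to the theoretical log-F moments
(digamma/trigamma based, with a Newton inversion of the trigamma function);
posterior variances are `(d0 s0² + df s²)/(d0 + df)`. Edge cases are pinned
down by contract: when the observed spread of `log s²` does not exceed the
sampling spread, `d0 = ∞` and the prior variance is the pooled mean of `s²`
(so that identical variances shrink to exactly their common value); `d0 = 0`
reproduces the ordinary pooled two-sample t-test; zero posterior variance
yields p = 0 for a nonzero fold change (with a warning). Genes with zero
variance or `df < 1` are excluded from prior estimation. The finite-`d0`
estimates agree with the standard limma implementation to about four decimal
places, and the test suite uses limma as an independent cross-check, never as
the implementation.

Significance is BH-adjusted; DEGs require `adj_p < 0.05` and
`|log2FC| > 0.58`, both strict.

## Signature derivation

A signature collects one direction of one contrast. Entries carry the weight
`w = −log10(p)` (the moderated-t p-value, not the adjusted one — adjusted
values are kept separately), the sign `I = sign(log2FC)`, and the fold
change. The B-cell contamination filter removes genes whose percentile rank
of mean Q3-normalized expression — ranked over **all** retained genes, the
natural reading of a percentile of average expression — is strictly greater
in the CD20 mask than in the CD68 mask; ties are retained. The filter is
skipped for the RLT signature, whose germinal-center ROIs have no matched
CD20 mask. Percentiles are computed over all AOIs of each mask (not only
shared ROIs); this was an open choice and is noted here. `top_k()` ranks by
absolute fold change (equal to signed ranking for an up-signature), breaking
ties by smaller p-value then lexicographic gene id, and defaults to 50 genes
for single-cell projection.

## Scoring, stratification, survival

The per-patient score of a paired signature is
`score = Σ −log10(pᵢ) · xᵢ · Iᵢ` over the union of the pair's (disjoint)
genes. The scale of `xᵢ` is genuinely under-determined: raw log2 expression
lets high-abundance genes dominate, so the default standardizes each gene to
a z-score across the cohort, and `standardize = FALSE` evaluates the literal
formula. At least 50% of the pair's genes must be present in the cohort;
zero-variance genes are dropped with a warning.

Tertiles are cut at the 1/3 and 2/3 type-7 quantiles; `score <= q1` is low,
`score > q2` is high, so a score exactly on a boundary falls to the lower
group — a deterministic tie rule. A consequence worth knowing: negating all
scores swaps the low and high groups exactly unless a cutpoint coincides
with an observed score (which type-7 interpolation produces when
`n mod 3 == 1`), in which case the boundary observation moves with the tie
rule.

The extreme tertiles are compared with a Cox proportional-hazards model
(Efron tie handling by default — ties are common in month-resolution survival
data — with Breslow by flag), the log-rank test, and per-group Kaplan–Meier
curves; the proportional-hazards assumption can be checked by the scaled
Schoenfeld-residual score test against Kaplan–Meier-transformed time. These
standard estimators are provided by the survival package behind the package's
interface; the test suite verifies them against hand product-limit
computations, a hand observed-minus-expected log-rank oracle and a
brute-force partial-likelihood grid.

Associations between tertile groups and clinical categories use the Fisher
exact test. Sidedness is ambiguous in practice, so both modes exist: the
default two-sided probability-mass rule, and the one-tailed hypergeometric
upper tail. The overlap ratio divides the group-category overlap by the
category size; BH adjustment runs over the whole group-by-category family of
one analysis, and the enrichment score is `−log10(adj p)`. Gene-set
enrichment reports the overlap count, the gene ratio (count over gene-set
size) and the hypergeometric upper-tail p-value, BH-adjusted across sets.

Single-cell module scores subtract the mean of control genes sampled from
equal-frequency expression bins (25 bins, 100 controls per signature gene,
seeded so calls are reproducible); cells with score > 0.1 are called
expressing. Single-cell QC removes cells with fewer than 200 detected genes
or more than 10% mitochondrial counts, then genes detected in fewer than 3
cells.

## The synthetic generator

`simulate_dsp_experiment()` emulates the study design: RLT patients
contribute one ROI per region, each segmented into the three masks; DLBCL
patients contribute one ROI (region label NONE), and 35% of them a duplicate
core whose AOIs share the patient's per-gene biology but get independent
counting noise. Counts are negative binomial with `var = mu + alpha mu²`
(`alpha = 0.1`), per-AOI lognormal size factors (log-sd 0.3), per-batch
per-gene lognormal effects (log2-sd 0.1, two batches split by patient), and
per-patient per-gene effects (log2-sd 0.2). Negative probes (100 by default —
the platform count is configurable since no canonical value exists) follow
the low-expression baseline. Saturation is synthesized as
`1 − exp(−library_size/φ)` with `φ = 60,000`, purely so the QC filter is
exercisable; raw reads are twice the library size.

Planted differential expression deserves its own paragraph, because two
choices matter. First, each contrast's effects are applied in its *B* stratum
(IF, DZ, DLBCL) with the opposite sign — an up gene of A-vs-B is lowered in
B. The B strata are mutually disjoint and appear in no other contrast,
whereas the germinal center is the A side of two contrasts, so planting there
would couple them and corrupt false-discovery accounting. Second, all planted
genes receive a +1 log2 shift across the whole CD68 mask: they model
macrophage-expressed genes, and without this the CD20-vs-CD68 percentile
comparison of the contamination filter reduces to a coin flip on noise and
removes half of any genuine signature. Planted genes are drawn from genes
with baseline mean ≥ 20 counts so the realized fold change on the
`log2(x+1)` scale stays near the nominal ±1.5 (pseudo-count attenuation
would otherwise bias low-count genes); a quarter of the GC-upregulated genes
additionally get a +3 log2 shift in all CD20 AOIs and are recorded as
contaminant ground truth. Hallmark mask markers (CD68/CD163/FCGR1A/CSF1R;
CD3D/CD3E/UBASH3A/CD2/TRBC2; MS4A1/CD79A/CD79B/CD19/PAX5) are boosted
+2.5 log2 in their own mask, driving the mask-validation checks.

`simulate_cohort()` draws a latent activity `a ~ N(0,1)` per patient, shifts
signature-gene expression by `a · I · 1.5`, and simulates Weibull event times
(shape 1.2, baseline median 36 months) with log-hazard `0.42 · a`. The
default 0.42 equals `log(2.5) / (2 E[Z | Z > q_{2/3}])`, so the ratio of
geometric-mean hazards between the top and bottom latent tertiles is 2.5 —
the planted end-to-end effect size. Censoring is independent uniform with its
upper bound solved by root finding against the realized event times, which
keeps the observed censoring fraction within a few percent of the 30% target.
Category labels follow a three-class softmax whose ABC-vs-GCB axis moves with
the latent activity.

What the generator does **not** emulate: real AOI count distributions (no
public distributional description exists, so the negative-binomial baselines
are stated assumptions, not estimates), spatial coordinates (the analysis
uses region labels only), empty-droplet/doublet artifacts in the single-cell
matrix, and informative censoring. Passing tests therefore demonstrate
correctness of the statistical machinery and recoverability of planted
structure under a plausible noise model — not performance on any particular
real dataset.

## Problem sizes and numerics

The default experiment is 2,000 genes × 225 AOIs, the default cohort 600
patients, and the test suite's planted-recovery checks use 20 AOIs per
stratum with dispersion 0.1 and |log2FC| = 1.5 — sizes chosen so the whole
suite, including the end-to-end prognosis recovery over ten cohort seeds and
a 100-seed null-uniformity check, runs in a few minutes on one core while
leaving the recovery criteria statistically comfortable rather than
borderline. Exact oracles (quantiles, BH, hypergeometric enumeration, ECDF
suprema) are compared at 1e-9 to 1e-12; Monte-Carlo recoveries use the
tolerances stated with each test. The Cox fit uses a 1e-9 Newton tolerance
with at most 100 iterations, and a fit whose standard errors exceed 10³ is
reported as monotone-likelihood failure rather than returned.

## Known limitations

Only two-group contrasts are supported (all the pipeline's contrasts are
two-group); covariate-adjusted differential expression designs are out of
scope. The duplicate-core treatment (averaging) is exact only for technical
replicates. The contamination filter presumes comparable gene panels between
the CD68 and CD20 masks. The module-score control sampling follows the usual
bin-matched convention and inherits its sensitivity to the bin count in very
small gene universes.
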