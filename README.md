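# dspmacro

Spatially resolved macrophage-signature analysis for GeoMx-style digital
spatial profiling (DSP) data.

In DSP experiments of lymphoid tissue, each region of interest (ROI) is
segmented by immunofluorescence masks into cell-type areas of interest (AOIs):
CD68 (macrophages), CD3 (T cells) and CD20 (B cells), across spatial
compartments of reactive lymphoid tissue (germinal center GC, interfollicular
region IF, light zone LZ, dark zone DZ) and diffuse large B-cell lymphoma
(DLBCL) tumors. `dspmacro` implements the full analysis chain that turns such
AOI-level count data into prognostic macrophage gene signatures ("MacroSigs")
and evaluates them in bulk survival cohorts and single-cell data — together
with a synthetic-data generator that plants known structure, so every stage is
testable without any external download.

## The method

1. **Preprocessing.** AOIs with fewer than 10,000 raw reads, sequencing
   saturation below 50%, or under 5% of target genes detected are removed.
   Genes must exceed the negative-probe limit of quantitation,
   `LOQ(aoi) = geomean(neg) * geoSD(neg)^2`, in at least 5% of AOIs. Counts
   are Q3-normalized (each AOI divided by its third quartile, re-anchored to
   the geometric mean of all third quartiles), log2-transformed, and batch
   effects are removed by per-gene linear models that protect the biological
   design (mask, tissue, region). PCA outlier flags (4 MADs on PC1/PC2) are
   advisory.
2. **Mask validation.** Per-AOI mean expression of hallmark macrophage / T /
   B marker sets is compared between masks with one-sided two-sample
   Kolmogorov–Smirnov tests, BH-adjusted.
3. **Differential expression.** Duplicate cores (same patient, mask, region,
   tissue) are averaged; two-group contrasts (GC vs IF, LZ vs DZ,
   RLT vs DLBCL, within the CD68 mask) are tested with an empirical-Bayes
   moderated t-test: per-gene variances are shrunk toward a prior `(d0, s0²)`
   estimated by matching moments of `log s²` to the theoretical log-F moments,
   and `t = log2FC / sqrt(post_var (1/n_A + 1/n_B))` is referred to a t
   distribution on `d0 + df` degrees of freedom, with BH correction.
4. **Signature derivation.** DEGs at BH-adjusted `p < 0.05` and
   `|log2FC| > 0.58` form one signed signature per contrast direction. Genes
   whose percentile rank of mean Q3-normalized expression is higher in the
   CD20 (B-cell) mask than in the CD68 (macrophage) mask are removed as
   contaminants (exempted for the RLT signature, which has no matched CD20
   data).
5. **Scoring and survival.** For a paired signature (up/down of one
   contrast), each patient in a bulk cohort gets

   `score = Σᵢ −log10(pᵢ) · xᵢ · Iᵢ`,  `Iᵢ = sign(log2FCᵢ)`,

   where `xᵢ` is the (by default z-scored) log2 expression of gene *i*.
   Patients are split into tertiles; the extreme tertiles are compared by
   Kaplan–Meier curves, the log-rank test and a Cox proportional-hazards
   model (Efron ties; `cox.zph`-style PH check available).
6. **Association and enrichment.** Tertile groups are associated with
   clinical categories (e.g. cell of origin GCB/ABC/UNC) by Fisher exact
   tests with BH adjustment and the enrichment score `−log10(adj p)`;
   signature genes are tested against gene-set collections (GMT) with
   hypergeometric upper-tail tests. Single cells are scored with
   expression-bin-matched control genes; cells with module score > 0.1 are
   called "expressing".

## Worked example

```r
library(dspmacro)
options(dspmacro.verbose = FALSE)

exp <- simulate_dsp_experiment(sim_params(seed = 7))
exp
#> dsp_experiment: 2000 genes x 225 AOIs (100 negative probes)
#>   tissues: DLBCL=81, RLT=144
#>   masks:   CD20=75, CD3=75, CD68=75
#>   planted truth recorded

pp  <- preprocess_dsp(exp)
dea <- run_dea(pp$log2, pp$annotations, "LZ_vs_DZ")
dea
#> dea_result: 1945 genes (prior d0 = 65.2, s0^2 = 0.298)
#>   50 up / 52 down at adj_p < 0.05, |log2FC| > 0.58

ranks <- percentile_ranks(pp$q3, pp$annotations$mask)
sig3  <- derive_macrosig("MacroSig3_LZ", dea, "up",   ranks = ranks)
sig4  <- derive_macrosig("MacroSig4_DZ", dea, "down", ranks = ranks)
sig4
#> macrosig 'MacroSig4_DZ' (down direction): 50 genes (52 before contamination filter)
#>   weight range -log10(p): [5.45, 13.05]

cohort <- simulate_cohort(sim_params(seed = 7), list(sig3, sig4))
strat  <- tertile_stratify(signature_score(cohort, list(sig3, sig4)))
ts     <- tertile_survival(strat, cohort$survival)
ts$cox
#> Cox PH fit: n = 400, events = 282
#>   grouphigh: HR = 2.477 (95% CI 1.930-3.179), p = 1.07e-12
```

The simulated LZ-vs-DZ contrast plants 100 differentially expressed genes at
|log2FC| = 1.5; the derived signatures recover them (50 + 52 DEGs, with two
planted B-cell contaminants filtered from the DZ signature). The cohort is
simulated with a latent-activity hazard coefficient giving a true
top-vs-bottom tertile hazard ratio near 2.5, and the fitted Cox model on the
recovered stratification estimates HR = 2.48 (log-rank p = 2.2e-13).

The whole pipeline can also be driven from one configuration:

```r
man <- run_pipeline(default_pipeline_config("out", seed = 7))
```

which writes every stage's tables plus JSON provenance records under `out/`.

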