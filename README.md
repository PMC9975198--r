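# ppglmetrisk

Integrative metastasis-risk marker analysis for pheochromocytoma /
paraganglioma (PPGL) cohorts.

About one PPGL patient in five develops metastatic disease, and no single
molecular marker predicts that outcome when the primary tumor is diagnosed.
`ppglmetrisk` is an R toolkit for cohorts with somatic variant calls,
copy-number segments, expression counts and clinical follow-up. It computes
the genomic-instability markers (tumor mutational burden, MSI score
dichotomies, SCNA burden, arm-level and whole-chromosome calls, genome
doubling), a composite ATRX/TERT alteration status, expression marker genes,
tumor-microenvironment (TME) subtypes, and — at its core — an exhaustive
search over OR-combinations of binary marker events as classifiers of
metastatic risk, plus the survival and regression models that tie markers to
time to progression (TTP).

## The core methods

**Variant curation and TMB.** Somatic calls pass a fixed removal ladder
(excluded consequence terms → population allele frequency > 0.1 →
artifact flag → VAF < 0.1). TMB is the count of retained coding variants
with VAF > 0.1. High-impact status (truncating / splice / start-stop, or
missense with ≥ 3 deleterious predictor votes or a COSMIC record) feeds the
ATRX event and enrichment gene lists.

**Copy-number metrics.** FACETS-style segments are filtered (total CN > 8
dropped; |log-ratio| < 0.1 dropped except copy-neutral LOH); SCNA burden
counts non-neutral survivors; arms are called gained/lost at ≥ 50% coverage;
whole-chromosome-5 gain requires both arms.

**OR-combination classifier search.** Nine dichotomized events
(Krebs-germline, MAML3-fusion, TERT-alt, ATRX-mut, MKI67-high, MSI > 0.15,
TMB > Q3, chr5 gain, CDK1 > Q3) define 2⁹ − 1 = 511 candidate classifiers;
each predicts positive when any of its events is present. With a binary
predictor the ROC has one operating point, so

    AUC = (sensitivity + specificity) / 2,

identical to the Mann–Whitney pair probability; 95% CIs are DeLong (closed
form) or stratified bootstrap. The search reports the full ranked table, the
max-AUC winner and the best classifier constrained to sensitivity 1.

**Expression and TME.** Median-of-ratios normalization; a metastasis
signature selected by |log2FC| > 0.75 in every genomic-subtype stratum with
consistent sign and pooled FDR < 0.01; rank-based single-sample gene-set
scores (weight rank^0.25); classic pre-ranked GSEA; seeded k-means (k = 4,
Euclidean, 1000 iterations) on z-scored Fges scores with quadrant-rule
archetype labels (IE, IE/F, F, D).

**Statistics.** Exact Fisher and Freeman–Halton tests, BH-FDR, Kaplan–Meier
with Greenwood errors and log-rank tests, logistic (OR) and Cox (HR, Efron
ties) models with design-matrix VIFs.

A seeded synthetic-cohort generator (`simulate_cohort()` and per-stage
helpers) plants group-specific TMB (medians 8 / 17.5 / 24), a TMB-coupled MSI
score, ATRX/TERT enrichment, arm events, a 26-gene expression signature, TME
archetypes and marker-dependent progression hazards, together with a truth
ledger for recovery testing.

## Worked example

```r
library(ppglmetrisk)

sim <- simulate_cohort(cohort_config(n_non_metastatic = 60,
                                     n_metastatic_primary = 40,
                                     n_metastasis = 10, n_genes = 900),
                       seed = 42)
sim$bundle
#> <ppgl_cohort> 110 samples (GRCh37)
#>   variants:   2427 rows
#>   segments:   515 rows
#>   expression: 900 genes x 110 samples
#>   no omics:   0 sample(s)

res <- run_pipeline(sim$bundle,
                    fges_sets     = sim$truth$fges_sets,
                    immune_sets   = sim$truth$fges_axes$immune,
                    fibrotic_sets = sim$truth$fges_axes$fibrotic,
                    seed = 1)
res$search
#> <ppgl_search> 511 OR-combination classifiers over 9 events, n = 100
#>   best (max AUC): {atrx_mut+cdk1_high+maml3_fusion+mki67_high+tert_alt}
#>   AUC = 0.900 (sens 0.90, spec 0.90)

km <- km_logrank(dplyr::mutate(sim$bundle$clinical,
                               group = ifelse(msi_score > 0.15,
                                              "MSI-high", "MSI-low")))
km
#> <ppgl_km> log-rank chi-square = 14.626, p = 0.000131
#> # A tibble: 2 × 5
#>   group        n events median    se
#>   <chr>    <dbl>  <dbl>  <dbl> <dbl>
#> 1 MSI-high    51     49    770  216.
#> 2 MSI-low     59     46   2213  411.
```

The search output reads as: of the 511 candidate OR-combinations evaluated on
the 100 complete-case primary tumors, the best scores an AUC of 0.900 at
sensitivity and specificity 0.90 on this simulated cohort. The Kaplan–Meier
comparison shows the MSI-high group progressing far earlier (median TTP 770
vs 2213 days; log-rank p ≈ 1.3 × 10⁻⁴), reflecting the planted
marker-dependent hazards. `tidy()`, `glance()` and `autoplot()` methods are
available for search, model and survival objects.

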