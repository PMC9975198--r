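---
title: "Methods: metastasis-risk genomic markers for PPGL cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metastasis-risk genomic markers for PPGL cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppglmetrisk)
```

# Scope and model

Pheochromocytomas and paragangliomas (PPGLs) are rare neuroendocrine tumors in
which roughly one patient in five eventually develops metastatic disease, and
no single molecular marker reliably predicts that outcome at diagnosis of the
primary tumor. `ppglmetrisk` implements an integrative marker analysis for
such cohorts: genomic-instability metrics (tumor mutational burden,
microsatellite-instability score, somatic copy-number burden and arm-level
events), a composite ATRX/TERT alteration status, expression-based marker
genes, tumor-microenvironment (TME) subtypes, and an exhaustive search over
OR-combinations of dichotomized marker events evaluated as binary classifiers
of metastatic versus non-metastatic primary tumors, with logistic and Cox
models tying the markers to metastasis risk and time to progression (TTP).

Every stage takes tidy tabular inputs (one row per sample, per variant or per
segment) and returns tibbles, so the pipeline composes with ordinary
dplyr/ggplot2 workflows; `run_pipeline()` wires the stages together.

# Variant curation and TMB

Somatic calls pass a fixed-order removal ladder:

1. *consequence exclusion* — eight non-coding/regulatory consequence terms
   (intronic, UTR, up/downstream, NMD, non-coding transcript, mature miRNA);
2. *germline-like* — gnomAD or 1000G allele frequency strictly above 0.1.
   A missing population frequency never removes a call: absence of evidence
   is not evidence of a germline origin;
3. *artifact* — an upstream blacklist flag (the package does not re-implement
   visual review);
4. *low VAF* — variant allele fraction strictly below 0.1.

Each removed variant records the first rung that caught it, but the survivor
set is order-independent (each filter is a pure predicate). TMB is the count
of retained coding (non-synonymous, non-excluded) variants with VAF strictly
above 0.1; a sample absent from the variant table reports `NA`, never 0.
High-impact status — used for the ATRX event and for over-representation
input lists — is truncating/splice/start-stop consequences, or missense with
at least three deleterious in-silico votes or a COSMIC record. The internal
tier numbering of intermediate curation categories is artifact-defined; the
package exposes exactly the two sets used downstream (the TMB set and the
high-impact set).

# Copy-number metrics

FACETS-style segments are filtered by dropping total copy number strictly
above 8 and log-ratios strictly inside (−0.1, 0.1), except copy-neutral LOH
segments, which are always kept. SCNA burden is the count of non-neutral
surviving segments. Arm calls use covered fraction of the arm length:
`min_fraction = 0.5` by default (half-arm coverage is the common convention;
the threshold is configurable because published cohort analyses rarely state one), larger
coverage wins when both directions qualify, and exact ties are neutral.
Whole-chromosome gain requires every cataloged arm gained; with a one-arm
catalog the call is made and flagged. Genome doubling is called when the
length-weighted fraction of the genome at major copy number ≥ 2 exceeds 0.5,
with `total_cn − 1` as a flagged fallback when minor copy number is missing
everywhere. Arm-frequency group differences use two-sided Fisher tests with
Benjamini–Hochberg correction across arm-direction tests at q < 0.1.

The bundled GRCh37/GRCh38 arm tables are cytoband-derived centromere
approximations rounded to the megabase; any user table with the same columns
can replace them.

# Composite TERT/ATRX alterations and marker dichotomization

TERT alteration is an OR over four evidence channels: targeted-panel mean
expression ≥ 4 counts (or an RNA-seq overexpression flag), promoter mutation
C228T *or* C250T (the assay targets both; that only C228T has been observed
in PPGL series is a property of cohorts, not of the assay), promoter
hypermethylation with mean UTSS ≥ 14.1, and GISTIC amplification score
equal to 2. With no evidence at all the call is missing, never negative, and
the call is monotone in added evidence. The ATRX event is any retained
high-impact somatic ATRX variant.

Continuous markers are dichotomized with strict `>` comparisons: MSI against
the fixed 0.15 cut, TMB and up-signature genes against the cohort third
quartile, down-signature genes against the cohort median. Quantiles use the
type-7 (linear interpolation) convention — the common default; the choice is
exposed because none of the published rules states one. Quantile-based
dichotomies commute with monotone transforms of the values.

# Expression markers

Counts are normalized by median-of-ratios size factors (library-size factors
as a flagged fallback when no gene is positive in all samples) with a
log2(x+1) view. Differential statistics are per-gene ordinary linear models
of log2-normalized expression on the group indicator plus an optional purity
covariate; the reported log2 fold change is the difference of group means so
that the selection rule operates on the same scale regardless of covariates.
The signature rule selects genes with |log2FC| strictly above 0.75 in every
genomic-subtype stratum, *consistent sign across strata*, and pooled FDR
strictly below 0.01. Sign consistency is an explicit design choice: a
magnitude-only reading would admit genes that flip direction between strata,
which cannot be dichotomized with a single direction downstream. The
negative-binomial machinery of dedicated DE engines is deliberately not
reimplemented — the package's contribution is the selection and
dichotomization contract, and any engine producing `gene`/`log2fc`/`fdr`
columns can be plugged into `select_signature()`.

Batch adjustment is per-batch location-scale standardization on the log scale
(a ComBat-like correction without empirical-Bayes shrinkage), adequate for
the rank-based scoring used downstream. Purity scoring is rank-based
single-sample enrichment of immune and stromal sets; the conventional
exclusion threshold 5900 is meaningful only on the original ESTIMATE scale,
so the function warns when the score scale is obviously different.

# Enrichment and TME subtyping

Single-sample scores use the weighted Kolmogorov–Smirnov running-sum
statistic with weight rank^α (α = 0.25), which depends on expression only
through within-sample ranks. This replaces the kernel-density step of GSVA
deliberately: the downstream use — k-means on z-scored signature scores — is
robust to the substitution, and the rank statistic is deterministic and
monotone-invariant. Pre-ranked GSEA uses the classic (unweighted) enrichment
score with gene-label permutations, matching pre-ranked semantics; set-size
bounds default to [10, 1000]. Over-representation uses one-sided Fisher
tests with fold enrichment > 1.8 and BH FDR < 0.05 as the significance rule.
BH is the multiple-testing procedure everywhere an FDR is quoted.

TME subtyping z-scores each signature (configurable off), then runs Lloyd's
k-means (Euclidean, k = 4, up to 1000 iterations, best of 25 seeded restarts
by inertia, farthest-point re-seeding on empty clusters). Clusters map to the
four archetypes — immune-enriched non-fibrotic (IE), immune-enriched fibrotic
(IE/F), fibrotic (F), depleted (D) — by the quadrant of centroid mean
immune-axis and fibrotic-axis scores relative to cross-centroid medians;
collisions fall back to the nearest unassigned quadrant with a warning. The
quadrant rule is the package's own, because published subtype labels are
assigned post hoc without a stated rule; it guarantees a bijection.

# The OR-combination classifier search

Nine binary events (Krebs-cycle germline mutation, MAML3 fusion, TERT
alteration, ATRX mutation, MKI67-high, MSI-high, TMB-high, chromosome-5 gain,
CDK1-high) yield 2^9 − 1 = 511 candidate classifiers; a candidate predicts
positive when *any* of its events is present. Training rows are
complete-case primary tumors only (metastases and relapses are excluded from
labels). For a binary predictor the ROC has a single operating point, so
AUC = (sensitivity + specificity)/2, which equals the Mann–Whitney pair
probability; confidence intervals use the DeLong variance of the binary score
(closed form) or a seeded stratified bootstrap. Because "highest AUC" and
"sensitivity = 1 with highest AUC" can disagree on arbitrary data, both
rankings are always reported: `best` is max-AUC (ties to smaller, then
lexicographically earlier subsets) and `best_sens1` is the constrained
winner. OR-monotonicity — supersets never lose sensitivity nor gain
specificity — is asserted property-style in the test suite.

# Copy-number / expression integration

Per gene and sample, the overlapping segment with maximal overlap assigns the
recode value (DUP/DUP-LOH → 1, none → 0, HEMYZIG → −1, DEL → −2); overlap
ties go to the more extreme value, deletions over gains at equal magnitude,
so a borderline gene is treated as altered rather than silently neutral.
Group enrichment uses two-sided Fisher tests per gene and direction
(p < 0.05); dosage association uses one-way ANOVA of expression across
observed CN levels (categorical over the observed levels, since the recode
alphabet is ordinal but effects need not be linear) with BH FDR < 0.05 and a
positive Pearson correlation. The final list is the intersection of the two.

# Survival and regression

TTP is days from primary diagnosis to first documented metastasis, censored
at last follow-up. Kaplan–Meier medians carry Greenwood-based standard
errors; the two-group comparison is the log-rank test. Cox models use the
Efron tie approximation (the common default; published analyses rarely state
one). Logistic and Cox fits report Wald 95% intervals; VIFs come from the
covariate design matrix with a warning at VIF ≥ 2. Logistic separation is
detected via non-convergence or runaway coefficients and triggers a lightly
ridge-penalized (λ = 10⁻³) refit, flagged in the output — a pragmatic
fallback chosen over Firth's correction, which would add a dependency for a
rare edge case. Exact 2×2 Fisher p-values sum hypergeometric probabilities no
larger than the observed table's; r×c tables use exact network enumeration up
to n = 200 and seeded fixed-margin Monte-Carlo beyond, with the Monte-Carlo
standard error reported.

# The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture: it generates
a full validated bundle plus a truth ledger sufficient to recompute every
downstream expectation. Its defaults are the study conditions the package is
tested under:

* group TMB is negative-binomial (size 4) with the baseline mean calibrated
  numerically so the *marginal* group medians — including the +3 additive
  shift carried by ATRX/TERT-altered samples — land on 8 (non-metastatic
  primaries), 17.5 (metastatic primaries) and 24 (metastases);
* the MSI score is an affine monotone function of TMB interpolating the
  group medians 0.13/0.16/0.18, plus Gaussian noise whose SD is set from the
  realized signal variance to achieve the configured TMB–MSI Pearson
  correlation (default 0.6, a moderate coupling), floored at 0.05;
* ATRX/TERT, Krebs-germline, MAML3-fusion and chromosome-5-gain events are
  Bernoulli with metastatic enrichment (defaults 0.25/0.20/0.25/0.15 in
  metastatic vs 0.03–0.05 in non-metastatic samples); planted ATRX events
  materialize as high-impact stop-gained ATRX variants so the caller can
  recover them;
* segments include arm-scale events (1p loss, chromosome-5 gains) plus
  Poisson focal segments; expression is negative-binomial (dispersion 0.2)
  with a 26-gene planted signature (|log2FC| drawn from [1, 2], CDK1 and
  MKI67 among the up-genes) and Fges-archetype structure on disjoint
  synthetic gene sets; progression times are exponential proportional-hazards
  draws with administrative censoring near 30–40% event rates.

Focused generators (`simulate_marker_cohort()`,
`simulate_signature_cohort()`, `simulate_integration_cohort()`,
`simulate_fges_scores()`, `simulate_logistic_cohort()`,
`simulate_cox_cohort()`) expose single stages at the same conditions. The
marker generator partitions positives across the four planted events, so the
planted OR-combination has sensitivity 1 by construction while decoy events
are noisy enough that adding one always costs more specificity than it gains.

What the generator does *not* emulate: mutational signatures and positional
clustering of variants, realistic segment breakpoint processes, platform
batch effects, correlated gene-gene expression beyond the planted blocks,
and informative censoring. Passing recovery tests therefore demonstrates the
correctness of the pipeline's logic under the stated stochastic model, not
performance on real sequencing data.

# Problem sizes and numerical choices

The test and acceptance workloads use cohorts of 150/100/50 samples (TMB/MSI
checks), 200 samples for classifier and TME recovery with 100 seeded
replicates of the search, three strata of 60 samples over 2000 genes for the
signature, 200 samples over 5000 genes with 50 planted concordant genes for
the integration chain, and 2000 null replicates for log-rank calibration —
sizes chosen to make planted effects comfortably detectable at the stated
thresholds while keeping a full run in minutes on a laptop. Ties in ranks are
mid-ranked; ties in quantile dichotomies resolve by the strict `>` rule;
k-means and all permutation/bootstrap machinery are seeded; degenerate inputs
(empty segment tables, all-censored groups, one-class truth vectors,
single-CN-level genes) return typed missing values or explicit errors rather
than silent zeros.

# Known limitations

The DeLong interval for a binary score is asymptotic and degenerates at
sensitivity or specificity of exactly 1 (the bootstrap option behaves
better there). The location-scale batch adjustment does not shrink per-gene
variances and can over-correct tiny batches. The arm-call rule is a coverage
heuristic, not a segmentation-aware caller. The exhaustive search reports
apparent (resubstitution) performance, matching the published analysis it
mirrors; cross-validation is intentionally out of scope.
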