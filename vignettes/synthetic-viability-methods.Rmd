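---
title: "Methods: synthetic-viability discovery and the six-pair ICI risk signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic-viability discovery and the six-pair ICI risk signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synviab)
```

## The model

A synthetic-viability (SV) pair is a gene pair in which alteration of a
rescuer gene (gene2) compensates the fitness loss from a primary lesion in
gene1. The package works with four pair classes built from tumor-suppressor
(TSG) and oncogene roles: TSG~L~–TSG~L~, OG~L~–OG~G~, OG~L~–TSG~L~ and
TSG~L~–OG~G~, where the subscript is the required loss (L) or gain (G) of
function. gene1 always carries the primary loss; a TSG rescues by loss, an
oncogene by gain.

The pipeline has three stages: (i) a feature-based classifier nominates
candidate pairs, (ii) a CRISPR dependency-screen regression confirms the
rescue functionally, and (iii) confirmed pairs feed per-sample scores — the
SV-score and the six-pair RiskScore — whose survival and immune correlates
are the downstream analytics.

## Loss/gain-of-function calling

Per sample, a gene is **LOF** on any of: a truncating mutation (nonsense,
frameshift, splice), a GISTIC call at or below −2, or a per-gene expression
z-score at or below −1.5; **GOF** on a GISTIC call at or above +2 or a
z-score at or above +1.5. Conflicting evidence yields **AMBIGUOUS**, which
is excluded from all co-occurrence counting because its direction is
undefined. Missense mutations alone are not evidence in either direction by
default — no hotspot-recurrence resource is assumed — but an allow-list of
activating variant classes can be configured. All thresholds live in
`calling_thresholds()` and are recorded with the calls; the defaults are the
package's own declared choices, and tightening the z cutoffs can only move
calls toward WT (a tested monotonicity).

## The 14 features

The registry (`default_feature_registry()`) covers functional-similarity
signals: shared PPI interactors (upper-tail hypergeometric over the PPI
node set minus the two genes), mean essentiality of the shared interactors,
reciprocal shortest PPI distance (1/d so that closer scores higher; 0 when
disconnected), Jaccard similarity of ancestor-closed GO term sets in the
BP, MF and CC namespaces (root excluded), Spearman co-expression, paralogy,
protein-complex co-membership, a one-sided Fisher test of co-occurring
alterations, shared pathway count, compartment-set Jaccard
(co-localization), mean per-gene conservation, and mean essentiality of
shared complex partners. Booleans are stored as 0/1 with the raw p-values
retained. The GO MF and CC similarities fill the registry's two open slots
with the same machinery as the BP similarity; the registry is pluggable, so
an alternative list can be swapped in without touching the classifier.

Missing values mean "resource does not cover this pair" and are imputed at
the classifier stage with training-set medians (boolean NA → 0): random
forests need complete inputs and median imputation avoids injecting class
signal.

## The classifier

`train_sv_classifier()` fits a 500-tree random forest with mtry 3 and
permutation importances; `build_training_set()` pairs the positives with an
equal-size negative set sampled uniformly (without replacement) from
non-positive pairs of the universe, deterministically per seed.
`evaluate_auc()` reports a pooled out-of-fold rank AUC over stratified
folds. The prediction is the fraction of trees voting SV; 0.5 is the
default nomination threshold.

## The dependency screen and its sign convention

For a candidate pair, `screen_pair()` fits OLS of gene1's dependency scores
across cell lines on a 0/1 indicator of gene2 carrying its rescuing state,
with lineage as one-hot covariates (reference dropped; lineages under 3
lines pooled into "other" to stabilize the fit). Dependency scores are
oriented as released by CRISPR screens: more negative = more essential. A
rescue therefore shifts gene1's dependency **toward 0** in altered lines —
a positive raw-scale coefficient. `run_screen()` reports the coefficient on
the essentiality scale (the negated raw coefficient) so that a rescue is
**negative**, which is the published pass rule: negative coefficient,
BH-FDR < 0.05 across all tested pairs, and gene2 altered in more than ten
lines (strict, i.e. at least 11). Because released dependency matrices can
be oriented either way, the pass-rule sign is configurable (`sv_sign`);
both the raw and screen-convention coefficients are returned. Rank-deficient
designs — e.g. alteration perfectly confounded with a lineage — yield NA
and are excluded rather than silently fit.

## Scores and survival analytics

The **SV-score** of a sample is the number of SV pairs whose both genes
carry their required states; the **drug-score** counts altered rescue
partners. Cohorts are split at the median with ties falling to "low" (the
tie rule is the package's choice; only strict exceedance is "high").
Kaplan–Meier/log-rank and Cox models are delegated to the survival package
(Efron ties), with toy-example oracle tests pinning the exact definitions;
Harrell's C-index and the rank AUC are implemented directly and pinned
against exhaustive pair enumeration. Stage enters Cox ordinally (I=1…IV=4);
a missing covariate drops the patient from that model only.

## The six-pair risk signature

The shipped `default_risk_model()` hard-codes the six published terms —
JUN~L~:NR4A3~G~ (0.96), CASP3~L~:BCL2L12~G~ (0.92), ETV6~L~:FGFR2~G~
(1.06), BCL10~L~:CBLC~G~ (0.98), EIF3E~L~:PIK3R1~L~ (−1.13), RUNX1~L~:LCK~L~
(0.98) — and cutoff 1. RiskScore = exp(Σ coefficient × indicator), so a
patient with no altered pair scores exactly 1 and falls (non-strictly) into
the low-risk group, and a patient with all six scores exp(3.77) ≈ 43.4.
The score is log-linear in the indicators, a tested invariant.
`select_pairs_univariate()` provides the re-derivation path — univariate
Cox per pair at α = 0.05 followed by a joint multivariate refit — for new
cohorts; it is **not** used to regenerate the defaults. Responder rules:
CR/PR vs PD with SD excluded (training-cohort rule) or CR/PR plus SD over
six months as responders (validation-cohort rule; SD without a duration is
excluded). High-TMB uses a cohort-median cut by default since no published
cut is fixed.

## ssGSEA and the immune landscape

`ssgsea()` implements the rank-weighted running sum: per sample, genes are
ranked by expression (descending, average ranks at ties); in-set steps are
proportional to rank^0.25 (normalized to sum 1 within the set), out-of-set
steps are −1/(N − set size), and the score integrates the running sum over
all positions. The weight exponent is configurable; min-max normalization
across samples is available but off by default. Scores are exactly
invariant under any strictly monotone transform of a sample's expression —
a tested property — so log vs linear input scale is immaterial. A 29-set
synthetic GMT ships for testing; real immune-process collections drop in as
standard GMT files. High/low-immune clustering is k-means (k = 2, 10
restarts, fixed seed) on per-set z-scores, with Ward hierarchical
clustering behind a flag; k-means was chosen for determinism, as no
clustering method is fixed by the analyses the package reproduces.
Group contrasts report FC = mean(low)/mean(high) with one-sided Wilcoxon
(low greater) and BH-FDR per variable family; over-representation and the
shared-PPI feature use one hypergeometric kernel.

## What the generator emulates — and what it does not

`simulate_panel()` builds a 200-gene, 200-cell-line, 4-lineage panel:
dependency baselines Normal(−0.4, 0.3) (mixed essentiality), per-lineage
offsets Normal(0, 0.1), measurement noise sd 0.2 — plausible magnitudes
chosen once, not fitted to any real screen. Planted pairs (40 by default,
gene-disjoint) receive the configured rescue shift where the rescuer is
altered, plus enriched features: extra shared PPI neighbors on an
Erdős–Rényi graph, paralogy, complex/pathway co-membership, shared GO
leaves on a 3-level random tree, shared compartments, co-expression, and
co-occurring alterations. Alteration evidence is written into the omics
layers (truncating mutations, ±2 copy-number calls, ±2.5 expression shifts)
so the calling module genuinely re-derives the states. `simulate_cohort()`
draws the six pair indicators Bernoulli(0.15), survival times exponential
with hazard ∝ RiskScore^scale (base median one year), independent
exponential censoring calibrated to a 30% rate, response probabilities
decreasing in risk, and TMB/neoantigen/cytolytic/immune expression higher
at low risk; non-signature genes are pure noise so the signature carries
all outcome signal.

The generator does **not** match real DepMap/TCGA marginal distributions,
mutual exclusivity structure, subclonality, or batch effects; passing tests
demonstrate that the machinery recovers planted signal under clean
conditions, not that the biological discoveries replicate. The moderate
enrichment preset is the default study condition; a documented strong
preset (`strong_feature_enrichment()`) is the condition for the
classifier-separability checks.

## Numerical choices and problem sizes

Exact small-sample tests (Fisher, Wilcoxon) are used when tie-free and
small, with normal approximation otherwise; BH correction is applied once
per declared family. The test suite and acceptance script run panels of
40–340 genes with 100–200 cell lines, cohorts of 120–500 patients, and
replicate counts of 60–200 per calibration check — sizes chosen so each
statistical claim is tested at adequate power on a single CPU. Degenerate
inputs fail loudly: zero overlapping samples, single-class labels, all-NA
feature columns, gene sets covering the whole matrix, all-censored cohorts
and constant covariates are errors, not silent results.

## Known limitations

The LOF/GOF calling thresholds and the exact 14-feature composition stand
in for unpublished detail and are therefore configurable rather than
canonical; co-occurring alteration can be computed on tumors or cell lines
(tumors by default); no information-content GO similarity, weighted PPI,
variant-effect prediction, allele-specific copy number, competing risks, or
deconvolution-based immune cell fractions are provided. Identifier
harmonization across sources is assumed to be symbol-level.
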