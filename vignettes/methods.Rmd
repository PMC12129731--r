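---
title: "Methods: differential phospho-/proteomics and minimal signature discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential phospho-/proteomics and minimal signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`phosphosig` analyses PBMC DIA-MS intensity tables from cohorts
stratified by LRRK2 mutation status. This vignette documents the
statistical models, the tunable parameters and their defaults, the
synthetic cohort the package uses in place of the original raw data,
and the design decisions taken where the underlying protocol left the
choice open.

## Preprocessing model

Both omic layers arrive as positive intensities with substantial
missingness. The proteome chain is: two-peptide filter → row
missingness filter → KNN imputation → log2 → quantile normalization.
The phospho chain is: site-level collapse → blank-column filter → row
missingness filter → KNN imputation → log2 → quantile normalization.

* **Peptide filter** (`min_peptides = 2`): proteins quantified by a
  single peptide sequence are too fragile for differential calls and
  are removed.
* **Missingness rules.** Feature rows are dropped when their missing
  fraction is **at or above** the cutoff (0.70 for proteins, 0.30 for
  collapsed sites); sample columns are dropped when **strictly above**
  0.70 blank. The strict/non-strict asymmetry is deliberate and
  mirrors the protocol wording for each rule; the 0.70 row cutoff
  keeps proteins detected in only one biological group, at negligible
  cost in rows relative to a 0.30 cutoff. The column rule exists to
  satisfy the KNN requirement of <80% blank columns.
* **Site collapse** (`localization_cutoff = 0.75`): phospho-peptide
  records are kept only when the PTM localization confidence is
  *strictly greater* than 0.75, grouped by (protein, residue,
  position), and aggregated per sample. The default aggregation is the
  **maximum** across contributing peptides — multiple peptides covering
  one site are overlapping evidence for the same stoichiometry, and
  summing would double-count shared signal. `sum` and `mean` are
  available via `site_aggregation`. Collapse runs before the row
  filter so the 30% rule applies to site-level rows.
* **KNN imputation** (`knn_k = 10`): neighbours are *feature rows*,
  not samples — with 10³–10⁴ features and ~10² samples, feature
  neighbourhoods are far better populated, and co-regulated features
  are the best predictors of a missing abundance. The distance is the
  root-mean-square Euclidean over co-observed samples (rescaling by
  the overlap count prevents sparsely overlapping rows from looking
  artificially close); donors are weighted by inverse distance.
  Observed cells are never altered, and `k` is clamped with a message
  when fewer neighbours exist. A row sharing no observed sample with
  any other row is an error naming the row, not a silent guess.
* **Quantile normalization**: each column's sorted values are replaced
  by across-column means of order statistics; within-column ties
  receive the mean of the target values they span, so permutation
  invariance holds exactly. The proteome is also quantile-normalized
  by default (`normalize_proteome = TRUE`): the differential analysis
  this package mirrors applied one quantile normalization to the
  proteome even though its stepwise protocol lists only the log2
  transform, and normalization is the safer default across centres.

## Moderated differential testing

For a contrast with (possibly pooled) sides A and B, pooled sides are
relabelled before fitting, group means are estimated per feature, and
the residual variance s²_g with d_g = n − 2 degrees of freedom is
shrunk towards a prior:

s̃²_g = (d₀·s²₀ + d_g·s²_g) / (d₀ + d_g),
t_g = Δ_g / (s̃_g·√(1/n_A + 1/n_B)),  t_g ~ t(d₀ + d_g) under the null.

The hyperparameters (d₀, s²₀) are estimated by moment-matching the
marginal distribution of log s²_g under a scaled-F model
(digamma/trigamma inversion, Newton iteration for the trigamma
inverse). When the trigamma equation has no positive solution the
prior is fully pooled (d₀ = ∞) with a log notice. `d0 = 0` reduces the
statistic to the ordinary pooled-variance t — both reductions are
exercised in the tests, and the whole fit is cross-checked against an
independent empirical-Bayes implementation on random matrices.

Design choices: the design matrix is a one-way group-means model with
no covariates (the analysis this mirrors adjusted for none); p-values
are two-sided; BH adjustment is applied within each contrast
separately; significance uses *strict* inequalities |log2FC| > 0.6 and
adjusted P < 0.05. A borderline reported hit at adjusted P = 0.05 can
be reproduced with `classify_hits(..., inclusive = TRUE)`; the strict
rule is the default because the stated criterion is "< 0.05" and the
boundary call is best read as a rounding artifact. The protocol's
"1.12 log₁₀" restatement of the 0.05 threshold is numerically
inconsistent (−log₁₀ 0.05 ≈ 1.30) and is ignored; the raw threshold is
used. The ANOVA screen feeding the ML stage uses **raw** p < 0.05 by
default (`anova_p_cutoff`): the signature-selection protocol states
P < 0.05 for the pre-selection even though the differential analyses
are FDR-adjusted, and a more permissive screen only widens the
candidate pool that RFE then prunes.

## Signature search

The classifier is a maximum-margin model (linear kernel, C = 1 by
default; the `grid_search_model()` helper searches kernels
{linear, RBF} × C ∈ {0.1, 1, 10}, with random forest and gradient
boosting as optional candidates). All scoring is **balanced accuracy**
(mean per-class recall), robust to the unbalanced group sizes.
Class imbalance is handled by SMOTE — synthetic minority points
interpolated uniformly between same-class k-nearest neighbours —
applied **strictly inside each training fold**; test folds contain
only original rows, asserted by row provenance in the tests. Folds are
stratified and fixed per run seed, so subset scores are paired across
the search.

The minimal-signature search is a Monte Carlo tree search over
add-feature actions plus an explicit STOP node:

* lookahead depth 5 (`depth`), budget `10 × |candidates|` tree
  evaluations per round (`trees_factor`);
* node selection by UCB1 with exploration constant √2 (a standard
  choice; the underlying protocol does not state one);
* a rollout's reward is the cross-validated balanced accuracy of the
  visited subset, memoized by subset key — without memoization the
  10× budget would be intractable;
* STOP's reward is the current subset's own score; the chain also
  halts when the best one-step improvement falls below
  `improvement_epsilon = 1e-3` ("no further improvement");
* every chain start (each candidate as first feature) is screened; all
  evaluated subsets scoring > 0.90 (`accept_threshold`) are collected,
  and refinement seeds a second search from the `refine_init = 5`
  most frequently represented features ("most prominently
  represented" is not quantified upstream; five matches the tree
  depth).

Within the pipeline, search rewards average **two** repeated
cross-validations (`n_reps = 2`): subset *selection* is far more
sensitive to fold-assignment luck than a single paired evaluation, and
single-assignment rewards let chance features displace planted ones.
The final signature is re-scored by `evaluate_signature()` on fold
assignments distinct from the reward folds — this held-out score is
the number reported, and under label permutation it sits at the 1/k
chance level, which the acceptance tests verify. Candidates enter the
search after ANOVA pre-selection and backwards RFE (drop the
lowest-importance 10% per iteration; importance = aggregated absolute
hyperplane weights for linear kernels, permutation importance
otherwise; score ties prefer the smaller set, then lexicographic), and
the pool is capped at the top `max_candidates = 10` by screen F
statistic to keep the subset lattice tractable on one CPU.

## Clinical correlation

Spearman's ρ (average ranks, tie-corrected) between each differential
feature and UPDRS-III motor scores, two-sided p from the t
approximation on n − 2 df, BH-adjusted within the tested set;
significant at |ρ| > 0.5 and adjusted P < 0.05, both strict. A
reported borderline correlate at ρ = 0.49 can be admitted with
`rho_inclusive_margin`; the default keeps the stated strict rule.
Constant features are skipped and reported, not silently dropped.

## The synthetic cohort

`simulate_cohort_data()` emulates the processed-data structure of the
motivating study so every stage is testable without any download:

* six groups at the post-QC sizes (32 / 22 / 13 / 7 / 39 / 42 = 155)
  across three centres with the study's centre split, ages, sex ratios
  and severity baselines;
* log-normal intensities (log2 mean 20, sd 2 across features — a
  typical DIA dynamic range; the source protocol describes no
  intensity distribution, so these are conventions exposed in the
  truth object);
* within-feature residual sd 0.7 (log2 units, scaled per feature by
  U(0.7, 1.3)). This is the one free noise knob: it was fixed so that
  the six planted informative features operate in the >0.90
  balanced-accuracy regime that the real 18-feature signature shows
  (per-class AUC ≈ 1.0), and was not revisited afterwards;
* planted effects: RAB12_S106 at +0.97 / +0.92 (manifesting /
  non-manifesting G2019S carriers, pooled ≈ 0.95), MON2_S205 at +1.25
  in non-manifesting carriers only, and shared down-regulated proteins
  ATIC (−0.97/−0.80), RAB9A (−1.17/−0.40), LAMP1 (−1.32/−1.10), SCLY
  (−1.58/0) — exactly the six features the recovery tests score
  against. Planted features get ≥2 peptides and upper-range baseline
  abundance, reflecting that headline biomarkers are robustly
  quantified;
* peptide counts are shifted-geometric with a 15% single-peptide
  fraction, so the two-peptide filter is exercised; 20% of phospho
  peptides carry low localization confidence (≤0.75), so collapse
  removes sites with only low-confidence evidence;
* missingness is MAR (5% proteome / 10% phospho) plus MNAR via a
  logistic in log-intensity with midpoint at the 10th percentile —
  low-abundance dropout; the mechanism upstream is undescribed, so
  this is a modelling convention;
* UPDRS-III scores are a group baseline plus a weighted planted-feature
  contribution plus noise, passed through a strictly increasing
  softplus to non-negative integers. The feature weight is calibrated
  per seed by root-finding so the *realized* Spearman ρ of each
  planted link matches its target (default: RAB12_S106 at +0.8) —
  calibrating on the realized ranks absorbs the rank distortion of
  rounding and the zero floor.

What the generator does **not** emulate: batch/centre effects beyond
group composition, peptide-level interference and ratio compression,
non-normal heavy-tailed intensity error, missingness that depends on
group, and correlated feature blocks. Passing recovery tests therefore
demonstrate that the machinery is correct and sensitive at realistic
effect-to-noise ratios — not that real data of this difficulty would
yield the same signature.

One RNG stream per artifact (sheet, matrix, missingness mask, scores,
folds) is derived from the master seed, so regenerating one artifact
never shifts another and identical (config, seed) runs are
byte-identical.

## Numerical choices and degenerate inputs

* Trigamma inversion by Newton iteration, 50-step cap, relative
  tolerance 1e-8; d₀ = ∞ handled as full pooling.
* Constant features: ANOVA F defined as 0 with p = 1; Spearman on a
  constant vector is an error (skipped and logged at the table level);
  a zero-variance column gets unit scale before classification.
* Quantile-normalization ties: mean of spanned target values, exact.
* KNN distances with zero overlap are infinite; a row with no finite
  distance and missing cells is an error naming the row.
* Tie-breaks are deterministic everywhere: grid search by declaration
  order, RFE and subset selection by score, then size, then
  lexicographic key; result files are sorted by adjusted p then
  feature id and serialized at 6 significant digits, so repeated runs
  are byte-identical.

## Problem sizes used by the tests

The default synthetic scale is 800 proteins and 1500 sites over 155
samples; the test suite's recovery loops use 20 seeds for the
differential/correlation checks and 10 seeds for the full signature
search, and the permutation floor uses 20 relabelings of a 90-sample,
3-class cohort — sizes chosen to make the Monte-Carlo bands in the
assertions tight while keeping a full run of the suite in the
minutes range on a single CPU. A "paper-scale" profile (3815 proteins,
10288 sites) is available through the pipeline wrapper.

## Known limitations

* The MCTS is stochastic search, not exhaustive optimization; the
  oracle-equivalence guarantee in the tests holds for small candidate
  pools with deterministic rewards.
* Balanced accuracy from the search path is optimistically biased;
  only the held-out re-evaluation should be quoted.
* The KNN imputer is O(p²) in features; at the paper-scale profile it
  is the slowest stage.
* No batch correction is applied (the mirrored protocol applied none
  beyond run randomization); centre-confounded signals would pass
  undetected.
* UniProt-style identifier disambiguation is out of scope; feature ids
  are taken as given (an optional local two-column mapping table can
  be applied upstream of the readers).
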