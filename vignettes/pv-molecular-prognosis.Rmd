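---
title: "Molecular prognostic modelling of polycythemia vera: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular prognostic modelling of polycythemia vera: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`pvhmr` implements a complete molecular-prognostic analysis pipeline for
polycythemia vera (PV) cohorts: panel-variant retention, mutation-landscape
and co-occurrence analysis, a three-tier genomic risk classification
(PV-HMR), an illness-death multistate survival model, and time-dependent
prognostic performance metrics. Because patient-level PV cohorts of this
kind are not publicly deposited, the package also ships a seeded synthetic
cohort generator that emulates the statistical structure of such a cohort;
every stage of the pipeline is exercised and tested against it.

The `analysis/` scripts at the repository root run the five stages in
order (simulate, landscape, classify, multistate, performance) and write
their tables under `results/`.

# Variant retention and the mutation matrix

Input variants are panel calls annotated with gene, effect class
(missense, nonsense, frameshift, splice, inframe), variant allele
frequency (VAF, percent of reads), pathogenicity class (pathogenic /
likely pathogenic / VUS) and a general-population minor allele frequency.
Retention applies three inclusive thresholds, all config-exposed
(`inst/extdata/pipeline_config.yaml`):

* `min_vaf = 2` — calls below a 2% VAF are treated as below the reliable
  detection floor of targeted panels;
* `common_maf = 1` — a population MAF of 1% or more marks a common
  polymorphism, removed regardless of annotation;
* `rare_vus_maf = 0.01` — a VUS with population MAF of 0.01% or more is a
  rare polymorphism, removed.

Only pathogenic and likely-pathogenic variants enter prognostic analyses.
Whether the VAF floor is applied before or after pathogenicity curation
does not change the retained set (the rules commute); both counts are
visible in step 2's log.

The mutation matrix aggregates a patient's variants per gene category.
TET2 and DNMT3A are split into truncating (nonsense/frameshift) versus
missense/other categories, since their truncating and missense lesions
show different biology and age associations. Per-category VAF is the
*maximum* across the patient's variants in the category: VAF proxies clone
size, and the largest clone is the prognostically relevant one (this is
also the reading that makes a "TET2 VAF ≥ 5%" rule well defined for
multi-hit patients). "Additional mutations" count retained non-driver
*variants*, not genes — two TET2 hits count as two — because multi-hit
patients are common enough to matter (about 6% of patients carry two or
more TET2 variants). The JAK2 driver never counts as an additional
mutation.

# Landscape and co-occurrence analyses

Pairwise association testing uses, by feature-type pair: the two-sided
exact test on the 2×2 table (odds ratio) for binary–binary; the Wilcoxon
rank-sum test with direction from the median shift for binary–continuous;
and Spearman rank correlation for continuous–continuous (VAF–VAF) pairs.
Rank-based tests were chosen because blood counts and VAFs are skewed and
the tests must be valid at small mutated-group sizes. q-values come from
Benjamini–Hochberg over the whole table; a `reported` flag marks rows at
p < 0.05 for figure-style displays, but the full table with q-values is
always written. Degenerate columns (a constant feature) yield a flagged
row with p = 1 rather than an error, so a sparse cohort never aborts the
table.

Gene co-occurrence structure is learned as a Bayesian network over the
binary presence matrix of categories mutated in at least `min_patients =
7` patients. The learner is greedy hill-climbing over single-edge
additions, deletions and reversals, scored by BIC for Bernoulli nodes with
tabular conditional distributions (one free parameter per parent
configuration, penalty `log(n)/2` each), starting from the empty graph,
with 5 seeded random restarts and lexicographic tie-breaking so results
are reproducible given the seed. Edge confidence is the fraction of
nonparametric bootstrap resamples (same algorithm) whose learned skeleton
contains the edge. Networks are learned on presence only; VAF–VAF rank
correlations are reported separately, because a principled joint
binary–continuous parameterisation would add assumptions the data cannot
check at this cohort size.

A known behaviour of score-based structure learning, verified during
development: on a fully independent generator the learner returns the
empty graph with high probability per node pair, but with ~90 pairs
(14 categories) the family-wise chance of one spurious edge is
substantial (roughly 40–50% at n = 2000). Bootstrap confidence is the
intended guard — chance edges earn low confidence. Tests therefore assert
the no-structure property at small panel size and assert exhaustive-search
optimality of the selected BIC for ≤3 nodes.

Hierarchical clustering of categories uses average linkage on the
distance `1 − |Spearman correlation|` between VAF profiles; constant
columns get distance 1 to everything and are flagged. Columns are
processed in lexicographic order so ties break deterministically.

# The PV-HMR classification

Classification is sequential per patient, from the retained prognostic
variants and CNV calls:

1. **high** — any mutation in SRSF2, IDH1, IDH2, EZH2 or NFE2; or ≥2
   additional (non-driver) mutations; or at least one CNV outside
   chromosome 9;
2. **intermediate** — otherwise, TET2 mutation with maximum VAF ≥ 5%;
3. **low** — otherwise.

All thresholds inclusive; the gene set and TET2 cutoff are arguments.
CBL is *not* in the default high-risk set: the classifier definition and
the forest-plot grouping disagree on CBL in the source material, and the
classifier definition was taken as authoritative; passing
`hmr_genes = c(..., "CBL")` restores the other reading. "Non-9p CNV"
means any region not on chromosome 9, so 9pUPD and 9p trisomy never
trigger the rule — chromosome 9 gains/UPD amplify the JAK2 driver and are
near-ubiquitous in PV rather than markers of clonal progression. A TET2
variant counts toward the ≥2-mutation rule like any other non-driver
variant.

Comparator scores (IWG-PV, MIPSS-PV) run on a generic rule-engine
(`score_rule_based()`): ordered criteria of (field, operator, value,
points) summed and bucketed by strictly increasing cut-points. Their
component weights come from the literature that defined them, not from
this package's analyses; the shipped YAML configs are marked to be
verified against the defining publications.

# The illness-death multistate model

States are 1 = chronic phase, 2 = hematologic transformation (secondary
myelofibrosis or MDS/AML), 3 = death. Each patient contributes cause-
specific rows for 1→2 and 1→3 over the chronic phase, and transformed
patients a 2→3 row. Modelling choices:

* **Clock**: time since diagnosis for all transitions (clock-forward
  Markov); the 2→3 model enters patients at their transformation time via
  left truncation. This keeps all hazards on one interpretable time scale.
* **Ties**: Breslow by default (matches the brute-force partial-likelihood
  oracle used in tests); Efron available via `ties = "efron"`.
* **Competing events**: cause-specific censoring — a 1→2 row is censored
  at death and vice versa.
* **Estimation**: Cox partial likelihood with left truncation and Breslow
  baseline cumulative hazard, Wald confidence intervals. Monotone
  likelihood (perfect separation) is detected and reported as an error
  naming the covariate, not silently returned as a huge coefficient.
  A null model (`covariates = NULL`) returns the Nelson–Aalen baseline.
* **Selection**: stepwise backward by Wald p at `alpha = 0.05` per
  transition, dropping the worst p first; ties (to 10 decimals) break by
  covariate name; non-identifiable terms drop first. Only the selection
  criterion is fixed here — the source analyses name downward selection
  without a criterion, and Wald-at-0.05 is the simplest reproducible one.
* **Occupation probabilities**: Aalen–Johansen product-integral over the
  interval data. Probabilities sum to 1 at every jump by construction and
  this is asserted to 1e-10 in tests.

Continuous covariates enter untransformed (age per year — the final model
reports hazard ratios per year of age); binary covariates as 0/1.

# Performance metrics

The metric suite fixes estimators that the cited methodology leaves
unnamed, choosing the standard survival-metrics forms:

* **Harrell's C** over censoring-usable pairs with 0.5 credit for risk
  ties;
* **cumulative/dynamic AUC(t)**: cases are events by t, controls are
  at-risk past t, IPCW-weighted (case weight `1/G(T−)`, control weight
  `1/G(t)`) with the censoring distribution G estimated by Kaplan–Meier
  on the whole sample;
* **Graf IPCW Brier score** with the same weights; subjects censored
  before the horizon get weight 0.

Horizons default to 6, 10 and 14 years. A horizon where G reaches 0 is
reported unevaluable rather than extrapolated. For the transformation
endpoint, death before transformation is treated as cause-specific
censoring; this overstates absolute risk when competing mortality is
heavy, which is acceptable for the *ranking* metrics used here, and the
Aalen–Johansen machinery is available for a competing-risk treatment of
absolute risks. Categorical models get predicted event probabilities from
per-category Kaplan–Meier curves; Cox models from
`1 − exp(−Λ₀(t)·exp(lp))`.

# The synthetic cohort generator

The generator is the package's stand-in for a request-only cohort; it
emulates the published cohort's *statistical structure*, not any
patient's data. Components (defaults in `default_sim_config()`; values
taken from the published cohort description are tagged `[PUBLISHED]` in the
source, the rest `[ASSUMED]`):

* **Mutation presence**: ancestral sampling from a DAG of Bernoulli
  conditionals. The default DAG encodes the qualitative co-occurrence
  structure (ASXL1 enriched given TET2; EZH2 and SRSF2 given ASXL1;
  IDH1/2 given SRSF2; BCOR given DNMT3A) with marginals set so that the
  share of patients with ≥1 additional mutation is ≈53% and with ≥2 is
  ≈23%. A second same-gene variant is drawn with probability 0.30 for
  TET2 (multi-hit TET2 in ≈6% of the cohort) and 0.05 elsewhere.
* **VAF**: per-gene two-component mixture on [2, 95]% — a low-clone
  component (2–20%) and a high-clone component centred near 40% — with
  gene-specific weights: mostly-low for DNMT3A and NFE2, mostly-high for
  IDH2 and SRSF2, balanced (bimodal) for TET2 and ASXL1.
* **CNV**: per-region Bernoulli draws; 9pUPD at 45%, the non-9p regions
  collectively ≈1.6%.
* **Clinical covariates**: age normal(66, 15.5) truncated to [18, 95]
  (median 66, IQR ≈ 55–76); 59% male; leukocytes, platelets and
  neutrophil/lymphocyte ratio log-normal with ≈48% of leukocyte counts
  ≥ 11 G/L; thrombosis histories at the published counts; one JAK2
  driver per patient (98% V617F) with driver VAF ≈ 37.6 ± 22%.
* **Outcomes**: competing 1→2 / 1→3 times by inversion of constant
  (optionally Weibull) cause-specific cumulative hazards times
  `exp(linear predictor)`; the linear predictors carry the genomic-group
  effects at the final-model hazard ratios (5.42 and 3.51 on 1→2 for
  high and intermediate; 1.92 on 1→3 for high) and age effects (1.07 and
  1.09 per year). If transformation comes first, the 2→3 time is drawn
  left-truncated at the transformation time on the same clock.
  Censoring is administrative at 20 years plus independent exponential
  noise. Baselines (0.0042, 0.014, 0.30 per year) were calibrated once so
  the defaults reproduce the published outcome mix (≈31% deaths, ≈10%
  transformations, median follow-up ≈8 years).
* **Determinism**: the seed is mandatory; random-number streams are split
  per component (mutations / CNV / clinical / outcomes) so toggling one
  block does not shift the others; identical seeds give byte-identical
  output files.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequencing noise and panel-specific artefacts;
clonal architecture and order of mutation acquisition; treatment effects
on outcomes; correlation between clinical covariates (age and blood
counts are drawn independently); non-proportional hazards or time-varying
effects; and cohort-specific enrolment patterns. Parameter-recovery
results demonstrate that the *fitting machinery is correct under the
generating model*, not that the generating model is true of PV.

# Parameter recovery and problem sizes

`simulate_hr_recovery()` is the recovery engine: it simulates seeded
replicate cohorts with a known group effect on one transition, refits the
transition-specific Cox model per replicate, and reports the mean fitted
hazard ratio. `scripts/acceptance.R` runs it at the final-model effect
sizes (5.42, 1.92, 3.51) with 100 replicates of n = 1500, ~15% high-risk
(and 10% intermediate where applicable) and ~30% random censoring. The
mean of replicate hazard ratios carries a small upward Jensen bias
(≈ exp(Var(β̂)/2), about 1–3% at these event counts), which is inherent to
averaging on the ratio scale and well inside the tolerances used.

Test-suite problem sizes were chosen to make each stochastic assertion's
own false-alarm rate small at a few tens of seconds of runtime: n = 10000
for closed-form occupation checks (2-percentage-point bands are then ≈4
standard errors), 60 replicates of n = 700 for Wald-interval coverage,
and 30 replicates for the empty-network property (true rate ≈98%,
asserted ≥27/30).

# Known limitations

* The Bayesian network is learned on presence/absence only and its
  directionality is an artefact of score equivalence; only the skeleton
  and bootstrap confidences should be interpreted.
* The comparator score configurations are conveniences for benchmarking
  the engine, not validated reconstructions of the published scores.
* Cause-specific metrics for the transformation endpoint ignore competing
  mortality in absolute terms (see above).
* The generator's independence assumptions between clinical covariates
  make the synthetic cohort easier to model than a real one; external
  validation on real cohorts is out of scope here.
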