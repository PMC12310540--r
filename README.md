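# pvhmr — molecular prognostic modelling of polycythemia vera

Polycythemia vera (PV) is a JAK2-driven myeloproliferative neoplasm. Beyond
the canonical driver, patients may carry additional somatic mutations
(most often in TET2, DNMT3A and ASXL1), and these additional lesions carry
prognostic information about the two complications that shape survival:
hematologic transformation (secondary myelofibrosis or MDS/AML) and death.
`pvhmr` implements, as a tested R package plus a numbered analysis
workflow, the full molecular-prognostic pipeline for such cohorts:

* **Variant retention** — inclusive thresholds (VAF ≥ 2%, common
  polymorphisms with population MAF ≥ 1% removed, VUS with MAF ≥ 0.01%
  removed), pathogenic/likely-pathogenic prognostic subset, and a
  patients × gene-category mutation matrix (TET2/DNMT3A split by
  truncating vs missense, per-category maximum VAF, per-variant
  "additional mutation" counts).
* **Landscape & co-occurrence** — landscape summaries, pairwise
  mutation–clinical association tests with Benjamini–Hochberg correction,
  a BIC hill-climbing Bayesian network over mutation presence with
  bootstrap edge confidence, and hierarchical clustering of genes on VAF
  profiles.
* **PV-HMR classification** — the sequential three-tier genomic risk
  classifier: **high** if SRSF2/IDH1/IDH2/EZH2/NFE2 mutation, ≥ 2
  additional mutations, or a non-chromosome-9 CNV; else **intermediate**
  if TET2 VAF ≥ 5%; else **low**. Plus a generic rule-based score engine
  hosting IWG-PV / MIPSS-PV comparator configurations.
* **Illness-death multistate model** — states chronic → transformation →
  death, cause-specific transition rows with left truncation,
  transition-specific Cox models (Breslow ties), stepwise backward
  selection, Aalen–Johansen state-occupation probabilities, Kaplan–Meier.
  The per-transition hazard for patient *i* is
  `λ_k(t | x_i) = λ0_k(t) · exp(β_k' x_i)` on the time-since-diagnosis
  clock for every transition *k*.
* **Performance metrics** — Harrell's C, IPCW cumulative/dynamic AUC(t)
  and Graf IPCW Brier score BS(t) at 6/10/14-year horizons, with a
  multi-model comparison report.
* **Synthetic cohort generator** — a seeded clinical-genomic simulator
  (mutation DAG, per-gene VAF mixtures, CNV rates, clinical covariates,
  competing-risk event histories) that emulates the statistical structure
  of a 439-patient PV cohort, used by every test and by the
  parameter-recovery engine.

See `vignettes/pv-molecular-prognosis.Rmd` for the methods account.

## Worked example

The analysis workflow runs in order:

```sh
Rscript analysis/01_simulate.R     # draw the synthetic cohort
Rscript analysis/02_landscape.R    # retention, matrix, associations, network
Rscript analysis/03_classify.R     # PV-HMR groups + comparator scores
Rscript analysis/04_multistate.R   # transition Cox fits + stepwise + AJ
Rscript analysis/05_performance.R  # C / AUC(t) / Brier(t) comparison
```

Step 1 prints the cohort headline (439 patients; median age 66; 59% male;
34.2% died, 11.6% transformed; median follow-up 8.8 years). Step 2 logs
the retention funnel (1073 raw calls → 810 retained, all
pathogenic/likely-pathogenic) and the burden summary — 52.6% of patients
with ≥ 1 additional mutation — and learns a 13-node network with 4 edges.
Step 3 partitions the cohort (267 low / 53 intermediate / 119 high).
Step 4's stepwise multistate fit keeps the genomic groups and age on the
chronic→transformation transition and prints, for this cohort draw:

```
1->2: kept {age_c, group_high, group_intermediate}
  age_c                  HR 1.07 [1.04-1.09], p = 1.76e-08
  group_high             HR 3.70 [2.01-6.79], p = 2.52e-05
  group_intermediate     HR 2.50 [1.09-5.75], p = 0.0314
1->3: kept {age_c, group_high}
  age_c                  HR 1.09 [1.07-1.11], p = 1.01e-22
  group_high             HR 1.63 [1.08-2.45], p = 0.0195
```

i.e. single-cohort estimates of the effects the generator planted
(5.42 / 3.51 on transformation, 1.92 on death, 1.07 / 1.09 per year of
age), each within its confidence interval. Step 5 reports that on this
cohort the genomic model has the best transformation discrimination
(C 0.72 vs 0.64 / 0.62 for the comparators; AUC 0.76/0.72/0.74 at
6/10/14 y) while the age-heavy IWG-PV comparator wins on overall
survival — the qualitative pattern expected when genomic lesions drive
transformation and age drives death.

In code, the core loop is:

```r
library(pvhmr)
co   <- simulate_cohort(default_sim_config(n = 439, seed = 1))
prog <- prognostic_subset(filter_variants(co$variants))
grp  <- classify_pv_hmr(prog, co$cnv, co$clinical$patient_id)

cl <- co$clinical
cl$group_high         <- as.integer(grp$genomic_group == "high")
cl$group_intermediate <- as.integer(grp$genomic_group == "intermediate")
cl$age_c              <- cl$age_dx - 66
ms <- to_multistate(cl)
fit_cox_transition(ms, "1->2", c("group_high", "group_intermediate", "age_c"))
```

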