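---
title: "Modeling comorbidity risk between chronic physical illness and mental health disorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling comorbidity risk between chronic physical illness and mental health disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorisk)
```

## The problem

Chronic physical illnesses (hypertension, diabetes, heart failure, ...)
and mental health disorders co-occur far more often than chance, and the
physical condition frequently precedes the psychiatric diagnosis.
`comorisk` implements a trajectory-based analysis of this comorbidity
from longitudinal hospital admission records coded in ICD-10: it asks
which chronic physical diagnoses, observed *before* any mental-disorder
code appears in a patient's record, predict the subsequent appearance of
one, and how strongly each (physical, mental) category pair co-occurs at
the population level.

The pipeline has five stages, each usable on its own:

1. **Code catalog** — normalize raw ICD-10 codes to 4-character
   resolution and map them to named disease categories flagged
   *physical* or *mental*.
2. **Cleaning and prevalence** — apply the cohort filters, tabulate
   per-category prevalence, and keep categories at or above a prevalence
   threshold (1% by default).
3. **Trajectory labeling** — turn each patient's chronologically ordered
   admissions into labeled classification instances that respect
   temporal order.
4. **Classifier bank** — train four tree ensembles on those instances
   and intersect their top-10 feature importances to nominate risk
   diseases.
5. **Comorbidity intensity** — compute relative risk and the phi
   coefficient for (risk physical, mental) category pairs, overall and
   within sex and sex-by-age strata.

A seeded synthetic cohort generator with *planted* comorbidity structure
replaces the private hospital data for validation: every statistic the
pipeline produces can be checked against the known generating values.

## Code normalization and the category catalog

ICD-10 exports are messy: casing varies, decimal points are dropped,
codes carry more specificity than analyses need, and wildcard forms like
`I10.x` appear. `normalize_code()` reduces every code to at most
letter + two digits + one decimal digit (`E78.51` becomes `E78.5`,
`i10.x` becomes `I10`); normalization is idempotent and rejects
malformed strings by name.

The catalog maps normalized codes to categories through three member
token kinds — exact codes (`I50.9`), 3-character prefixes (`N40`, which
also claims `N40.0`–`N40.9`), and inclusive ranges (`F00-F09`,
`F51.0-F51.3`). Exact members win over prefixes, which win over
range-derived membership. Validation enforces that mental members lie in
the F chapter, physical members do not, and no code is claimed by two
categories of the same class; an unmatched code is a legitimate outcome,
not an error.

The bundled default catalog carries the 11 mental-disorder groups and
the named chronic physical illness categories of a regional
mental-health inpatient cohort. Code memberships are shipped only for
the physical categories attested by the reported risk-disease rankings
(12 codes in 10 categories); the remaining physical categories are
present by name with open member lists, because inventing code ranges
the source material does not state would silently change every
downstream count. Users with fuller local mappings supply their own
catalog CSV (`category, klass, members`).

## Cleaning and prevalence

`clean_records()` applies, in order: deletion of rows with missing age,
sex, or codes (no imputation — admission records are near-complete and
deletion is unbiased at these missingness levels; a warning fires if
more than 5% of rows drop), removal of exact duplicate rows, and removal
of patients left with fewer than two admissions (a trajectory needs at
least one consecutive pair). The report tallies every drop reason and
the record-level retention percentage, so the cleaning funnel of any
dataset is auditable.

Duplicate *diagnoses* — the same category recorded at several
hospitalizations — are deliberately **not** removed from the records:
the admission sequence is needed for trajectory labeling. Instead, all
patient-level statistics (`prevalence()`, `patient_categories()`, the
pair counts) count each patient at most once per category.

Prevalence is the fraction of distinct patients carrying at least one
member code anywhere in their trajectory. `apply_inclusion_filter()`
compares the *unrounded* prevalence against the threshold, so a category
at exactly 1.00% is included. Age bands are half-open and
lower-inclusive — `[0,18)`, `[18,45)`, `[45,60)`, `[60,80)`,
`[80,Inf)` — because the printed band labels (0-18, 18-45, ...) overlap
at their boundaries and a partition is required; the direction of the
convention is arbitrary and documented here. A patient's stratum age is
the age at the first cleaned admission, which anchors the trajectory.

## Trajectory labeling

For each patient, consecutive admission pairs $(r_k, r_{k+1})$ are
scanned from the first record. While $r_k$ contains no target-category
code, an instance is emitted with label 1 if $r_{k+1}$ contains a target
code and 0 otherwise; emission stops at the first positive label or when
records are exhausted. Consequences of this rule:

* each patient contributes at most one positive instance;
* patients whose *first* record already carries the target contribute
  nothing (their pre-onset history is unobserved) — they are excluded
  and counted;
* a patient with no target anywhere contributes a chain of negatives.

The default target is "any mental disorder" (the union of the mental
categories passed in, typically the eight retained by the 1% filter);
per-category targets are supported. Feature sets are the non-target
codes of $r_k$ (`feature_mode = "single"`, the default and the most
literal reading of using the record as the feature) or the running union
of non-target codes up to $r_k$ (`"cumulative"`, provided because
trajectory language suggests accumulating history). Codes mapping to a
target category are excluded from features, and the exclusion is
asserted on every build as a leakage guard.

`prune_rare()` drops codes present in fewer than 5 instances (sparse
features invite overfitting), then drops instances left empty. The
patient-level split (70/30 by default, stratified on the patient's
label) guarantees that no patient contributes to both sides; the
vocabulary is fixed at the pruning step, before the split, following the
stage order of the dataset construction. `vectorize()` produces a
multi-hot code matrix plus `age` and `sex` (male = 1) columns in stable
order.

## The classifier bank

Four tree-ensemble families are trained with fixed published defaults:

| family | backend | defaults |
|---|---|---|
| `random_forest` | ranger | gini, mtry = sqrt(p), 500 trees, balanced class weights |
| `extra_trees` | ranger (extratrees, no bootstrap) | 500 trees, balanced class weights |
| `hist_gradient_boosting` | xgboost (`tree_method = "hist"`, leaf-wise) | depth 5, 31 leaves, eta 0.01, alpha 0.9, lambda 1, 5000 rounds, unbalance scaling |
| `regularized_gradient_boosting` | xgboost | depth 6, eta 0.01, 5000 rounds, colsample 0.4, subsample 0.8 |

Hyperparameter keys are given in each tool's conventional names and
mapped through a translation table; an unsupported key is an error,
never silently dropped. There is no default tuning grid — the defaults
are fixed values — but a user-declared grid is selected over by 5-fold
cross-validated F1 (a single selection criterion across families).
Class imbalance is addressed by random duplication of minority
instances, applied inside training folds and the final training set
only; evaluation data are never resampled. Training is deterministic
for a fixed seed (single-threaded backends, seeded RNG).

Metrics follow the standard confusion-matrix formulas; ratios with zero
denominators are reported as `NA` rather than 0. AUC uses the rank
(Mann–Whitney) formulation with mean ranks for ties, and the reported
optimal threshold maximizes Youden's J with ties broken toward higher
specificity (the J criterion is our choice; "optimal threshold" is not
otherwise pinned down).

Feature importance uses each family's native measure: mean impurity
decrease for the forests, total gain for the regularized booster, and
the integer split count per feature for the histogram booster. Ties are
broken lexicographically so rankings are reproducible. The *consensus*
intersects the four top-10 code sets (core risk codes) and unions them
(extended set), then maps codes to categories through the catalog.
`example_rankings()` bundles four such top-10 rankings as a worked
example; their union spans 12 codes in 10 categories and their
intersection 8 codes in 7 categories.

A caveat worth stating: split-count importance structurally favors
features that admit many distinct splits — continuous age, common
binary codes — over rare binary codes, however informative. In
validation experiments a planted code must therefore be reasonably
prevalent (roughly 20% and up at these sample sizes) before the
histogram booster's split count ranks it alongside the other three
families' measures. This is a property of that importance measure, not
of the planted signal.

## Comorbidity intensity

For categories $i$ and $j$ with patient-level counts $C_{ij}$ (both),
$P_i$, $P_j$ (each), and cohort size $N$:

$$RR_{ij} = \frac{C_{ij}\,N}{P_i\,P_j}, \qquad
\Phi_{ij} = \frac{C_{ij}N - P_iP_j}
{\sqrt{P_iP_j(N-P_i)(N-P_j)}}.$$

$RR$ is observed co-occurrence over the expectation under independence
(equivalently the incidence ratio $(C/P_i)/(P_j/N)$), and $\Phi$ is
identical to the Pearson correlation of the two binary patient
indicators — both identities are exercised as test oracles. Pairs with
a degenerate margin ($P \in \{0, N\}$) are undefined and carried with a
reason code instead of NaN. Screening excludes pairs with $RR \le 1$ or
$\Phi \le 0$ (mutually exclusive or independent combinations), flags
$RR > 1.2$ and $\Phi > 0.1$ as high intensity, and ranks by RR with
$\Phi$ as tiebreaker. No multiple-testing adjustment is applied, by
design, matching the descriptive screening character of the analysis.

`stratified_analysis()` repeats the computation within the full cohort,
each sex, and the 10 sex-by-age strata, each with its own $N$ — the
stratum-specific baseline is what lets an association confined to, say,
men aged 45–60 surface only there. Strata below a configurable minimum
size (default 50 patients; permissive because even pediatric strata are
reportable) are skipped with a message.

## The synthetic cohort generator

`cohort_spec()` fixes the study conditions; `generate_cohort()` draws a
deterministic cohort from them. Per patient: a sex/age-band cell from
the 10-cell weight vector (defaults are the published cell counts of a
46,649-patient cohort), independent physical-category indicators,
mental-category indicators at the baseline rate or at the planted
conditional rate given the planted physical parent, and an admission
count of $2 + \mathrm{Geom}(0.4)$ capped at 12. Default mental
baselines are the published prevalences of the eight retained mental
categories. Physical prevalences are not published, so the defaults are
plausible chronic-disease scales for an older inpatient cohort
(hypertension 0.25 down to prostate disease and other metabolic disease
at 0.05), chosen once and kept. Three default planted pairs emulate the
scale of the strongest reported physical-mental combinations
(closed-form RR about 2.0, 1.6 and 1.5).

Planted effects are parameterized as conditional probabilities rather
than RR so the implied population RR has the closed form

$$RR = \frac{p(j\mid i)}{p_i\,p(j\mid i) + (1-p_i)\,p(j\mid\neg i)}$$

(`expected_rr()`), making parameter recovery exact in expectation. The
temporal layout enforces the structure the labeling presumes: each
patient with any mental category receives a uniformly drawn onset
admission (from the second onward); physical codes are placed strictly
before onset, mental codes from onset onward, and dates increase
strictly. One representative code stands in for each category — the
statistics operate at category level, so within-category code
multiplicity is irrelevant. Admissions that draw no disease code carry
a neutral uncatalogued code (`Z00`).

What the generator does *not* emulate: age- or sex-dependent disease
prevalence, correlated physical conditions, seasonality, realistic
lengths of stay, code multiplicity within categories, or coding error.
Passing tests on synthetic cohorts therefore demonstrate that the
estimators recover known planted structure under clean conditions — not
that the pipeline is robust to real-world EHR pathologies.

## Problem sizes, tolerances and numerical choices

* Parameter recovery of planted RR is checked at 50,000 patients
  against a 5% relative-error band, and at 4,000 patients (the cohort
  shared across the fast tests) against a 25% band, about 2.5 standard
  errors for the smallest planted cell there.
* The classifier-bank detection experiment uses roughly 22,000 labeled
  instances from a 10,000-patient cohort with three strong, well
  supported planted effects (prevalence 0.25–0.30, conditional
  contrast 0.45 vs 0.035) in three different mental categories, labeled
  against their union; one planted parent per mental category keeps
  `expected_rr()` well defined.
* The phi/Pearson identity is asserted to 1e-12 over 1,000 random small
  cohorts; AUC is asserted equal to exhaustive pair counting on
  fixtures up to 50 instances.
* End-to-end determinism is asserted by digest equality of every output
  file over two pipeline runs at the same seed.
* All RNG flows from explicit seeds; functions that draw randomness
  save and restore the caller's RNG state.

## Interfaces

The canonical input is a long CSV, one row per admission
(`patient_id, sex, age, admit_date, discharge_date, codes` with
semicolon-separated codes); a wide dialect with `diag1..diag16` columns
is converted on read. `run_pipeline()` executes the configured stages
and writes every table (cleaning report, prevalence, instances and
vocabulary, per-model metrics/importances/ROC points, consensus, pair
tables full and stratified) plus a manifest with file digests. A thin
command-line wrapper (`inst/cli/comorisk.R`) exposes `simulate` and
`run`; the per-stage operations are reached through the config's stage
toggles rather than separate subcommands, since each stage is a plain
exported function.

## Known limitations

* The default catalog's physical code map covers only the attested
  codes; analyses of other physical categories require a user catalog.
* Split-count importance for the histogram booster under-ranks rare
  informative binary codes (see above).
* The labeling uses admission order only; inter-admission gaps and
  time-to-event structure are out of scope.
* Synthetic validation bounds what the tests can show about real EHR
  data (see the generator section).
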