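---
title: "Pattern-based classification of binned serum mass spectra with ladmass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-based classification of binned serum mass spectra with ladmass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladmass)
```

## The problem and the method

`ladmass` implements logical analysis of data (LAD), a two-class
classification methodology rooted in Boolean function theory and
combinatorial optimization, for binned mass-spectral intensity profiles.
The motivating application is serum proteomics of chronic kidney disease:
SELDI-TOF spectra of patients whose glomerular filtration rate declines
rapidly ("rapid progressors", the positive class) versus slowly ("slow
progressors", the negative class), with the goal of a small, interpretable
panel of m/z peaks whose joint intensity thresholds predict the progression
phenotype.

LAD proceeds in five stages, each exposed as a package function and
orchestrated by `lad()`:

1. **Discretization** (`find_cutpoints()`, `binarize()`). Each numeric
   feature is converted to threshold indicators `value >= c`. Candidate
   cutpoints are midpoints between consecutive distinct observed values and
   only *essential* cutpoints are kept: those across which the class
   composition changes. A value observed in both classes generates
   cutpoints on both of its sides. This is the standard LAD construction;
   it loses no ability to separate opposite-class observations (a property
   the test suite verifies against a brute-force check).
2. **Support-set selection** (`greedy_support_set()`,
   `exhaustive_support_set()`). From the binary features, a small
   ("irredundant") subset is chosen that still distinguishes every
   (positive, negative) patient pair. This is a set-cover problem over the
   pair universe; the package uses greedy cover with lowest-column-index
   tie-breaking followed by a reverse-order redundancy prune. An exact
   enumeration solver is provided as a reference oracle for small
   instances (guard: 25 binary features); on real panels the greedy solver
   is the practical tool and the exact solver certifies its behaviour in
   tests.
3. **Pattern generation** (`enumerate_patterns()`). Patterns are signed
   conjunctions of threshold literals. Degree-2 enumeration pairs literals
   on two distinct features, matching the convention that a combinatorial
   biomarker couples two masses. Each pattern is scored by *prevalence*
   (fraction of own-class patients covered) and *homogeneity* (fraction of
   covered patients that are own-class); both are exact integer ratios.
   Enumeration is exhaustive over the induced literal space — no pruning —
   so its output is checkable against naive literal-pair enumeration;
   model economy is the next stage's job.
4. **Classification** (`select_model()`, `discriminant()`). Per sign, a
   greedy minimum cover of the own-class patients selects a small pattern
   model (ties: homogeneity, then prevalence, then lexicographic literal
   order; then a reverse prune). For a model with `P` positive and `N`
   negative patterns, a patient covered by `p` and `n` of them has
   discriminant `delta = p/P - n/N` in `[-1, 1]`; the sign predicts the
   class and `delta = 0` is reported as *unclassified*, never silently
   assigned. The risk score `(delta + 1)/2` rescales `delta` to `[0, 1]`
   for quantile risk stratification (`risk_groups()`) and ROC analysis
   (`lad_auc()`).
5. **Cross-validation** (`lad_cv()`). Repeated stratified k-fold CV refits
   the *entire* pipeline — cutpoints, screen, support set, patterns, model
   — on every training split, so reported accuracy, sensitivity and
   specificity are free of test-set leakage.

Before stage 2 a **degree-1 screen** (`degree1_feature_filter()`) discards
features that carry no single-threshold pattern with homogeneity and
prevalence of at least 80%/80%, the conventional screen for this kind of
serum panel; only surviving features enter support-set selection.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `filter_homogeneity`, `filter_prevalence` | 0.8 / 0.8 | degree-1 screen thresholds (proportions) |
| `pattern_homogeneity`, `pattern_prevalence` | 0.75 / 0.3 | candidate thresholds for model patterns |
| `max_degree` | 2 | literals per pattern |
| `binning_spec()` | [500, 12000] Da, 2 Da | bin grid; 5,751 features |
| standard m/z, window | 5,734.5 Da, ±10 Da | insulin-like internal standard detection |
| `k`, `repeats` | 10 / 10 | CV folds and rerandomizations (100 tests) |

The candidate thresholds are deliberately laxer than the screen: final
two-mass patterns in panels of this kind average well below 80% prevalence
per pattern, so a 0.8 prevalence floor at the candidate stage would empty
the pool. Homogeneity 0.75 keeps candidates decision-relevant while
allowing the greedy cover to reach every training patient.

## Design choices where the design was open

**Bin convention.** Bin centers sit on the grid `low, low + w, ..., high`
(inclusive), each bin covering `[c - w/2, c + w/2)`. This is the only
half-open centered convention that yields 5,751 features for [500, 12000]
at 2 Da, so it is fixed and stated. Multiple peaks landing in a bin are
*summed*, preserving total ion intensity.

**Boundary rule.** Binary features use `value >= cutpoint`. Cutpoints are
midpoints of distinct observed values, so ties cannot occur on training
data; the rule only matters for new data and is fixed for determinism. The
`< c` literal is the stored column's complement, so only `>=` columns are
materialized.

**Degree-2 literal space.** Pairs combine literals on two distinct
features. Two thresholds on the same feature would encode an interval
condition, which is outside the two-mass biomarker idiom this package
targets.

**Unclassified observations.** `delta = 0` is surfaced as its own
category. For accuracy/sensitivity/specificity the default policy counts
unclassified patients as misclassified (the conservative choice);
`classification_metrics(..., unclassified = "exclude")` gives the
alternative, and the unclassified count is always reported.

**Screen relaxation.** On weakly structured data (and on label-permuted
null data) the 0.8/0.8 screen can retain nothing, which would make the
later stages infeasible. `lad()` therefore relaxes both screen thresholds
deterministically (multiplicative 0.9 steps, floors at 0.5/0.1); if even
the floor retains too little, the best `max_filter_features` features by
degree-1 screening margin are used. The thresholds actually applied are
recorded on the fit (`fit$filter`), so a relaxed fit is visible, not
silent.

**Coverage repair.** The model invariant is that every training patient is
covered by at least one own-sign pattern. If the thresholded candidate
pool misses a patient, the best pattern covering that patient (highest
homogeneity, then prevalence, over the support-set features; the pair
search is bounded to the 40 purest literals satisfied by the patient) is
added to the pool before greedy selection. This observation-driven step is
standard LAD practice and guarantees feasibility unless a positive and a
negative patient are identical on every feature — in which case the fit
fails loudly and, inside CV, is recorded as a failed fold.

**AUC interval.** The AUC is the Mann–Whitney probability with ties
counted one half. No single interval convention dominates this
literature, so the default is the Hanley–McNeil normal approximation,
labeled as such in the output, with a seeded bootstrap alternative.

**CV dispersion.** The summary reports both the standard deviation over
all `k * repeats` fold records and the standard deviation of the
per-repeat means. The two conventions differ by roughly a factor of
`sqrt(k)` and published tables rarely say which was used; emitting both
avoids guessing.

## The synthetic cohort generator

Since no public serum panel accompanies this methodology, the package
ships a generator (`simulate_cohort()`) whose defaults encode the study
conditions the pipeline is meant for: 57 positive ("rapid") and 59
negative ("slow") patients, duplicate runs, an insulin-like internal
standard at m/z 5,734.5 with per-run intensity drawn from a zero-truncated
normal with mean 28.96 and sd 2.02, raw emission over [0, 20000] Da later
truncated to [500, 12000] by binning, about 200 peak positions shared
across the cohort, and seven planted discriminative masses, five of them
enriched in the slow class (discriminative serum peaks in this disease
area are mostly *elevated in slow progressors*).

The intensity model is deliberately minimal:

* base intensities across peak positions are log-normal
  (`meanlog = log 3`, `sdlog = 0.7`), giving the right-skewed intensity
  spread of real spectra;
* per-patient biological variation is additive Gaussian (`noise_sd`,
  default 0.6 intensity units), shared by a patient's replicates, so that
  a planted additive effect is recovered *exactly* at `noise_sd = 0`;
* replicate noise is additive Gaussian with variance solved in closed form
  from the target between-replicate Pearson correlation `r`:
  `var_rep = var(latent) * (1 - r)/r`, so the expected within-patient
  correlation across peaks equals `r` (default 0.82; the generator's
  calibration is tested at ±0.05 over 116 patients). `r = 0` would need
  infinite noise, so the admissible range is `(0, 1]`.

What the generator does *not* emulate: baseline drift, detector
saturation, mass-dependent resolution, peak-shape effects, or correlated
biology between peaks. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline recovers planted threshold structure under
realistic noise and replicate correlation — not that any particular
clinical panel will reach a given accuracy.

## Numerical notes and degenerate inputs

* Prevalence and homogeneity are ratios of integer counts; tests assert
  `homogeneity * |covered|` and `prevalence * |own class|` are integers.
* Unsorted peak lists are an error in `bin_spectrum()` (upstream
  corruption should fail, not be resorted away).
* A record whose detected internal standard is nonpositive or absent
  within the ±10 Da window fails normalization with the record named.
* Ties in risk scores are ordered by patient id so quantile groups are a
  deterministic partition; for 116 patients in quintiles the sizes are
  23/23/23/23/24 with the remainder on the highest-risk group.
* All simulation, fold assignment and bootstrap randomness is seeded;
  stage seeds in the pipeline derive from one master seed
  (`seed * 131 + stage`).

## Problem sizes used in the shipped checks

The test suite exercises the full pipeline at the cohort scale the
generator emulates (116 patients in duplicate, ~200 peak positions binned
to 5,751 features) with 10 × 10-fold cross-validation, and the solver
oracles on hundreds of randomly drawn small instances (up to 12 patients
and 25 binary features for the exact support-set solver, up to 10 patients
and 5 features for the pattern-enumeration oracle). These sizes keep the
exact reference solvers tractable while leaving the greedy/enumerative
production paths identical to what larger panels would use.

## Limitations

* Binary (two-class) outcomes only; no multi-class extension.
* Degree > 2 patterns are enumerable in principle but unoptimized and
  outside the intended two-mass biomarker idiom.
* The greedy support set and greedy model are heuristics; optimality is
  certified only on small instances via the exact oracles.
* No time-to-event machinery: risk groups are cross-sectional summaries,
  not survival models.
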