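---
title: "Detecting active, carryover and additive drug effects on the gut microbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting active, carryover and additive drug effects on the gut microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(drugmem)
library(dplyr)
```

## The problem

Medication use is one of the strongest host factors shaping the gut
microbiome, and its footprint is not limited to drugs taken at the moment a
stool sample is collected. A drug dispensed years earlier can still leave a
detectable *carryover* signal, and repeated courses can act *additively* —
the more prescriptions in the past, the larger the shift. When such
long-term effects are ignored, they masquerade as disease or lifestyle
signals and confound microbiome association studies.

drugmem implements an end-to-end pipeline for quantifying these effects
from two linked inputs: an ATC-coded prescription registry (one row per
dispensing: subject, 7-character ATC level-5 code, date) and shotgun-
metagenomic taxon profiles for the same subjects at one or two sampling
time points (T1, optionally T2). Four study questions structure the
analysis:

* **Q1 — active usage.** Subjects actively using a drug at T1 versus
  subjects with no use of it in the preceding 5 years.
* **Q2 — carryover.** Former users whose last purchase lies more than 1,
  2, 3 or 4 years before T1 versus 5-year non-users.
* **Q3 — additive effects.** Does past usage (binary, or as a
  prescription count) explain variation on top of active usage? Decided by
  an AIC race between three models.
* **Q4 — two-timepoint validation.** Drug initiation, post-initiation
  carryover and discontinuation effects on within-subject changes between
  T1 and T2.

## Exposure classification

`classify_exposure()` reduces the registry to one state per subject and
drug: *active* (a purchase within the activity window before sampling),
*former* (a purchase within the 5-year lookback but outside the activity
window; `years_since_last` records the gap in 365.25-day years) or
*never*. Antimicrobials (ATC group J by default) use a 90-day activity
window. Registries rarely state how long a dispensed human-targeted
prescription lasts, so the human-targeted window is a configurable
parameter (`active_window_days`); the default of 90 days treats both drug
kinds symmetrically, keeps the rule auditable, and can be set per analysis
when duration-of-supply information exists. Window comparisons are strict
(">1 year" means strictly greater), prescriptions dated on the sampling
day count as before sampling (dispensing precedes stool collection), and
the 5-year lookback is measured as 5 × 365.25 days.

`n_past_prescriptions` counts lookback purchases with the active-defining
ones excluded, so an active user's count reflects genuinely *past* load.
Same-day duplicate records each count toward the total (refills dispensed
together are distinct purchases) but activity is a yes/no question.
Drug classes at ATC levels 3 and 4 are prefix roll-ups of the level-5
codes; no external dictionary is needed. `select_drugs()` applies the
cohort-entry rule: at least 20 distinct active users at T1.

## Compositional treatment

Taxon profiles are compositional, so all abundance analysis happens on
centered log-ratio (CLR) values and community distances are Euclidean on
CLR rows (Aitchison distances). Zeros are imputed with a single
pseudocount equal to half the smallest non-zero relative abundance of the
*whole matrix*: the global rule keeps the imputation deterministic across
subjects, where a per-sample rule would give identical zero counts
different imputed values in different samples. Natural logarithms are used
throughout (CLR and Shannon); this only scales effect sizes, never test
decisions. Counts are not rarefied.

Alpha and beta diversity are computed on the full profile; univariate
models use CLR values computed on the full profile with the ≥10%-prevalence
taxa then selected as responses. The order matters — filtering before the
CLR would change the geometric-mean reference — and is fixed and tested.

## Association models

For each drug and taxon, the abundance model is ordinary least squares of
the CLR value on age, gender, BMI and the case/control indicator. The
reported effect size is the partial Pearson correlation between response
and indicator given the covariates, computed as the correlation of the two
residual vectors after projecting out covariates and intercept; it equals
the sign-consistent transform t/√(t² + df) of the indicator's
t-statistic, a property the test suite asserts on random fixtures.
Presence–absence models are maximum-likelihood logistic regressions with a
two-sided Wald test on the indicator (the Wald default is a documented
choice; the source of the presence p-value is not otherwise pinned down).
Perfect separation and taxa that are constant within an analysis subset
yield flagged `NA` rows, never exceptions, and so do near-saturated taxa
whose minority presence class falls below ~10 events per estimated
parameter: with only a handful of absences the Wald statistic degenerates
and its p-values pile near 1, so such fits are reported as unsupported
rather than tested.

Multiple testing uses Benjamini–Hochberg q-values, by default within each
(drug, response kind, question) family — matching the per-drug reporting
style of the association heatmaps — with a pooled mode behind `by = NULL`.
The carryover scan (`carryover_scan()`) re-tests only pairs significant
for active usage (FDR ≤ 0.1), in four windows, skipping windows whose arm
falls below a configurable floor (default 10 subjects). A likelihood-ratio
test (`dosage_lrt()`) probes dosage effects where a dosage class is
recorded.

PERMANOVA on Aitchison distances is implemented directly (Gower double
centering, pseudo-F, seeded permutations with the add-one estimator
`p = (1 + #{F* ≥ F}) / (n_perm + 1)`, study default 10,000 permutations)
so that the permutation null is seed-reproducible; the test suite checks
it against vegan's `adonis2` and against exhaustive enumeration on a
4-sample fixture. Per-drug R² is computed with the drug as the sole term,
mirroring single-factor PERMANOVA.

## The additive-model race (Q3)

Three models of increasing complexity are fit to all subjects (active,
former and never users — the complex models need variation in past usage
among the non-active): M1 (active usage only), M2 (active + any past
usage), M3 (active + past-prescription count, raw scale). A complex model
wins only if its AIC undercuts M1 by more than 2. M2 and M3 are not
nested in each other and the tie rule is not pinned down by the threshold
alone, so the package fixes its own deterministic rule: when both clear
the margin the lower AIC wins, and an exact tie falls to M2, the model
making fewer assumptions about dose–response. Presence–absence responses
run the same race on the binomial likelihood. A constant prescription
count makes M3 non-identifiable; it is then removed from the race rather
than fit with an aliased coefficient.

## Deconfounding

Each naive drug–taxon association is interrogated against a panel of
candidate confounders (other drugs, diseases, lifestyle, diet,
anthropometrics — panel membership is data, not code). For each candidate,
two nested comparisons on the naive model's subjects, both adjusted for
age, gender and BMI: does the drug add signal on top of the candidate, and
does the candidate add signal on top of the drug? "Predictive ability" is
operationalized as the partial F-test for Gaussian responses and the LRT
for binary ones, at α = 0.05 (configurable) — the natural reading of a
nested-linear-model comparison. The association is *confounded* when at
least one candidate adds signal while the drug does not, and *confidently
deconfounded* otherwise. A candidate collinear with the drug indicator is
flagged indeterminate and can never flip a status silently. Swapping
roles (disease as exposure, prescription counts as candidates) reuses the
same machinery for disease–microbiome associations.

## Two-timepoint analysis (Q4)

`build_delta()` subtracts aligned CLR matrices, each computed with its own
pseudocount (the imputation rule is per matrix; this affects taxa absent
at only one time point and is therefore stated explicitly). Initiation
cases are subjects with no use in the 5 years before T1 who started
between T1 and T2 and are active at T2; post-initiation carryover cases
last used more than a year before T2; discontinuation cases were active at
T1 with no use afterwards. Controls are drug-naive across the whole
recorded span, and drugs need at least 10 cases. Age enters as age at T1
for consistency with the cross-sectional models, and follow-up duration is
not a default covariate (the delta-model specification omits it; a flag
exists).

## Variance partitioning and prediction transfer

`dbrda_forward()` partitions community variance over factor groups by
constrained ordination on the distance matrix. Forward selection adds, at
each step, the candidate with the smallest marginal permutation p-value
given the already-selected factors, while that p-value clears the entry
threshold; the criterion is deliberately the package's own (permutation
p < 0.05 with 999 permutations, both configurable) rather than an
emulation of any specific ordistep version, whose dual AIC/permutation
behavior varies between releases. Each selected factor's conditional R² is
the variance it constrains given all other selected factors. Aitchison
distances are Euclidean, so the embedding has no negative eigenvalues;
non-Euclidean input is rejected outright rather than silently corrected.

`train_antibiotic_model()` fits elastic-net logistic classifiers of
antibiotic usage on CLR profiles: a 75:25 label-stratified split, 5-fold
cross-validation repeated 4 times, and a 50-combination grid — 5 mixing
values uniform on [0, 1] crossed with a 10-point log-spaced penalty path
(the combination count is fixed; the geometry is the package's choice).
`transfer_auroc()` then scores a *different* drug's usage labels on the
held-out split with all users of the source antibiotic removed, repeats
the whole procedure on 5 random splits and averages — transfer above
chance indicates overlapping microbial signatures.

## The synthetic cohort generator

Real registry-linked cohorts are access-restricted, so every stage is
exercised on synthetic cohorts with known truth. The generator plants, per
drug–taxon edge, an active shift (CLR units), a carryover effect that
decays with years since last use, an additive slope per past
prescription, and an optional presence-elimination probability; a latent
disease can tilt both drug usage odds and taxon abundances
(confounding-by-indication). Effects act on latent log-abundances that are
closed to compositions and sampled to counts by per-subject multinomial
draws, and — crucially — the exposure states used to apply effects are
recomputed from the generated registry by `classify_exposure()` itself, so
the generator and the pipeline cannot drift apart.

Defaults define the reference study conditions: 500 subjects, 150 taxa,
12 drugs across 3 ATC4 classes, 5-year ever-use prevalence 0.25 per drug,
residual latent SD 1, taxon baselines with log-SD 2 and sequencing depth
10,000 — a regime in which roughly half the taxa are informative for
presence–absence analysis and nearly all pass the 10% prevalence filter,
mirroring the prevalence structure of species-level mOTU tables. Cohort
demography follows a population biobank profile (age ≈ N(50, 15) within
23–89, 70% female, BMI ≈ N(26.5, 5.3)). Purchase streams distinguish PRN
drugs (sporadic Poisson purchases, default 2/year) from continuous-regime
drugs (30-day refills), and per-drug archetype weights (ongoing user,
past-only user, and — with a second time point — initiator, initiator with
carryover, discontinuer) control the size of every study-question arm
directly instead of leaving them to rejection sampling. Carryover decay is
exponential with half-life τ by default — the simplest monotone choice
consistent with effects that remain visible more than 3 years after last
use — with step and linear forms available.

What the generator does *not* emulate: strain-level ecology, taxon–taxon
interactions, longitudinal autocorrelation beyond two time points, or the
marginal distributions of any particular cohort. Passing tests therefore
demonstrate that the statistical machinery recovers known truth under a
realistic compositional observation model, not that any specific
biological result will replicate.

One compositional subtlety is deliberate: closure makes a planted
single-taxon shift induce small opposite-signed shifts elsewhere, so
recovery is scored on planted edges (detection, sign) and false
discoveries on unplanted pairs, rather than expecting exact nulls
everywhere.

## Numerical choices and degenerate inputs

* CLR rows sum to zero within 1e-9; a single-taxon matrix is rejected
  (CLR is undefined up to closure), as is an all-zero subject row.
* Partial correlations guard |r| = 1 rounding and return flagged `NA` for
  rank-deficient covariates or an indicator collinear with them.
* Permutation p-values use the add-one estimator and are therefore never
  0 and bounded below by 1/(n_perm + 1).
* Logistic separation is detected both from glm warnings and from
  boundary fitted probabilities / absurd log-odds (|β| > 30).
* A zero-variance response gives a dosage LRT statistic of 0 and p = 1.
* Elastic-net tie-breaks on the tuning grid are deterministic: best mean
  CV AUROC, then the strongest penalty, then the smallest mixing value.

## Problem sizes in the test suite

The packaged checks run the reference conditions at sizes chosen for a
single-CPU workstation: the null-calibration and recovery analyses use
500-subject, 150-taxon cohorts (100 seeds for recovery rates); carryover
power uses 2,000 subjects so that each window retains ~500 subjects per
arm; the AIC race uses 2,000 subjects × 100 seeds per generating model;
deconfounding status rates use 1,000 subjects × 200 seeds; transfer uses
600 subjects with the full 5-repeat, 50-combination protocol. These sizes
are the package's reference experiment; scaling them up only sharpens the
same estimates.

## A worked example

```{r example, eval = FALSE}
truth <- sim_truth(edges = tibble::tibble(
  drug_code = "J01FA09", taxon = 1:5, beta_active = c(1, 1, -1, 1, -1)
))
cohort <- simulate_cohort(truth, n_subjects = 500, seed = 1)

exposures <- classify_exposure(cohort$prescriptions, cohort$subjects, level = 5)
groups <- build_q_groups(exposures, "Q1",
                         prescriptions = cohort$prescriptions,
                         subjects = cohort$subjects)
clr <- clr_transform(cohort$taxa_t1)
records <- associate(groups, clr, cohort$subjects) |> add_fdr()
score_recovery(truth, dplyr::filter(records, drug_code == "J01FA09"))
```

## Known limitations

* Exposure is inferred from dispensing, assuming dispensed drugs are
  taken; dose-to-DDD conversion and over-the-counter drugs are out of
  scope.
* The human-targeted activity window is a modeling choice, not a measured
  quantity.
* Zero handling is a single global pseudocount; multiplicative or
  Bayesian replacement schemes are not offered.
* Mixed-effects, zero-inflated and interaction models are out of scope;
  the model set is exactly the one the study questions require.
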