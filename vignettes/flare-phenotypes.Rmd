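---
title: "Flare episodes and flare phenotypes from daily symptom diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flare episodes and flare phenotypes from daily symptom diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(flarediary)
```

## The problem

Axial spondyloarthritis (axSpA) alternates between flares — self-reported
periods of worsened disease — and more stable periods. Smartphone symptom
diaries record up to ten variables ("petals") per day on a 1–5 Likert
scale, with 1 the least healthy outcome and 5 the healthiest; eight petals
are fixed (pain, mood, fatigue, sleep quality, stress, flare, recommended
exercise, anti-inflammatory use) and each participant picks two more from
a list of thirteen optional petals. `flarediary` turns such diaries into:

1. **flare episodes** — maximal runs of flare-on days with a
   single-missing-day bridge rule — and their duration/frequency summaries,
2. **flare-conditioned symptom profiles** — per-participant mean scores in
   and out of flare, their differences, and paired t-tests per variable,
3. **flare phenotypes** — affinity propagation clusters of participants on
   min–max-normalized difference features, characterized by Welch t-tests
   on symptom profiles, episode durations and baseline clinical covariates.

Because diary cohorts of this kind are not publicly shareable, the package
includes a first-class synthetic cohort generator with planted phenotypes;
every pipeline stage is exercised and tested against it.

## Flare state and episode reconstruction

The flare petal is scored 1–5 like every other petal. How the study
operationalized the 1–5 score as a binary flare state is not something a
reader of the published tables can recover, so the package makes it an
explicit parameter: a day is *flare-on* when the flare score is at or
below a threshold `T`, default `T = 3` (the scale midpoint). All
downstream statistics are reproducible under any `T`; a missing flare
score makes the day's state undefined and excludes it from all
flare-conditioned aggregation, though the day still counts as "data
entered" for the gap logic below.

Episodes are maximal runs of flare-on days with one allowance: two
flare-on days exactly two calendar days apart are merged into a single
episode when the intervening day has **no diary entry at all**. The merged
missing day is counted in the episode duration. A recorded flare-off day
— or an entry day without a flare score — always terminates an episode,
and gaps of two or more missing days are never bridged. Published
descriptions of this rule mix two phrasings ("within 3 days" vs "missing
1 day of data"); we implement the strict reading — exactly one
entry-free intervening calendar day — which is the only one consistent
with both phrasings. The segmentation is validated exhaustively against an
independent brute-force implementation (pairwise bridging links plus
connected components) on **all** `3^10` diary patterns of length ten.

Two further conventions, both exposed and logged:

* **Frequency.** "One flare every X days" is the participant's observation
  span (last entry day − first entry day + 1) divided by the episode
  count. This definition reproduces the reported extreme values (a
  single-flare participant followed for two years gives X in the
  hundreds); the alternative mean onset-to-onset gap is available via
  `method = "onset_gap"`.
* **Censoring.** Episodes are never truncated at the observation
  boundary; episodes touching the first or last entry day are flagged
  (`at_boundary`) instead.

## Features, inference and normalization

For each participant and variable we compute the mean score over
flare-on days and over flare-off days (`mean_on`, `mean_off`) and the
difference `diff = mean_on − mean_off`; negative differences mean the
variable worsens during flare. A difference exists only when the
participant has at least one scored entry on each side — this is why the
per-variable sample sizes differ, and optional petals (chosen by few
participants) have small `n`.

Per-variable inference is a paired t-test of the differences against
zero with a 95% CI (`build_table1()`); p-values are reported raw with a
`p < 0.01` significance convention and no multiple-testing correction.
Between-cluster comparisons use Welch's unequal-variance t-test with
Satterthwaite degrees of freedom throughout — including 0/1 baseline
indicators, where Welch on indicators is equivalent to an unpooled
two-proportion z-test up to the df (a chi-square alternative sits behind
`binary_test = "chisq"`). Degenerate inputs (n < 2, zero variance) yield
flagged results rather than errors.

Clustering uses the seven fixed symptom/behaviour difference features
(pain, fatigue, sleep quality, recommended exercise, mood,
anti-inflammatory use, stress): every participant tracks them, so the
complete-case matrix loses only participants lacking a flare-on or
flare-off observation. Optional-petal differences are reported
descriptively only — each optional petal is chosen by too few
participants to support a complete matrix or a stable test. Eligibility
requires at least 10 distinct entry days (`min_days = 10`, "<10 days
excluded", boundary inclusive).

Each difference column is then min–max normalized onto `[-1, 1]`
(`x ↦ 2(x − min)/(max − min) − 1`), the stated target interval; the
per-column min/max are recorded for provenance, a constant column maps to
zeros with a degeneracy flag, and max-abs scaling (which preserves the
zero point but not the full interval) is available behind
`method = "maxabs"`.

## Affinity propagation

`affinity_propagation()` is a from-scratch implementation of the
responsibility/availability message-passing scheme on the similarity
matrix `S[i,k] = −d(i,k)^r` with `r = 2` (negative squared Euclidean
distance). The shared diagonal preference is the `q`-th quantile (linear
interpolation) of the off-diagonal similarities; `q = 0` — the minimum —
deliberately favors few clusters, appropriate for a cohort of ~129
participants where each cluster must stay interpretable. Updates are
damped with `λ = 0.9`; iteration stops when the exemplar set is unchanged
for 100 consecutive iterations (cap 1000). These control defaults mirror
the documented defaults of the established R implementation of the
algorithm. After convergence the standard refinement pass is applied:
within each cluster the exemplar moves to the member maximizing the
intra-cluster similarity sum, and points are reassigned until stable —
the same polishing step mainstream implementations perform.

Numerical choices worth knowing:

* **Exact ties.** Duplicate feature rows create symmetric message ties
  that can cycle. A deterministic, seeded, *non-positive* jitter of
  magnitude `1e-12 × range(S)` is subtracted once from the similarities
  (and the quantile preference recomputed on the jittered matrix), which
  resolves duplicate degeneracies toward fewer exemplars. `jitter =
  FALSE` disables this for exact-arithmetic comparisons. The fully
  degenerate instance — all points identical — short-circuits to one
  cluster, which is the optimum for any preference.
* **Validation oracle.** `ap_exemplar_oracle()` enumerates every
  non-empty exemplar subset (n ≤ 12) and maximizes the net similarity
  `Σ_{i∉E} max_{k∈E} S[i,k] + Σ_{k∈E} p_k` exactly, with lexicographic
  tie-breaking. The test suite requires the message-passing result to
  attain this optimum on 50 seeded two-blob instances whose
  centre-to-centre distance is at least four blob diameters. At weaker
  separations the global optimum can flip to a single exemplar while
  message passing settles on two (or vice versa) — a known property of
  the approximation, not a defect, and the reason the equivalence check
  is defined on separated instances.
* **No exemplar.** If no point's self-responsibility plus
  self-availability turns positive by the iteration cap, the best-scoring
  point is returned as a single exemplar with `converged = FALSE`.

## The synthetic cohort generator

`generate_cohort(cohort_config(), seed)` draws a cohort that mirrors the
structure the pipeline assumes. Per participant:

* a phenotype from a two-component mixture (default weights 96:33, the
  published cluster sizes);
* a number of logged diary days from a lognormal (meanlog 5.115, sdlog
  0.747: mean ≈ 220, sd ≈ 190, clamped to [10, 711]). The published
  whole-registry mean of ≈157 days averages over the roughly one third of
  registrants who logged fewer than 10 days and enter no analysis;
  removing that mass from the reported moments leaves ≈220 days for the
  eligible cohort the defaults emulate. Whole-day missingness (default
  probability 0.2) is applied on top of an accordingly inflated window so
  the logged-day count keeps this distribution;
* an alternating renewal flare process: shifted-geometric inter-episode
  gaps and episode durations (support ≥ 1 day). Default duration means
  are 7.2 and 3.5 days for the two phenotypes and gap means 28.1/31.8
  days, so a full flare cycle averages ≈35 days — the published flare
  frequency. A shifted negative-binomial duration option
  (`duration_dispersion`) produces the heavier tails implied by a
  duration sd well above the mean;
* daily latent scores per variable: phenotype baseline (flare-off Likert
  means from the published per-cluster tables) + a participant offset
  (sd 0.45) + the phenotype's flare shift on flare days (published
  difference values; individual shifts jittered with sd 0.05) + daily
  noise (sd 0.5), rounded and clipped to 1..5. Anti-inflammatory use is
  published on an apparent 0–1 scale; the generator keeps the uniform 1–5
  scale, rescaling only its baseline (≈2.7) while leaving the published
  difference values untouched, and the discrepancy is simply documented;
* a flare petal on the correct side of the binarization threshold with
  probability 0.995 (`flare_fidelity`);
* two optional petals, uniformly chosen;
* MCAR missingness for whole days and individual petals (an informative
  mode with extra missingness during flare exists, off by default, to
  probe adherence bias);
* baseline covariates: per-phenotype normals for the clinical indices and
  Bernoullis/multinomials for the indicators, parameterized from the
  published baseline table, with MCAR missingness.

**Calibration and the planted regime.** The noise defaults were fixed at
design time by two computations. First, discretization bias: rounding and
clipping latent Gaussians onto 1..5 attenuates a configured shift; an
exact rounding-cell calculation shows that at daily sd 0.5 and
between-participant sd 0.45 the attenuation stays below 0.05 Likert
points for every configured shift, so realized per-phenotype mean
differences track their configured values within the tolerance the
calibration tests use (±0.1 at n = 500). Second, recoverability: the
planted-partition design requires the within-phenotype spread of the
difference features to stay below the between-phenotype contrast, which
bounds the individual shift heterogeneity (sd 0.05) and daily noise. The
generator is therefore a *low-noise planted regime*: passing its recovery
tests demonstrates that the pipeline machinery works, **not** that real
cohorts — with correlated symptoms, informative missingness, and far more
between-person heterogeneity — would cluster this cleanly. The
ground-truth ARI of the published cohort is unknowable, and nothing here
estimates it.

Within-day correlation between symptoms (`shared_daily_sd`) is off by
default because only marginal summaries are published; it exists to probe
sensitivity.

## The pipeline and reproducibility

`run_full_pipeline(pipeline_config(...))` chains every stage and writes
`episodes.csv`, `features.csv`, `table1.csv` (paired tests),
`table2.csv`/`table3.csv` (per-cluster differences and flare-on/off
means), `table4.csv` (baseline covariates), `labels.csv`, a structured
`report.json` and a `run.log`. Every filter logs its before/after
participant counts, making cohort-flow numbers auditable. Reports are
byte-identical across reruns of the same configuration and seed;
wall-clock timestamps appear only in `run.log`. A thin command-line
wrapper (`inst/scripts/flarediary-cli.R`, subcommands `simulate`,
`episodes`, `features`, `test`, `cluster`, `run`, `fixtures`) exposes the
same functions for shell use.

Problem sizes in the shipped tests were chosen to keep the full suite
fast while leaving Monte-Carlo margins honest: exhaustive episode
enumeration at 10 days, 50 clustering-oracle instances at n ≤ 8, 2000
replicates for type-I error and CI coverage, 25 cohort replicates at the
default n = 129 for phenotype recovery, and one n = 500 cohort plus 2000
episodes per phenotype for generator calibration.

## Known limitations

* The flare binarization threshold and the frequency definition are
  package conventions for quantities the published record leaves
  unspecified; both are parameters, not claims.
* Welch-on-indicators for proportions is a documented convention;
  exact/chi-square tests may differ for very small cells.
* The generator's independence assumptions (across variables and days)
  and MCAR missingness are simplifications; the informative-missingness
  switch probes only the simplest violation.
* Affinity propagation at `q = 0` on weakly separated data need not
  match the global exemplar optimum and can return one cluster; the
  pipeline reports convergence and cluster counts so such runs are
  visible rather than silent.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  synthetic = cohort_config(),  # planted two-phenotype cohort, n = 129
  out_dir = tempfile("flare-run-"),
  seed = 1L
)
report <- run_full_pipeline(cfg)
report
head(report$table1)
report$comparison$duration_welch
```
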