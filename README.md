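# flarediary

Flare episode segmentation, flare-conditioned symptom profiling and
phenotype clustering for daily self-reported symptom diaries, modelled on
smartphone tracking of axial spondyloarthritis (axSpA).

People with axSpA score up to ten "petal" variables each day on a 1–5
Likert scale (1 = least healthy), including a flare petal. From such a
diary the package answers three questions:

1. **When was each participant in flare, and for how long?** Days with
   flare score ≤ T (default T = 3) are flare-on; maximal runs of flare-on
   days form episodes, with one rule — two flare-on days separated by
   exactly one calendar day with *no diary entry* are merged into a
   single episode. Durations, frequency ("one flare every X days" =
   observation span / episode count) and their mean/sd/range are
   summarized.
2. **Which symptoms move with flare?** For each participant and variable
   v the difference feature `diff(v) = mean_on(v) − mean_off(v)` captures
   the flare effect; a paired t-test per variable with 95% CI
   (`t = x̄ / (s/√n)`, df = n − 1) tests it across the cohort.
3. **Are there distinct flare phenotypes?** Participants with ≥10 entry
   days are clustered by affinity propagation (implemented from scratch:
   responsibility/availability message passing, damping λ = 0.9) on
   min–max normalized difference features, with similarity
   `S[i,k] = −‖x_i − x_k‖²` and shared preference = the q = 0 quantile
   (minimum) of the similarities, which favors few clusters. Clusters are
   compared with Welch's t-test (Satterthwaite df) on symptom profiles,
   episode durations and baseline clinical covariates (BASDAI/BASMI/BASFI
   and friends).

Real diary cohorts of this kind are not publicly available, so the
package ships a synthetic cohort generator with planted phenotypes
(two groups with distinct symptom-shift vectors and episode-duration
means of 7.2 vs 3.5 days, mixed 96:33) that emulates the data structure —
irregular follow-up, missing days and petals, baseline covariates — and
makes the whole pipeline testable end to end. See the methods vignette
(`vignettes/flare-phenotypes.Rmd`) for the model, all defaults and their
rationale, and what the planted regime does and does not demonstrate.

## Worked example

```r
library(flarediary)

cfg <- pipeline_config(
  synthetic = cohort_config(),   # planted two-phenotype cohort, n = 129
  out_dir   = "flare-run",
  seed      = 1L
)
report <- run_full_pipeline(cfg)
report
#> Flare diary analysis run
#>   participants: 129 registered, 127 with >= 1 flare, 129 eligible, 127 clustered
#> 1207 flare episodes in 127 participants
#>   duration (days): mean 4.41, sd 4.56, range 1-35
#>   frequency (one flare every X days): mean 34.00, sd 22.33, range 10.16667-197
#> Affinity propagation: 2 clusters (sizes 95/32), 129 iterations, converged
#>   preference -10.39, net similarity -77.18

print(head(report$table1, 3), digits = 4)
#>        variable estimate   p_value  ci_low ci_high   n significant
#> 1          pain  -0.7446 1.128e-64 -0.7885 -0.7007 127        TRUE
#> 2       fatigue  -0.4971 1.080e-32 -0.5577 -0.4365 127        TRUE
#> 3 sleep quality  -0.2117 6.057e-20 -0.2500 -0.1733 127        TRUE

report$comparison$duration_welch
#> Welch t-test: means 4.902 vs 2.638 (n = 942/265), t = 10.837, df = 989.41, p = 6.168e-26
```

Reading: the cohort's mean pain score during flare is ~0.74 Likert points
lower (worse) than out of flare with a CI far from zero; the clustering
recovers a 95/32 split of the planted 96:33 phenotypes, and pooled
episode durations differ sharply between the clusters (4.9 vs 2.6
observed days; the planted latent means are 7.2 vs 3.5 — observed
episodes are shorter because missing flare scores fragment and censor
them). The printed numbers come from this exact command and reproduce
bit for bit at seed 1.

Individual stages are available as plain functions — `read_diary()`,
`segment_episodes()`, `flare_features()`, `build_table1()`,
`normalize_features()`, `affinity_propagation()`, `compare_clusters()` —
and as a thin CLI (`inst/scripts/flarediary-cli.R`).

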