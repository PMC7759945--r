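# dielcam

Diel activity patterns and spatial co-occurrence of a mammal community
from camera-trap records.

Camera traps accumulate time-stamped photos of elusive species around the
clock. `dielcam` turns those records into the standard community-level
analyses used for forest ungulates (its bundled example emulates a
six-species duiker survey across Central African rainforests):

- **Independent detection events.** Repeat photos of a species at one
  station within a fixed window (default 1 h) are collapsed to a single
  event; multi-individual photos count once; a photo of two species
  counts once per species.
- **Diel classification.** Each event time is classified against a solar
  schedule (default 06:00/18:00 with ±1 h twilight windows), and each
  species is categorised from its nocturnal fraction *p*ₙ:
  strongly diurnal (*p*ₙ ≤ 0.10), mostly diurnal (0.10 < *p*ₙ < 0.30),
  cathemeral (0.30 ≤ *p*ₙ < 0.70), mostly nocturnal (0.70 ≤ *p*ₙ < 0.90),
  strongly nocturnal (*p*ₙ ≥ 0.90).
- **Circular activity densities.** Event times are angles
  θ = 2π·t/24 on the diel circle. Activity is estimated with a von Mises
  kernel, f̂(θ) = n⁻¹ Σᵢ vM(θ; tᵢ, κ_b), with the AMISE plug-in
  concentration κ_b; a non-negative trigonometric-sum fit cross-checks
  sample-size adequacy; the Hermans–Rasson statistic with Monte-Carlo
  null tests circular uniformity; the circular median and the activity
  level (mean/peak detection rate, â = 1/(2π·max f̂)) summarise each
  species.
- **Temporal overlap.** The coefficient of overlapping
  Δ̂ = ∫ min(f̂, ĝ) dθ between two species, via the grid estimator Δ̂₁
  (smaller sample < 75 events) or the density-ratio estimator Δ̂₄,
  with smoothed-bootstrap percentile CIs, a pooled-permutation test that
  two samples share one distribution, and Watson's two-sample U².
  Δ̂ > 0.75 is strong overlap, Δ̂ ≤ 0.5 low.
- **Spatial co-occurrence.** For each species pair over N stations with
  margins N₁, N₂ fixed, the number of shared stations is hypergeometric:
  P_j = C(N₁, j)·C(N−N₁, N₂−j)/C(N, N₂). Exact tails p_lt and p_gt
  classify pairs as negative / positive / random at α = 0.05, with the
  standardised effect size (Q_obs − N₁N₂/N)/N.
- **Matrix association.** A Mantel test (exact enumeration of label
  permutations for ≤ 7 species) relates the temporal-overlap matrix to
  the spatial effect-size matrix.
- **Synthetic surveys.** `study_replica_config()` bundles a 12-site,
  428-station, six-species survey replica whose diel schedules, event
  totals, activity levels and pairwise structure mirror the published
  duiker community, so the whole pipeline can be exercised and tested
  without field data.

## Worked example

```r
library(dielcam)

cfg    <- study_replica_config(seed = 42)
sim    <- simulate_survey(cfg, seed = 42)          # 5296 raw records
events <- filter_independent_events(sim$records)   # 4258 independent events

s <- event_series(events, "P. congica")
classify_diel(s$times)
#> Diel summary: 2472 events, 92% diurnal / 8% nocturnal, 15% twilight
#> Category: strongly diurnal

radians_to_hours(circular_median(s$times))
#> [1] 11.10528  — late-morning median activity

b <- event_series(events, "C. castaneus")          # strongly nocturnal
ov <- overlap_ci(s$times, b$times, seed = 2)
#> Dhat (delta4): 0.14 [0.11, 0.16]  — day/night schedules barely overlap

kept <- retain_informative_stations(events, deployed = rownames(sim$presence))
kept$retention_pct
#> [1] 74.5

mat <- build_detection_matrix(events, stations = kept$stations)
cc  <- cooccurrence_pairs(mat, exclude = "C. nigrifrons")
head(cc$pairs[, c("species_a", "species_b", "Q_obs", "p_gt", "classification")], 4)
#>        species_a      species_b Q_obs     p_gt classification
#>  C. callipygus    C. castaneus   109  6.5e-06       positive
#>  C. callipygus  C. leucogaster    28  5.2e-05       positive
#>  C. callipygus  C. silvicultor    89  9.3e-12       positive
#>  C. callipygus      P. congica   130  6.8e-03       positive
```

The four positive pairs are exactly the associations built into the
replica's occupancy model. `run_pipeline(run_config(...))` chains all
stages and writes the event, diel, activity, overlap, co-occurrence and
Mantel tables plus a run manifest; `inst/exec/dielcam` exposes the same
steps as shell subcommands (`simulate`, `events`, `density`, `overlap`,
`cooccur`, `mantel`, `run`).

## Vignette

`vignettes/duiker-diel-activity.Rmd` documents the statistical models,
the estimator and tuning-parameter choices, what the synthetic generator
does and does not emulate, and known limitations.
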