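---
title: "Diel activity, temporal overlap and co-occurrence of a duiker community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diel activity, temporal overlap and co-occurrence of a duiker community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dielcam` implements the community-level analysis of time-stamped
camera-trap detections: independence filtering, diel classification,
circular density estimation, pairwise temporal overlap, probabilistic
spatial co-occurrence, and the association between the two pairwise
structures. This vignette explains the models behind each stage, the
tunable parameters and why their defaults are what they are, what the
synthetic survey generator does and does not emulate, and the numerical
choices a user should know about. Every empirical claim here is one the
package's test suite or `scripts/acceptance.R` computes.

```{r setup}
library(dielcam)
```

## From photos to independent events

A passive camera photographs the same animal repeatedly while it lingers.
Treating every photo as an observation pseudo-replicates; the standard
remedy is an independence window: within one station and species, a
record falling less than `window_min` (default 60) minutes after the
previous **retained** record is discarded. Comparing against the last
retained record (a greedy forward scan) rather than the last raw record
makes the rule idempotent — filtering a filtered series changes nothing —
which the test suite checks as a property. A photo of several
conspecifics is one event (group size is kept as metadata); a photo of
two species is one event for each. Records with unparseable timestamps
are dropped with a warning, never silently.

Stations that never produced an identifiable detection carry no
information about any species and are dropped; the retention fraction is
reported as a percentage to one decimal.

## Diel classification

Clock times map to angles on the diel circle, $\theta = 2\pi t/24$, with
midnight at zero. An event is diurnal on $[\mathrm{sunrise},
\mathrm{sunset})$ and nocturnal otherwise; the half-open convention puts
an event at exactly sunrise in the day and one at exactly sunset in the
night. Twilight is the ±1 h window around both transitions, so twilight
counts overlap the day and night counts and are reported against total
events. The default schedule, 06:00/18:00, is the equatorial site
average; a per-site, per-date table can replace it where deployments
span latitudes or seasons.

Species categories follow the nocturnal fraction $p_n$ with half-open
bands — strongly diurnal $p_n \le 0.10$, mostly diurnal
$0.10 < p_n < 0.30$, cathemeral $0.30 \le p_n < 0.70$, mostly nocturnal
$0.70 \le p_n < 0.90$, strongly nocturnal $p_n \ge 0.90$. The published
verbal bands leave the 0.10 and 0.90 boundaries ambiguous; we honour the
one inclusive phrase ("at least 90%") on both tails, so a series with
exactly 10% nocturnal events is still strongly diurnal. Classification
uses unrounded fractions; reported percentages are rounded half-up,
matching how such tables are printed.

## Circular density estimation

Activity is a density on the circle. The workhorse estimator is the von
Mises kernel,
$$\hat f(\theta) = \frac1n \sum_{i=1}^n
  \mathrm{vM}(\theta;\, t_i,\, \kappa_b),$$
tabulated on a 128-point equally spaced grid and renormalised so its
trapezoidal integral is $1 \pm 10^{-6}$. The kernel concentration comes
from the AMISE plug-in rule
$\kappa_b = [3 n \hat\kappa^2 I_2(2\hat\kappa) / (4\sqrt{\pi}
I_0(\hat\kappa)^2)]^{2/5}$, where $\hat\kappa$ is the maximum-likelihood
concentration of a single von Mises fit capped at `kmax = 3` — the cap
guards against over-concentration when the data are multimodal, as diel
data almost always are. The `adjust` argument divides into the
concentration: 0.8 (more smoothing absorbed into the estimator) when
feeding the integral overlap estimator and 1.0 for the density-ratio
estimator, the combinations recommended for those estimators in the
overlap literature. Evaluation between grid points is periodic linear
interpolation; at 128 points the interpolation error is below 1% of the
density scale, which the rotation-equivariance test bounds.

The non-negative trigonometric-sum density estimates Fourier
coefficients up to order 3 by empirical trigonometric moments, clips
negative values and renormalises. This is deliberately a moment-based
approximation, not full non-negative-trigonometric-sums maximum
likelihood: its only job here is to cross-check the kernel fit — when a
sample is too small to pin down the activity shape, the two fits
diverge. We report their total-variation distance and leave the
adequacy threshold to the user, since no published cut-off exists.

**Uniformity.** The Hermans–Rasson statistic
$$T = \sum_i \sum_j \Big[\big(|\pi - |\theta_i - \theta_j|| - \tfrac\pi2\big)
  - 2.895\,\big(|\sin(\theta_i - \theta_j)| - \tfrac2\pi\big)\Big]$$
is used with a Monte-Carlo null (default 1000 uniform samples). The
centred sine term is subtracted, not added: that sign is what gives the
test its power against axial and bimodal alternatives, and bimodal
(twin-peaked) schedules are exactly what crepuscular mammals produce.
The statistic is quadratic in $n$, so the pipeline tests a random
subsample of at most 300 events for very large series — at that size the
test's power against any realistic diel pattern is already saturated.

**Median and activity level.** The circular median minimises the mean
circular absolute deviation; candidates are the data points and the
circular midpoints of adjacent sorted points, with ties broken by the
smallest angle (so two events at 23:00 and 01:00 give a midnight
median). The activity level — the proportion of the diel cycle spent
active, assuming all animals are active at the peak — is the mean-to-peak
rate ratio $\hat a = 1/(2\pi \max \hat f)$, with a percentile bootstrap
CI over ordinary event resamples (smoothing is re-estimated per
resample). Kernel smoothing flattens peaks, so $\hat a$ is biased upward
at small $n$; the bias is visible for the rarest species in the bundled
replica and is one reason published activity levels from tens of events
carry very wide intervals.

## Temporal overlap

The coefficient of overlapping between two activity densities is
$\Delta = \int_0^{2\pi} \min\{f(\theta), g(\theta)\}\,d\theta \in [0,1]$.
Two estimators are provided and selected by sample size, following the
published recommendation: the grid estimator $\hat\Delta_1$ (trapezoidal
integral of the pointwise minimum of the two kernel fits, bandwidth
adjust 0.8) when the smaller sample has fewer than 75 events, and the
density-ratio estimator
$$\hat\Delta_4 = \frac12\Big[\frac1n \sum_i \min\{1, \hat g(x_i)/\hat f(x_i)\}
 + \frac1m \sum_i \min\{1, \hat f(y_i)/\hat g(y_i)\}\Big]$$
(adjust 1.0, densities floored at $10^{-12}$) otherwise. Identical
samples give $\hat\Delta_4 = 1$ exactly; both estimators are symmetric
and clipped to $[0,1]$, and $\hat\Delta_1$ converges to the true
min-density integral (the suite checks $|{\rm bias}| < 0.05$ at
$n = 1000$ against fine-grid quadrature).

Confidence intervals use the smoothed bootstrap — resampling from the
fitted kernel densities, as in the methodology the estimators come
from — with one correction: smoothed resamples see a doubly-smoothed
pattern, which biases bootstrap replicates of $\hat\Delta$ (upward for
well-separated pairs), so the percentile bounds are shifted by the
bootstrap mean minus the point estimate. Without the shift the interval
can fail to contain the estimate; with it, replica day/night pairs give
intervals like 0.14 [0.11, 0.16]. Ordinary resampling is available
behind `smoothed = FALSE`. Which exact CI variant produced published
intervals is rarely stated; mean-shifted percentile is the default here
and is recorded as such in the output.

Whether two samples share one distribution is tested by pooled
relabelling: the discrepancy $1 - \hat\Delta$ is recomputed over random
relabellings that preserve the two sample sizes, with
$p = (1 + \#\{{\rm perm} \ge {\rm obs}\})/(1 + B)$. Watson's two-sample
$U^2$ (rank-based, midranks under heavy ties, asymptotic-series p-value
plus the standard critical-value bands) is offered as the classical
alternative. Overlap strength bands resolve a garbled published
statement the only consistent way: low $\le 0.5 <$ moderate
$\le 0.75 <$ strong.

## Spatial co-occurrence

Presence is "at least one independent event at the station". With
margins fixed — species occupy $N_1$ and $N_2$ of $N$ stations — the
number of shared stations under independent placement is hypergeometric,
$$P_j = \binom{N_1}{j} \binom{N - N_1}{N_2 - j} \Big/ \binom{N}{N_2},$$
and the exact tails $p_{lt} = \sum_{j < Q_{obs}} P_j$,
$p_{gt} = \sum_{j > Q_{obs}} P_j$ classify a pair as negative
($p_{lt} < \alpha$), positive ($p_{gt} < \alpha$) or random. The
published formulation sums $j$ "to $N$"; outside the hypergeometric
support every term is zero, so the package sums over the support only —
numerically identical and explicit. Evaluation goes through R's
log-space hypergeometric distribution functions; the tests pin them to a
full enumeration of placements at small $N$ and to a 100,000-shuffle
fixed-margin permutation oracle at $N = 50$. The standardised effect
size $(Q_{obs} - N_1 N_2 / N)/N$ is reported per pair, pairs whose rarer
species occupies fewer than 5 stations are flagged low-power, and
imperfect detection is deliberately **not** modelled: this is naïve
co-occurrence, and occupancy-detection models are out of scope.

## Relating the two structures

The Mantel test correlates the upper triangles of the temporal-overlap
matrix ($\hat\Delta$ values) and the spatial effect-size matrix — the
two standardised pairwise quantities the analysis produces — under
simultaneous row/column permutation of one matrix. With up to 7 species
all label permutations are enumerated (5 species → 120), so the p-value
is exact rather than Monte-Carlo; beyond that, random permutations with
$p = (1 + \#\{r^* \ge r\})/(1 + B)$. One-sided "greater" is the default
(positive association between shared space and shared time is the
natural alternative); a two-sided option on $|r|$ and a Spearman variant
(invariant to monotone rescaling) are available.

## The synthetic survey generator

Real station-level detection data for the community this package
emulates were never deposited, so the generator is a first-class module
rather than a test fixture. It simulates:

- **Occupancy with controllable association.** Species are placed
  sequentially over stations; each species' log-odds at a station is a
  calibrated intercept plus $\log(\mathrm{OR})$ for every
  already-present associated species. The intercept is solved against
  the realised presence of the predecessors, so marginal occupancy hits
  its target (within ±0.03 at 1000 stations, a tested property) while
  pairwise odds ratios carry the association. Infeasible combinations
  raise a diagnostic error.
- **Detections as a marked Poisson process.** Each occupied
  station-species pair accumulates detections whose time-of-day law is
  the species' von Mises mixture; per-site weights shape where each
  species is detectable. When a configuration specifies target totals,
  the process is conditioned on them (a Poisson process given its total
  is a multinomial allocation over stations), which keeps the rarest
  species' totals within a few percent instead of the ±15% that
  unconditioned Poisson noise would give at 42 events.
- **Filter fodder.** Photo bursts (extra records 5–40 min after a
  detection, probability 0.15 per event in the replica) exercise the
  independence filter, and group sizes exercise the multi-individual
  rule; only the blue duiker gets a substantial pair rate (13% pairs, 1%
  trios), the others ≤ 4%.

`study_replica_config()` freezes a 12-site, 428-station, 42-day survey
whose six species reproduce the published community's structure: event
totals at the published scale (the bundled site-by-species table
supplies both the totals and the site weights, which concentrates
*C. leucogaster* in Gabon and *C. nigrifrons* in the single DRC site),
diel categories with deliberate margin inside their bands, circular
medians within half an hour of the published values, activity levels
inside the published 0.31–0.46 range, four strongly overlapping pairs
(> 0.75) against clearly separated day/night pairs, and positive
station-level association (odds ratios 6–8) between *C. callipygus* and
the four other analysed species.

Choices a reader should know about, made once when the replica was
designed:

- Where a published fraction sits on a category boundary (the
  white-bellied duiker is 90.2% diurnal from 61 events), the replica's
  true parameter is placed inside the band (≈ 95% diurnal) so that the
  category is a property of the species, not of the sampling noise of a
  single run; the same reasoning gives the black-fronted duiker a
  nocturnal fraction near the middle of its band.
- Mixture concentrations were set so that *estimated* activity levels at
  the published sample sizes fall in the published range. Kernel
  smoothing inflates the estimate at small $n$, so the rare species'
  true mean-to-peak ratios are lower than their estimates; the replica
  encodes the estimates' behaviour, not the printed values as latent
  truths.
- Sample medians of a bimodal density sit in a density valley and have
  standard error $\approx 1/(2 f(m) \sqrt n)$ — at 42–61 events that is
  close to the half-hour tolerance itself. Recovery checks therefore
  average medians (circularly), levels and overlap matrices over six
  replicate surveys and take diel categories by majority; the
  co-occurrence power criterion uses 25 replicates. These sizes keep the
  whole recovery suite within a few minutes on one core.
- The day/night separation between the mostly-diurnal and
  mostly-nocturnal species is bounded below by their minority-time
  activity (a mostly-diurnal species must spend > 10% of events at
  night to be "mostly" rather than "strongly" diurnal), so their overlap
  cannot fall much below ≈ 0.25; only pairs involving the *strongly*
  nocturnal species reach the published 0.06–0.16 range, and the
  recovery checks are scoped accordingly.

What the generator does **not** emulate: animal movement and
home-range structure (stations are conditionally independent given
occupancy), detection-distance effects, seasonal or weather forcing,
inter-annual variation, and deployment-length heterogeneity (the real
survey ran cameras 1–4 months; the replica uses a uniform 42 days scaled
to comparable total effort). Passing recovery tests therefore shows the
estimators recover the structure this process encodes — not that real
detection data are this clean.

## Numerical and reproducibility notes

- All internal angles are radians on $[0, 2\pi)$; `hours_to_radians()`
  and `radians_to_hours()` convert at the boundaries of the package.
- Von Mises densities use exponentially scaled Bessel functions, so
  large concentrations neither overflow nor lose the normalising
  constant; the concentration MLE uses the standard series inversion of
  $A_1(\kappa)$, ample for bandwidth selection.
- Von Mises sampling is Best–Fisher rejection; concentration zero falls
  back to the circular uniform.
- Every randomised routine takes an explicit integer seed; when one is
  omitted it is drawn, used and *reported* in the result so the run can
  be replayed. `run_pipeline()` derives fixed per-stage substreams from
  one root seed, so a stage rerun in isolation reproduces its
  pipeline-level result, and identical seeds give byte-identical
  simulated CSVs.
- Monte-Carlo p-values use $(1 + k)/(1 + B)$, which makes permutation
  tests exact at the attainable levels; the suite verifies type-I error
  for the uniformity, same-distribution and Mantel tests at
  $\alpha = 0.05$ over hundreds of null replicates, scoring the
  uniformity replicates against one shared null reference to keep the
  quadratic statistic affordable.
- Degenerate inputs fail loudly: a zero-variance circular sample, an
  empty station set, a constant Mantel matrix, an observed co-occurrence
  outside the hypergeometric support, and an event series of one for
  density fitting are all explicit errors.

## Limitations

The analysis inherits the assumptions of its field: detections proxy
activity (an animal photographed is "active"), independence windows are
a heuristic against pseudo-replication rather than a movement model, the
co-occurrence null ignores imperfect detection, and community-level
curves pool across sites. The pipeline reports per-pair low-power flags
and sample sizes so that thin species (here, 42–61 events) are read with
the caution their intervals demand.
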