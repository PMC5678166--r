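---
title: "Models and calibration behind urbanforay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and calibration behind urbanforay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanforay)
```

# The problem

Animals that raid human settlements — here, adult male chacma baboons at a
suburban edge — trade a large energetic reward against the risk of being
deterred by rangers. Quantifying that trade-off from collar data requires
four ingredients: an activity proxy from tri-axial acceleration, a cleaned
and spatially annotated GPS track, gridded maps of food energy and
deterrence risk, and statistics that respect the spatial and repeated-
measures structure of the data. `urbanforay` implements each stage and a
synthetic collar-study generator so the whole chain can be validated
against known ground truth.

# Activity from acceleration

Raw tri-axial acceleration (in g) is decomposed into a *static* component —
the gravity-dominated, posture-encoding part, estimated per axis by a
centred running mean of 2 s — and a *dynamic* component, raw minus static.
VeDBA, the vectorial dynamic body acceleration, is the Euclidean norm of
the three dynamic components,

$$\mathrm{VeDBA} = \sqrt{X^2 + Y^2 + Z^2},$$

and serves as the fix-level activity proxy after averaging over the 30 s
before and after each GPS fix.

Numerical choices:

* The running mean is **centred**, with the window length in samples
  computed from each trace's own sampling rate (`round(2 * rate)`, forced
  odd), truncating at trace or burst edges. Whether the original field
  workflow used a centred or trailing mean is not recoverable; centred is
  the standard reading of "running mean" for static acceleration, and the
  oracle tests cover the implemented choice. Rate-awareness matters because
  one collar (male 2) records at 20 Hz: its window is 41 samples where the
  40 Hz collars use 81.
* An empty fix-anchoring window yields `NA`, never zero — a zero would
  masquerade as rest.
* The 60 s total window is justified by `window_sensitivity()`: for an
  activity series whose autocorrelation time is about a minute, the
  dispersion of per-fix means stabilises once the window covers the
  correlation time.

# Track cleaning

The filter cascade has a fixed order and records the fix count after every
stage: raw fixes, fixes with activity coverage, fixes inside daylight,
fixes surviving the jump filter.

* **Daylight filter.** A fix is retained when `sunrise <= t <= sunset` for
  its date. The boundary is closed: an explicit rule is needed, and
  inclusion is the weaker filter.
* **Jump filter.** Successive fixes more than 1 km apart are treated as
  positional errors. "A pair ... removed" is ambiguous about which member
  goes; dropping the *later* fix and rescanning forward avoids cascading
  deletion of valid positions. The rule is idempotent and tested against a
  repeated-pass oracle.
* **Projection.** Lon/lat input is converted to UTM (single zone) via the
  standard transverse-Mercator series; already-planar input passes
  through. Distances are planar Euclidean after projection.

# Landscape layers

The study extent is tiled by square cells of 150 m side, aligned to the
lower-left corner; the default scenario is 20 x 10 cells = 200. A cell
whose water coverage exceeds 50% ("mostly covered") is removed — exactly
one in the default landscape, leaving 199. Cells take the habitat of
majority area, with ties broken by the fixed ordering fynbos < trees <
meadows < vineyards < urban.

*Energy.* Each 1 m^2 quadrat scores the unweighted mean kcal/bite of the
food items present (an empty quadrat scores 0 — sampled, found nothing);
cell energy is the mean over its quadrats, and unsampled cells carry `NA`
rather than an imputed value. Urban cells are surveyed per residence under
the same averaging contract.

*Risk.* Eleven rangers score every cell 0 (allowed at any time), 1
(sometimes) or 2 (consistently chased); the composite deterrence score is
their sum, spanning 0-22. The composite is additive and
permutation-invariant in rangers by construction.

*Geometry.* Distance to the urban edge is 0 inside the urban region and
the minimum distance to its boundary otherwise. A fine (10 m) raster of
mean VeDBA supports map-style summaries.

# Forays and behavioural summaries

A *foray* (raid) is operationalised as a maximal run of consecutive
urban-habitat fixes for one male, broken by a non-urban fix, a recording
gap longer than twice the fix interval, or a day boundary; its duration is
`n_fixes x interval`, each fix representing its surrounding 5 minutes.
The printed mean raid duration (11 min at 5-min fixes, about 2 fixes) is
consistent with this rule. The activity contrast pools fix-level VeDBA
inside versus outside forays (the quantities the source reports as mean
+/- sd over observations); per-male summaries are also emitted. Time in
habitat is the share of retained daytime fixes, mirroring fix-based
accounting.

# Statistics

* **Kruskal-Wallis** uses mid-ranks and the standard ties correction (via
  `stats::kruskal.test`), with an exact enumeration option for small
  pooled n; the all-tied degenerate case returns H = 0.
* **Partial Mantel.** The deterrence dissimilarity (absolute composite
  difference), urbanisation dissimilarity (binary indicator difference)
  and spatial control (Euclidean centre distance) enter as distance
  matrices; the statistic is the correlation of the off-diagonal residuals
  after regressing each of the first two on the control, and significance
  comes from permuting the row/column order of the first matrix with the
  one-sided upper-tail `(count + 1)/(n_perm + 1)` rule (999 permutations,
  seeded). The variable encodings are this package's stated convention —
  the source names the variables but not their encodings.
* **Spatial mixed model.** `log(VeDBA) ~ risk` with a per-male random
  intercept and an exponential spatial correlation with nugget, fitted by
  REML (`nlme::lme`) with a small multi-start grid on (range, nugget) to
  guard against local optima. Non-convergence is reported with
  diagnostics. Data generated exactly on the fixed-effects line defeat
  likelihood fitting and are detected and solved exactly by least squares
  with per-male intercepts, flagged in the result. Note a documentation
  caveat: the comparable published fit reports a *negative* slope while
  describing activity as increasing with deterrence risk; under this
  package's coding (risk 0-22, larger = stricter deterrence) the
  recovered slope on the default synthetic data is positive, and the
  discrepancy is flagged rather than matched.

# The synthetic collar study

The generator's defaults *are* the study conditions: six males, 10
recording days each, GPS every 5 min from 07:30 to 18:00, acceleration at
40 Hz (20 Hz for male 2), and 49 planted urban incursions in total
(per-male defaults 5, 17, 8, 6, 6, 7 — each within the observed 5-17
range).

*States.* Outside the urban space the animal alternates between edge
resting, natural foraging and travelling: a renewal process with
exponential dwell times (means 40, 12 and 6 min) entered with stationary
occupancy (0.805, 0.080, 0.115), started in its stationary regime so
occupancy is exact over any finite day. Dwell times outside urban forays
are not reported anywhere; these are calibration choices, not claims about
the study system.

*VeDBA levels.* Each state has a mean VeDBA level, lognormally modulated
between fixes. Foraging and travel are set to 0.13 and 0.30 g and the
rest level is *solved* so the occupancy-weighted outside mean equals the
calibrated 0.08 g; urban forays are 0.19 g. The implied pooled outside sd
(~0.09 g) and inside sd (~0.11 g) fall out of the mixture rather than
being imposed. Acceleration is synthesised as a slowly tilting unit
gravity vector plus isotropic Gaussian dynamic noise whose scale makes
the *pipeline-recovered* VeDBA unbiased for the state level: the
running-mean residual attenuates white noise by `sqrt(1 - 1/n_win)`
(about 0.6% at 40 Hz), and because the calibration targets are themselves
outputs of that estimator, the synthesis pre-compensates by the inverse
factor, per collar sampling rate.

*Movement.* Distance to the urban edge follows an Ornstein-Uhlenbeck
process reflected at zero with stationary mean 300 m, sd 261 m and a
30-min correlation time; under a folded normal this reproduces the
calibrated quartiles (about 150 and 500 m) without prescribing behaviour
rules. An independent OU governs the along-edge coordinate, and small
per-state jitter (scaled by nominal state speeds) is added on top. All
positions are clamped inside the extent and never cross the urban
boundary except during planted forays.

*Planted forays.* Each foray occupies k consecutive fix ticks with
P(k = 1..4) = (0.35, 0.30, 0.15, 0.20) — mean 2.2 fixes, hence mean
duration 11.0 min. Foray fixes are always recorded (a raid is defined by
its recorded urban fixes); forays are separated by at least two non-urban
ticks so fix dropout can never merge two runs (two dropped separators
leave a 15-min gap, which the gap guard splits); they sit at least 30 min
inside the daylight window; and the animal closes to within ~450 m of the
edge on the flanking ticks so entry and exit steps stay far below the
1 km jump threshold. Together these guarantee the detector recovers the
planted count exactly.

*Observation model.* A scheduled non-foray fix is recorded with
probability 0.862, and 1% of recorded non-foray fixes are displaced by
more than 1.2 km (to be caught by the jump filter). These two rates were
solved jointly so that, after the daylight and jump filters, the expected
cross-male mean share of urban fixes is 1.8%. The synthetic daylight
table drifts sunrise later and sunset earlier by tens of seconds per day
(a fixed-offset time zone; no ephemeris), which both trims the 07:30-18:00
recording window to about 116 daytime fixes per day and exercises the
closed-boundary rule mid-period.

*Focals.* 311 thirty-minute focal observations (52 per male, 51 for the
last) sample uniform windows over the recording days; each minute is
labelled from the true state (foraging for natural-foraging and foray
minutes, travelling for travel, resting/grooming split 3:1 within rest).
The design foraging fraction is the occupancy solution 0.080 plus the
urban share, about 9.5%.

*Energy and risk surveys.* Food items are split into a natural pool (mean
0.5 kcal/bite) and an anthropogenic pool (mean 5.0), giving the 10:1
urban:natural cell-energy ratio in expectation because items are present
with equal probability within a pool. Ranger score profiles are
(0.05, 0.15, 0.80) over scores 0/1/2 in urban cells, (0.80, 0.15, 0.05)
in vineyards and (0.96, 0.035, 0.005) in natural habitat, which yields a
composite risk contrast of roughly 25x between urban and other cells.

*What the generator does not emulate.* Real collar data have
posture-dependent static acceleration, non-Gaussian dynamic noise,
GPS position error correlated with canopy, social travel, and ranger
behaviour that responds to the baboons in time. Passing the recovery
tests therefore shows the *pipeline* is correct and well calibrated, not
that the generative model is a faithful animal-movement model.

*Duty cycling.* By default acceleration is synthesised in bursts of
+/- 31.5 s around each recorded fix — enough to cover the +/- 30 s VeDBA
window plus the 2-s static window with full support — because only those
samples enter any downstream quantity; a continuous mode is available in
the configuration. The default six-male study processes in well under a
minute per seed on one core; the multi-seed recovery checks use 20
replicate studies.

# Known limitations

* The urban-versus-other VeDBA ratio is structurally the inside/outside
  foray contrast (urban fixes *are* foray fixes under the maximal-run
  rule), so it sits near 0.19/0.08 ~ 2.4 here; a published four-fold
  urban contrast cannot be reproduced jointly with the 0.19/0.08
  calibration under this operationalisation.
* Habitat geometry is rectangular by construction; the geometry helpers
  accept arbitrary simple polygons but the generator does not produce
  them.
* The jump filter assumes per-male time-ordered fixes and planar
  coordinates; it is not a speed filter and uses no HDOP/satellite
  quality information.
* `cell_energy` treats residence surveys and vegetation quadrats under
  one averaging contract; the real residence protocol is looser, and the
  aggregation here is a stated convention.
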