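# urbanforay

Tools for analysing GPS/tri-axial accelerometer collar data from animals
that exploit a risky, resource-rich urban edge — built around the study
design of raiding male chacma baboons at a suburban boundary, and usable
for any collared animal making brief incursions into a mapped "risk"
polygon.

The package implements the full chain from raw sensor streams to the
behavioural and statistical results:

* **Accelerometry** — decomposition of raw tri-axial acceleration into
  static (gravity/posture, centred 2-s running mean) and dynamic
  components, and VeDBA, the vectorial dynamic body acceleration
  `sqrt(X² + Y² + Z²)` of the dynamic components, averaged in a 60-s
  window centred on each GPS fix.
* **GPS cleaning** — UTM projection, a daylight filter (closed
  `[sunrise, sunset]` interval) and a 1-km forward-scan jump filter, with
  stage-by-stage fix bookkeeping.
* **Landscape** — a 150-m cell lattice with >50%-water cells removed,
  majority-area habitat assignment, quadrat-derived mean kcal/bite per
  cell, and a composite ranger deterrence score (eleven rangers scoring
  each cell 0/1/2, summed to 0–22).
* **Behaviour** — time-in-habitat fractions, distance-to-urban-edge
  quartiles, urban foray detection (maximal runs of consecutive urban
  fixes with gap and day guards), the inside/outside foray activity
  contrast, and focal time budgets compared against published foraging
  ranges.
* **Statistics** — ties-corrected Kruskal–Wallis (with exact enumeration
  for small n), a seeded permutation partial Mantel test with spatial
  control, and a REML mixed model of log-VeDBA on deterrence risk with a
  per-male random intercept and exponential spatial correlation with
  nugget (`nlme`).
* **Synthetic collar studies** — a seeded generator producing landscapes,
  ranger maps, quadrat surveys, state-switching GPS/acceleration streams
  with planted urban forays, focal observations, and full ground-truth
  labels, calibrated so the pipeline recovers the published headline
  values (1.8% urban time, 300 m median edge distance, 11-min forays at
  0.19 g versus 0.08 g outside, 9.5% foraging, 199 grid cells, 49 raids,
  10× urban energy).

## Worked example

Run the default six-male synthetic study end to end and summarise it:

```r
library(urbanforay)

cfg <- scenario_config()      # seed 42, 6 males, 10 days, 49 planted raids
run <- run_scenario(cfg)      # simulate -> decompose -> VeDBA -> clean -> annotate
run
#> scenario_run: 6 males, 199 cells, 5968 retained fixes, 49 forays

run$counts
#>            raw  with_activity after_daylight     after_jump
#>           6544           6544           6020           5968

tih <- time_in_habitat(run$annotated)
100 * tih$summary$mean[tih$summary$habitat == "urban"]
#> [1] 1.696114

edge_distance_summary(run$annotated)
#>       q1   median       q3
#> 171.2300 319.3702 487.2084

mean(run$forays$duration_min)
#> [1] 10.30612

foray_activity_contrast(run$forays, run$annotated)$inside[c("mean", "sd")]
#>      mean        sd
#> 0.1948218 0.0999211
```

Reading: the males kept ~1.7% of their daytime fixes inside the urban
space while staying a median ~320 m from its edge, and the detector found
exactly the 49 planted incursions, each brief (~10 min) and at roughly
2.5× the activity level of the time outside forays (0.195 g vs 0.078 g
VeDBA in this seed). `analyze_run(run)` adds the Kruskal–Wallis tests,
the partial Mantel test of deterrence vs urbanisation controlling for
space, the spatial mixed model, and the urban/natural energy ratio
(~10.6 here).

The same pipeline is available as disk-based subcommands
(`cmd_simulate()`, `cmd_process()`, `cmd_report()`, or the thin wrapper
script `inst/scripts/urbanforay`) that exchange CSV/GeoJSON files and
write a JSON run manifest at every stage.

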