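# Cached scenario runs shared across test files. The default six-male
# study takes ~15 s per seed, so the seed-42 run and the 20-seed batch are
# computed once per test session.

.test_cache <- new.env(parent = emptyenv())

default_run42 <- function() {
  if (is.null(.test_cache$run42))
    .test_cache$run42 <- run_scenario(scenario_config())
  .test_cache$run42
}

# Per-seed summary statistics over 20 replicate studies (seeds fixed and
# unrelated to any scenario seed).
acceptance_batch <- function(n_seeds = 20L) {
  key <- paste0("batch", n_seeds)
  if (!is.null(.test_cache[[key]])) return(.test_cache[[key]])
  out <- data.frame()
  for (s in seq_len(n_seeds)) {
    cfg <- scenario_config(seed = 70420 + s * 13)
    run <- run_scenario(cfg)
    tih <- time_in_habitat(run$annotated)
    ctr <- foray_activity_contrast(run$forays, run$annotated)
    bud <- focal_time_budget(run$focals)
    rat <- habitat_ratios(run$grid, run$annotated)
    out <- rbind(out, data.frame(
      urban_pct = 100 * tih$summary$mean[tih$summary$habitat == "urban"],
      dur = mean(run$forays$duration_min),
      inside = unname(ctr$inside["mean"]),
      outside = unname(ctr$outside["mean"]),
      forage_pct = 100 * bud$pooled$mean[bud$pooled$behaviour == "foraging"],
      vratio = rat$vedba_ratio,
      n_forays = nrow(run$forays),
      planted = sum(cfg$planted_incursions)))
  }
  .test_cache[[key]] <- out
  out
}

# A small, fast scenario for pipeline round-trip tests.
tiny_config <- function(seed = 7L) {
  scenario_config(seed = seed, n_males = 2L, n_days_per_male = 2L,
                  rec_start = "09:00", rec_end = "11:30",
                  accel_rates = c(40, 20),
                  planted_incursions = c(5L, 5L),
                  n_focals = c(4L, 4L),
                  daylight = list(sunrise = "07:52:00", sunrise_drift = 25,
                                  sunset = "17:39:00", sunset_drift = -30))
}
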