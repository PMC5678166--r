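# The synthetic collar-study generator: determinism, calibration,
# ground-truth conservation, geometry.

test_that("identical configurations generate byte-identical datasets", {
  cfg <- tiny_config(seed = 31L)
  d1 <- simulate_scenario(cfg, keep_accel = TRUE)
  d2 <- simulate_scenario(cfg, keep_accel = TRUE)
  expect_identical(serialize(d1$fixes, NULL), serialize(d2$fixes, NULL))
  expect_identical(serialize(d1$accel, NULL), serialize(d2$accel, NULL))
  expect_identical(serialize(d1$quadrats, NULL), serialize(d2$quadrats, NULL))
  expect_identical(d1$ranger_maps, d2$ranger_maps)
  # geometry determinism
  l1 <- gen_landscape(cfg$landscape, 42); l2 <- gen_landscape(cfg$landscape, 42)
  expect_identical(l1, l2)
})

test_that("generated landscape partitions the extent with one water cell", {
  spec <- landscape_spec()
  land <- gen_landscape(spec, 42)
  expect_setequal(names(land$habitat),
                  c("fynbos", "trees", "meadows", "vineyards", "urban"))
  areas <- vapply(land$habitat, poly_area, numeric(1))
  expect_equal(sum(areas), prod(spec$extent), tolerance = 1e-9)
  # exactly one cell majority-covered by water
  g <- build_grid(land, cell_side = spec$cell_side)
  expect_equal(nrow(attr(g, "removed")), 1)
  expect_error(gen_landscape(landscape_spec(extent = c(0, 100))), "positive")
})

test_that("ranger maps score every cell, high in urban and low in natural", {
  spec <- landscape_spec()
  land <- gen_landscape(spec, 1)
  g <- assign_habitat(build_grid(land, cell_side = 150), land$habitat)
  maps <- gen_ranger_maps(g, spec, 99)
  expect_equal(dim(maps), c(nrow(g), spec$ranger_count))
  expect_true(all(maps %in% 0:2))
  comp <- composite_risk(g, maps)
  urb <- comp$habitat == "urban"
  expect_gt(mean(comp$risk[urb]), mean(comp$risk[!urb]))
})

test_that("quadrat surveys reproduce the configured urban:natural energy ratio", {
  spec <- landscape_spec()
  land <- gen_landscape(spec, 1)
  g <- assign_habitat(build_grid(land, cell_side = 150), land$habitat)
  et <- default_energy_table(spec)
  # pool construction: urban pool mean is ratio x natural pool mean
  expect_equal(mean(et$kcal_per_bite[et$pool == "urban"]) /
               mean(et$kcal_per_bite[et$pool == "natural"]),
               spec$energy_ratio)
  expect_equal(et$kcal_per_bite, et$bite_mass_g * et$kcal_per_g,
               tolerance = 1e-12)
  qq <- gen_quadrats(g, et, spec, 7)
  # natural quadrats only contain natural-pool items
  nat_cells <- g$cell_id[g$habitat != "urban"]
  nat_q <- qq$quadrats$quadrat_id[qq$quadrats$cell_id %in% nat_cells]
  expect_true(all(qq$items$item[qq$items$quadrat_id %in% nat_q] %in%
                  et$item[et$pool == "natural"]))
  gE <- cell_energy(g, qq, et)
  r <- habitat_ratios(gE)$energy_ratio
  expect_equal(r, spec$energy_ratio, tolerance = 0.2)
  # unsampled cells are NA, not zero
  qq2 <- qq
  drop_cell <- nat_cells[1]
  keep <- qq2$quadrats$cell_id != drop_cell
  qq2$quadrats <- qq2$quadrats[keep, ]
  gE2 <- cell_energy(g, qq2, et)
  expect_true(is.na(gE2$energy[gE2$cell_id == drop_cell]))
})

test_that("a rest-only day stays out of the urban space at the rest level", {
  cfg <- tiny_config()
  cfg$states <- state_model(occupancy = c(rest_edge = 1, forage_natural = 0,
                                          travel = 0))
  land <- gen_landscape(cfg$landscape, 1)
  dl <- gen_daylight_table(cfg)
  day <- gen_collar_day(cfg, 1, dl$date[1], 0, 55L, land, dl[1, ])
  expect_true(all(day$truth$state == "rest_edge"))
  expect_true(all(day$fixes$x > cfg$landscape$urban_width))
  v <- vedba(decompose(day$accel))
  m <- mean_vedba_at_fixes(v, day$fixes$time)
  expect_equal(mean(m), unname(cfg$states$vedba_means["rest_edge"]),
               tolerance = 0.15)
})

test_that("planted incursions appear as exactly that many maximal urban runs", {
  cfg <- tiny_config()
  land <- gen_landscape(cfg$landscape, 1)
  dl <- gen_daylight_table(cfg)
  day <- gen_collar_day(cfg, 1, dl$date[1], 3, 77L, land, dl[1, ])
  r <- rle(!is.na(day$truth$bout_id))
  expect_equal(sum(r$values), 3)
  expect_equal(nrow(day$bouts), 3)
  # truth conservation at scenario level: planted total equals the number
  # of maximal urban runs in the emitted truth labels
  run <- default_run42()
  runs <- 0
  for (id in unique(run$truth$male_id)) {
    tr <- run$truth[run$truth$male_id == id, ]
    runs <- runs + length(unique(tr$bout_id[!is.na(tr$bout_id)]))
  }
  expect_equal(runs, sum(run$config$planted_incursions))
})

test_that("every generated GPS position lies inside the landscape extent", {
  run <- default_run42()
  ext <- run$landscape$extent
  fx <- run$annotated
  expect_true(all(fx$x >= 0 & fx$x <= ext[1]))
  expect_true(all(fx$y >= 0 & fx$y <= ext[2]))
})

test_that("dynamic-noise scaling calibrates the expected VeDBA level", {
  # E||N3(0, sd)|| equals the requested level, within 3 SE at n = 1e5
  set.seed(33)
  for (L in c(0.05, 0.19)) {
    s <- vedba_noise_sd(L)
    n <- 1e5
    v <- sqrt(rnorm(n, 0, s)^2 + rnorm(n, 0, s)^2 + rnorm(n, 0, s)^2)
    expect_lt(abs(mean(v) - L), 3 * sd(v) / sqrt(n))
  }
})

test_that("focal observations follow the state truth", {
  cfg <- tiny_config()
  # all-resting truth: zero foraging
  segs <- data.frame(start_min = 0, end_min = 150, state = "rest_edge",
                     male_id = "M1", date = as.Date(cfg$start_date))
  segs <- rbind(segs, transform(segs, date = as.Date(cfg$start_date) + 1,
                                male_id = "M1"))
  cfg1 <- cfg; cfg1$n_males <- 1L; cfg1$n_focals <- 10L
  cfg1$accel_rates <- 40; cfg1$planted_incursions <- 5L
  foc <- gen_focals(cfg1, list(segments = segs, bouts = NULL), 5)
  expect_true(all(foc$behaviour %in% c("resting", "grooming")))

  # requested focal count is honoured: 311 records of 30 minutes
  cfg2 <- scenario_config(n_days_per_male = 2)
  segs2 <- do.call(rbind, lapply(1:6, function(m)
    data.frame(start_min = 0, end_min = 630, state = "forage_natural",
               male_id = sprintf("M%d", m),
               date = rep(as.Date(cfg2$start_date) + 0:1, each = 1))))
  foc2 <- gen_focals(cfg2, list(segments = segs2, bouts = NULL), 5)
  expect_equal(length(unique(foc2$focal_id)), 311)
  expect_equal(nrow(foc2), 311 * 30)
})

test_that("scenario configs validate and survive a YAML round-trip", {
  expect_error(scenario_config(n_males = 0), "n_males")
  expect_error(scenario_config(planted_incursions = 3L), "between 5 and 17")
  expect_error(scenario_config(gps_interval = 0), "gps_interval")
  cfg <- tiny_config(seed = 9L)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, f)
  back <- read_scenario_config(f)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$states$vedba_means, cfg$states$vedba_means)
  expect_equal(back$landscape$extent, cfg$landscape$extent)
  expect_equal(back$planted_incursions, cfg$planted_incursions)
  # identical config => identical data
  d1 <- simulate_scenario(cfg, keep_accel = FALSE)
  d2 <- simulate_scenario(back, keep_accel = FALSE)
  expect_identical(serialize(d1$fixes, NULL), serialize(d2$fixes, NULL))
})

test_that("daylight table is generated with sunrise before sunset", {
  dl <- gen_daylight_table(scenario_config())
  expect_equal(nrow(dl), 10)
  expect_true(all(dl$sunrise < dl$sunset))
})
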