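# Habitat time shares, edge distances, foray detection, activity
# contrast, focal budgets.

mk_ann <- function(habitats, male_id = "M1",
                   t0 = as.POSIXct("2014-04-03 08:00", tz = "Etc/GMT-2"),
                   interval = 300, vedba = 0.1) {
  data.frame(male_id = male_id, time = t0 + (seq_along(habitats) - 1) * interval,
             habitat = factor(habitats,
                              levels = c("fynbos", "trees", "meadows",
                                         "vineyards", "urban")),
             mean_vedba = rep_len(vedba, length(habitats)))
}

test_that("habitat time shares are fix fractions with cross-male summary", {
  ann <- rbind(mk_ann(c(rep("fynbos", 98), rep("urban", 2))),
               mk_ann(rep("fynbos", 50), male_id = "M2"))
  tih <- time_in_habitat(ann)
  expect_equal(unname(tih$per_male["M1", "urban"]), 0.02)
  expect_equal(unname(tih$per_male["M2", "urban"]), 0)
  # per-male fractions sum to one over the five habitats
  expect_equal(unname(rowSums(tih$per_male)), c(1, 1), tolerance = 1e-9)
  s <- tih$summary[tih$summary$habitat == "urban", ]
  expect_equal(s$mean, 0.01)
  expect_equal(s$se, sd(c(0.02, 0)) / sqrt(2))
  expect_equal(c(s$min, s$max), c(0, 0.02))
  # males with zero classified fixes are excluded and reported
  ann3 <- rbind(ann, data.frame(male_id = "M3", time = ann$time[1],
                                habitat = factor(NA, levels = levels(ann$habitat)),
                                mean_vedba = NA))
  tih3 <- time_in_habitat(ann3)
  expect_equal(attr(tih3, "excluded_males"), "M3")
})

test_that("edge distance summary pools quartiles with urban fixes at zero", {
  ann <- data.frame(dist_urban_edge = c(0, 100, 200, 300, 400))
  s <- edge_distance_summary(ann)
  expect_equal(unname(s["median"]), 200)
  expect_true(s["q1"] < s["median"] && s["median"] < s["q3"])
  expect_equal(unname(edge_distance_summary(
    data.frame(dist_urban_edge = rep(0, 9)))["median"]), 0)
})

test_that("foray detection finds maximal urban runs with gap and day guards", {
  f <- detect_forays(mk_ann(c("fynbos", "fynbos", "urban", "urban", "fynbos")))
  expect_equal(nrow(f), 1)
  expect_equal(f$n_fixes, 2)
  expect_equal(f$duration_min, 10)

  f2 <- detect_forays(mk_ann(c("urban", "fynbos", "urban")))
  expect_equal(nrow(f2), 2)
  expect_equal(f2$n_fixes, c(1, 1))

  # recording gap > 2 x interval splits a run
  ann <- mk_ann(rep("urban", 4))
  ann$time[3:4] <- ann$time[3:4] + 601
  expect_equal(nrow(detect_forays(ann)), 2)
  ann$time[3:4] <- ann$time[3:4] - 601 + 300  # exactly 2 x interval: no split
  expect_equal(nrow(detect_forays(ann)), 1)

  # runs never merge across days
  ann2 <- mk_ann(rep("urban", 2))
  ann2$time[2] <- ann2$time[2] + 86400 - 300
  expect_equal(nrow(detect_forays(ann2)), 2)

  # invariant to pre/appending non-urban fixes
  base <- mk_ann(c("urban", "urban"))
  padded <- rbind(mk_ann("fynbos", t0 = base$time[1] - 300), base,
                  mk_ann("trees", t0 = base$time[2] + 300))
  expect_equal(detect_forays(padded)$n_fixes, detect_forays(base)$n_fixes)

  expect_equal(nrow(detect_forays(mk_ann(rep("fynbos", 5)))), 0)
})

test_that("foray fix counts conserve the urban fix total", {
  run <- default_run42()
  expect_equal(sum(run$forays$n_fixes),
               sum(run$annotated$habitat == "urban", na.rm = TRUE))
})

test_that("activity contrast stratifies fix-level VeDBA by foray membership", {
  ann <- mk_ann(c("fynbos", "urban", "urban", "fynbos"), vedba = 0.2)
  f <- detect_forays(ann)
  ctr <- foray_activity_contrast(f, ann)
  expect_equal(unname(ctr$inside["mean"]), unname(ctr$outside["mean"]))
  expect_equal(unname(ctr$inside["n"]), 2)
  # no forays: inside stratum missing
  ann2 <- mk_ann(rep("fynbos", 4))
  ctr2 <- foray_activity_contrast(detect_forays(ann2), ann2)
  expect_true(is.na(ctr2$inside["mean"]))
  expect_equal(unname(ctr2$outside["n"]), 4)
})

test_that("focal budgets compute per-class minute fractions", {
  foc <- data.frame(male_id = "M1",
                    behaviour = c(rep("foraging", 3), rep("resting", 27)))
  b <- focal_time_budget(foc)
  expect_equal(unname(b$per_male["M1", "foraging"]), 0.10)
  expect_equal(sum(b$per_male), 1)
  foc2 <- data.frame(male_id = "M1", behaviour = rep("grooming", 5))
  b2 <- focal_time_budget(foc2)
  expect_equal(unname(b2$per_male["M1", "grooming"]), 1)
  expect_error(focal_time_budget(data.frame(male_id = "M1",
                                            behaviour = "flying")), "flying")
})

test_that("literature budgets stay inside the published range and drive the comparison", {
  lit <- literature_budgets()
  expect_true(all(lit$foraging_pct >= 20.3 & lit$foraging_pct <= 59.3))
  b <- focal_time_budget(data.frame(
    male_id = rep(c("M1", "M2"), each = 30),
    behaviour = rep(c(rep("foraging", 3), rep("resting", 27)), 2)))
  cmp <- budget_comparison(b)
  expect_equal(cmp$flag, "below range")
  expect_equal(cmp$groups$focal, c(10, 10))
  # a budget equal to a literature entry differs from it by zero
  b2 <- focal_time_budget(data.frame(
    male_id = "M1",
    behaviour = c(rep("foraging", 203), rep("resting", 797))))
  cmp2 <- budget_comparison(b2)
  expect_equal(min(abs(cmp2$groups$focal[1] - cmp2$groups$literature)), 0)
  expect_equal(cmp2$flag, "within range")
})

test_that("foray detection recovers planted counts as recording lengthens", {
  # one male, no acceleration needed: habitat annotation alone drives the
  # detector; planted count must be recovered at 10 and at 40 days
  for (nd in c(10L, 40L)) {
    cfg <- scenario_config(n_males = 1L, n_days_per_male = nd,
                           accel_rates = 40, planted_incursions = 8L,
                           n_focals = 5L, burst_margin = 0.3)
    land <- gen_landscape(cfg$landscape, 1)
    dl <- gen_daylight_table(cfg)
    sm <- sim_male(cfg, 1, land, dl)
    grid <- assign_habitat(build_grid(land, cell_side = 150), land$habitat)
    casc <- filter_cascade(sm$fixes, dl)
    ann <- annotate_fixes(casc$fixes, grid, land$urban)
    expect_equal(nrow(detect_forays(ann, cfg$gps_interval)), 8)
    # pooled edge-distance median stays near the configured attraction point
    med <- unname(edge_distance_summary(ann)["median"])
    expect_lt(abs(med - cfg$states$movement$mu_dist) /
              cfg$states$movement$mu_dist, 0.15)
  }
})
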