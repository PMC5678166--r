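# End-to-end orchestration: in-memory pipeline (generate -> decompose ->
# VeDBA -> clean -> grid -> annotate -> summarise), disk-based subcommands
# (simulate / process / report), run manifests, and the reference-target
# computation.

# Static (non-collar) scenario layers shared by simulate and run.
gen_scenario_static <- function(cfg) {
  landscape <- gen_landscape(cfg$landscape, derive_seed(cfg$seed, 1))
  grid <- build_grid(landscape, cell_side = cfg$landscape$cell_side)
  grid <- assign_habitat(grid, landscape$habitat)
  ranger_maps <- gen_ranger_maps(grid, cfg$landscape, derive_seed(cfg$seed, 2))
  energy_table <- default_energy_table(cfg$landscape)
  quadrats <- gen_quadrats(grid, energy_table, cfg$landscape,
                           derive_seed(cfg$seed, 3))
  grid <- cell_energy(grid, quadrats, energy_table)
  grid <- composite_risk(grid, ranger_maps)
  list(landscape = landscape, grid = grid, ranger_maps = ranger_maps,
       energy_table = energy_table, quadrats = quadrats,
       daylight = gen_daylight_table(cfg))
}

#' Run the full synthetic study through the analysis pipeline in memory
#'
#' For each male: simulate the collar streams, decompose the acceleration,
#' compute VeDBA and its fix-anchored means, then (per the fixed cascade
#' order) apply the daylight and jump filters, annotate the retained fixes
#' against the grid, and detect forays. Acceleration traces are processed
#' male-by-male and released, so the default six-male scenario runs in
#' modest memory.
#'
#' @param cfg A [scenario_config()].
#' @return A list of class `scenario_run` with `config`, `grid`,
#'   `landscape`, `annotated` (annotated fixes), `counts` (cascade stage
#'   counts), `forays`, `truth`, `bouts`, `segments`, `focals`,
#'   `energy_table`, `quadrats`, `ranger_maps`, `daylight`.
#' @export
run_scenario <- function(cfg) {
  validate_scenario_config(cfg)
  st <- gen_scenario_static(cfg)
  fixes <- list(); truth <- list(); bouts <- list(); segments <- list()
  for (m in seq_len(cfg$n_males)) {
    sm <- sim_male(cfg, m, st$landscape, st$daylight)
    tr <- decompose(sm$accel)
    vs <- vedba(tr)
    sm$fixes$mean_vedba <- mean_vedba_at_fixes(vs, sm$fixes$time)
    rm(tr, vs)
    fixes[[m]] <- sm$fixes
    truth[[m]] <- sm$truth
    bouts[[m]] <- sm$bouts
    segments[[m]] <- sm$segments
  }
  fixes <- project_to_planar(do.call(rbind, fixes))
  casc <- filter_cascade(fixes, st$daylight)
  annotated <- annotate_fixes(casc$fixes, st$grid, st$landscape$urban)
  segments <- do.call(rbind, segments)
  bouts <- do.call(rbind, bouts)
  focals <- gen_focals(cfg, list(segments = segments, bouts = bouts),
                       derive_seed(cfg$seed, 4))
  run <- list(config = cfg, grid = st$grid, landscape = st$landscape,
              annotated = annotated, counts = casc$counts,
              forays = detect_forays(annotated, cfg$gps_interval),
              truth = do.call(rbind, truth), bouts = bouts,
              segments = segments, focals = focals,
              energy_table = st$energy_table, quadrats = st$quadrats,
              ranger_maps = st$ranger_maps, daylight = st$daylight)
  class(run) <- "scenario_run"
  run
}

#' Summarise a pipeline run into the full results set
#'
#' Computes habitat time shares, the distance-to-edge distribution, foray
#' statistics and activity contrast, focal budgets with the literature
#' comparison, urban/non-urban ratios, the Kruskal-Wallis tests of energy
#' and VeDBA by habitat, the partial Mantel test of deterrence versus
#' urbanisation controlling for space, and the spatial mixed model of
#' log-VeDBA on risk.
#'
#' @param run A [run_scenario()] result.
#' @param n_perm Permutations for the partial Mantel test.
#' @param fit_lmm Fit the (comparatively slow) spatial mixed model.
#' @return A named list of results.
#' @export
analyze_run <- function(run, n_perm = 999, fit_lmm = TRUE) {
  ann <- run$annotated
  grid <- run$grid
  tih <- time_in_habitat(ann)
  edge <- edge_distance_summary(ann)
  forays <- run$forays
  contrast <- foray_activity_contrast(forays, ann)
  budget <- focal_time_budget(run$focals)
  comparison <- budget_comparison(budget)
  ratios <- habitat_ratios(grid, ann)
  kw_energy <- kruskal_wallis(split(grid$energy[!is.na(grid$energy)],
                                    droplevels(grid$habitat[!is.na(grid$energy)])))
  ok <- !is.na(ann$mean_vedba) & !is.na(ann$habitat)
  kw_vedba <- kruskal_wallis(split(ann$mean_vedba[ok],
                                   droplevels(ann$habitat[ok])))
  kw_budget <- kruskal_wallis(comparison$groups)
  sp <- as.matrix(stats::dist(cbind(grid$cx, grid$cy)))
  risk_d <- as.matrix(stats::dist(grid$risk))
  urb_d <- as.matrix(stats::dist(as.numeric(grid$habitat == "urban")))
  mantel <- partial_mantel(risk_d, urb_d, sp, n_perm = n_perm,
                           seed = derive_seed(run$config$seed, 5))
  # a failed fit is reported with its diagnostics, not raised mid-report
  lmm <- if (fit_lmm)
    tryCatch(fit_vedba_lmm(ann),
             error = function(e) list(converged = FALSE,
                                      error = conditionMessage(e)))
    else NULL
  list(time_in_habitat = tih, edge_distance = edge, forays = forays,
       foray_duration_mean = if (nrow(forays)) mean(forays$duration_min) else NA,
       activity_contrast = contrast, focal_budget = budget,
       budget_comparison = comparison, habitat_ratios = ratios,
       kw_energy = kw_energy, kw_vedba = kw_vedba, kw_budget = kw_budget,
       partial_mantel = mantel, lmm = lmm, counts = run$counts)
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf(
    "scenario_run: %d males, %d cells, %d retained fixes, %d forays\n",
    x$config$n_males, nrow(x$grid), nrow(x$annotated), nrow(x$forays)))
  invisible(x)
}

# ---- disk-based subcommands ----------------------------------------------

fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3%z")

parse_time <- function(s, tz) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS%z",
                                         tz = tz)

write_fixes_csv <- function(fixes, path) {
  df <- fixes
  df$time <- fmt_time(df$time)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_fixes_csv <- function(path, tz) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$time <- parse_time(df$time, tz)
  df
}

#' Simulate a synthetic dataset to disk
#'
#' Writes the full synthetic dataset (per-male acceleration and GPS CSVs,
#' landscape GeoJSON, ranger/quadrat/energy/daylight/focal tables, truth
#' labels, the scenario config, and a run manifest) under `out_dir`.
#' Deterministic: the same config produces an identical directory tree.
#'
#' @param config A [scenario_config()] or the path to one written by
#'   [write_scenario_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_scenario_config(config) else config
  validate_scenario_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_scenario(cfg, keep_accel = TRUE)
  write_scenario_config(cfg, file.path(out_dir, "scenario.yaml"))
  for (id in names(ds$accel))
    write_accel_csv(ds$accel[[id]], file.path(out_dir,
                                              sprintf("accel_%s.csv", id)))
  write_fixes_csv(ds$fixes, file.path(out_dir, "gps_fixes.csv"))
  jsonlite::write_json(
    list(type = "FeatureCollection",
         features = lapply(names(ds$landscape$habitat), function(h)
           list(type = "Feature", properties = list(habitat = h),
                geometry = list(type = "Polygon",
                                coordinates = list(lapply(
                                  seq_len(nrow(ds$landscape$habitat[[h]])),
                                  function(i) ds$landscape$habitat[[h]][i, ])))))),
    file.path(out_dir, "landscape.geojson"), auto_unbox = TRUE, digits = NA)
  if (length(ds$landscape$water))
    utils::write.csv(as.data.frame(ds$landscape$water[[1]]),
                     file.path(out_dir, "water_polygon.csv"), row.names = FALSE)
  rm_long <- data.frame(cell_id = rep(rownames(ds$ranger_maps),
                                      ncol(ds$ranger_maps)),
                        ranger = rep(colnames(ds$ranger_maps),
                                     each = nrow(ds$ranger_maps)),
                        score = as.vector(ds$ranger_maps))
  utils::write.csv(rm_long, file.path(out_dir, "ranger_maps.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$quadrats$quadrats, file.path(out_dir, "quadrats.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$quadrats$items, file.path(out_dir, "quadrat_items.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$energy_table, file.path(out_dir, "energy_table.csv"),
                   row.names = FALSE)
  dl <- ds$daylight
  dl$sunrise <- fmt_time(dl$sunrise); dl$sunset <- fmt_time(dl$sunset)
  utils::write.csv(dl, file.path(out_dir, "daylight.csv"), row.names = FALSE)
  tr <- ds$truth; tr$time <- fmt_time(tr$time)
  utils::write.csv(tr, file.path(out_dir, "truth_labels.csv"),
                   row.names = FALSE)
  if (!is.null(ds$bouts))
    utils::write.csv(ds$bouts, file.path(out_dir, "truth_bouts.csv"),
                     row.names = FALSE)
  utils::write.csv(ds$focals, file.path(out_dir, "focals.csv"),
                   row.names = FALSE)
  manifest <- list(stage = "simulate", version = pkg_version(),
                   seed = cfg$seed, n_males = cfg$n_males,
                   counts = list(gps_fixes = nrow(ds$fixes),
                                 planted_incursions = sum(cfg$planted_incursions)),
                   accel_rates = cfg$accel_rates,
                   outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Process a simulated dataset directory through the pipeline
#'
#' Reads the collar streams written by [cmd_simulate()], runs decompose ->
#' VeDBA -> filter cascade -> grid build -> annotation, and writes the
#' annotated fixes, populated grid and a manifest with stage-by-stage fix
#' counts. Missing acceleration files degrade to missing VeDBA with a
#' warning rather than failing.
#'
#' @param data_dir Directory produced by [cmd_simulate()].
#' @param out_dir Output directory.
#' @return The manifest, invisibly.
#' @export
cmd_process <- function(data_dir, out_dir) {
  need <- c("scenario.yaml", "gps_fixes.csv", "daylight.csv")
  for (f in need)
    if (!file.exists(file.path(data_dir, f)))
      stop("missing input file: ", file.path(data_dir, f))
  cfg <- read_scenario_config(file.path(data_dir, "scenario.yaml"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fixes <- read_fixes_csv(file.path(data_dir, "gps_fixes.csv"), cfg$tz)
  dl <- utils::read.csv(file.path(data_dir, "daylight.csv"),
                        stringsAsFactors = FALSE)
  dl$date <- as.Date(dl$date)
  dl$sunrise <- parse_time(dl$sunrise, cfg$tz)
  dl$sunset <- parse_time(dl$sunset, cfg$tz)
  fixes$mean_vedba <- NA_real_
  for (m in seq_len(cfg$n_males)) {
    id <- sprintf("M%d", m)
    f <- file.path(data_dir, sprintf("accel_%s.csv", id))
    if (!file.exists(f)) {
      warning("no acceleration data for ", id, "; VeDBA left missing")
      next
    }
    tr <- read_accel_csv(f, cfg$accel_rates[m], id, cfg$tz)
    vs <- vedba(decompose(tr))
    sel <- fixes$male_id == id
    fixes$mean_vedba[sel] <- mean_vedba_at_fixes(vs, fixes$time[sel])
  }
  landscape <- gen_landscape(cfg$landscape, derive_seed(cfg$seed, 1))
  grid <- assign_habitat(build_grid(landscape,
                                    cell_side = cfg$landscape$cell_side),
                         landscape$habitat)
  rm_long <- utils::read.csv(file.path(data_dir, "ranger_maps.csv"),
                             stringsAsFactors = FALSE)
  grid <- composite_risk(grid, rm_long)
  qq <- list(quadrats = utils::read.csv(file.path(data_dir, "quadrats.csv")),
             items = utils::read.csv(file.path(data_dir, "quadrat_items.csv"),
                                     stringsAsFactors = FALSE))
  etab <- utils::read.csv(file.path(data_dir, "energy_table.csv"),
                          stringsAsFactors = FALSE)
  grid <- cell_energy(grid, qq, etab)
  fixes <- project_to_planar(fixes)
  casc <- filter_cascade(fixes, dl)
  annotated <- annotate_fixes(casc$fixes, grid, landscape$urban)
  write_fixes_csv(annotated, file.path(out_dir, "annotated_fixes.csv"))
  gdf <- as.data.frame(grid)
  utils::write.csv(gdf, file.path(out_dir, "grid_layers.csv"),
                   row.names = FALSE)
  write_grid_geojson(grid, file.path(out_dir, "grid_layers.geojson"))
  file.copy(file.path(data_dir, c("scenario.yaml", "focals.csv")),
            out_dir, overwrite = TRUE)
  manifest <- list(stage = "process", version = pkg_version(),
                   seed = cfg$seed,
                   counts = as.list(casc$counts),
                   n_annotated = nrow(annotated),
                   outputs = c("annotated_fixes.csv", "grid_layers.csv",
                               "grid_layers.geojson"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Produce the results bundle from processed outputs
#'
#' Emits the behavioural and statistical results tables (habitat time,
#' edge distances, forays, activity contrast, focal budgets and literature
#' comparison, habitat ratios, rank tests, partial Mantel, mixed model) as
#' CSV/JSON, plus simple density-plot figures.
#'
#' @param processed_dir Directory produced by [cmd_process()].
#' @param out_dir Output directory (defaults to `processed_dir`).
#' @param figures Write PNG figures.
#' @param n_perm Permutations for the partial Mantel test.
#' @return The results list, invisibly.
#' @export
cmd_report <- function(processed_dir, out_dir = processed_dir,
                       figures = TRUE, n_perm = 999) {
  cfg <- read_scenario_config(file.path(processed_dir, "scenario.yaml"))
  annotated <- read_fixes_csv(file.path(processed_dir, "annotated_fixes.csv"),
                              cfg$tz)
  annotated$habitat <- factor(annotated$habitat,
                              levels = c("fynbos", "trees", "meadows",
                                         "vineyards", "urban"))
  gdf <- utils::read.csv(file.path(processed_dir, "grid_layers.csv"),
                         stringsAsFactors = FALSE)
  gdf$habitat <- factor(gdf$habitat, levels = levels(annotated$habitat))
  focals <- utils::read.csv(file.path(processed_dir, "focals.csv"),
                            stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- list(config = cfg, grid = gdf, annotated = annotated,
              forays = detect_forays(annotated, cfg$gps_interval),
              focals = focals, counts = c(retained = nrow(annotated)))
  class(run) <- "scenario_run"
  res <- analyze_run(run, n_perm = n_perm)
  utils::write.csv(res$forays |> transform(entry_time = fmt_time(entry_time),
                                           exit_time = fmt_time(exit_time)),
                   file.path(out_dir, "forays.csv"), row.names = FALSE)
  utils::write.csv(res$time_in_habitat$summary,
                   file.path(out_dir, "time_in_habitat.csv"), row.names = FALSE)
  utils::write.csv(res$budget_comparison$table,
                   file.path(out_dir, "time_budgets.csv"), row.names = FALSE)
  n_forays <- nrow(res$forays)
  summary_json <- list(
    n_forays = n_forays,
    foray_note = if (n_forays == 0) "no urban incursions detected" else NULL,
    foray_duration_mean_min = res$foray_duration_mean,
    vedba_inside = as.list(res$activity_contrast$inside),
    vedba_outside = as.list(res$activity_contrast$outside),
    edge_distance_m = as.list(res$edge_distance),
    urban_time_pct = 100 * res$time_in_habitat$summary$mean[
      res$time_in_habitat$summary$habitat == "urban"],
    foraging_pct = 100 * res$focal_budget$pooled$mean[
      res$focal_budget$pooled$behaviour == "foraging"],
    budget_flag = res$budget_comparison$flag,
    habitat_ratios = res$habitat_ratios[c("energy_ratio", "risk_ratio",
                                          "vedba_ratio")],
    kw_energy = unclass(res$kw_energy), kw_vedba = unclass(res$kw_vedba),
    kw_budget = unclass(res$kw_budget),
    partial_mantel = unclass(res$partial_mantel),
    lmm = if (!is.null(res$lmm)) unclass(res$lmm) else NULL,
    counts = as.list(res$counts))
  jsonlite::write_json(summary_json, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (figures) report_figures(res, annotated, gdf, out_dir)
  invisible(res)
}

# Density-plot figures (energy and VeDBA by habitat, distance to edge).
report_figures <- function(res, annotated, grid, out_dir) {
  safe_density <- function(vals, groups, main, xlab, file) {
    grDevices::png(file.path(out_dir, file), width = 800, height = 500)
    on.exit(grDevices::dev.off())
    groups <- droplevels(factor(groups))
    cols <- grDevices::hcl.colors(max(2, nlevels(groups)), "Dark 3")
    first <- TRUE
    for (i in seq_len(nlevels(groups))) {
      v <- vals[groups == levels(groups)[i]]
      v <- v[!is.na(v)]
      if (length(v) < 2) next
      d <- stats::density(v)
      if (first) {
        plot(d, main = main, xlab = xlab, col = cols[i], lwd = 2)
        first <- FALSE
      } else graphics::lines(d, col = cols[i], lwd = 2)
    }
    graphics::legend("topright", legend = levels(groups), col = cols, lwd = 2)
  }
  ok <- !is.na(grid$energy)
  safe_density(grid$energy[ok], grid$habitat[ok],
               "Cell energy by habitat", "kcal/bite", "fig_energy.png")
  ok <- !is.na(annotated$mean_vedba) & !is.na(annotated$habitat)
  safe_density(annotated$mean_vedba[ok], annotated$habitat[ok],
               "Fix VeDBA by habitat", "VeDBA (g)", "fig_vedba.png")
  grDevices::png(file.path(out_dir, "fig_edge_distance.png"),
                 width = 800, height = 500)
  plot(stats::density(annotated$dist_urban_edge),
       main = "Distance to urban edge", xlab = "metres")
  grDevices::dev.off()
  invisible(NULL)
}

pkg_version <- function() {
  as.character(utils::packageVersion("urbanforay"))
}

#' Compute the reference-target quantities for the default scenario
#'
#' Re-runs the full pipeline on the default synthetic study and measures
#' the headline quantities: urban time fraction, edge-distance median,
#' foray count/duration, inside/outside VeDBA, foraging budget, maximum
#' composite risk, and the energy and VeDBA habitat ratios. Single-seed
#' quantities use the default scenario seed (42); multi-seed quantities
#' average over `n_seeds` seeds derived from `seed`.
#'
#' @param seed Base seed for the multi-seed batch.
#' @param n_seeds Number of scenario replicates for averaged quantities.
#' @param progress Print per-seed progress lines.
#' @return Named list of `list(value =, n =)` entries.
#' @export
compute_reference_targets <- function(seed = 1L, n_seeds = 20L,
                                      progress = FALSE) {
  # maximum attainable composite score: eleven rangers x top score
  spec <- landscape_spec()
  land <- gen_landscape(spec)
  g0 <- assign_habitat(build_grid(land, cell_side = spec$cell_side),
                       land$habitat)
  allmax <- matrix(2L, nrow(g0), spec$ranger_count)
  t8 <- max(composite_risk(g0, allmax)$risk)

  # default-seed scenario (the scenario's own seed, 42)
  run42 <- run_scenario(scenario_config())
  edge <- edge_distance_summary(run42$annotated)
  t2 <- unname(edge["median"])
  t9 <- nrow(run42$forays)
  t10 <- habitat_ratios(run42$grid)$energy_ratio

  per_seed <- data.frame(urban_pct = numeric(0), dur = numeric(0),
                         inside = numeric(0), outside = numeric(0),
                         forage_pct = numeric(0), vratio = numeric(0),
                         n_fixes = numeric(0))
  for (s in seq_len(n_seeds)) {
    cfg <- scenario_config(seed = derive_seed(seed, 50 + s))
    run <- run_scenario(cfg)
    tih <- time_in_habitat(run$annotated)
    contrast <- foray_activity_contrast(run$forays, run$annotated)
    budget <- focal_time_budget(run$focals)
    ratios <- habitat_ratios(run$grid, run$annotated)
    per_seed[s, ] <- c(
      100 * tih$summary$mean[tih$summary$habitat == "urban"],
      mean(run$forays$duration_min),
      contrast$inside["mean"], contrast$outside["mean"],
      100 * budget$pooled$mean[budget$pooled$behaviour == "foraging"],
      ratios$vedba_ratio, nrow(run$annotated))
    if (progress)
      message(sprintf("seed %d/%d: urban %.2f%%, dur %.2f min",
                      s, n_seeds, per_seed$urban_pct[s], per_seed$dur[s]))
  }
  n_fix <- round(mean(per_seed$n_fixes))
  list(
    t1 = list(value = mean(per_seed$urban_pct), n = n_seeds),
    t2 = list(value = t2, n = nrow(run42$annotated)),
    t3 = list(value = mean(per_seed$dur), n = n_seeds),
    t4 = list(value = mean(per_seed$outside), n = n_seeds),
    t5 = list(value = mean(per_seed$inside), n = n_seeds),
    t6 = list(value = mean(per_seed$forage_pct), n = n_seeds),
    t8 = list(value = t8, n = nrow(g0)),
    t9 = list(value = t9, n = nrow(run42$annotated)),
    t10 = list(value = t10, n = nrow(run42$grid)),
    t11 = list(value = mean(per_seed$vratio), n = n_seeds)
  )
}

#' Write the reference targets as JSON (CLI `targets` subcommand)
#'
#' @param out Output JSON path.
#' @inheritParams compute_reference_targets
#' @return The targets list, invisibly.
#' @export
cmd_targets <- function(out, seed = 1L, n_seeds = 20L) {
  tg <- compute_reference_targets(seed = seed, n_seeds = n_seeds)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(tg, out, auto_unbox = TRUE, digits = NA)
  invisible(tg)
}
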