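# Synthetic collar-study generator: landscape, ranger score maps, quadrat
# surveys, state-switching GPS/acceleration streams with planted urban
# forays, and minute-level focal observations — all with ground-truth
# labels so every downstream stage can be tested against known answers.

# Expected norm of a standard trivariate normal; used to scale dynamic
# acceleration noise so that E[VeDBA] equals the configured state level.
.chi3_mean <- sqrt(2) * gamma(2) / gamma(3 / 2)

vedba_noise_sd <- function(level) level / .chi3_mean

#' Generate the synthetic landscape
#'
#' Partitions a rectangular extent into the five habitat classes with the
#' urban region occupying the full western edge (so the urban edge is the
#' vertical line `x = urban_width`), vineyards bordering the urban strip,
#' a trees/meadows band, and fynbos covering the remainder. One circular
#' water body is placed at a configured cell centre. The geometry is a
#' deterministic function of the spec; the seed argument is accepted for
#' interface uniformity with the other generators.
#'
#' @param spec A [landscape_spec()].
#' @param seed Integer seed (unused by the default deterministic geometry).
#' @return List with `extent`, `habitat` (named list of polygons), `water`
#'   (list of polygons), `urban` (the urban region polygon) and `spec`.
#' @export
gen_landscape <- function(spec, seed = 0L) {
  validate_landscape_spec(spec)
  W <- spec$extent[1]; H <- spec$extent[2]; uw <- spec$urban_width
  vine_w <- min(300, (W - uw) * 0.2)
  mid_w <- min(300, (W - uw) * 0.2)
  habitat <- list(
    urban = rect_polygon(0, uw, 0, H),
    vineyards = rect_polygon(uw, uw + vine_w, 0, H),
    trees = rect_polygon(uw + vine_w, uw + vine_w + mid_w, 0, H / 2),
    meadows = rect_polygon(uw + vine_w, uw + vine_w + mid_w, H / 2, H),
    fynbos = rect_polygon(uw + vine_w + mid_w, W, 0, H)
  )
  water <- list()
  if (!is.null(spec$water)) {
    cc <- unlist(spec$water$cell)
    if (is.null(names(cc))) names(cc) <- c("col", "row")
    cx <- (cc[["col"]] - 0.5) * spec$cell_side
    cy <- (cc[["row"]] - 0.5) * spec$cell_side
    r <- spec$water$radius
    if (cx - r < 0 || cx + r > W || cy - r < 0 || cy + r > H)
      stop("water body does not fit inside the extent")
    water <- list(circle_polygon(cx, cy, r))
  }
  list(extent = spec$extent, habitat = habitat, water = water,
       urban = habitat$urban, spec = spec)
}

#' Generate per-ranger deterrence score maps
#'
#' Every ranger scores every retained cell in \{0, 1, 2\}, drawn from the
#' habitat's score profile (urban cells from the high-score profile,
#' vineyards intermediate, natural habitats from the low-score profile).
#'
#' @param grid A [build_grid()] layer with habitat assigned.
#' @param spec A [landscape_spec()].
#' @param seed Integer seed.
#' @return Integer matrix, cells x rangers, rows in `grid$cell_id` order.
#' @export
gen_ranger_maps <- function(grid, spec, seed) {
  if (is.null(grid$habitat)) stop("grid must have habitat assigned")
  set.seed(seed)
  prof <- function(h) {
    switch(as.character(h),
           urban = spec$risk_profiles$urban,
           vineyards = spec$risk_profiles$vineyards,
           spec$risk_profiles$natural)
  }
  m <- matrix(0L, nrow(grid), spec$ranger_count)
  for (i in seq_len(nrow(grid)))
    m[i, ] <- sample(0:2, spec$ranger_count, replace = TRUE,
                     prob = prof(grid$habitat[i]))
  rownames(m) <- grid$cell_id
  colnames(m) <- paste0("ranger", seq_len(spec$ranger_count))
  m
}

#' Default food-item energy table
#'
#' Six natural and six anthropogenic food items with bite mass (g/bite) and
#' energy density (kcal/g); `kcal_per_bite` is their product. Item values
#' are scaled so the natural pool mean equals `natural_energy_mean` and the
#' urban pool mean equals `natural_energy_mean * energy_ratio` (10:1 by
#' default). All items and values are synthetic.
#'
#' @param spec A [landscape_spec()].
#' @return Data frame with `item`, `pool`, `bite_mass_g`, `kcal_per_g`,
#'   `kcal_per_bite`.
#' @export
default_energy_table <- function(spec = landscape_spec()) {
  nat <- data.frame(
    item = c("fynbos_flowers", "grass_seeds", "roots_bulbs", "acorns",
             "pine_nuts", "berries"),
    pool = "natural",
    bite_mass_g = c(0.80, 0.40, 1.50, 1.80, 0.55, 1.00),
    base = c(0.12, 0.08, 0.30, 0.90, 1.10, 0.50))
  urb <- data.frame(
    item = c("bread", "cultivated_fruit", "processed_snacks", "refuse_mixed",
             "grapes", "cooked_food"),
    pool = "urban",
    bite_mass_g = c(1.68, 4.00, 1.70, 2.65, 2.75, 2.80),
    base = c(4.2, 2.8, 8.5, 5.3, 2.2, 7.0))
  nat$kcal_per_bite <- nat$base * spec$natural_energy_mean / mean(nat$base)
  urb$kcal_per_bite <- urb$base *
    spec$natural_energy_mean * spec$energy_ratio / mean(urb$base)
  tab <- rbind(nat, urb)
  tab$kcal_per_g <- tab$kcal_per_bite / tab$bite_mass_g
  tab[, c("item", "pool", "bite_mass_g", "kcal_per_g", "kcal_per_bite")]
}

#' Generate quadrat / residence survey records
#'
#' Natural-habitat cells receive 1-m2 vegetation quadrats (count drawn
#' around the configured mean); urban cells are surveyed per residence with
#' item lists from the anthropogenic pool, under the same
#' presence/absence-plus-bite-count record structure. Cells drawing zero
#' quadrats stay unsampled (missing, not zero-energy).
#'
#' @param grid A [build_grid()] layer with habitat assigned.
#' @param energy_table An energy table (see [default_energy_table()]).
#' @param spec A [landscape_spec()].
#' @param seed Integer seed.
#' @return List with `quadrats` (`cell_id`, `quadrat_id`, `kind`) and
#'   `items` (`quadrat_id`, `item`, `bites`).
#' @export
gen_quadrats <- function(grid, energy_table, spec, seed) {
  if (nrow(energy_table) == 0) stop("energy table is empty")
  if (is.null(grid$habitat)) stop("grid must have habitat assigned")
  set.seed(seed)
  nat_items <- energy_table$item[energy_table$pool == "natural"]
  urb_items <- energy_table$item[energy_table$pool == "urban"]
  qrows <- list(); irows <- list(); qid <- 0L
  for (i in seq_len(nrow(grid))) {
    urban <- grid$habitat[i] == "urban"
    n <- if (urban) 2L + stats::rpois(1, 3) else
      max(0L, min(15L, round(stats::rnorm(1, spec$quadrat_mean,
                                          spec$quadrat_sd))))
    if (n == 0L) next
    pool <- if (urban) urb_items else nat_items
    for (k in seq_len(n)) {
      qid <- qid + 1L
      qrows[[qid]] <- data.frame(cell_id = grid$cell_id[i], quadrat_id = qid,
                                 kind = if (urban) "residence" else "quadrat")
      present <- pool[stats::runif(length(pool)) < spec$presence_prob]
      if (length(present))
        irows[[length(irows) + 1L]] <- data.frame(
          quadrat_id = qid, item = present,
          bites = 1L + stats::rpois(length(present), 8))
    }
  }
  list(quadrats = do.call(rbind, qrows),
       items = if (length(irows)) do.call(rbind, irows) else
         data.frame(quadrat_id = integer(0), item = character(0),
                    bites = integer(0)))
}

# ---- collar-day simulation ------------------------------------------------

# Sample a semi-Markov out-of-urban state sequence covering `total_min`
# minutes, started in its stationary regime (state drawn with stationary
# occupancy; exponential dwells are memoryless, so the residual dwell is a
# fresh exponential). Returns a data frame of segments.
sample_state_segments <- function(sm, total_min) {
  occ <- sm$occupancy
  tau <- sm$dwell_means_min[names(occ)]
  q <- occ / tau; q <- q / sum(q)   # segment-entry distribution
  states <- names(occ)
  st <- sample(states, 1, prob = occ)   # stationary start
  starts <- 0; labels <- st
  cur <- stats::rexp(1, 1 / tau[[st]])
  while (cur < total_min) {
    st <- sample(states, 1, prob = q)
    starts <- c(starts, cur)
    labels <- c(labels, st)
    cur <- cur + stats::rexp(1, 1 / tau[[st]])
  }
  data.frame(start_min = starts,
             end_min = c(starts[-1], total_min),
             state = labels)
}

state_at_minutes <- function(segments, minutes) {
  idx <- findInterval(minutes, segments$start_min)
  idx[idx < 1L] <- 1L
  segments$state[idx]
}

# Place `n` urban bouts (k consecutive fix ticks each) on the day's tick
# grid: inside the daylight window with a 30-min buffer, at least 3 ticks
# from the day edges, and separated from each other by at least 2
# non-urban ticks so recording dropout can never merge two bouts.
place_bouts <- function(n, sizes, tick_times, sunrise, sunset) {
  n_ticks <- length(tick_times)
  eligible <- which(tick_times >= sunrise + 1800 &
                    tick_times <= sunset - 1800)
  eligible <- eligible[eligible >= 4L & eligible <= n_ticks - 4L]
  occupied <- rep(FALSE, n_ticks)
  out <- vector("list", n)
  for (b in seq_len(n)) {
    k <- sizes[b]
    ok_start <- eligible[vapply(eligible, function(s) {
      span <- max(1L, s - 3L):min(n_ticks, s + k + 2L)
      s + k - 1L <= max(eligible) && !any(occupied[span])
    }, logical(1))]
    if (!length(ok_start))
      stop("cannot place ", n, " incursions in one day; reduce the count")
    s <- if (length(ok_start) == 1L) ok_start else sample(ok_start, 1)
    occupied[s:(s + k - 1L)] <- TRUE
    out[[b]] <- data.frame(start_tick = s, n_fixes = k)
  }
  do.call(rbind, out)
}

#' Simulate one collar-day for one male
#'
#' Draws a stationary-start state sequence, plants the requested urban
#' incursions as runs of consecutive fixes inside the urban strip,
#' integrates an Ornstein-Uhlenbeck distance-to-edge process for the
#' out-of-urban positions, applies GPS fix dropout and occasional >1 km
#' positional error spikes, and synthesises tri-axial acceleration so the
#' expected VeDBA of each sample equals the (lognormally modulated) state
#' level. Planted foray fixes are always recorded and the animal closes to
#' within 450 m of the edge on the ticks flanking a foray, so entry and
#' exit steps stay well under the 1 km jump-filter threshold.
#'
#' @param cfg A [scenario_config()].
#' @param male Male index (1-based; determines the accelerometer rate).
#' @param date Date of the simulated day.
#' @param incursions Number of urban forays to plant this day.
#' @param seed Integer seed for this male-day.
#' @param landscape A [gen_landscape()] result.
#' @param daylight_row One row of [gen_daylight_table()] for `date`.
#' @return List with `fixes` (recorded fixes: `male_id`, `time`, `x`, `y`,
#'   `spike`), `truth` (all ticks: `state`, `bout_id`, `vedba_level`,
#'   `recorded`), `bouts`, `segments`, and `accel` (an [accel_trace()]).
#' @export
gen_collar_day <- function(cfg, male, date, incursions, seed, landscape,
                           daylight_row) {
  set.seed(seed)
  sm <- cfg$states
  mv <- sm$movement
  W <- landscape$extent[1]; H <- landscape$extent[2]
  uw <- cfg$landscape$urban_width
  male_id <- sprintf("M%d", male)
  rate <- cfg$accel_rates[male]
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = cfg$tz) +
    hms_to_sec(cfg$rec_start)
  t_end <- as.POSIXct(paste(date, "00:00:00"), tz = cfg$tz) +
    hms_to_sec(cfg$rec_end)
  dt <- cfg$gps_interval
  tick_times <- seq(from = t0, to = t_end, by = dt)
  n_ticks <- length(tick_times)
  total_min <- as.numeric(difftime(t_end, t0, units = "mins"))

  segments <- sample_state_segments(sm, total_min)
  state <- state_at_minutes(segments,
                            as.numeric(difftime(tick_times, t0, units = "mins")))

  bouts <- NULL
  bout_id <- rep(NA_integer_, n_ticks)
  if (incursions > 0) {
    sizes <- as.integer(sample(names(sm$foray_fix_probs), incursions,
                               replace = TRUE, prob = sm$foray_fix_probs))
    bouts <- place_bouts(incursions, sizes, tick_times,
                         daylight_row$sunrise, daylight_row$sunset)
    for (b in seq_len(nrow(bouts))) {
      ii <- bouts$start_tick[b]:(bouts$start_tick[b] + bouts$n_fixes[b] - 1L)
      state[ii] <- "urban_foray"
      bout_id[ii] <- b
    }
  }
  in_bout <- !is.na(bout_id)

  # distance-to-edge OU (reflected at 0.5 m) + along-edge OU
  phi_d <- exp(-dt / 60 / mv$tau_dist_min)
  sd_d <- mv$sd_dist * sqrt(1 - phi_d^2)
  phi_y <- exp(-dt / 60 / mv$tau_y_min)
  sd_y <- mv$sd_y * sqrt(1 - phi_y^2)
  d <- numeric(n_ticks); yy <- numeric(n_ticks)
  d_prev <- abs(stats::rnorm(1, mv$mu_dist, mv$sd_dist))
  y_prev <- min(max(stats::rnorm(1, H / 2, mv$sd_y), 5), H - 5)
  x <- numeric(n_ticks)
  pre_bout <- c(in_bout[-1], FALSE) & !in_bout
  post_bout <- c(FALSE, in_bout[-n_ticks]) & !in_bout
  pre2_bout <- c(pre_bout[-1], FALSE) & !in_bout  # staged approach to the edge
  for (j in seq_len(n_ticks)) {
    if (in_bout[j]) {
      x[j] <- stats::runif(1, max(10, uw - 130), uw - 20)
      d[j] <- 0
      d_prev <- min(d_prev, stats::runif(1, 150, 300))  # re-enter near edge
    } else {
      dj <- abs(mv$mu_dist + phi_d * (d_prev - mv$mu_dist) +
                stats::rnorm(1, 0, sd_d))
      if (pre_bout[j] || post_bout[j]) dj <- min(dj, stats::runif(1, 150, 450))
      if (pre2_bout[j]) dj <- min(dj, stats::runif(1, 400, 800))
      d[j] <- max(dj, 0.5)
      d_prev <- d[j]
      x[j] <- uw + d[j]
    }
    y_prev <- H / 2 + phi_y * (y_prev - H / 2) + stats::rnorm(1, 0, sd_y)
    y_prev <- min(max(y_prev, 5), H - 5)
    yy[j] <- y_prev
  }
  # per-state local jitter, clamped so a fix never changes urban side
  js <- mv$jitter_speed[state] * dt / 4
  x <- x + stats::rnorm(n_ticks, 0, js)
  yy <- pmin(pmax(yy + stats::rnorm(n_ticks, 0, js), 5), H - 5)
  x[in_bout] <- pmin(pmax(x[in_bout], 10), uw - 10)
  x[!in_bout] <- pmin(pmax(x[!in_bout], uw + 0.5), W - 5)

  recorded <- in_bout | stats::runif(n_ticks) < cfg$fix_success

  # positional error spikes (>1.2 km), isolated and away from bouts
  spike <- rep(FALSE, n_ticks)
  if (cfg$spike_prob > 0) {
    near_bout <- rep(FALSE, n_ticks)
    for (j in which(in_bout))
      near_bout[max(1, j - 3):min(n_ticks, j + 3)] <- TRUE
    cand <- which(recorded & !near_bout)
    cand <- cand[cand > 1 & cand < n_ticks]
    sel <- cand[stats::runif(length(cand)) < cfg$spike_prob]
    if (length(sel) > 1) sel <- sel[c(TRUE, diff(sel) > 2)]  # keep spikes isolated
    for (j in sel) {
      for (try in 1:50) {
        xs <- stats::runif(1, 0, W); ys <- stats::runif(1, 0, H)
        if (sqrt((xs - x[j])^2 + (ys - yy[j])^2) > 1200) {
          x[j] <- xs; yy[j] <- ys; spike[j] <- TRUE
          break
        }
      }
    }
  }

  # lognormal between-fix modulation of the state VeDBA level
  mu_v <- sm$vedba_means[state]
  cv <- sm$vedba_sds[state] / mu_v
  slog <- sqrt(log(1 + cv^2))
  level <- mu_v * exp(stats::rnorm(n_ticks, 0, slog) - slog^2 / 2)

  accel <- synth_accel(cfg, male_id, rate, tick_times, level, recorded, t0)

  fixes <- data.frame(male_id = male_id, time = tick_times, x = x, y = yy,
                      spike = spike)[recorded, , drop = FALSE]
  rownames(fixes) <- NULL
  truth <- data.frame(male_id = male_id, time = tick_times, tick = seq_len(n_ticks),
                      state = state, bout_id = bout_id,
                      vedba_level = as.numeric(level), recorded = recorded)
  if (!is.null(bouts)) {
    bouts$male_id <- male_id
    bouts$date <- date
  }
  segments$male_id <- male_id
  segments$date <- date
  list(fixes = fixes, truth = truth, bouts = bouts, segments = segments,
       accel = accel)
}

# Synthesise tri-axial acceleration: a gravity-aligned static vector with
# slow orientation drift plus isotropic dynamic noise. The noise scale is
# chosen so the VeDBA *recovered by the analysis* (dynamic = raw minus a
# centred 2-s running mean) is unbiased for the fix-level `level`: the
# running-mean residual attenuates per-axis noise by sqrt(1 - 1/n_win), and
# the printed state levels the generator is calibrated to are themselves
# outputs of that estimator, so the synthesis pre-compensates for it.
synth_accel <- function(cfg, male_id, rate, tick_times, level, recorded, t0) {
  n_win <- round(2 * rate)
  if (n_win %% 2 == 0) n_win <- n_win + 1
  smoothing_comp <- 1 / sqrt(1 - 1 / n_win)
  if (cfg$accel_coverage == "bursts") {
    m <- floor(cfg$burst_margin * rate)
    off <- (-m:m) / rate
    ticks <- which(recorded)
    if (!length(ticks)) return(NULL)
    tt <- rep(as.numeric(tick_times[ticks]), each = length(off)) +
      rep(off, length(ticks))
    lv <- rep(level[ticks], each = length(off))
  } else {
    tt <- seq(as.numeric(tick_times[1]) - cfg$burst_margin,
              as.numeric(tick_times[length(tick_times)]) + cfg$burst_margin,
              by = 1 / rate)
    idx <- pmax(1L, findInterval(tt, as.numeric(tick_times) -
                                   cfg$gps_interval / 2))
    idx <- pmin(idx, length(level))
    lv <- level[idx]
  }
  n <- length(tt)
  rel <- tt - as.numeric(t0)
  theta <- 0.20 * sin(2 * pi * rel / 557) + 0.05
  phi_az <- 2 * pi * rel / 733
  sx <- sin(theta) * cos(phi_az)
  sy <- sin(theta) * sin(phi_az)
  sz <- cos(theta)
  sd_dyn <- vedba_noise_sd(lv) * smoothing_comp
  ax <- sx + stats::rnorm(n, 0, sd_dyn)
  ay <- sy + stats::rnorm(n, 0, sd_dyn)
  az <- sz + stats::rnorm(n, 0, sd_dyn)
  accel_trace(.POSIXct(tt, tz = cfg$tz), ax, ay, az, rate, male_id)
}

# Spread a male's planted incursions over recording days (at most
# `cap` per day).
assign_incursion_days <- function(k, n_days, cap = 3L) {
  cap <- max(cap, ceiling(k / n_days))
  repeat {
    days <- sample(seq_len(n_days), k, replace = TRUE)
    if (max(tabulate(days, n_days)) <= cap) return(days)
  }
}

#' Simulate one male's full recording period
#'
#' @param cfg A [scenario_config()].
#' @param male Male index.
#' @param landscape A [gen_landscape()] result.
#' @param daylight Daylight table from [gen_daylight_table()].
#' @return List with `fixes`, `truth`, `bouts`, `segments` (data frames over
#'   all days) and `accel` (one [accel_trace()] spanning the period, with
#'   inter-burst gaps).
#' @export
sim_male <- function(cfg, male, landscape, daylight) {
  set.seed(derive_seed(cfg$seed, 100 + male))
  days <- assign_incursion_days(cfg$planted_incursions[male],
                                cfg$n_days_per_male)
  per_day <- tabulate(days, cfg$n_days_per_male)
  out <- vector("list", cfg$n_days_per_male)
  for (dix in seq_len(cfg$n_days_per_male)) {
    out[[dix]] <- gen_collar_day(
      cfg, male, daylight$date[dix], per_day[dix],
      seed = derive_seed(cfg$seed, male * 1000 + dix),
      landscape = landscape, daylight_row = daylight[dix, ])
    if (!is.null(out[[dix]]$bouts)) {
      out[[dix]]$bouts$day <- dix
      out[[dix]]$truth$bout_id <- ifelse(
        is.na(out[[dix]]$truth$bout_id), NA_integer_,
        out[[dix]]$truth$bout_id + 1000L * dix)
    }
  }
  accel_parts <- Filter(Negate(is.null), lapply(out, `[[`, "accel"))
  accel <- do.call(rbind, accel_parts)
  if (!is.null(accel)) {
    attr(accel, "sampling_rate") <- cfg$accel_rates[male]
    attr(accel, "male_id") <- sprintf("M%d", male)
    class(accel) <- c("accel_trace", "data.frame")
  }
  list(fixes = do.call(rbind, lapply(out, `[[`, "fixes")),
       truth = do.call(rbind, lapply(out, `[[`, "truth")),
       bouts = do.call(rbind, lapply(out, `[[`, "bouts")),
       segments = do.call(rbind, lapply(out, `[[`, "segments")),
       accel = accel)
}

#' Simulate the full synthetic collar study
#'
#' Generates the landscape, grid, ranger maps, quadrat surveys, daylight
#' table, per-male collar streams with ground truth, and focal
#' observations. With `keep_accel = FALSE` the (large) acceleration traces
#' are dropped after generation; use [run_scenario()] to process them
#' through the analysis pipeline without retaining them.
#'
#' @param cfg A [scenario_config()].
#' @param keep_accel Keep per-male acceleration traces in the result.
#' @return A list of class `collar_dataset`.
#' @export
simulate_scenario <- function(cfg, keep_accel = TRUE) {
  validate_scenario_config(cfg)
  landscape <- gen_landscape(cfg$landscape, derive_seed(cfg$seed, 1))
  grid <- build_grid(landscape, cell_side = cfg$landscape$cell_side)
  grid <- assign_habitat(grid, landscape$habitat)
  ranger_maps <- gen_ranger_maps(grid, cfg$landscape, derive_seed(cfg$seed, 2))
  energy_table <- default_energy_table(cfg$landscape)
  quadrats <- gen_quadrats(grid, energy_table, cfg$landscape,
                           derive_seed(cfg$seed, 3))
  daylight <- gen_daylight_table(cfg)
  males <- lapply(seq_len(cfg$n_males), function(m)
    sim_male(cfg, m, landscape, daylight))
  truth <- do.call(rbind, lapply(males, `[[`, "truth"))
  segments <- do.call(rbind, lapply(males, `[[`, "segments"))
  bouts <- do.call(rbind, lapply(males, `[[`, "bouts"))
  focals <- gen_focals(cfg, list(segments = segments, bouts = bouts),
                       derive_seed(cfg$seed, 4))
  accel <- if (keep_accel)
    stats::setNames(lapply(males, `[[`, "accel"),
                    sprintf("M%d", seq_len(cfg$n_males))) else NULL
  ds <- list(config = cfg, landscape = landscape, grid = grid,
             ranger_maps = ranger_maps, energy_table = energy_table,
             quadrats = quadrats, daylight = daylight,
             fixes = do.call(rbind, lapply(males, `[[`, "fixes")),
             truth = truth, bouts = bouts, segments = segments,
             focals = focals, accel = accel)
  class(ds) <- "collar_dataset"
  ds
}

#' Generate minute-level focal observations from the state truth
#'
#' Samples 30-min focal windows uniformly over each male's recording days
#' and labels every minute from the true behavioural state: foraging for
#' natural-foraging and urban-foray minutes, travelling for travel, and
#' resting/grooming (3:1 within-state split) for edge-resting minutes.
#'
#' @param cfg A [scenario_config()].
#' @param state_truth List with `segments` and `bouts` as produced by
#'   [simulate_scenario()] / [sim_male()].
#' @param seed Integer seed.
#' @return Data frame with `male_id`, `focal_id`, `date`, `minute`
#'   (offset within the recording day) and `behaviour`.
#' @export
gen_focals <- function(cfg, state_truth, seed) {
  set.seed(seed)
  total_min <- (hms_to_sec(cfg$rec_end) - hms_to_sec(cfg$rec_start)) / 60
  dates <- as.Date(cfg$start_date) + seq_len(cfg$n_days_per_male) - 1L
  out <- list()
  fid <- 0L
  for (m in seq_len(cfg$n_males)) {
    male_id <- sprintf("M%d", m)
    segs <- state_truth$segments[state_truth$segments$male_id == male_id, ]
    bts <- state_truth$bouts
    bts <- if (is.null(bts)) NULL else bts[bts$male_id == male_id, ]
    for (f in seq_len(cfg$n_focals[m])) {
      fid <- fid + 1L
      dix <- sample(cfg$n_days_per_male, 1)
      start <- sample(0:(total_min - cfg$focal_len), 1)
      minutes <- start + seq_len(cfg$focal_len) - 1L
      dsegs <- segs[segs$date == dates[dix], ]
      st <- state_at_minutes(dsegs, minutes + 0.5)
      if (!is.null(bts) && nrow(bts)) {
        db <- bts[bts$date == dates[dix], ]
        for (b in seq_len(nrow(db))) {
          s0 <- (db$start_tick[b] - 1) * cfg$gps_interval / 60 -
            cfg$gps_interval / 120
          s1 <- s0 + db$n_fixes[b] * cfg$gps_interval / 60
          st[minutes + 0.5 >= s0 & minutes + 0.5 < s1] <- "urban_foray"
        }
      }
      beh <- ifelse(st %in% c("forage_natural", "urban_foray"), "foraging",
             ifelse(st == "travel", "travelling",
                    ifelse(stats::runif(length(st)) < 0.75, "resting",
                           "grooming")))
      out[[fid]] <- data.frame(male_id = male_id, focal_id = fid,
                               date = dates[dix], minute = minutes,
                               behaviour = beh)
    }
  }
  do.call(rbind, out)
}
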