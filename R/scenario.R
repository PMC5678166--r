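# Scenario configuration for the synthetic collar study.
#
# Defaults reproduce the study conditions the analysis is calibrated to:
# six collared adult males, 5-min GPS from 07:30 to 18:00 over 10 days each,
# 40 Hz tri-axial acceleration (20 Hz for male 2), 49 planted urban
# incursions in total (5-17 per male), an urban edge at one side of a
# 3000 x 1500 m extent gridded into 200 cells of 150 m side, and state-level
# VeDBA calibrated to 0.08 g outside forays and 0.19 g inside.

#' Landscape specification for the synthetic study area
#'
#' Describes a rectangular extent partitioned into five habitat classes with
#' the urban region occupying one full edge (so a well-defined urban edge
#' line exists), one water body, per-habitat ranger deterrence profiles and
#' the urban:natural energy ratio.
#'
#' @param extent Numeric length-2, extent width and height in metres.
#' @param cell_side Grid cell side in metres (cells are squares).
#' @param urban_width Width in metres of the urban strip along the x = 0 edge.
#' @param water Either `NULL` (no water body) or a list with `cell = c(col,
#'   row)` and `radius` (metres) placing one circular water body at a cell
#'   centre.
#' @param natural_energy_mean Mean kcal/bite of the natural food-item pool.
#' @param energy_ratio Target ratio of urban to natural mean kcal/bite.
#' @param ranger_count Number of rangers scoring every cell (composite risk
#'   therefore spans 0 to `2 * ranger_count`).
#' @param risk_profiles Named list of probability vectors over scores
#'   \{0, 1, 2\} for urban, vineyard and natural cells.
#' @param quadrat_mean,quadrat_sd Per-cell quadrat count distribution
#'   (rounded normal, truncated at 0 and 15).
#' @param presence_prob Per-item presence probability within a quadrat.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(extent = c(3000, 1500),
                           cell_side = 150,
                           urban_width = 450,
                           water = list(cell = c(col = 12, row = 5), radius = 65),
                           natural_energy_mean = 0.5,
                           energy_ratio = 10,
                           ranger_count = 11L,
                           risk_profiles = list(
                             urban    = c(0.05, 0.15, 0.80),
                             vineyards = c(0.80, 0.15, 0.05),
                             natural  = c(0.96, 0.035, 0.005)
                           ),
                           quadrat_mean = 7, quadrat_sd = 3.5,
                           presence_prob = 0.35) {
  spec <- list(extent = as.numeric(extent), cell_side = cell_side,
               urban_width = urban_width, water = water,
               natural_energy_mean = natural_energy_mean,
               energy_ratio = energy_ratio,
               ranger_count = as.integer(ranger_count),
               risk_profiles = risk_profiles,
               quadrat_mean = quadrat_mean, quadrat_sd = quadrat_sd,
               presence_prob = presence_prob)
  class(spec) <- "landscape_spec"
  validate_landscape_spec(spec)
  spec
}

validate_landscape_spec <- function(spec) {
  if (any(spec$extent <= 0)) stop("landscape extent must have positive area")
  if (spec$cell_side <= 0) stop("cell_side must be positive")
  if (spec$urban_width <= 0 || spec$urban_width >= spec$extent[1])
    stop("urban_width must lie strictly inside the extent")
  for (p in spec$risk_profiles)
    if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("risk profiles must be probability vectors over scores {0,1,2}")
  invisible(spec)
}

#' Behavioural state model for the synthetic generator
#'
#' A continuous-time state process with exponential dwell times. Outside the
#' urban space the animal alternates between edge resting, natural foraging
#' and travelling with the given stationary occupancy; urban forays are
#' planted separately (see [scenario_config()]). Per-state VeDBA levels are
#' lognormally modulated between fixes; the rest-state mean is solved so the
#' occupancy-weighted outside mean equals `outside_vedba_mean`.
#'
#' @param dwell_means_min Named mean dwell times in minutes for
#'   `rest_edge`, `forage_natural`, `travel` and `urban_foray`.
#' @param occupancy Stationary occupancy of the three out-of-urban states
#'   (must sum to 1).
#' @param outside_vedba_mean Target fix-level mean VeDBA (g) outside forays.
#' @param vedba_means Mean VeDBA (g) per state; the `rest_edge` entry may be
#'   `NA`, in which case it is solved from `outside_vedba_mean`.
#' @param vedba_sds Between-fix sd of the state VeDBA level (g).
#' @param movement List of Ornstein-Uhlenbeck parameters for the
#'   distance-to-edge process (`mu_dist`, `sd_dist`, `tau_dist_min`), the
#'   along-edge process (`sd_y`, `tau_y_min`) and per-state jitter speeds in
#'   m/s.
#' @param foray_fix_probs Distribution of the number of consecutive GPS
#'   fixes per planted urban foray (names are fix counts).
#' @return An object of class `state_model`.
#' @export
state_model <- function(dwell_means_min = c(rest_edge = 40, forage_natural = 12,
                                            travel = 6, urban_foray = 11),
                        occupancy = c(rest_edge = 0.805, forage_natural = 0.080,
                                      travel = 0.115),
                        outside_vedba_mean = 0.08,
                        vedba_means = c(rest_edge = NA, forage_natural = 0.13,
                                        travel = 0.30, urban_foray = 0.19),
                        vedba_sds = c(rest_edge = 0.035, forage_natural = 0.05,
                                      travel = 0.07, urban_foray = 0.10),
                        movement = list(mu_dist = 300, sd_dist = 261,
                                        tau_dist_min = 30,
                                        sd_y = 400, tau_y_min = 60,
                                        jitter_speed = c(rest_edge = 0.01,
                                                         forage_natural = 0.07,
                                                         travel = 0.40,
                                                         urban_foray = 0.30)),
                        foray_fix_probs = c("1" = 0.35, "2" = 0.30,
                                            "3" = 0.15, "4" = 0.20)) {
  if (abs(sum(occupancy) - 1) > 1e-9)
    stop("out-of-urban occupancy must sum to 1")
  if (any(dwell_means_min <= 0)) stop("dwell means must be positive")
  if (is.na(vedba_means["rest_edge"])) {
    # solve occupancy-weighted outside mean for the rest level
    other <- occupancy["forage_natural"] * vedba_means["forage_natural"] +
      occupancy["travel"] * vedba_means["travel"]
    vedba_means["rest_edge"] <-
      (outside_vedba_mean - unname(other)) / occupancy["rest_edge"]
  }
  if (any(vedba_means < 0)) stop("state VeDBA means must be non-negative")
  if (abs(sum(foray_fix_probs) - 1) > 1e-9)
    stop("foray_fix_probs must sum to 1")
  sm <- list(states = c("rest_edge", "forage_natural", "travel", "urban_foray"),
             dwell_means_min = dwell_means_min, occupancy = occupancy,
             outside_vedba_mean = outside_vedba_mean,
             vedba_means = vedba_means, vedba_sds = vedba_sds,
             movement = movement, foray_fix_probs = foray_fix_probs)
  class(sm) <- "state_model"
  sm
}

#' Full scenario configuration for the synthetic collar study
#'
#' @param seed Integer master seed; identical configurations (including the
#'   seed) generate byte-identical data.
#' @param n_males Number of collared males.
#' @param n_days_per_male Recording days per male.
#' @param gps_interval GPS fix interval in seconds.
#' @param accel_rates Per-male accelerometer sampling rates in Hz; the
#'   default records male 2 at 20 Hz and all others at 40 Hz.
#' @param rec_start,rec_end Recording window as "HH:MM" local clock times.
#' @param start_date First recording date (ISO string).
#' @param tz Time zone; a fixed local offset by default.
#' @param planted_incursions Integer vector (recycled to `n_males`) of urban
#'   incursions planted per male; each must lie in \[5, 17\].
#' @param fix_success Probability that a scheduled GPS fix outside a foray is
#'   actually recorded (planted foray fixes are always recorded).
#' @param spike_prob Probability that a recorded non-foray fix is displaced
#'   by a positional error of more than 1 km (to be caught by the jump
#'   filter).
#' @param n_focals Number of 30-min focal observations per male (recycled).
#' @param focal_len Focal length in minutes.
#' @param landscape A [landscape_spec()].
#' @param states A [state_model()].
#' @param accel_coverage `"bursts"` synthesises acceleration only around each
#'   recorded GPS fix (enough to cover the VeDBA window); `"continuous"`
#'   synthesises the full day.
#' @param burst_margin Half-width in seconds of the synthesised acceleration
#'   burst around each fix.
#' @param daylight List with `sunrise`, `sunset` ("HH:MM:SS") on the first
#'   day and per-day drifts in seconds (`sunrise_drift`, `sunset_drift`);
#'   used by [gen_daylight_table()].
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 42L,
                            n_males = 6L,
                            n_days_per_male = 10L,
                            gps_interval = 300,
                            accel_rates = c(40, 20, 40, 40, 40, 40),
                            rec_start = "07:30", rec_end = "18:00",
                            start_date = "2014-04-03",
                            tz = "Etc/GMT-2",
                            planted_incursions = c(5L, 17L, 8L, 6L, 6L, 7L),
                            fix_success = 0.862,
                            spike_prob = 0.01,
                            n_focals = c(52L, 52L, 52L, 52L, 52L, 51L),
                            focal_len = 30L,
                            landscape = landscape_spec(),
                            states = state_model(),
                            accel_coverage = c("bursts", "continuous"),
                            burst_margin = 31.5,
                            daylight = list(sunrise = "07:52:00",
                                            sunrise_drift = 25,
                                            sunset = "17:39:00",
                                            sunset_drift = -30)) {
  cfg <- list(seed = as.integer(seed), n_males = as.integer(n_males),
              n_days_per_male = as.integer(n_days_per_male),
              gps_interval = gps_interval,
              accel_rates = rep_len(accel_rates, n_males),
              rec_start = rec_start, rec_end = rec_end,
              start_date = start_date, tz = tz,
              planted_incursions = rep_len(as.integer(planted_incursions),
                                           n_males),
              fix_success = fix_success, spike_prob = spike_prob,
              n_focals = rep_len(as.integer(n_focals), n_males),
              focal_len = as.integer(focal_len),
              landscape = landscape, states = states,
              accel_coverage = match.arg(accel_coverage),
              burst_margin = burst_margin,
              daylight = daylight)
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' @param cfg A `scenario_config`.
#' @return The configuration, invisibly; stops with a field-level message on
#'   the first violated constraint.
#' @export
validate_scenario_config <- function(cfg) {
  if (!inherits(cfg, "scenario_config")) stop("not a scenario_config")
  if (cfg$n_males < 1L) stop("n_males: must be at least 1")
  if (cfg$n_days_per_male < 1L) stop("n_days_per_male: must be at least 1")
  if (cfg$gps_interval <= 0) stop("gps_interval: must be positive")
  if (any(cfg$accel_rates <= 0)) stop("accel_rates: must be positive")
  if (any(cfg$planted_incursions < 5L | cfg$planted_incursions > 17L))
    stop("planted_incursions: each male must have between 5 and 17")
  if (cfg$fix_success <= 0 || cfg$fix_success > 1)
    stop("fix_success: must be in (0, 1]")
  if (cfg$spike_prob < 0 || cfg$spike_prob >= 1)
    stop("spike_prob: must be in [0, 1)")
  validate_landscape_spec(cfg$landscape)
  invisible(cfg)
}

#' Write / read a scenario configuration as YAML
#'
#' The file carries a schema version; nested specs are reconstructed through
#' their constructors so invariants are re-validated on read.
#'
#' @param cfg A `scenario_config`.
#' @param path File path.
#' @return `write_scenario_config` returns `path` invisibly;
#'   `read_scenario_config` returns a `scenario_config`.
#' @export
write_scenario_config <- function(cfg, path) {
  validate_scenario_config(cfg)
  x <- unclass(cfg)
  x$landscape <- unclass(x$landscape)
  x$states <- lapply(unclass(x$states), function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  x$states$movement$jitter_speed <- as.list(cfg$states$movement$jitter_speed)
  if (!is.null(x$landscape$water))
    x$landscape$water$cell <- as.list(x$landscape$water$cell)
  yaml::write_yaml(list(schema = "urbanforay-scenario/1", config = x), path,
                   precision = 15)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$schema) || !startsWith(y$schema, "urbanforay-scenario"))
    stop("not an urbanforay scenario config: ", path)
  x <- y$config
  ls <- x$landscape
  spec <- landscape_spec(extent = unlist(ls$extent), cell_side = ls$cell_side,
                         urban_width = ls$urban_width, water = ls$water,
                         natural_energy_mean = ls$natural_energy_mean,
                         energy_ratio = ls$energy_ratio,
                         ranger_count = ls$ranger_count,
                         risk_profiles = lapply(ls$risk_profiles, unlist),
                         quadrat_mean = ls$quadrat_mean,
                         quadrat_sd = ls$quadrat_sd,
                         presence_prob = ls$presence_prob)
  st <- x$states
  mv <- st$movement
  mv$jitter_speed <- unlist(mv$jitter_speed)
  sm <- state_model(dwell_means_min = unlist(st$dwell_means_min),
                    occupancy = unlist(st$occupancy),
                    outside_vedba_mean = st$outside_vedba_mean,
                    vedba_means = unlist(st$vedba_means),
                    vedba_sds = unlist(st$vedba_sds),
                    movement = mv,
                    foray_fix_probs = unlist(st$foray_fix_probs))
  scenario_config(seed = x$seed, n_males = x$n_males,
                  n_days_per_male = x$n_days_per_male,
                  gps_interval = x$gps_interval,
                  accel_rates = unlist(x$accel_rates),
                  rec_start = x$rec_start, rec_end = x$rec_end,
                  start_date = x$start_date, tz = x$tz,
                  planted_incursions = unlist(x$planted_incursions),
                  fix_success = x$fix_success, spike_prob = x$spike_prob,
                  n_focals = unlist(x$n_focals), focal_len = x$focal_len,
                  landscape = spec, states = sm,
                  accel_coverage = x$accel_coverage,
                  burst_margin = x$burst_margin, daylight = x$daylight)
}

# Deterministic sub-seed derivation; keeps values inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

hms_to_sec <- function(s) {
  p <- as.numeric(strsplit(s, ":")[[1]])
  sum(p * c(3600, 60, 1)[seq_along(p)])
}

#' Generate the daylight table for a scenario
#'
#' Sunrise and sunset times are generated with a slow per-day drift rather
#' than computed from an ephemeris, which keeps the generator free of any
#' astronomy dependency while still exercising the daylight filter's closed
#' boundary rule.
#'
#' @param cfg A [scenario_config()].
#' @return Data frame with `date`, `sunrise`, `sunset` (POSIXct).
#' @export
gen_daylight_table <- function(cfg) {
  dates <- as.Date(cfg$start_date) + seq_len(cfg$n_days_per_male) - 1L
  d <- seq_along(dates) - 1L
  sr <- as.POSIXct(paste(dates, "00:00:00"), tz = cfg$tz) +
    hms_to_sec(cfg$daylight$sunrise) + d * cfg$daylight$sunrise_drift
  ss <- as.POSIXct(paste(dates, "00:00:00"), tz = cfg$tz) +
    hms_to_sec(cfg$daylight$sunset) + d * cfg$daylight$sunset_drift
  stopifnot(all(sr < ss))
  data.frame(date = dates, sunrise = sr, sunset = ss)
}
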