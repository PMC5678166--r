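# Behavioural summaries from annotated fixes: habitat time shares,
# distance-to-edge distribution, urban foray detection with duration and
# activity contrast, and focal time budgets with literature comparison.

#' Time spent per habitat
#'
#' Per-male habitat fractions are shares of retained daytime fixes (the
#' fix-based accounting used for collar data); the cross-male summary is an
#' unweighted mean with SE = sd/sqrt(n_males) and the min-max range. Males
#' with zero classified fixes are excluded and reported.
#'
#' @param annotated Annotated fixes (columns `male_id`, `habitat`).
#' @return List with `per_male` (male x habitat fraction matrix) and
#'   `summary` (data frame per habitat: `mean`, `se`, `min`, `max`),
#'   fractions in \[0, 1\]; attribute `excluded_males`.
#' @export
time_in_habitat <- function(annotated) {
  lev <- levels(annotated$habitat) %||%
    sort(unique(as.character(annotated$habitat)))
  a <- annotated[!is.na(annotated$habitat), , drop = FALSE]
  males <- unique(annotated$male_id)
  tab <- table(factor(a$male_id, levels = males),
               factor(a$habitat, levels = lev))
  n <- rowSums(tab)
  excluded <- rownames(tab)[n == 0]
  tab <- tab[n > 0, , drop = FALSE]
  frac <- sweep(unclass(tab), 1, rowSums(tab), "/")
  summary <- data.frame(
    habitat = lev,
    mean = colMeans(frac),
    se = apply(frac, 2, stats::sd) / sqrt(nrow(frac)),
    min = apply(frac, 2, min),
    max = apply(frac, 2, max))
  rownames(summary) <- NULL
  out <- list(per_male = frac, summary = summary)
  attr(out, "excluded_males") <- excluded
  out
}

#' Distance-to-urban-edge distribution
#'
#' Pooled median and first/third quartiles over all fixes; fixes inside the
#' urban space contribute 0.
#'
#' @param annotated Annotated fixes (column `dist_urban_edge`).
#' @return Named numeric vector `c(q1, median, q3)` in metres.
#' @export
edge_distance_summary <- function(annotated) {
  q <- stats::quantile(annotated$dist_urban_edge, c(0.25, 0.5, 0.75),
                       na.rm = TRUE, names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

#' Detect urban forays in annotated fixes
#'
#' A foray is a maximal run of consecutive urban-habitat fixes for one
#' male, uninterrupted by a non-urban fix, by a recording gap longer than
#' `2 * gps_interval`, or by a day boundary. Duration is
#' `n_fixes * gps_interval` (each fix represents its surrounding interval).
#'
#' @param annotated Annotated fixes, per-male time-ordered.
#' @param gps_interval Nominal fix interval in seconds (default 300).
#' @return Data frame with one row per foray: `male_id`, `entry_time`,
#'   `exit_time`, `n_fixes`, `duration_min`, `mean_vedba_inside`.
#' @export
detect_forays <- function(annotated, gps_interval = 300) {
  out <- list()
  for (id in unique(annotated$male_id)) {
    a <- annotated[annotated$male_id == id, , drop = FALSE]
    a <- a[order(a$time), , drop = FALSE]
    urban <- !is.na(a$habitat) & a$habitat == "urban"
    if (!any(urban)) next
    tnum <- as.numeric(a$time)
    day <- as.Date(a$time, tz = attr(a$time, "tzone") %||% "UTC")
    new_run <- urban & (
      !c(FALSE, urban[-length(urban)]) |                 # previous not urban
      c(TRUE, diff(tnum) > 2 * gps_interval) |            # recording gap
      c(TRUE, day[-1] != day[-length(day)]))              # day boundary
    run <- cumsum(new_run)
    run[!urban] <- NA
    for (r in unique(run[!is.na(run)])) {
      ii <- which(!is.na(run) & run == r)
      out[[length(out) + 1L]] <- data.frame(
        male_id = id,
        entry_time = a$time[ii[1]],
        exit_time = a$time[ii[length(ii)]],
        n_fixes = length(ii),
        duration_min = length(ii) * gps_interval / 60,
        mean_vedba_inside = mean(a$mean_vedba[ii], na.rm = TRUE))
    }
  }
  if (!length(out))
    return(data.frame(male_id = character(0), entry_time = as.POSIXct(character(0)),
                      exit_time = as.POSIXct(character(0)), n_fixes = integer(0),
                      duration_min = numeric(0), mean_vedba_inside = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Activity contrast inside versus outside urban forays
#'
#' Pools fix-level mean VeDBA over all males, stratified by foray
#' membership (a fix is inside a foray exactly when it is an urban-habitat
#' fix belonging to a detected run). Reports pooled mean +/- sd per
#' stratum, plus per-male summaries.
#'
#' @param forays Foray table from [detect_forays()].
#' @param annotated The annotated fixes the forays were detected in.
#' @return List with `inside` and `outside` (each `c(mean, sd, n)`) and
#'   `per_male` data frame. With no forays the inside stratum is `NA`.
#' @export
foray_activity_contrast <- function(forays, annotated) {
  inside_flag <- rep(FALSE, nrow(annotated))
  if (nrow(forays)) {
    for (i in seq_len(nrow(forays))) {
      inside_flag <- inside_flag |
        (annotated$male_id == forays$male_id[i] &
         annotated$time >= forays$entry_time[i] &
         annotated$time <= forays$exit_time[i])
    }
  }
  v <- annotated$mean_vedba
  strat <- function(keep) {
    vv <- v[keep & !is.na(v)]
    if (!length(vv)) return(c(mean = NA_real_, sd = NA_real_, n = 0))
    c(mean = mean(vv), sd = stats::sd(vv), n = length(vv))
  }
  per_male <- do.call(rbind, lapply(unique(annotated$male_id), function(id) {
    sel <- annotated$male_id == id
    data.frame(male_id = id,
               mean_inside = mean(v[sel & inside_flag], na.rm = TRUE),
               mean_outside = mean(v[sel & !inside_flag], na.rm = TRUE))
  }))
  list(inside = strat(inside_flag), outside = strat(!inside_flag),
       per_male = per_male)
}

#' Focal-observation time budget
#'
#' Fractions of focal minutes in each behaviour class per male, plus the
#' pooled cross-male mean +/- SE.
#'
#' @param focals Focal records with `male_id` and `behaviour` in
#'   \{resting, grooming, foraging, travelling\}.
#' @return List with `per_male` (male x behaviour fraction matrix) and
#'   `pooled` (data frame: behaviour, mean, se).
#' @export
focal_time_budget <- function(focals) {
  classes <- c("resting", "grooming", "foraging", "travelling")
  bad <- setdiff(unique(focals$behaviour), classes)
  if (length(bad))
    stop("unknown behaviour label(s): ", paste(bad, collapse = ", "))
  tab <- table(focals$male_id, factor(focals$behaviour, levels = classes))
  frac <- sweep(unclass(tab), 1, rowSums(tab), "/")
  pooled <- data.frame(behaviour = classes,
                       mean = colMeans(frac),
                       se = apply(frac, 2, stats::sd) / sqrt(nrow(frac)))
  rownames(pooled) <- NULL
  list(per_male = frac, pooled = pooled)
}

#' Literature time budgets shipped with the package
#'
#' Foraging-time percentages for baboon populations as printed in the
#' comparative literature (only the published range endpoints are encoded).
#'
#' @return Data frame with `population`, `raiding`, `foraging_pct`.
#' @export
literature_budgets <- function() {
  path <- system.file("extdata", "literature_time_budgets.csv",
                      package = "urbanforay")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Compare a focal time budget with literature budgets
#'
#' Emits per-population foraging fractions (the study males' pooled focal
#' budget alongside the literature populations) ready for a Kruskal-Wallis
#' comparison, and flags whether the focal budget falls below, inside or
#' above the literature range.
#'
#' @param budget Result of [focal_time_budget()].
#' @param literature Literature table (default the packaged one).
#' @return List with `table` (population, foraging_pct, source), `flag`
#'   (`"below range"`, `"within range"` or `"above range"`) and `groups`
#'   (list of numeric vectors for [kruskal_wallis()]: per-male focal
#'   foraging percentages vs literature percentages).
#' @export
budget_comparison <- function(budget, literature = literature_budgets()) {
  focal_pct <- budget$per_male[, "foraging"] * 100
  pooled <- mean(focal_pct)
  lo <- min(literature$foraging_pct); hi <- max(literature$foraging_pct)
  flag <- if (pooled < lo) "below range"
          else if (pooled > hi) "above range" else "within range"
  tab <- rbind(
    data.frame(population = rownames(budget$per_male),
               foraging_pct = as.numeric(focal_pct), source = "focal observations"),
    data.frame(population = literature$population,
               foraging_pct = literature$foraging_pct, source = "literature"))
  list(table = tab, flag = flag,
       groups = list(focal = as.numeric(focal_pct),
                     literature = literature$foraging_pct))
}
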