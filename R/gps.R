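# GPS track cleaning: projection to planar coordinates, daylight filter,
# distance-jump filter, and spatial/activity annotation of retained fixes.

# WGS84 transverse Mercator (standard USGS series), accurate to well under
# a metre across a UTM zone. Used when collar fixes arrive as lon/lat.
.wgs84 <- list(a = 6378137, f = 1 / 298.257223563)

utm_zone <- function(lon) floor((lon + 180) / 6) + 1

#' Project lon/lat to UTM metres (and back)
#'
#' @param lon,lat Coordinates in degrees.
#' @param zone UTM zone; defaults to the zone of the first point.
#' @param south Logical, southern hemisphere (adds the 10^7 m false
#'   northing).
#' @return `utm_forward` returns a data frame with `easting`, `northing`,
#'   `zone`, `south`; `utm_inverse` returns a data frame with `lon`, `lat`.
#' @export
utm_forward <- function(lon, lat, zone = NULL, south = NULL) {
  a <- .wgs84$a; f <- .wgs84$f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2); k0 <- 0.9996
  if (is.null(zone)) zone <- utm_zone(lon[1])
  if (is.null(south)) south <- lat[1] < 0
  lam0 <- (-183 + 6 * zone) * pi / 180
  phi <- lat * pi / 180; lam <- lon * pi / 180
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- (lam - lam0) * cos(phi)
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
            (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
            (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
            (35 * e2^3 / 3072) * sin(6 * phi))
  x <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                 (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 500000
  y <- k0 * (M + N * tan(phi) * (A^2 / 2 +
             (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
             (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (south) y <- y + 1e7
  data.frame(easting = x, northing = y, zone = zone, south = south)
}

#' @rdname utm_forward
#' @export
utm_inverse <- function(easting, northing, zone, south = FALSE) {
  a <- .wgs84$a; f <- .wgs84$f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2); k0 <- 0.9996
  lam0 <- (-183 + 6 * zone) * pi / 180
  x <- easting - 500000
  y <- if (south) northing - 1e7 else northing
  M <- y / k0
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  N1 <- a / sqrt(1 - e2 * sin(phi1)^2)
  R1 <- a * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
  T1 <- tan(phi1)^2
  C1 <- ep2 * cos(phi1)^2
  D <- x / (N1 * k0)
  phi <- phi1 - (N1 * tan(phi1) / R1) *
    (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
     (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam <- lam0 + (D - (1 + 2 * T1 + C1) * D^3 / 6 +
                 (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) *
                 D^5 / 120) / cos(phi1)
  data.frame(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Project GPS fixes to planar (UTM) coordinates
#'
#' Fixes already carrying `x`/`y` in metres pass through unchanged. Lon/lat
#' fixes are converted to UTM in the single zone covering the extent; input
#' straddling two zones is rejected.
#'
#' @param fixes Data frame with either `x`, `y` (metres, pass-through) or
#'   `lon`, `lat` (degrees).
#' @return The fixes with planar `x`, `y` columns (metres) and attributes
#'   `utm_zone`/`utm_south` when a projection was applied.
#' @export
project_to_planar <- function(fixes) {
  if (all(c("x", "y") %in% names(fixes))) return(fixes)
  if (!all(c("lon", "lat") %in% names(fixes)))
    stop("fixes need either x/y (metres) or lon/lat (degrees)")
  if (any(abs(fixes$lat) > 90) || any(abs(fixes$lon) > 180))
    stop("lon/lat out of valid range")
  zones <- unique(utm_zone(fixes$lon))
  if (length(zones) > 1)
    stop("fixes straddle UTM zones ", paste(zones, collapse = ", "),
         "; project per zone before merging")
  pr <- utm_forward(fixes$lon, fixes$lat, zone = zones, south = fixes$lat[1] < 0)
  fixes$x <- pr$easting
  fixes$y <- pr$northing
  attr(fixes, "utm_zone") <- zones
  attr(fixes, "utm_south") <- pr$south[1]
  fixes
}

#' Remove GPS fixes recorded outside daylight
#'
#' Retains fixes with `sunrise <= t <= sunset` for the fix's date (closed
#' interval: fixes exactly at sunrise or sunset are retained). Every fix
#' date must be present in the daylight table.
#'
#' @param fixes Data frame with a POSIXct `time` column.
#' @param daylight Data frame with `date`, `sunrise`, `sunset` (see
#'   [gen_daylight_table()]).
#' @return The retained fixes.
#' @export
daylight_filter <- function(fixes, daylight) {
  if (nrow(fixes) == 0) return(fixes)
  d <- as.Date(fixes$time, tz = attr(fixes$time, "tzone") %||% "UTC")
  idx <- match(d, daylight$date)
  if (anyNA(idx))
    stop("daylight table is missing date(s): ",
         paste(unique(d[is.na(idx)]), collapse = ", "))
  keep <- fixes$time >= daylight$sunrise[idx] &
    fixes$time <= daylight$sunset[idx]
  fixes[keep, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove implausible GPS jumps
#'
#' Scans each male's time-ordered track forward: whenever the planar
#' distance from the last retained fix to the next fix exceeds `threshold`,
#' the next fix is dropped; scanning continues until no successive retained
#' pair exceeds the threshold. The rule is idempotent and never increases
#' the fix count. (Dropping the later member of an offending pair, rather
#' than both, avoids cascading deletion of valid positions.)
#'
#' @param fixes Projected fixes (`x`, `y` in metres), per-male time-ordered,
#'   with a `male_id` column (a single unnamed track is also accepted).
#' @param threshold Distance threshold in metres (default 1000).
#' @return The retained fixes.
#' @export
jump_filter <- function(fixes, threshold = 1000) {
  if (nrow(fixes) == 0) return(fixes)
  if (!all(c("x", "y") %in% names(fixes)))
    stop("fixes must be projected before jump filtering")
  ids <- if ("male_id" %in% names(fixes)) fixes$male_id else rep(1L, nrow(fixes))
  keep <- logical(nrow(fixes))
  for (id in unique(ids)) {
    ii <- which(ids == id)
    x <- fixes$x[ii]; y <- fixes$y[ii]
    last <- 1L
    k <- logical(length(ii))
    k[1L] <- TRUE
    for (j in seq_along(ii)[-1]) {
      if (sqrt((x[j] - x[last])^2 + (y[j] - y[last])^2) <= threshold) {
        k[j] <- TRUE
        last <- j
      }
    }
    keep[ii] <- k
  }
  fixes[keep, , drop = FALSE]
}

#' Run the full GPS filter cascade with stage bookkeeping
#'
#' Applies, in the fixed order, the daylight filter then the jump filter,
#' recording the fix count after every stage (mirroring the raw ->
#' with-activity -> daylight -> jump bookkeeping used for collar data).
#'
#' @param fixes Projected fixes with `time`, `x`, `y`, `male_id`, and
#'   optionally `mean_vedba` (used only for the `with_activity` count).
#' @param daylight Daylight table.
#' @param threshold Jump threshold in metres.
#' @return List with `fixes` (retained) and `counts` (named integer vector:
#'   `raw`, `with_activity`, `after_daylight`, `after_jump`).
#' @export
filter_cascade <- function(fixes, daylight, threshold = 1000) {
  n_raw <- nrow(fixes)
  n_act <- if ("mean_vedba" %in% names(fixes))
    sum(!is.na(fixes$mean_vedba)) else NA_integer_
  f1 <- daylight_filter(fixes, daylight)
  f2 <- jump_filter(f1, threshold)
  list(fixes = f2,
       counts = c(raw = n_raw, with_activity = n_act,
                  after_daylight = nrow(f1), after_jump = nrow(f2)))
}

#' Annotate cleaned fixes with activity, habitat, risk and edge distance
#'
#' Joins each fix with its mean VeDBA (computed from `vedba_series` in a
#' +/- `half_width` window if supplied, otherwise taken from an existing
#' `mean_vedba` column), the containing grid cell's habitat and composite
#' risk score, and the distance to the nearest urban edge (0 inside the
#' urban space). Fixes outside the grid extent are retained with `NA` cell
#' annotation and counted in the `n_outside_grid` attribute.
#'
#' @param fixes Cleaned, projected fixes.
#' @param grid A [build_grid()] layer with habitat (and optionally risk)
#'   filled.
#' @param urban_poly Urban region polygon (two-column matrix, metres).
#' @param vedba_series Optional [vedba()] series (single male) or named list
#'   of series keyed by `male_id`.
#' @param half_width VeDBA window half-width in seconds.
#' @return The fixes with `mean_vedba`, `cell_id`, `habitat`, `risk_score`,
#'   `dist_urban_edge` columns; rows keep their input order.
#' @export
annotate_fixes <- function(fixes, grid, urban_poly, vedba_series = NULL,
                           half_width = 30) {
  if (!is.null(vedba_series)) {
    if (is.data.frame(vedba_series)) {
      fixes$mean_vedba <- mean_vedba_at_fixes(vedba_series, fixes$time,
                                              half_width)
    } else {
      fixes$mean_vedba <- NA_real_
      for (id in names(vedba_series)) {
        ii <- fixes$male_id == id
        if (any(ii))
          fixes$mean_vedba[ii] <- mean_vedba_at_fixes(vedba_series[[id]],
                                                      fixes$time[ii],
                                                      half_width)
      }
    }
  } else if (!"mean_vedba" %in% names(fixes)) {
    fixes$mean_vedba <- NA_real_
  }
  cid <- locate_cells(grid, fixes$x, fixes$y)
  fixes$cell_id <- cid
  gi <- match(cid, grid$cell_id)
  fixes$habitat <- grid$habitat[gi]
  fixes$risk_score <- if ("risk" %in% names(grid)) grid$risk[gi] else NA_integer_
  fixes$dist_urban_edge <- distance_to_urban_edge(cbind(fixes$x, fixes$y),
                                                  urban_poly)
  attr(fixes, "n_outside_grid") <- sum(is.na(cid))
  fixes
}
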