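# Gridded landscape layers: the 150 m cell lattice with habitat class,
# quadrat-derived energy per bite, and the composite ranger deterrence
# score; plus distance-to-urban-edge geometry and a fine VeDBA raster.

#' Build the cell lattice over the study extent
#'
#' Lays a square-cell lattice aligned to the extent's lower-left corner and
#' removes cells whose water coverage exceeds 50% ("mostly covered");
#' removals are logged in the `removed` attribute.
#'
#' @param extent Numeric length-2 (width, height) in metres, or a landscape
#'   list from [gen_landscape()].
#' @param cell_side Cell side in metres (default 150).
#' @param water_polygons List of water polygons (two-column matrices), or
#'   NULL.
#' @param origin Lower-left corner of the lattice.
#' @return A data frame of class `grid_layer` with one row per retained
#'   cell: `cell_id`, `col`, `row`, `cx`, `cy` (centre), `xmin..ymax`,
#'   `water_frac`. Attributes: `extent`, `cell_side`, `origin`, `nx`, `ny`,
#'   `removed` (data frame of removed cells).
#' @export
build_grid <- function(extent, cell_side = 150, water_polygons = NULL,
                       origin = c(0, 0)) {
  if (is.list(extent) && !is.null(extent$extent)) {
    if (is.null(water_polygons)) water_polygons <- extent$water
    extent <- extent$extent
  }
  if (cell_side <= 0) stop("cell_side must be positive")
  nx <- ceiling(extent[1] / cell_side)
  ny <- ceiling(extent[2] / cell_side)
  cells <- expand.grid(col = seq_len(nx), row = seq_len(ny))
  cells$cell_id <- (cells$row - 1L) * nx + cells$col
  cells$xmin <- origin[1] + (cells$col - 1) * cell_side
  cells$xmax <- cells$xmin + cell_side
  cells$ymin <- origin[2] + (cells$row - 1) * cell_side
  cells$ymax <- cells$ymin + cell_side
  cells$cx <- (cells$xmin + cells$xmax) / 2
  cells$cy <- (cells$ymin + cells$ymax) / 2
  cells$water_frac <- 0
  if (length(water_polygons)) {
    for (wp in water_polygons) {
      # only test cells overlapping the polygon's bounding box
      bb <- apply(as.matrix(wp), 2, range)
      cand <- which(cells$xmax > bb[1, 1] & cells$xmin < bb[2, 1] &
                    cells$ymax > bb[1, 2] & cells$ymin < bb[2, 2])
      for (i in cand) {
        clipped <- clip_polygon_rect(wp, cells$xmin[i], cells$xmax[i],
                                     cells$ymin[i], cells$ymax[i])
        cells$water_frac[i] <- cells$water_frac[i] +
          poly_area(clipped) / cell_side^2
      }
    }
  }
  removed <- cells[cells$water_frac > 0.5, , drop = FALSE]
  kept <- cells[cells$water_frac <= 0.5, , drop = FALSE]
  kept <- kept[order(kept$cell_id),
               c("cell_id", "col", "row", "cx", "cy",
                 "xmin", "xmax", "ymin", "ymax", "water_frac")]
  rownames(kept) <- NULL
  attr(kept, "extent") <- as.numeric(extent)
  attr(kept, "cell_side") <- cell_side
  attr(kept, "origin") <- as.numeric(origin)
  attr(kept, "nx") <- nx
  attr(kept, "ny") <- ny
  attr(kept, "removed") <- removed
  class(kept) <- c("grid_layer", "data.frame")
  kept
}

# Map planar points to retained cell ids (NA outside the extent or in a
# removed cell).
locate_cells <- function(grid, px, py) {
  org <- attr(grid, "origin"); side <- attr(grid, "cell_side")
  nx <- attr(grid, "nx"); ny <- attr(grid, "ny")
  col <- floor((px - org[1]) / side) + 1L
  row <- floor((py - org[2]) / side) + 1L
  # points exactly on the upper/right extent boundary belong to the last cell
  col[px == org[1] + nx * side] <- nx
  row[py == org[2] + ny * side] <- ny
  ok <- col >= 1L & col <= nx & row >= 1L & row <= ny
  cid <- ifelse(ok, (row - 1L) * nx + col, NA_integer_)
  cid[!cid %in% grid$cell_id] <- NA_integer_
  cid
}

#' Assign a habitat class to every grid cell
#'
#' Cells take the habitat of majority area among the supplied polygons;
#' ties are broken by the fixed habitat ordering fynbos < trees < meadows <
#' vineyards < urban.
#'
#' @param grid A [build_grid()] layer.
#' @param habitat_polygons Named list of polygons (or list of lists per
#'   habitat).
#' @return The grid with a `habitat` factor column.
#' @export
assign_habitat <- function(grid, habitat_polygons) {
  lev <- c("fynbos", "trees", "meadows", "vineyards", "urban")
  nms <- names(habitat_polygons)
  areas <- matrix(0, nrow(grid), length(nms), dimnames = list(NULL, nms))
  for (h in nms) {
    polys <- habitat_polygons[[h]]
    if (!is.list(polys)) polys <- list(polys)
    for (pp in polys) {
      bb <- apply(as.matrix(pp), 2, range)
      cand <- which(grid$xmax > bb[1, 1] & grid$xmin < bb[2, 1] &
                    grid$ymax > bb[1, 2] & grid$ymin < bb[2, 2])
      for (i in cand)
        areas[i, h] <- areas[i, h] +
          poly_area(clip_polygon_rect(pp, grid$xmin[i], grid$xmax[i],
                                      grid$ymin[i], grid$ymax[i]))
    }
  }
  ord <- intersect(lev, nms)  # tie-break order
  areas <- areas[, ord, drop = FALSE]
  pick <- apply(areas, 1, function(a) ord[which.max(a)])
  grid$habitat <- factor(pick, levels = lev)
  grid
}

#' Mean energy per bite of one quadrat
#'
#' Unweighted mean of `kcal_per_bite` over the food items present in the
#' quadrat; an empty quadrat (sampled, nothing found) scores 0.
#'
#' @param items Character vector of item names present (may be empty).
#' @param energy_table Data frame with `item` and `kcal_per_bite`.
#' @return Mean kcal/bite.
#' @export
quadrat_energy <- function(items, energy_table) {
  items <- items[!is.na(items)]
  if (length(items) == 0) return(0)
  idx <- match(items, energy_table$item)
  if (anyNA(idx))
    stop("unknown food item(s): ", paste(items[is.na(idx)], collapse = ", "))
  mean(energy_table$kcal_per_bite[idx])
}

#' Aggregate quadrat energies to cell energy
#'
#' Cell energy is the mean of its quadrat energies. Cells with no quadrats
#' carry `NA` (unsampled, which is distinct from sampled-and-found-nothing:
#' a cell whose quadrats were all empty scores 0). Urban cells surveyed per
#' residence are aggregated under the same averaging contract.
#'
#' @param grid A [build_grid()] layer.
#' @param quadrats A quadrat set as returned by [gen_quadrats()]: list with
#'   `quadrats` (one row per quadrat: `cell_id`, `quadrat_id`) and `items`
#'   (`quadrat_id`, `item`, `bites`).
#' @param energy_table Data frame with `item` and `kcal_per_bite`.
#' @return The grid with an `energy` column (kcal/bite, NA where unsampled).
#' @export
cell_energy <- function(grid, quadrats, energy_table) {
  q <- quadrats$quadrats
  by_quadrat <- split(quadrats$items$item, quadrats$items$quadrat_id)
  qe <- vapply(as.character(q$quadrat_id), function(qid) {
    quadrat_energy(by_quadrat[[qid]], energy_table)
  }, numeric(1), USE.NAMES = FALSE)
  agg <- tapply(qe, q$cell_id, mean)
  grid$energy <- as.numeric(agg[as.character(grid$cell_id)])
  grid
}

#' Composite ranger deterrence score per cell
#'
#' Sums the per-cell scores of all rangers; with `R` rangers scoring in
#' \{0, 1, 2\} the composite spans \[0, 2R\] (0-22 for the default 11
#' rangers).
#'
#' @param grid A [build_grid()] layer.
#' @param ranger_maps Integer matrix, cells x rangers, rows matching
#'   `grid$cell_id` order (or a data frame with `cell_id`, `ranger`,
#'   `score` in long form).
#' @return The grid with a `risk` integer column.
#' @export
composite_risk <- function(grid, ranger_maps) {
  if (is.data.frame(ranger_maps)) {
    if (!all(ranger_maps$score %in% 0:2))
      stop("ranger scores must be in {0, 1, 2}")
    if (!all(grid$cell_id %in% ranger_maps$cell_id))
      stop("ranger maps must cover every retained cell")
    tot <- tapply(ranger_maps$score, ranger_maps$cell_id, sum)
    grid$risk <- as.integer(tot[as.character(grid$cell_id)])
    return(grid)
  }
  ranger_maps <- as.matrix(ranger_maps)
  if (nrow(ranger_maps) != nrow(grid))
    stop("ranger maps must cover every retained cell")
  if (!all(ranger_maps %in% 0:2))
    stop("ranger scores must be in {0, 1, 2}")
  grid$risk <- as.integer(rowSums(ranger_maps))
  grid
}

#' Distance from points to the nearest urban edge
#'
#' Zero for points inside (or on the boundary of) the urban region,
#' otherwise the minimum Euclidean distance to the region's boundary.
#'
#' @param points Two-column matrix of planar coordinates (metres).
#' @param urban_poly Urban region polygon (two-column matrix, metres).
#' @return Numeric vector of distances in metres.
#' @export
distance_to_urban_edge <- function(points, urban_poly) {
  if (is.null(urban_poly) || nrow(as.matrix(urban_poly)) < 3)
    stop("urban boundary is empty")
  points <- matrix(as.numeric(points), ncol = 2)
  d <- dist_to_ring(points[, 1], points[, 2], urban_poly)
  inside <- point_in_polygon(points[, 1], points[, 2], urban_poly)
  d[inside] <- 0
  d
}

#' Fine-grid mean-VeDBA raster
#'
#' Averages fix-level mean VeDBA within fine square cells (10 m side by
#' default); cells without fixes are absent from the output.
#'
#' @param annotated Annotated fixes (with `x`, `y`, `mean_vedba`).
#' @param fine_cell_side Fine cell side in metres.
#' @param origin Raster origin.
#' @return Data frame with `fx`, `fy` (cell indices), `cx`, `cy` (centres),
#'   `n` and `mean_vedba`.
#' @export
vedba_surface <- function(annotated, fine_cell_side = 10, origin = c(0, 0)) {
  ok <- !is.na(annotated$mean_vedba)
  a <- annotated[ok, , drop = FALSE]
  if (nrow(a) == 0)
    return(data.frame(fx = integer(0), fy = integer(0), cx = numeric(0),
                      cy = numeric(0), n = integer(0),
                      mean_vedba = numeric(0)))
  fx <- floor((a$x - origin[1]) / fine_cell_side)
  fy <- floor((a$y - origin[2]) / fine_cell_side)
  key <- paste(fx, fy)
  agg <- tapply(a$mean_vedba, key, mean)
  cnt <- tapply(a$mean_vedba, key, length)
  kk <- do.call(rbind, strsplit(names(agg), " "))
  out <- data.frame(fx = as.integer(kk[, 1]), fy = as.integer(kk[, 2]))
  out$cx <- origin[1] + (out$fx + 0.5) * fine_cell_side
  out$cy <- origin[2] + (out$fy + 0.5) * fine_cell_side
  out$n <- as.integer(cnt)
  out$mean_vedba <- as.numeric(agg)
  out[order(out$fx, out$fy), ]
}

#' Export a grid layer as GeoJSON
#'
#' Writes each retained cell as a Polygon feature carrying its habitat,
#' energy, risk and water fraction as properties. Coordinates are emitted
#' in the grid's planar frame.
#'
#' @param grid A populated [build_grid()] layer.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_geojson <- function(grid, path) {
  feats <- lapply(seq_len(nrow(grid)), function(i) {
    ring <- rbind(
      c(grid$xmin[i], grid$ymin[i]), c(grid$xmax[i], grid$ymin[i]),
      c(grid$xmax[i], grid$ymax[i]), c(grid$xmin[i], grid$ymax[i]),
      c(grid$xmin[i], grid$ymin[i]))
    props <- list(cell_id = grid$cell_id[i], water_frac = grid$water_frac[i])
    if ("habitat" %in% names(grid)) props$habitat <- as.character(grid$habitat[i])
    if ("energy" %in% names(grid)) props$energy <- grid$energy[i]
    if ("risk" %in% names(grid)) props$risk <- grid$risk[i]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}
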