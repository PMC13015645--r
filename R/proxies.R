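# Road-traffic proxies at village level: population-weighted road network
# density (WRND) on a fishnet grid aligned to the population raster, and
# Euclidean distances from the village centroid to the nearest main road
# (EM) and highway (EH).

#' Fishnet cells intersecting a boundary polygon
#'
#' Returns the square grid cells of a population raster whose polygon
#' overlaps the boundary with positive area (cells that merely touch the
#' boundary are excluded). Cell corners coincide with raster cell corners,
#' so the fishnet is exactly aligned to the population grid.
#'
#' @param grid An `rp_popgrid` (origin, cell size, counts).
#' @param boundary Two-column polygon vertex matrix (m).
#' @return data.frame with `cell_id`, `row`, `col`, `xmin`, `ymin`, `xmax`,
#'   `ymax`, `population`, `overlap_area` (m2 of cell-boundary overlap).
#' @export
build_fishnet <- function(grid, boundary) {
  boundary <- as.matrix(boundary)
  cs <- grid$cell_size
  x0 <- grid$origin[1]; y0 <- grid$origin[2]
  c1 <- max(1L, floor((min(boundary[, 1]) - x0) / cs) + 1L)
  c2 <- min(grid$ncols, floor((max(boundary[, 1]) - x0 - 1e-12) / cs) + 1L)
  r1 <- max(1L, floor((min(boundary[, 2]) - y0) / cs) + 1L)
  r2 <- min(grid$nrows, floor((max(boundary[, 2]) - y0 - 1e-12) / cs) + 1L)
  if (c2 < c1 || r2 < r1)
    stop("boundary does not intersect the population grid extent")
  rows <- integer(0); cols <- integer(0); ov <- numeric(0)
  for (r in r1:r2) {
    for (cc in c1:c2) {
      xmin <- x0 + (cc - 1L) * cs; ymin <- y0 + (r - 1L) * cs
      clip <- .clip_polygon_to_rect(boundary, xmin, ymin, xmin + cs, ymin + cs)
      a <- if (nrow(clip) >= 3) .polygon_area(clip) else 0
      if (a > 1e-9) {
        rows <- c(rows, r); cols <- c(cols, cc); ov <- c(ov, a)
      }
    }
  }
  if (length(rows) == 0)
    stop("boundary does not overlap any grid cell with positive area")
  data.frame(
    cell_id = sprintf("c_%d_%d", rows, cols), row = rows, col = cols,
    xmin = x0 + (cols - 1L) * cs, ymin = y0 + (rows - 1L) * cs,
    xmax = x0 + cols * cs, ymax = y0 + rows * cs,
    population = grid$counts[cbind(rows, cols)],
    overlap_area = ov
  )
}

#' Per-cell road length and road network density
#'
#' Clips the road network (all classes) to the boundary polygon, splits the
#' clipped segments along the fishnet gridlines, and accumulates road length
#' per cell. Density is `rnd = road_length / area` in km/km2; cells with no
#' road get length 0.
#'
#' @param roads Road vertex data.frame (see [road_segments()]).
#' @param cells Fishnet data.frame from [build_fishnet()].
#' @param boundary Boundary polygon matrix; roads are clipped to it first.
#' @return `cells` with `road_length_km`, `area_km2` and `rnd` appended.
#' @export
road_length_per_cell <- function(roads, cells, boundary) {
  boundary <- as.matrix(boundary)
  segs <- road_segments(roads)
  cs <- cells$xmax[1] - cells$xmin[1]
  x0 <- min(cells$xmin) - (min(cells$col) - 1L) * cs
  y0 <- min(cells$ymin) - (min(cells$row) - 1L) * cs
  acc <- new.env(parent = emptyenv())
  if (nrow(segs) > 0) {
    bb <- c(min(boundary[, 1]), min(boundary[, 2]), max(boundary[, 1]), max(boundary[, 2]))
    for (j in seq_len(nrow(segs))) {
      if (max(segs$x1[j], segs$x2[j]) < bb[1] || min(segs$x1[j], segs$x2[j]) > bb[3] ||
          max(segs$y1[j], segs$y2[j]) < bb[2] || min(segs$y1[j], segs$y2[j]) > bb[4]) next
      clipped <- .clip_segment_to_polygon(segs$x1[j], segs$y1[j],
                                          segs$x2[j], segs$y2[j], boundary)
      for (k in seq_len(nrow(clipped))) {
        pieces <- .split_segment_by_grid(clipped[k, 1], clipped[k, 2],
                                         clipped[k, 3], clipped[k, 4],
                                         x0, y0, cs)
        for (m in seq_len(nrow(pieces))) {
          key <- sprintf("c_%d_%d", pieces$row[m], pieces$col[m])
          acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + pieces$len[m]
        }
      }
    }
  }
  lens <- vapply(cells$cell_id, function(k) {
    v <- acc[[k]]; if (is.null(v)) 0 else v
  }, 0)
  cells$road_length_km <- lens / 1000
  cells$area_km2 <- (cs / 1000)^2
  cells$rnd <- cells$road_length_km / cells$area_km2
  cells
}

#' Population-weighted road network density
#'
#' `wrnd = sum(rnd_i * pop_i) / sum(pop_i)` over the fishnet cells of a
#' village. When the total population is zero the weighted mean is
#' undefined; the unweighted mean density is returned with the
#' `"zero-population-fallback"` flag. By default each cell contributes its
#' full population count; with `area_weight_population = TRUE` edge cells
#' contribute only the fraction of their count proportional to the
#' cell-boundary overlap (requires an `overlap_area` column).
#'
#' @param cells data.frame with `rnd` and `population` columns (and
#'   `overlap_area`, m2, when area weighting is requested).
#' @param area_weight_population Scale edge-cell populations by their
#'   boundary overlap fraction?
#' @return list with `wrnd` (km/km2) and `flags` (character vector).
#' @export
wrnd <- function(cells, area_weight_population = FALSE) {
  if (nrow(cells) == 0) stop("empty cell list")
  pop <- cells$population
  if (area_weight_population) {
    if (is.null(cells$overlap_area))
      stop("area weighting requires an `overlap_area` column")
    pop <- pop * cells$overlap_area /
      ((cells$xmax - cells$xmin) * (cells$ymax - cells$ymin))
  }
  if (sum(pop) > 0) {
    list(wrnd = sum(cells$rnd * pop) / sum(pop), flags = character(0))
  } else {
    list(wrnd = mean(cells$rnd), flags = "zero-population-fallback")
  }
}

#' Euclidean distance from a point to the nearest road of a class
#'
#' Minimum straight-line distance from the centroid to any segment of the
#' requested class, allowing the nearest location to fall in a segment
#' interior. Regions may lack a class entirely (e.g. no highways): that
#' returns `NA` with a flag rather than an error.
#'
#' @param centroid Numeric length-2 point (m).
#' @param roads Road vertex data.frame.
#' @param road_class `"highway"`, `"main"` or `"other"`.
#' @return list with `distance_km` (`NA` when no segment of the class
#'   exists) and `flags`.
#' @export
distance_to_road_class <- function(centroid, roads, road_class) {
  segs <- suppressWarnings(road_segments(roads, classes = road_class))
  if (nrow(segs) == 0) {
    return(list(distance_km = NA_real_,
                flags = paste0("no-", road_class, "-in-region")))
  }
  d <- .min_dist_to_segments(centroid[1], centroid[2], segs)
  list(distance_km = d / 1000, flags = character(0))
}

#' Compute all road-traffic proxies for one village
#'
#' Composition of the fishnet, per-cell density, weighted-mean and distance
#' steps: WRND over the cells overlapping the village boundary (with road
#' lengths computed on the boundary-clipped network, so edge cells
#' contribute only in-boundary road length), and EM / EH from the village
#' centroid to the nearest main road / highway of the full network.
#'
#' @param landscape An `rp_landscape` (or any list with `roads`,
#'   `population`, `villages` shaped the same way).
#' @param village_id Village identifier.
#' @param area_weight_population Passed to [wrnd()].
#' @return One-row data.frame: `village_id`, `wrnd`, `em`, `eh`, `flags`
#'   (comma-separated, `""` when none).
#' @export
compute_village_proxies <- function(landscape, village_id,
                                    area_weight_population = FALSE) {
  ids <- vapply(landscape$villages, `[[`, "", "id")
  i <- match(village_id, ids)
  if (is.na(i)) stop("unknown village: ", village_id)
  v <- landscape$villages[[i]]
  cells <- build_fishnet(landscape$population, v$boundary)
  cells <- road_length_per_cell(landscape$roads, cells, v$boundary)
  w <- wrnd(cells, area_weight_population = area_weight_population)
  em <- distance_to_road_class(v$centroid, landscape$roads, "main")
  eh <- distance_to_road_class(v$centroid, landscape$roads, "highway")
  data.frame(
    village_id = village_id, wrnd = w$wrnd,
    em = em$distance_km, eh = eh$distance_km,
    flags = paste(c(w$flags, em$flags, eh$flags), collapse = ",")
  )
}

#' Proxy table for every village in a landscape
#'
#' @param landscape An `rp_landscape`.
#' @return data.frame with one row per village (see
#'   [compute_village_proxies()]).
#' @export
village_proxy_table <- function(landscape) {
  ids <- vapply(landscape$villages, `[[`, "", "id")
  out <- do.call(rbind, lapply(ids, compute_village_proxies, landscape = landscape))
  rownames(out) <- NULL
  out
}
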