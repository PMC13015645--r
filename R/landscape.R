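#' Generate a synthetic study landscape
#'
#' Builds a self-contained landscape in a metric planar frame: a classed road
#' network (highway / main / other), village boundary polygons with interior
#' centroids, building footprints clustered inside villages, a square-cell
#' population raster whose mass is concentrated around village centres
#' (a sum of isotropic Gaussian bumps discretised to cells), and optional
#' non-traffic pollution hotspots. The landscape emulates the structure of
#' open geodata commonly used for exposure proxies (road vectors, 100 m
#' gridded population, village polygons, building footprints) without any
#' external data.
#'
#' @param seed Integer seed; the same seed reproduces the landscape exactly.
#' @param extent Numeric length-4 vector `c(xmin, ymin, xmax, ymax)` in metres.
#' @param n_highways,n_main,n_other Number of roads per class. Roads are
#'   generated as jittered polylines spanning the extent.
#' @param n_villages Number of villages.
#' @param n_buildings_per_village Building footprints (small axis-aligned
#'   rectangles) placed inside each village boundary.
#' @param cell_size Population raster cell size in metres (default 100, the
#'   resolution of typical gridded population products). The extent is padded
#'   outward so the cell size divides both dimensions.
#' @param n_hotspots Number of non-traffic point sources (e.g. open burning,
#'   marketplaces) placed uniformly at random.
#' @param hotspot_amplitude,hotspot_decay Amplitude (ug/m3) and exponential
#'   decay length (m) attached to each generated hotspot.
#' @param village_radius Range (m) of mean village boundary radius.
#' @param pop_per_village Range of total population per village.
#' @param pop_sigma Standard deviation (m) of the Gaussian population bump
#'   around each village centre.
#' @return An object of class `rp_landscape`: a list with elements `extent`,
#'   `roads` (vertex data.frame: road_id, class, x, y), `population`
#'   (`rp_popgrid`), `villages` (list of id, boundary matrix, centroid),
#'   `buildings` (list of polygon matrices with a `village_id` attribute) and
#'   `hotspots` (data.frame x, y, amplitude, decay).
#' @examples
#' ls <- generate_landscape(seed = 1, n_villages = 3)
#' ls
#' @export
generate_landscape <- function(seed,
                               extent = c(0, 0, 10000, 10000),
                               n_highways = 2,
                               n_main = 3,
                               n_other = 0,
                               n_villages = 4,
                               n_buildings_per_village = 25,
                               cell_size = 100,
                               n_hotspots = 0,
                               hotspot_amplitude = 30,
                               hotspot_decay = 300,
                               village_radius = c(300, 600),
                               pop_per_village = c(500, 3000),
                               pop_sigma = 300) {
  if (length(extent) != 4 || extent[3] <= extent[1] || extent[4] <= extent[2])
    stop("`extent` must be c(xmin, ymin, xmax, ymax) with positive area")
  counts <- c(n_highways, n_main, n_other, n_villages, n_buildings_per_village, n_hotspots)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (cell_size <= 0) stop("`cell_size` must be positive")

  # pad the extent outward so cell_size divides both dimensions
  w <- extent[3] - extent[1]; h <- extent[4] - extent[2]
  extent[3] <- extent[1] + ceiling(w / cell_size) * cell_size
  extent[4] <- extent[2] + ceiling(h / cell_size) * cell_size

  .with_seed(seed, {
    roads <- .gen_roads(extent, n_highways, n_main, n_other)
    villages <- .gen_villages(extent, n_villages, village_radius)
    population <- .gen_population(extent, cell_size, villages, pop_per_village, pop_sigma)
    buildings <- .gen_buildings(extent, villages, n_buildings_per_village)
    hotspots <- if (n_hotspots > 0) {
      data.frame(
        x = runif(n_hotspots, extent[1], extent[3]),
        y = runif(n_hotspots, extent[2], extent[4]),
        amplitude = rep(hotspot_amplitude, n_hotspots),
        decay = rep(hotspot_decay, n_hotspots)
      )
    } else {
      data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0), decay = numeric(0))
    }
    structure(
      list(extent = extent, roads = roads, population = population,
           villages = villages, buildings = buildings, hotspots = hotspots),
      class = "rp_landscape"
    )
  })
}

# Roads: each road connects two points on different borders of the extent,
# with interior vertices jittered perpendicular to the chord and clamped to
# the extent so every vertex stays inside.
#' @keywords internal
.gen_roads <- function(extent, n_highways, n_main, n_other) {
  classes <- c(rep("highway", n_highways), rep("main", n_main), rep("other", n_other))
  out <- list()
  for (i in seq_along(classes)) {
    sides <- sample(4L, 2)  # distinct borders
    p1 <- .point_on_border(extent, sides[1])
    p2 <- .point_on_border(extent, sides[2])
    nv <- 5L
    tt <- seq(0, 1, length.out = nv)
    x <- p1[1] + tt * (p2[1] - p1[1])
    y <- p1[2] + tt * (p2[2] - p1[2])
    chord <- sqrt((p2[1] - p1[1])^2 + (p2[2] - p1[2])^2)
    nx <- -(p2[2] - p1[2]) / chord; ny <- (p2[1] - p1[1]) / chord
    jit <- c(0, rnorm(nv - 2L, 0, chord * 0.03), 0)
    x <- pmin(extent[3], pmax(extent[1], x + jit * nx))
    y <- pmin(extent[4], pmax(extent[2], y + jit * ny))
    out[[i]] <- data.frame(road_id = sprintf("road_%02d", i),
                           class = classes[i], x = x, y = y)
  }
  if (length(out) == 0)
    return(data.frame(road_id = character(0), class = character(0),
                      x = numeric(0), y = numeric(0)))
  do.call(rbind, out)
}

#' @keywords internal
.point_on_border <- function(extent, side) {
  switch(side,
    c(extent[1], runif(1, extent[2], extent[4])),  # west
    c(extent[3], runif(1, extent[2], extent[4])),  # east
    c(runif(1, extent[1], extent[3]), extent[2]),  # south
    c(runif(1, extent[1], extent[3]), extent[4])   # north
  )
}

# Villages: centres sampled with an edge margin and greedy minimum
# separation; boundaries are star-shaped 12-gons with jittered radii, so the
# centre is guaranteed interior.
#' @keywords internal
.gen_villages <- function(extent, n_villages, village_radius) {
  if (n_villages == 0) return(list())
  margin <- max(village_radius) * 1.2
  w <- extent[3] - extent[1]; h <- extent[4] - extent[2]
  margin <- min(margin, 0.25 * min(w, h))
  minsep <- min(2.2 * max(village_radius), sqrt(w * h / n_villages) * 0.7)
  centres <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(centres) < n_villages && tries < 20000L) {
    tries <- tries + 1L
    p <- c(runif(1, extent[1] + margin, extent[3] - margin),
           runif(1, extent[2] + margin, extent[4] - margin))
    if (nrow(centres) == 0 ||
        min(sqrt((centres[, 1] - p[1])^2 + (centres[, 2] - p[2])^2)) >= minsep) {
      centres <- rbind(centres, p)
    }
  }
  while (nrow(centres) < n_villages) {  # relax separation if space ran out
    centres <- rbind(centres, c(runif(1, extent[1] + margin, extent[3] - margin),
                                runif(1, extent[2] + margin, extent[4] - margin)))
  }
  lapply(seq_len(n_villages), function(i) {
    r0 <- runif(1, village_radius[1], village_radius[2])
    ang <- seq(0, 2 * pi, length.out = 13)[-13]
    rr <- r0 * (1 + runif(12, -0.25, 0.25))
    bx <- pmin(extent[3], pmax(extent[1], centres[i, 1] + rr * cos(ang)))
    by <- pmin(extent[4], pmax(extent[2], centres[i, 2] + rr * sin(ang)))
    list(id = sprintf("village_%02d", i),
         boundary = cbind(x = bx, y = by),
         centroid = c(x = centres[i, 1], y = centres[i, 2]))
  })
}

#' @keywords internal
.gen_population <- function(extent, cell_size, villages, pop_per_village, pop_sigma) {
  ncols <- as.integer(round((extent[3] - extent[1]) / cell_size))
  nrows <- as.integer(round((extent[4] - extent[2]) / cell_size))
  counts <- matrix(0, nrow = nrows, ncol = ncols)
  if (length(villages) > 0) {
    cx <- extent[1] + (seq_len(ncols) - 0.5) * cell_size
    cy <- extent[2] + (seq_len(nrows) - 0.5) * cell_size
    for (v in villages) {
      target <- runif(1, pop_per_village[1], pop_per_village[2])
      gx <- exp(-(cx - v$centroid[1])^2 / (2 * pop_sigma^2))
      gy <- exp(-(cy - v$centroid[2])^2 / (2 * pop_sigma^2))
      bump <- outer(gy, gx)  # rows = y
      counts <- counts + bump * (target / sum(bump))
    }
  }
  structure(
    list(origin = c(x = extent[1], y = extent[2]), cell_size = cell_size,
         ncols = ncols, nrows = nrows, counts = counts),
    class = "rp_popgrid"
  )
}

# Buildings: small axis-aligned rectangles whose centres are rejection-
# sampled inside the village boundary (biased toward the centre like real
# settlements, via a truncated Gaussian around the centroid).
#' @keywords internal
.gen_buildings <- function(extent, villages, n_per_village) {
  out <- list()
  for (v in villages) {
    r_max <- max(sqrt((v$boundary[, 1] - v$centroid[1])^2 +
                      (v$boundary[, 2] - v$centroid[2])^2))
    k <- 0L; tries <- 0L
    while (k < n_per_village && tries < 10000L) {
      tries <- tries + 1L
      p <- v$centroid + stats::rnorm(2, 0, r_max / 2.5)
      if (!.point_in_polygon(p[1], p[2], v$boundary)) next
      w <- runif(1, 8, 15); h <- runif(1, 8, 15)
      poly <- cbind(x = p[1] + c(-w, w, w, -w) / 2,
                    y = p[2] + c(-h, -h, h, h) / 2)
      if (any(poly[, 1] < extent[1] | poly[, 1] > extent[3] |
              poly[, 2] < extent[2] | poly[, 2] > extent[4])) next
      attr(poly, "village_id") <- v$id
      k <- k + 1L
      out[[length(out) + 1L]] <- poly
    }
  }
  out
}

#' Add pollution hotspots to a landscape
#'
#' Places non-traffic point sources either at given coordinates or, with
#' `placement = "far_from_roads"`, at sampled locations that maximise the
#' distance to the road network. The latter emulates settings where dominant
#' PM2.5 sources (agricultural burning, marketplaces) are decoupled from
#' traffic, which reverses the usual distance-decay relationship.
#'
#' @param landscape An `rp_landscape`.
#' @param n Number of hotspots (ignored when `points` given).
#' @param amplitude,decay Source amplitude (ug/m3) and decay length (m).
#' @param points Optional matrix/data.frame of x, y coordinates.
#' @param placement `"random"` or `"far_from_roads"`.
#' @param classes Road classes considered for `"far_from_roads"`.
#' @param seed Integer seed for the placement sampling.
#' @return The landscape with the `hotspots` element replaced.
#' @export
with_hotspots <- function(landscape, n = 3, amplitude = 60, decay = 1200,
                          points = NULL, placement = c("random", "far_from_roads"),
                          classes = c("highway", "main"), seed = 1) {
  placement <- match.arg(placement)
  ext <- landscape$extent
  if (is.null(points)) {
    points <- .with_seed(seed, {
      if (placement == "random") {
        cbind(runif(n, ext[1], ext[3]), runif(n, ext[2], ext[4]))
      } else {
        cand <- cbind(runif(500, ext[1], ext[3]), runif(500, ext[2], ext[4]))
        segs <- road_segments(landscape$roads, classes = classes)
        d <- .min_dist_to_segments(cand[, 1], cand[, 2], segs)
        sel <- integer(0)
        ord <- order(d, decreasing = TRUE)
        for (i in ord) {
          if (length(sel) == n) break
          if (length(sel) == 0 ||
              min(sqrt((cand[sel, 1] - cand[i, 1])^2 +
                       (cand[sel, 2] - cand[i, 2])^2)) > 1500) {
            sel <- c(sel, i)
          }
        }
        cand[sel, , drop = FALSE]
      }
    })
  }
  points <- as.matrix(points)
  landscape$hotspots <- data.frame(
    x = points[, 1], y = points[, 2],
    amplitude = rep_len(amplitude, nrow(points)),
    decay = rep_len(decay, nrow(points))
  )
  landscape
}

#' Extract road segments from a road vertex table
#'
#' Converts the per-vertex road representation into one row per segment
#' (columns `x1, y1, x2, y2, class, road_id`), optionally restricted to a
#' set of road classes. Zero-length segments are dropped with a warning.
#'
#' @param roads Road vertex data.frame (`road_id`, `class`, `x`, `y`).
#' @param classes Optional character vector of classes to keep.
#' @return A data.frame of segments.
#' @export
road_segments <- function(roads, classes = NULL) {
  if (!is.null(classes)) roads <- roads[roads$class %in% classes, , drop = FALSE]
  if (nrow(roads) == 0)
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), class = character(0), road_id = character(0)))
  pieces <- lapply(split(roads, roads$road_id), function(r) {
    n <- nrow(r)
    if (n < 2) return(NULL)
    data.frame(x1 = r$x[-n], y1 = r$y[-n], x2 = r$x[-1], y2 = r$y[-1],
               class = r$class[-n], road_id = r$road_id[-n])
  })
  segs <- do.call(rbind, pieces)
  rownames(segs) <- NULL
  zl <- (segs$x1 == segs$x2) & (segs$y1 == segs$y2)
  if (any(zl)) {
    warning(sum(zl), " zero-length road segment(s) dropped")
    segs <- segs[!zl, , drop = FALSE]
  }
  segs
}

#' @export
print.rp_landscape <- function(x, ...) {
  segs <- road_segments(x$roads)
  cat("Synthetic landscape\n")
  cat(sprintf("  extent: [%g, %g] x [%g, %g] m\n",
              x$extent[1], x$extent[3], x$extent[2], x$extent[4]))
  cat(sprintf("  roads: %d (%s)\n", length(unique(x$roads$road_id)),
              paste(sprintf("%s=%d", names(table(unique(x$roads[c('road_id','class')])$class)),
                            table(unique(x$roads[c('road_id','class')])$class)), collapse = ", ")))
  cat(sprintf("  villages: %d; buildings: %d; hotspots: %d\n",
              length(x$villages), length(x$buildings), nrow(x$hotspots)))
  cat(sprintf("  population: %d x %d cells of %g m, total %.0f\n",
              x$population$nrows, x$population$ncols, x$population$cell_size,
              sum(x$population$counts)))
  invisible(x)
}

#' @export
print.rp_popgrid <- function(x, ...) {
  cat(sprintf("Population grid: %d x %d cells of %g m, origin (%g, %g), total %.0f\n",
              x$nrows, x$ncols, x$cell_size, x$origin[1], x$origin[2], sum(x$counts)))
  invisible(x)
}
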