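# Planar geometry primitives shared by the proxy, mobility and tessellation
# code. Everything works in a metric planar frame (metres); polygons are
# two-column matrices of vertices, not closed (last vertex != first).

#' @keywords internal
.polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Signed centroid of a simple polygon (shoelace formula).
#' @keywords internal
.polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Point-in-polygon, vectorised over points. Ray casting with an explicit
# on-boundary test; points on the boundary count as inside (convention used
# for building footprints and hexagon membership).
#' @keywords internal
.point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1L), 1]; y2 <- poly[c(2:n, 1L), 2]
  inside <- rep(FALSE, length(px))
  onb <- rep(FALSE, length(px))
  for (j in seq_len(n)) {
    dx <- x2[j] - x1[j]; dy <- y2[j] - y1[j]
    L2 <- dx * dx + dy * dy
    if (L2 > 0) {
      t <- pmin(1, pmax(0, ((px - x1[j]) * dx + (py - y1[j]) * dy) / L2))
      d2 <- (px - (x1[j] + t * dx))^2 + (py - (y1[j] + t * dy))^2
      onb <- onb | d2 <= eps * eps
    }
    crosses <- (y1[j] > py) != (y2[j] > py)
    if (any(crosses)) {
      xint <- x1[j] + (py - y1[j]) * dx / dy
      inside <- xor(inside, crosses & px < xint)
    }
  }
  inside | onb
}

# Minimum Euclidean distance from each point to a set of segments.
# segs: data.frame/list with x1, y1, x2, y2. Zero-length segments are skipped.
#' @keywords internal
.min_dist_to_segments <- function(px, py, segs) {
  best <- rep(Inf, length(px))
  for (j in seq_along(segs$x1)) {
    dx <- segs$x2[j] - segs$x1[j]; dy <- segs$y2[j] - segs$y1[j]
    L2 <- dx * dx + dy * dy
    if (L2 == 0) next
    t <- pmin(1, pmax(0, ((px - segs$x1[j]) * dx + (py - segs$y1[j]) * dy) / L2))
    d2 <- (px - (segs$x1[j] + t * dx))^2 + (py - (segs$y1[j] + t * dy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Clip one segment to the inside of a simple polygon. Splits the segment at
# every polygon-edge crossing and keeps the pieces whose midpoint is inside.
# Returns a matrix with columns x1, y1, x2, y2 (possibly zero rows).
#' @keywords internal
.clip_segment_to_polygon <- function(x1, y1, x2, y2, poly) {
  n <- nrow(poly)
  ex1 <- poly[, 1]; ey1 <- poly[, 2]
  ex2 <- poly[c(2:n, 1L), 1]; ey2 <- poly[c(2:n, 1L), 2]
  rx <- x2 - x1; ry <- y2 - y1
  ts <- c(0, 1)
  for (j in seq_len(n)) {
    sx <- ex2[j] - ex1[j]; sy <- ey2[j] - ey1[j]
    den <- rx * sy - ry * sx
    if (abs(den) < 1e-12) next  # parallel
    t <- ((ex1[j] - x1) * sy - (ey1[j] - y1) * sx) / den
    u <- ((ex1[j] - x1) * ry - (ey1[j] - y1) * rx) / den
    if (t > 0 && t < 1 && u >= 0 && u <= 1) ts <- c(ts, t)
  }
  ts <- sort(unique(ts))
  keep <- matrix(numeric(0), ncol = 4)
  for (k in seq_len(length(ts) - 1L)) {
    tm <- (ts[k] + ts[k + 1L]) / 2
    mx <- x1 + tm * rx; my <- y1 + tm * ry
    if (.point_in_polygon(mx, my, poly)) {
      keep <- rbind(keep, c(x1 + ts[k] * rx, y1 + ts[k] * ry,
                            x1 + ts[k + 1L] * rx, y1 + ts[k + 1L] * ry))
    }
  }
  colnames(keep) <- c("x1", "y1", "x2", "y2")
  keep
}

# Sutherland-Hodgman clip of a simple polygon against an axis-aligned
# rectangle (the clip window is convex so the algorithm is exact up to
# floating point). Returns a vertex matrix, possibly with 0 rows.
#' @keywords internal
.clip_polygon_to_rect <- function(poly, xmin, ymin, xmax, ymax) {
  clip_half <- function(pts, inside, intersect) {
    if (nrow(pts) == 0) return(pts)
    n <- nrow(pts)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      a <- pts[i, ]; b <- pts[if (i == n) 1L else i + 1L, ]
      ain <- inside(a); bin <- inside(b)
      if (ain) out <- rbind(out, a)
      if (ain != bin) out <- rbind(out, intersect(a, b))
    }
    out
  }
  p <- poly
  p <- clip_half(p, function(q) q[1] >= xmin, function(a, b) {
    t <- (xmin - a[1]) / (b[1] - a[1]); c(xmin, a[2] + t * (b[2] - a[2]))
  })
  p <- clip_half(p, function(q) q[1] <= xmax, function(a, b) {
    t <- (xmax - a[1]) / (b[1] - a[1]); c(xmax, a[2] + t * (b[2] - a[2]))
  })
  p <- clip_half(p, function(q) q[2] >= ymin, function(a, b) {
    t <- (ymin - a[2]) / (b[2] - a[2]); c(a[1] + t * (b[1] - a[1]), ymin)
  })
  p <- clip_half(p, function(q) q[2] <= ymax, function(a, b) {
    t <- (ymax - a[2]) / (b[2] - a[2]); c(a[1] + t * (b[1] - a[1]), ymax)
  })
  p
}

# Split a segment at the gridlines of a square-cell grid and attribute each
# piece to the cell containing its midpoint. Returns data.frame(row, col, len).
# Rows count upward from the grid origin (row 1 = southernmost).
#' @keywords internal
.split_segment_by_grid <- function(x1, y1, x2, y2, x0, y0, cell_size) {
  rx <- x2 - x1; ry <- y2 - y1
  len <- sqrt(rx * rx + ry * ry)
  if (len == 0) return(data.frame(row = integer(0), col = integer(0), len = numeric(0)))
  ts <- c(0, 1)
  if (rx != 0) {
    ks <- seq(ceiling((min(x1, x2) - x0) / cell_size), floor((max(x1, x2) - x0) / cell_size))
    tx <- (x0 + ks * cell_size - x1) / rx
    ts <- c(ts, tx[tx > 0 & tx < 1])
  }
  if (ry != 0) {
    ks <- seq(ceiling((min(y1, y2) - y0) / cell_size), floor((max(y1, y2) - y0) / cell_size))
    ty <- (y0 + ks * cell_size - y1) / ry
    ts <- c(ts, ty[ty > 0 & ty < 1])
  }
  ts <- sort(unique(ts))
  a <- ts[-length(ts)]; b <- ts[-1]
  tm <- (a + b) / 2
  data.frame(
    row = as.integer(floor((y1 + tm * ry - y0) / cell_size)) + 1L,
    col = as.integer(floor((x1 + tm * rx - x0) / cell_size)) + 1L,
    len = (b - a) * len
  )
}

# Evaluate and temporarily set the RNG seed, restoring the caller's stream.
#' @keywords internal
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
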