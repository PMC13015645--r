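# Independent brute-force oracles, deliberately written without reusing any
# package internals, plus small fixture builders.

# Spearman rho via the explicit mid-rank + product-moment formula.
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, 0)
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2); syy <- sum((ry - mean(ry))^2)
  sxy / sqrt(sxx * syy)
}

# Two-sided Monte-Carlo permutation p-value for Spearman rho.
oracle_spearman_perm_p <- function(x, y, n_perm = 1e5, seed = 801) {
  rho <- oracle_spearman_rho(x, y)
  rx <- rank(x); ry <- rank(y)
  set.seed(seed)
  M <- matrix(ry[replicate(n_perm, sample.int(length(y)))], nrow = length(y))
  rp <- as.numeric(stats::cor(rx, M))
  list(p = mean(abs(rp) >= abs(rho) - 1e-12),
       se = sqrt(mean(abs(rp) >= abs(rho) - 1e-12) *
                   (1 - mean(abs(rp) >= abs(rho) - 1e-12)) / n_perm))
}

# Minimum point-to-polyline distance by dense sampling along each segment.
oracle_dense_min_dist <- function(px, py, segs, step = 1) {
  best <- Inf
  for (j in seq_len(nrow(segs))) {
    len <- sqrt((segs$x2[j] - segs$x1[j])^2 + (segs$y2[j] - segs$y1[j])^2)
    if (len == 0) next
    tt <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    sx <- segs$x1[j] + tt * (segs$x2[j] - segs$x1[j])
    sy <- segs$y1[j] + tt * (segs$y2[j] - segs$y1[j])
    best <- min(best, min(sqrt((sx - px)^2 + (sy - py)^2)))
  }
  best
}

# Independent re-evaluation of the generative exposure formula at given
# positions (own point-segment distance code).
oracle_exposure <- function(landscape, params, x, y, indoor) {
  pt_seg <- function(px, py, x1, y1, x2, y2) {
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx^2 + dy^2
    if (L2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
    t <- max(0, min(1, ((px - x1) * dx + (py - y1) * dy) / L2))
    sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2)
  }
  segs <- road_segments(landscape$roads, classes = params$traffic_classes)
  vapply(seq_along(x), function(i) {
    base <- params$background
    if (nrow(segs) > 0 && params$traffic_amplitude > 0) {
      d <- min(vapply(seq_len(nrow(segs)), function(j)
        pt_seg(x[i], y[i], segs$x1[j], segs$y1[j], segs$x2[j], segs$y2[j]), 0))
      base <- base + params$traffic_amplitude * exp(-d / params$traffic_decay_length)
    }
    hs <- landscape$hotspots
    if (nrow(hs) > 0) {
      for (h in seq_len(nrow(hs))) {
        base <- base + hs$amplitude[h] *
          exp(-sqrt((x[i] - hs$x[h])^2 + (y[i] - hs$y[h])^2) / hs$decay[h])
      }
    }
    if (indoor[i]) base * params$indoor_attenuation else base
  }, 0)
}

# Random star-shaped test polygon around a centre.
random_polygon <- function(cx, cy, r0, k = 10) {
  ang <- sort(runif(k, 0, 2 * pi))
  rr <- r0 * runif(k, 0.6, 1.4)
  cbind(x = cx + rr * cos(ang), y = cy + rr * sin(ang))
}

# Minimal population grid builder for proxy tests.
make_popgrid <- function(origin, cell_size, counts) {
  structure(
    list(origin = c(x = origin[1], y = origin[2]), cell_size = cell_size,
         ncols = ncol(counts), nrows = nrow(counts), counts = counts),
    class = "rp_popgrid"
  )
}

# Hand-built landscape: one straight horizontal highway at y = y_road, one
# main road at x = x_main, one square village, uniform population.
toy_landscape <- function(y_road = 50, x_main = 350) {
  roads <- rbind(
    data.frame(road_id = "r1", class = "highway",
               x = c(-100, 300), y = c(y_road, y_road)),
    data.frame(road_id = "r2", class = "main",
               x = c(x_main, x_main), y = c(-100, 300))
  )
  boundary <- cbind(x = c(0, 200, 200, 0), y = c(0, 0, 200, 200))
  structure(
    list(extent = c(-100, -100, 400, 300),
         roads = roads,
         population = make_popgrid(c(0, 0), 100, matrix(25, 2, 2)),
         villages = list(list(id = "v1", boundary = boundary,
                              centroid = c(x = 100, y = 100))),
         buildings = list(),
         hotspots = data.frame(x = numeric(0), y = numeric(0),
                               amplitude = numeric(0), decay = numeric(0))),
    class = "rp_landscape"
  )
}

# Fixed 20-pair fixture with ties (digits of pi against digits of e).
ties_fixture <- function() {
  list(x = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3, 2, 3, 8, 4),
       y = c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8, 4, 5, 9, 0, 4, 5, 2, 3, 5, 3))
}
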