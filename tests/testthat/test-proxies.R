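test_that("fishnet cells align with the raster and follow the positive-overlap rule", {
  g <- make_popgrid(c(0, 0), 100, matrix(1, 10, 10))
  # boundary exactly one cell: neighbours share only an edge (zero overlap)
  one <- build_fishnet(g, cbind(c(200, 300, 300, 200), c(200, 200, 300, 300)))
  expect_equal(nrow(one), 1)
  expect_equal(one$xmin, 200); expect_equal(one$ymin, 200)
  # a 3x3 block
  nine <- build_fishnet(g, cbind(c(100, 400, 400, 100), c(100, 100, 400, 400)))
  expect_equal(nrow(nine), 9)
  expect_true(all(nine$xmin %% 100 == 0))  # corners coincide with raster corners
  expect_error(build_fishnet(g, cbind(c(5000, 6000, 6000), c(5000, 5000, 6000))),
               "extent")
})

test_that("cell-boundary overlap areas sum to the boundary area", {
  g <- make_popgrid(c(0, 0), 100, matrix(1, 30, 30))
  set.seed(101)
  for (i in 1:20) {
    poly <- random_polygon(runif(1, 800, 2200), runif(1, 800, 2200),
                           runif(1, 150, 600))
    cells <- build_fishnet(g, poly)
    expect_equal(sum(cells$overlap_area), roadproxy:::.polygon_area(poly),
                 tolerance = 1e-6)
  }
})

test_that("per-cell road lengths and densities follow direct arithmetic", {
  g <- make_popgrid(c(0, 0), 100, matrix(1, 4, 4))
  boundary <- cbind(c(0, 400, 400, 0), c(0, 0, 400, 400))
  cells <- build_fishnet(g, boundary)
  # a single 100 m segment crossing two cells 80 m / 20 m
  r_single <- data.frame(road_id = "a", class = "main",
                         x = c(120, 220), y = c(50, 50))
  cd <- road_length_per_cell(r_single, cells, boundary)
  expect_equal(cd$road_length_km[cd$cell_id == "c_1_2"], 0.08)
  expect_equal(cd$road_length_km[cd$cell_id == "c_1_3"], 0.02)
  expect_equal(cd$rnd[cd$cell_id == "c_1_2"], 0.08 / 0.01)
  expect_equal(sum(cd$road_length_km), 0.1)

  # a segment fully inside one cell
  r_in <- data.frame(road_id = "b", class = "highway",
                     x = c(110, 210), y = c(150, 150))
  cd2 <- road_length_per_cell(r_in, cells, boundary)
  expect_equal(cd2$road_length_km[cd2$cell_id == "c_2_2"], 0.09)
  expect_equal(cd2$road_length_km[cd2$cell_id == "c_2_3"], 0.01)
})

test_that("fishnet splitting conserves clipped network length", {
  set.seed(202)
  g <- make_popgrid(c(0, 0), 100, matrix(1, 30, 30))
  for (i in 1:20) {
    poly <- random_polygon(1500, 1500, runif(1, 400, 900))
    cells <- build_fishnet(g, poly)
    roads <- do.call(rbind, lapply(1:4, function(k)
      data.frame(road_id = paste0("r", k), class = "main",
                 x = runif(3, 0, 3000), y = runif(3, 0, 3000))))
    cd <- road_length_per_cell(roads, cells, poly)
    segs <- road_segments(roads)
    clipped_total <- 0
    for (j in seq_len(nrow(segs))) {
      cl <- roadproxy:::.clip_segment_to_polygon(segs$x1[j], segs$y1[j],
                                                 segs$x2[j], segs$y2[j], poly)
      if (nrow(cl)) clipped_total <- clipped_total +
          sum(sqrt((cl[, 3] - cl[, 1])^2 + (cl[, 4] - cl[, 2])^2))
    }
    expect_equal(sum(cd$road_length_km) * 1000, clipped_total,
                 tolerance = 1e-6)
  }
})

test_that("population weighting follows the weighted-mean definition", {
  cells <- data.frame(rnd = c(2, 4), population = c(100, 300))
  expect_equal(wrnd(cells)$wrnd, 3.5)
  # uniform weights collapse to the unweighted mean
  cells2 <- data.frame(rnd = c(1, 5, 9), population = c(7, 7, 7))
  expect_equal(wrnd(cells2)$wrnd, 5)
  # zero total population: flagged fallback to the unweighted mean
  z <- wrnd(data.frame(rnd = c(1, 3), population = c(0, 0)))
  expect_equal(z$wrnd, 2)
  expect_equal(z$flags, "zero-population-fallback")
  expect_error(wrnd(data.frame(rnd = numeric(0), population = numeric(0))),
               "empty")
  # optional area weighting scales edge-cell populations by overlap fraction
  cells4 <- data.frame(rnd = c(2, 4), population = c(100, 100),
                       xmin = c(0, 100), xmax = c(100, 200),
                       ymin = 0, ymax = 100,
                       overlap_area = c(10000, 5000))  # full vs half cell
  expect_equal(wrnd(cells4, area_weight_population = TRUE)$wrnd,
               (2 * 100 + 4 * 50) / 150)
  expect_error(wrnd(data.frame(rnd = 1, population = 1),
                    area_weight_population = TRUE), "overlap_area")
  # brute-force agreement and bounds on random cells
  set.seed(303)
  for (i in 1:10) {
    cells3 <- data.frame(rnd = runif(50, 0, 30), population = rpois(50, 5))
    w <- wrnd(cells3)$wrnd
    expect_equal(w, sum(cells3$rnd * cells3$population) / sum(cells3$population),
                 tolerance = 1e-12)
    pos <- cells3$population > 0
    expect_gte(w, min(cells3$rnd[pos]))
    expect_lte(w, max(cells3$rnd[pos]))
  }
})

test_that("distance to road class matches geometry and dense sampling", {
  roads <- data.frame(road_id = "m1", class = "main",
                      x = c(3000, 3000), y = c(-4000, 4000))
  expect_equal(distance_to_road_class(c(0, 0), roads, "main")$distance_km, 3)
  # centroid on a highway
  hw <- data.frame(road_id = "h1", class = "highway",
                   x = c(-100, 100), y = c(0, 0))
  expect_equal(distance_to_road_class(c(50, 0), hw, "highway")$distance_km, 0)
  # absent class is a flagged missing value, not an error
  miss <- distance_to_road_class(c(0, 0), roads, "highway")
  expect_true(is.na(miss$distance_km))
  expect_match(miss$flags, "no-highway")
  # dense-sampling oracle on random polylines
  set.seed(404)
  for (i in 1:10) {
    roads <- do.call(rbind, lapply(1:4, function(k)
      data.frame(road_id = paste0("r", k), class = "main",
                 x = runif(5, 0, 2000), y = runif(5, 0, 2000))))
    p <- runif(2, 0, 2000)
    d <- distance_to_road_class(p, roads, "main")$distance_km
    d_oracle <- oracle_dense_min_dist(p[1], p[2], road_segments(roads)) / 1000
    expect_lt(abs(d - d_oracle), 1e-3)
  }
})

test_that("village proxies match the hand-computed toy fixture", {
  toy <- toy_landscape(y_road = 50, x_main = 350)
  rec <- compute_village_proxies(toy, "v1")
  # highway runs along y = 50 through the bottom two 100 m cells: 0.1 km in
  # each, rnd 10 km/km2; main road at x = 350 clips out of the boundary, so
  # only the highway contributes; uniform population -> wrnd = mean(10,10,0,0)
  expect_equal(rec$wrnd, 5)
  expect_equal(rec$eh, 0.05)          # centroid (100,100) to y = 50
  expect_equal(rec$em, 0.25)          # centroid to x = 350
  expect_identical(compute_village_proxies(toy, "v1"), rec)  # deterministic
  expect_error(compute_village_proxies(toy, "nope"), "unknown village")
})

test_that("proxies are translation invariant and insensitive to population scaling", {
  ls <- generate_landscape(seed = 91, n_villages = 2, cell_size = 200)
  base <- village_proxy_table(ls)
  shift <- c(5000, -3000)
  ls2 <- ls
  ls2$roads$x <- ls2$roads$x + shift[1]; ls2$roads$y <- ls2$roads$y + shift[2]
  ls2$population$origin <- ls2$population$origin + shift
  ls2$villages <- lapply(ls2$villages, function(v) {
    v$boundary[, 1] <- v$boundary[, 1] + shift[1]
    v$boundary[, 2] <- v$boundary[, 2] + shift[2]
    v$centroid <- v$centroid + shift
    v
  })
  moved <- village_proxy_table(ls2)
  expect_equal(moved$wrnd, base$wrnd, tolerance = 1e-9)
  expect_equal(moved$em, base$em, tolerance = 1e-9)
  expect_equal(moved$eh, base$eh, tolerance = 1e-9)

  ls3 <- ls
  ls3$population$counts <- ls3$population$counts * 2
  expect_equal(village_proxy_table(ls3)$wrnd, base$wrnd, tolerance = 1e-12)
})

test_that("adding road segments never increases class distances", {
  set.seed(505)
  p <- c(500, 500)
  roads <- data.frame(road_id = "h1", class = "highway",
                      x = c(0, 4000), y = c(3000, 3500))
  d0 <- distance_to_road_class(p, roads, "highway")$distance_km
  roads2 <- rbind(roads, data.frame(road_id = "h2", class = "highway",
                                    x = c(0, 1000), y = c(800, 900)))
  d1 <- distance_to_road_class(p, roads2, "highway")$distance_km
  expect_lte(d1, d0)
})
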