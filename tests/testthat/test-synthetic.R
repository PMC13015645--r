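test_that("landscape honours requested structure and degenerate inputs", {
  ls <- generate_landscape(seed = 1, n_highways = 2, n_main = 3, n_villages = 4)
  per_road <- unique(ls$roads[c("road_id", "class")])
  expect_equal(sum(per_road$class == "highway"), 2)
  expect_equal(sum(per_road$class == "main"), 3)
  expect_equal(length(ls$villages), 4)
  expect_error(generate_landscape(seed = 1, extent = c(0, 0, -10, 10)), "extent")

  empty <- generate_landscape(seed = 2, n_villages = 0,
                              n_buildings_per_village = 0)
  expect_length(empty$villages, 0)
  expect_true(all(empty$population$counts == 0))
})

test_that("landscape invariants: centroids interior, geometry in extent, population valid", {
  ls <- generate_landscape(seed = 3, n_villages = 5, n_hotspots = 2)
  for (v in ls$villages)
    expect_true(roadproxy:::.point_in_polygon(v$centroid[1], v$centroid[2], v$boundary))
  ext <- ls$extent
  expect_true(all(ls$roads$x >= ext[1] & ls$roads$x <= ext[3]))
  expect_true(all(ls$roads$y >= ext[2] & ls$roads$y <= ext[4]))
  for (b in ls$buildings) {
    expect_true(all(b[, 1] >= ext[1] & b[, 1] <= ext[3]))
    expect_true(all(b[, 2] >= ext[2] & b[, 2] <= ext[4]))
  }
  expect_true(all(is.finite(ls$population$counts)))
  expect_true(all(ls$population$counts >= 0))
})

test_that("identical seeds reproduce landscapes and traces exactly", {
  a <- generate_landscape(seed = 11, n_villages = 3, n_hotspots = 1)
  b <- generate_landscape(seed = 11, n_villages = 3, n_hotspots = 1)
  expect_identical(a, b)
  pa <- exposure_params(seed = 5)
  ta <- simulate_traces(a, pa, n_participants = 2, minutes_per_participant = 60)
  tb <- simulate_traces(b, pa, n_participants = 2, minutes_per_participant = 60)
  expect_identical(ta, tb)
})

test_that("noise-free exposure collapses to the stated constants and formula", {
  ls <- generate_landscape(seed = 4, n_villages = 2)
  flat <- exposure_params(traffic_amplitude = 0, noise_sigma_log = 0,
                          indoor_attenuation = 0.6, seed = 6)
  tr <- simulate_traces(ls, flat, n_participants = 2, minutes_per_participant = 80)
  expect_equal(tr$pm25[tr$truth_env == "outdoor"],
               rep(15, sum(tr$truth_env == "outdoor")))
  expect_equal(tr$pm25[tr$truth_env == "indoor"],
               rep(15 * 0.6, sum(tr$truth_env == "indoor")))

  # a point exactly on a road sees background + amplitude
  toy <- toy_landscape()
  par <- exposure_params(traffic_amplitude = 40, noise_sigma_log = 0)
  expect_equal(roadproxy:::.exposure_base(toy, par, 100, 50), 15 + 40)

  # full oracle equivalence at every logged position, noise off, hotspots on
  ls2 <- with_hotspots(ls, n = 2, amplitude = 30, decay = 400, seed = 9)
  par2 <- exposure_params(noise_sigma_log = 0, seed = 7)
  tr2 <- simulate_traces(ls2, par2, n_participants = 2, minutes_per_participant = 60)
  expect_equal(tr2$pm25,
               oracle_exposure(ls2, par2, tr2$x, tr2$y, tr2$truth_env == "indoor"),
               tolerance = 1e-12)
})

test_that("movement respects configured step ranges", {
  ls <- generate_landscape(seed = 8, n_villages = 2)
  par <- exposure_params(seed = 12)
  tr <- simulate_traces(ls, par, n_participants = 3, minutes_per_participant = 200)
  for (p in unique(tr$participant_id)) {
    t1 <- tr[tr$participant_id == p, ]
    d <- sqrt(diff(t1$x)^2 + diff(t1$y)^2)
    env_pair <- paste(t1$truth_env[-nrow(t1)], t1$truth_env[-1])
    expect_true(all(d[env_pair == "indoor indoor"] < 2))
  }
  # outdoor-only traces: every step within the configured range
  tr2 <- simulate_traces(ls, par, n_participants = 2,
                         minutes_per_participant = 100, indoor = FALSE)
  for (p in unique(tr2$participant_id)) {
    t1 <- tr2[tr2$participant_id == p, ]
    d <- sqrt(diff(t1$x)^2 + diff(t1$y)^2)
    # reflection at the extent can shorten an apparent step, never lengthen it
    expect_true(all(d <= 110 + 1e-9))
    expect_true(mean(d >= 60 - 1e-9) > 0.95)
  }
})

test_that("outdoor mean matches the analytic mean of the generative model", {
  ls <- generate_landscape(seed = 21, n_villages = 4)
  par <- exposure_params(noise_sigma_log = 0.3, seed = 22)
  tr <- simulate_traces(ls, par, n_participants = 5, minutes_per_participant = 600)
  expect_equal(nrow(tr), 3000)
  out <- tr[tr$truth_env == "outdoor", ]
  base <- oracle_exposure(ls, par, out$x, out$y, rep(FALSE, nrow(out)))
  analytic_mean <- mean(base) * exp(par$noise_sigma_log^2 / 2)
  mc_se <- sd(out$pm25) / sqrt(nrow(out))
  expect_lt(abs(mean(out$pm25) - analytic_mean), 3 * mc_se)
})

test_that("raising traffic amplitude never lowers any outdoor concentration", {
  ls <- generate_landscape(seed = 31, n_villages = 2)
  lo <- simulate_traces(ls, exposure_params(traffic_amplitude = 20, seed = 33),
                        n_participants = 2, minutes_per_participant = 120)
  hi <- simulate_traces(ls, exposure_params(traffic_amplitude = 60, seed = 33),
                        n_participants = 2, minutes_per_participant = 120)
  expect_identical(lo$x, hi$x)  # positions unaffected by exposure parameters
  out <- lo$truth_env == "outdoor"
  expect_true(all(hi$pm25[out] >= lo$pm25[out]))
})

test_that("trace and landscape writers round-trip through plain text", {
  ls <- generate_landscape(seed = 41, n_villages = 2, cell_size = 500)
  tr <- simulate_traces(ls, exposure_params(seed = 42), n_participants = 2,
                        minutes_per_participant = 30)
  tmp <- tempfile(fileext = ".csv")
  write_traces_csv(tr, tmp)
  back <- read_traces_csv(tmp)
  expect_equal(back$pm25, tr$pm25)
  expect_equal(back$truth_env, tr$truth_env)

  asc <- tempfile(fileext = ".asc")
  write_popgrid_asc(ls$population, asc)
  pg <- read_popgrid_asc(asc)
  expect_equal(pg$ncols, ls$population$ncols)
  expect_equal(pg$counts, ls$population$counts, tolerance = 1e-6,
               ignore_attr = TRUE)

  gj <- tempfile()
  write_landscape_geojson(ls, gj)
  expect_true(all(file.exists(file.path(gj, c("roads.geojson",
                                              "villages.geojson",
                                              "buildings.geojson")))))
})

test_that("indoor episodes without buildings raise a configuration error", {
  ls <- generate_landscape(seed = 51, n_villages = 2, n_buildings_per_village = 0)
  expect_error(simulate_traces(ls, exposure_params(), 2, 30), "buildings")
})
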