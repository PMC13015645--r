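test_that("metric identities hold on fixed prediction vectors", {
  obs <- c(5, 10, 20, 40, 80, 15, 33)
  m <- roadproxy:::.reg_metrics(obs, obs)
  expect_equal(m$r2, 1); expect_equal(m$rmse, 0)
  expect_equal(m$mae, 0); expect_equal(m$mbe, 0)
  set.seed(12)
  pred <- obs + rnorm(7, 2, 5)
  m2 <- roadproxy:::.reg_metrics(pred, obs)
  expect_gte(m2$rmse, m2$mae)
  expect_gte(m2$mae, 0)
  expect_gte(m2$rmse, abs(m2$mbe))
})

test_that("cross-validation folds partition the data and results are deterministic", {
  d <- simulate_proxy_observations(seed = 3, n = 90)
  f1 <- fit_rf_cv(d, c("wrnd", "em", "eh"), n_folds = 3, seed = 4)
  expect_equal(sort(unique(f1$oof$fold)), 1:3)
  expect_equal(as.integer(table(f1$oof$fold)), rep(30L, 3))
  expect_false(anyNA(f1$oof$predicted))  # every observation predicted once
  f2 <- fit_rf_cv(d, c("wrnd", "em", "eh"), n_folds = 3, seed = 4)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$oof, f2$oof)
  expect_error(fit_rf_cv(d[1:2, ], "eh", n_folds = 3), "n_folds")
  d_na <- d; d_na$eh[1] <- NA
  expect_error(fit_rf_cv(d_na, "eh"), "missing")
  # mtry default: floor(sqrt(p)) with a floor of 1
  expect_equal(f1$spec$mtry, 1)
})

test_that("the forest recovers a noise-free single-feature map out of fold", {
  set.seed(21)
  d <- data.frame(eh = runif(300, 0, 10))
  d$pm25 <- 10 + 5 * d$eh
  fit <- fit_rf_cv(d, "eh", seed = 22)
  expect_gte(fit$metrics$r2, 0.95)
  expect_null(fit$importance)  # single-feature models carry no importances
  expect_error(feature_importance(fit), "combined")
})

test_that("pure-noise targets show no out-of-fold skill", {
  r2 <- vapply(1:20, function(s) {
    d <- roadproxy:::.with_seed(1000 + s, {
      data.frame(wrnd = runif(150), em = runif(150), eh = runif(150),
                 pm25 = rnorm(150, 30, 10))
    })
    fit_rf_cv(d, c("wrnd", "em", "eh"), seed = s)$metrics$r2
  }, 0)
  expect_true(all(r2 <= 0.1))
})

test_that("predict, residuals and plot methods work on the fitted object", {
  d <- simulate_proxy_observations(seed = 6, n = 60)
  fit <- fit_rf_cv(d, c("wrnd", "em", "eh"), seed = 7)
  expect_equal(predict(fit), fit$oof$predicted)
  p <- predict(fit, d[1:5, ])
  expect_length(p, 5)
  expect_equal(residuals(fit), d$pm25 - fit$oof$predicted)
  pdf(NULL); on.exit(dev.off())
  expect_no_error(plot(fit))
  expect_output(print(summary(fit)), "out-of-fold")
})

test_that("the model suite enumerates strata and model forms", {
  d <- simulate_proxy_observations(seed = 8, n = 120, n_strata = 3)
  suite <- run_model_suite(d, stratum_col = "stratum", seed = 9)
  expect_equal(nrow(suite$metrics), 16)  # 4 models x (3 strata + global)
  expect_setequal(unique(suite$metrics$model),
                  c("WRND", "EM", "EH", "Combined"))
  expect_setequal(unique(suite$metrics$stratum),
                  c("site-1", "site-2", "site-3", "global"))
  expect_length(suite$fits, 16)
})

test_that("impurity importances are normalised and follow the dominant signal", {
  # target driven only by EH
  top <- vapply(1:20, function(s) {
    d <- simulate_proxy_observations(seed = 2000 + s, n = 120,
                                     beta_wrnd = 0, amp_em = 0, amp_eh = 12,
                                     noise_sd = 1.5)
    imp <- feature_importance(fit_rf_cv(d, c("wrnd", "em", "eh"), seed = s))
    expect_equal(sum(imp), 1, tolerance = 1e-9)
    names(which.max(imp))
  }, "")
  expect_gte(mean(top == "eh"), 0.9)
  # duplicated features share importance approximately symmetrically
  gaps <- vapply(1:10, function(s) {
    d <- simulate_proxy_observations(seed = 3000 + s, n = 120,
                                     beta_wrnd = 0, amp_em = 0, amp_eh = 12,
                                     noise_sd = 1.5)
    d$em <- d$eh
    imp <- feature_importance(fit_rf_cv(d, c("wrnd", "em", "eh"), seed = s))
    abs(imp[["em"]] - imp[["eh"]])
  }, 0)
  expect_lt(mean(gaps), 0.15)
})

test_that("binned bias profiles match a group-by oracle and sensible CIs", {
  set.seed(31)
  obs <- runif(400, 0, 100)
  pred <- obs + rnorm(400, 3, 6)
  bp <- binned_bias(pred, obs, bin_width = 20, n_boot = 500, seed = 32)
  expect_s3_class(bp, "rp_bias_profile")
  bias <- pred - obs
  grp <- floor(obs / 20)
  for (i in seq_len(nrow(bp))) {
    v <- bias[grp == bp$bin_low[i] / 20]
    expect_equal(bp$n[i], length(v))
    expect_equal(bp$mean_bias[i], mean(v), tolerance = 1e-12)
    expect_equal(bp$median_bias[i], median(v), tolerance = 1e-12)
    expect_lte(bp$ci95_low[i], bp$mean_bias[i])
    expect_gte(bp$ci95_high[i], bp$mean_bias[i])
    # bootstrap CI close to the normal approximation for well-filled bins
    if (length(v) >= 30) {
      half_boot <- (bp$ci95_high[i] - bp$ci95_low[i]) / 2
      half_norm <- 1.96 * sd(v) / sqrt(length(v))
      expect_lt(abs(half_boot - half_norm) / half_norm, 0.2)
    }
  }
  expect_equal(sum(bp$n), 400)
  # constant shift: every bin shows that bias exactly
  bp5 <- binned_bias(obs + 5, obs, bin_width = 20, n_boot = 200, seed = 33)
  expect_true(all(abs(bp5$mean_bias - 5) < 1e-12))
  expect_true(all(abs(bp5$median_bias - 5) < 1e-12))
  bp0 <- binned_bias(obs, obs, bin_width = 20, n_boot = 200, seed = 34)
  expect_true(all(bp0$mean_bias == 0))
  expect_error(binned_bias(numeric(0), numeric(0)), "non-empty")
  expect_error(binned_bias(1, 1, bin_width = 0), "bin_width")
  pdf(NULL); on.exit(dev.off())
  expect_no_error(plot(bp))
})

test_that("an informative EH survives permutation-control comparison", {
  gain <- vapply(1:5, function(s) {
    d <- simulate_proxy_observations(seed = 4000 + s, n = 150,
                                     beta_wrnd = 0, amp_em = 0, amp_eh = 12,
                                     noise_sd = 2)
    real <- fit_rf_cv(d, "eh", seed = s)$metrics$r2
    d$eh <- roadproxy:::.with_seed(s, sample(d$eh))
    perm <- fit_rf_cv(d, "eh", seed = s)$metrics$r2
    real - perm
  }, 0)
  expect_gte(mean(gain), 0.2)
})
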