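# Random-forest land-use regression of PM2.5 on road-traffic proxies with
# k-fold cross-validation, pooled out-of-fold metrics, binned mean-bias
# profiles and impurity-based feature importance.

#' Cross-validated random-forest land-use regression
#'
#' Shuffles the observations with the given seed, splits them into
#' `n_folds` near-equal folds, trains a random forest (bootstrap per tree,
#' `mtry` candidate predictors per split, mean-aggregated tree predictions)
#' on each training remainder and predicts the held-out fold. Metrics are
#' computed on the pooled out-of-fold predictions:
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)`,
#' `RMSE = sqrt(mean((yhat - y)^2))`, `MAE = mean(|yhat - y|)`,
#' `MBE = mean(yhat - y)`; per-fold metrics are retained as well. A final
#' forest trained on all observations backs [predict.rf_lur()].
#'
#' @param data data.frame containing the feature and target columns.
#' @param features Character vector of feature column names.
#' @param target Target column name (default `"pm25"`).
#' @param ntree Trees per forest (default 50).
#' @param mtry Candidate predictors per split; default
#'   `max(1, floor(sqrt(length(features))))`.
#' @param n_folds Cross-validation folds (default 3; must not exceed n).
#' @param seed Integer seed; identical data and spec give identical results.
#' @return An object of class `rf_lur`: list with `spec`, `metrics`
#'   (`r2`, `rmse`, `mae`, `mbe`), `per_fold`, `oof` (data.frame `observed`,
#'   `predicted`, `fold`), `importance` (normalised, combined models only),
#'   `forest` (full-data fit), `flags`.
#' @examples
#' d <- simulate_proxy_observations(seed = 1, n = 90)
#' fit <- fit_rf_cv(d, c("wrnd", "em", "eh"), seed = 1)
#' fit
#' @export
fit_rf_cv <- function(data, features, target = "pm25", ntree = 50,
                      mtry = NULL, n_folds = 3, seed = 1) {
  n <- nrow(data)
  if (n < n_folds) stop("need at least `n_folds` observations")
  if (n_folds < 2) stop("`n_folds` must be >= 2")
  if (!all(features %in% names(data))) stop("missing feature column(s)")
  X <- data[, features, drop = FALSE]
  if (anyNA(X)) stop("missing feature values; apply complete-case filtering upstream")
  y <- data[[target]]
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(features))))
  flags <- character(0)

  fold_id <- integer(n)
  .with_seed(seed, fold_id[sample.int(n)] <- rep(seq_len(n_folds), length.out = n))
  oof <- rep(NA_real_, n)
  per_fold <- vector("list", n_folds)
  imp_folds <- matrix(0, nrow = length(features), ncol = n_folds,
                      dimnames = list(features, NULL))
  for (f in seq_len(n_folds)) {
    tr <- fold_id != f
    fit <- .with_seed(seed + 7919L * f,
      randomForest::randomForest(x = X[tr, , drop = FALSE], y = y[tr],
                                 ntree = ntree, mtry = min(mtry, length(features))))
    oof[!tr] <- predict(fit, X[!tr, , drop = FALSE])
    imp_folds[, f] <- fit$importance[features, "IncNodePurity"]
    per_fold[[f]] <- .reg_metrics(oof[!tr], y[!tr])
  }
  metrics <- .reg_metrics(oof, y)
  if (stats::var(y) == 0) {
    metrics$r2 <- NA_real_
    flags <- c(flags, "constant-target")
  }
  importance <- NULL
  if (length(features) >= 2) {
    im <- rowMeans(imp_folds)
    importance <- if (sum(im) > 0) im / sum(im) else rep(1 / length(im), length(im))
  }
  final <- .with_seed(seed,
    randomForest::randomForest(x = X, y = y, ntree = ntree,
                               mtry = min(mtry, length(features))))
  structure(
    list(spec = list(features = features, target = target, ntree = ntree,
                     mtry = min(mtry, length(features)), n_folds = n_folds,
                     seed = seed, n = n),
         metrics = metrics,
         per_fold = do.call(rbind, lapply(seq_len(n_folds), function(f)
           cbind(data.frame(fold = f), as.data.frame(per_fold[[f]])))),
         oof = data.frame(observed = y, predicted = oof, fold = fold_id),
         importance = importance, forest = final, flags = flags),
    class = "rf_lur"
  )
}

#' @keywords internal
.reg_metrics <- function(pred, obs) {
  sst <- sum((obs - mean(obs))^2)
  list(
    r2 = if (sst > 0) 1 - sum((obs - pred)^2) / sst else NA_real_,
    rmse = sqrt(mean((pred - obs)^2)),
    mae = mean(abs(pred - obs)),
    mbe = mean(pred - obs)
  )
}

#' @export
print.rf_lur <- function(x, ...) {
  cat(sprintf("Random-forest LUR (%d-fold CV): %s ~ %s\n",
              x$spec$n_folds, x$spec$target,
              paste(x$spec$features, collapse = " + ")))
  cat(sprintf("  n = %d, ntree = %d, mtry = %d, seed = %d\n",
              x$spec$n, x$spec$ntree, x$spec$mtry, x$spec$seed))
  with(x$metrics, cat(sprintf(
    "  out-of-fold: R2 = %.3f, RMSE = %.2f, MAE = %.2f, MBE = %+.2f ug/m3\n",
    r2, rmse, mae, mbe)))
  invisible(x)
}

#' @export
summary.rf_lur <- function(object, ...) {
  print(object)
  cat("\nPer-fold metrics:\n")
  print(object$per_fold, row.names = FALSE, digits = 3)
  if (!is.null(object$importance)) {
    cat("\nFeature importance (normalised impurity decrease):\n")
    print(round(object$importance, 3))
  }
  invisible(object)
}

#' Predict from the full-data forest of a cross-validated fit
#'
#' @param object An `rf_lur`.
#' @param newdata data.frame with the feature columns; omitted, returns the
#'   out-of-fold predictions (honest in-sample predictions).
#' @param ... Unused.
#' @export
predict.rf_lur <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$oof$predicted)
  predict(object$forest, newdata[, object$spec$features, drop = FALSE])
}

#' @export
residuals.rf_lur <- function(object, ...) {
  object$oof$observed - object$oof$predicted
}

#' Observed-versus-predicted plot for a cross-validated fit
#'
#' @param x An `rf_lur`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rf_lur <- function(x, ...) {
  graphics::plot(x$oof$observed, x$oof$predicted,
                 xlab = expression(paste("observed PM"[2.5], " (", mu, "g/", m^3, ")")),
                 ylab = expression(paste("predicted PM"[2.5], " (", mu, "g/", m^3, ")")),
                 main = sprintf("%s (R2 = %.2f, RMSE = %.1f)",
                                paste(x$spec$features, collapse = "+"),
                                x$metrics$r2, x$metrics$rmse), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Feature importance of a combined model
#'
#' Impurity-decrease importances averaged over the cross-validation folds
#' and normalised to sum to one. Defined for combined models only
#' (>= 2 features).
#'
#' @param fit An `rf_lur`.
#' @return Named numeric vector of proportions.
#' @export
feature_importance <- function(fit) {
  if (is.null(fit$importance))
    stop("feature importance is defined for combined models (>= 2 features) only")
  fit$importance
}

#' Fit the four-model suite per stratum and globally
#'
#' For each stratum and for the pooled data (`"global"`), fits the three
#' single-proxy models (WRND, EM, EH) and the combined model, mirroring the
#' standard reporting layout. Observations with missing values in a model's
#' features are dropped for that model (complete-case).
#'
#' @param data Observation table with proxy columns, target and optionally
#'   a stratum column.
#' @param stratum_col Stratum column name, or `NULL` for global only.
#' @param feature_sets Named list of feature vectors; default
#'   `list(WRND = "wrnd", EM = "em", EH = "eh",
#'   Combined = c("wrnd", "em", "eh"))`.
#' @param target,ntree,n_folds,seed Passed to [fit_rf_cv()].
#' @return list with `metrics` (data.frame: stratum, model, n, r2, rmse,
#'   mae, mbe) and `fits` (named list of `rf_lur` objects,
#'   `"<stratum>/<model>"`).
#' @export
run_model_suite <- function(data, stratum_col = NULL,
                            feature_sets = list(WRND = "wrnd", EM = "em",
                                                EH = "eh",
                                                Combined = c("wrnd", "em", "eh")),
                            target = "pm25", ntree = 50, n_folds = 3, seed = 1) {
  strata <- if (is.null(stratum_col)) character(0)
            else sort(unique(data[[stratum_col]]))
  fits <- list()
  rows <- list()
  for (s in c(strata, "global")) {
    tab <- if (s == "global") data
           else data[data[[stratum_col]] == s, , drop = FALSE]
    for (mn in names(feature_sets)) {
      fs <- feature_sets[[mn]]
      ok <- stats::complete.cases(tab[, c(fs, target), drop = FALSE])
      sub <- tab[ok, , drop = FALSE]
      fit <- fit_rf_cv(sub, fs, target = target, ntree = ntree,
                       n_folds = n_folds, seed = seed)
      fits[[paste(s, mn, sep = "/")]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, model = mn, n = nrow(sub),
        r2 = fit$metrics$r2, rmse = fit$metrics$rmse,
        mae = fit$metrics$mae, mbe = fit$metrics$mbe)
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(metrics = metrics, fits = fits)
}

#' Binned mean-bias-error profile
#'
#' Bins observations by observed PM2.5 (default 20 ug/m3 bins from 0) and
#' reports the per-bin mean and median of the bias (predicted - observed)
#' with a nonparametric bootstrap 95% confidence interval for the mean
#' bias. Bins with fewer than 3 observations are flagged.
#'
#' @param predictions,targets Aligned numeric vectors (ug/m3).
#' @param bin_width Bin width, ug/m3 (> 0).
#' @param n_boot Bootstrap resamples for the CI (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `rp_bias_profile`: data.frame with `bin_low`,
#'   `bin_high`, `n`, `mean_bias`, `median_bias`, `ci95_low`, `ci95_high`,
#'   `flag`.
#' @export
binned_bias <- function(predictions, targets, bin_width = 20,
                        n_boot = 1000, seed = 1) {
  if (length(predictions) == 0 || length(predictions) != length(targets))
    stop("`predictions` and `targets` must be non-empty and aligned")
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  bias <- predictions - targets
  bin <- floor(targets / bin_width)
  bins <- sort(unique(bin))
  out <- .with_seed(seed, {
    rows <- lapply(bins, function(b) {
      v <- bias[bin == b]
      ci <- if (length(v) >= 2) {
        bm <- vapply(seq_len(n_boot), function(i)
          mean(v[sample.int(length(v), replace = TRUE)]), 0)
        stats::quantile(bm, c(0.025, 0.975), names = FALSE)
      } else c(NA_real_, NA_real_)
      data.frame(bin_low = b * bin_width, bin_high = (b + 1) * bin_width,
                 n = length(v), mean_bias = mean(v), median_bias = stats::median(v),
                 ci95_low = ci[1], ci95_high = ci[2],
                 flag = if (length(v) < 3) "sparse-bin" else "")
    })
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  class(out) <- c("rp_bias_profile", "data.frame")
  out
}

#' @export
plot.rp_bias_profile <- function(x, ...) {
  mid <- (x$bin_low + x$bin_high) / 2
  ylim <- range(c(x$ci95_low, x$ci95_high, x$mean_bias, x$median_bias, 0),
                na.rm = TRUE)
  graphics::plot(mid, x$mean_bias, type = "n", ylim = ylim,
                 xlab = expression(paste("observed PM"[2.5], " bin (", mu, "g/", m^3, ")")),
                 ylab = expression(paste("bias (", mu, "g/", m^3, ")")), ...)
  ok <- !is.na(x$ci95_low)
  if (any(ok))
    graphics::polygon(c(mid[ok], rev(mid[ok])),
                      c(x$ci95_low[ok], rev(x$ci95_high[ok])),
                      col = grDevices::grey(0.85), border = NA)
  graphics::lines(mid, x$mean_bias, col = "black", lwd = 2)
  graphics::lines(mid, x$median_bias, col = "red", lwd = 2)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
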