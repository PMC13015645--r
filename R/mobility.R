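# Indoor/outdoor classification of minute-resolution monitor traces:
# displacement-speed threshold, building-footprint validation, and
# confusion-matrix reconciliation with the building label as ground truth.

#' Per-reading displacement speeds for one participant trace
#'
#' Speed at reading i is the Euclidean displacement from reading i-1
#' divided by the elapsed minutes; the first reading carries back the speed
#' of the second. Speeds across time gaps longer than `gap_cutoff` minutes
#' are set to `NA` (a long gap says nothing about instantaneous movement).
#'
#' @param trace data.frame for a single participant, sorted by `t`, with
#'   columns `t` (minutes), `x`, `y` (m).
#' @param gap_cutoff Maximum gap (minutes) across which a speed is computed.
#' @return Numeric vector of speeds (m/min), `NA` where undefined.
#' @export
compute_speeds <- function(trace, gap_cutoff = 5) {
  n <- nrow(trace)
  if (n < 2) {
    warning("trace has fewer than 2 readings; all speeds missing")
    return(rep(NA_real_, n))
  }
  if (is.unsorted(trace$t, strictly = TRUE))
    stop("trace timestamps must be strictly increasing")
  dt <- diff(trace$t)
  d <- sqrt(diff(trace$x)^2 + diff(trace$y)^2)
  sp <- d / dt
  sp[dt > gap_cutoff] <- NA_real_
  c(sp[1], sp)
}

#' Speed-threshold outdoor labels
#'
#' Labels a reading `"outdoor"` when its displacement speed is at or above
#' the threshold (default 100 m/min, the sustained outdoor-movement
#' threshold; the boundary is inclusive). Missing speeds are labelled
#' `"not-outdoor"`: a conservative default that avoids classifying gaps and
#' stationary periods as outdoor movement.
#'
#' @param speeds Numeric speeds in m/min (may contain `NA`).
#' @param threshold Speed threshold in m/min (> 0).
#' @return Character vector, `"outdoor"` / `"not-outdoor"`.
#' @export
classify_by_speed <- function(speeds, threshold = 100) {
  if (threshold <= 0) stop("`threshold` must be > 0")
  ifelse(!is.na(speeds) & speeds >= threshold, "outdoor", "not-outdoor")
}

#' Building-footprint labels by point-in-polygon
#'
#' Labels each position `"indoor"` if it lies inside or on the boundary of
#' any building polygon, `"outdoor"` if inside none but within the
#' building-data coverage region, and `"uncovered"` outside the coverage
#' region. Coverage keeps "no building here" distinct from "no building
#' data here".
#'
#' @param x,y Numeric position vectors (m).
#' @param buildings List of building polygons (two-column vertex matrices).
#' @param coverage Coverage region: either a length-4 extent rectangle
#'   `c(xmin, ymin, xmax, ymax)` or a polygon matrix. `NULL` means full
#'   coverage.
#' @return Character vector of labels.
#' @export
classify_by_buildings <- function(x, y, buildings, coverage = NULL) {
  stopifnot(length(x) == length(y))
  for (i in seq_along(buildings)) {
    b <- buildings[[i]]
    if (nrow(b) < 3 || .polygon_area(b) <= 0)
      stop("invalid building polygon at index ", i)
  }
  indoor <- rep(FALSE, length(x))
  for (b in buildings) {
    bb <- c(min(b[, 1]), min(b[, 2]), max(b[, 1]), max(b[, 2]))
    cand <- which(!indoor & x >= bb[1] - 1e-9 & x <= bb[3] + 1e-9 &
                    y >= bb[2] - 1e-9 & y <= bb[4] + 1e-9)
    if (length(cand))
      indoor[cand] <- .point_in_polygon(x[cand], y[cand], b)
  }
  covered <- if (is.null(coverage)) {
    rep(TRUE, length(x))
  } else if (is.matrix(coverage) || is.data.frame(coverage)) {
    .point_in_polygon(x, y, as.matrix(coverage))
  } else {
    x >= coverage[1] & x <= coverage[3] & y >= coverage[2] & y <= coverage[4]
  }
  ifelse(!covered, "uncovered", ifelse(indoor, "indoor", "outdoor"))
}

#' Reconcile speed and building labels
#'
#' Where building data covers a reading, the building-derived label is
#' treated as ground truth and becomes the final label; uncovered readings
#' keep their speed-based label (outdoor, or indoor for "not-outdoor"). The
#' confusion matrix of the speed labels against the building labels is
#' computed over covered readings *before* correction: outdoor is the
#' positive class, so sensitivity is the fraction of building-outdoor
#' readings the speed rule recovers.
#'
#' @param speed_labels Character vector from [classify_by_speed()].
#' @param building_labels Character vector from [classify_by_buildings()].
#' @return A list with `final_labels` ("indoor"/"outdoor") and `confusion`
#'   (class `rp_confusion`: counts `true_outdoor`, `false_outdoor`,
#'   `true_not_outdoor`, `false_not_outdoor`, plus `accuracy`,
#'   `sensitivity`, `specificity`, `n_covered`).
#' @export
reconcile_labels <- function(speed_labels, building_labels) {
  if (length(speed_labels) != length(building_labels))
    stop("label vectors must have equal length")
  covered <- building_labels != "uncovered"
  sp_out <- speed_labels == "outdoor"
  bl_out <- building_labels == "outdoor"
  tp <- sum(covered & sp_out & bl_out)
  fp <- sum(covered & sp_out & !bl_out)
  fn <- sum(covered & !sp_out & bl_out)
  tn <- sum(covered & !sp_out & !bl_out)
  nc <- sum(covered)
  confusion <- structure(
    list(true_outdoor = tp, false_outdoor = fp,
         false_not_outdoor = fn, true_not_outdoor = tn,
         n_covered = nc,
         accuracy = if (nc > 0) (tp + tn) / nc else NA_real_,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
    class = "rp_confusion"
  )
  final <- ifelse(covered,
                  ifelse(bl_out, "outdoor", "indoor"),
                  ifelse(sp_out, "outdoor", "indoor"))
  list(final_labels = final, confusion = confusion)
}

#' @export
print.rp_confusion <- function(x, ...) {
  cat("Speed-vs-building confusion matrix (covered readings, pre-correction)\n")
  m <- matrix(c(x$true_outdoor, x$false_outdoor, x$false_not_outdoor, x$true_not_outdoor),
              2, 2, byrow = TRUE,
              dimnames = list(speed = c("outdoor", "not-outdoor"),
                              building = c("outdoor", "indoor")))
  print(m)
  cat(sprintf("accuracy %.3f, sensitivity %.3f, specificity %.3f (n = %d)\n",
              x$accuracy, x$sensitivity, x$specificity, x$n_covered))
  invisible(x)
}

#' Classify a multi-participant trace table
#'
#' Runs the full classification chain — per-participant displacement
#' speeds, speed-threshold labels, building point-in-polygon labels, and
#' reconciliation — over a trace table as produced by [simulate_traces()]
#' or read from CSV.
#'
#' @param traces data.frame with `participant_id`, `t`, `x`, `y` (and any
#'   other columns, carried through).
#' @param buildings List of building polygons.
#' @param coverage Building-data coverage region (see
#'   [classify_by_buildings()]); defaults to full coverage.
#' @param threshold Speed threshold, m/min.
#' @param gap_cutoff Speed gap cutoff, minutes.
#' @return A list: `classified` (the input with `speed`, `speed_label`,
#'   `building_label`, `final_label` columns appended) and `confusion`.
#' @export
classify_readings <- function(traces, buildings, coverage = NULL,
                              threshold = 100, gap_cutoff = 5) {
  ord <- order(match(traces$participant_id, unique(traces$participant_id)), traces$t)
  traces <- traces[ord, , drop = FALSE]
  sp <- unlist(lapply(split(traces, factor(traces$participant_id,
                                           levels = unique(traces$participant_id))),
                      compute_speeds, gap_cutoff = gap_cutoff),
               use.names = FALSE)
  traces$speed <- sp
  traces$speed_label <- classify_by_speed(sp, threshold)
  traces$building_label <- classify_by_buildings(traces$x, traces$y, buildings, coverage)
  rec <- reconcile_labels(traces$speed_label, traces$building_label)
  traces$final_label <- rec$final_labels
  rownames(traces) <- NULL
  list(classified = traces, confusion = rec$confusion)
}

#' Restrict a classified table to outdoor readings
#'
#' @param classified data.frame with a `final_label` column.
#' @return The rows with `final_label == "outdoor"`, order preserved. An
#'   empty result triggers a warning, not an error.
#' @export
filter_outdoor <- function(classified) {
  out <- classified[classified$final_label == "outdoor", , drop = FALSE]
  if (nrow(out) == 0) warning("no readings classified outdoor")
  rownames(out) <- NULL
  out
}
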