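# Hexagonal tessellation: build a gap-free grid of regular hexagons,
# aggregate village-level exposure and proxies to hexagons by centroid
# containment, and assign the bivariate display classes.

#' Regular hexagonal grid covering an extent
#'
#' Flat-top regular hexagons with flat-to-flat width `width` (default
#' 5000 m), on the standard hexagonal lattice (column spacing 1.5 R, row
#' spacing `width`, odd columns offset by half a row), tiling the plane with
#' no gaps or overlaps. Every hexagon whose polygon can intersect the extent
#' is returned; ids are assigned row-major (south to north, west to east)
#' and are deterministic for a given extent and width.
#'
#' @param extent Numeric `c(xmin, ymin, xmax, ymax)` (m), positive area.
#' @param width Flat-to-flat hexagon width (m).
#' @return data.frame with `hex_id`, `cx`, `cy` and attribute `circumradius`;
#'   use [hex_vertices()] for the polygon of a hexagon.
#' @export
make_hex_grid <- function(extent, width = 5000) {
  if (extent[3] <= extent[1] || extent[4] <= extent[2])
    stop("`extent` must have positive area")
  if (width <= 0) stop("`width` must be > 0")
  R <- width / sqrt(3)   # circumradius: flat-to-flat = sqrt(3) * R
  dx <- 1.5 * R
  dy <- width
  ci <- seq(floor((extent[1] - R) / dx), ceiling((extent[3] + R) / dx))
  out <- list()
  for (cc in ci) {
    off <- if (cc %% 2 == 0) 0 else dy / 2
    ri <- seq(floor((extent[2] - off - dy / 2) / dy),
              ceiling((extent[4] - off + dy / 2) / dy))
    for (r in ri) {
      out[[length(out) + 1L]] <- c(r, cc, cc * dx, r * dy + off)
    }
  }
  m <- do.call(rbind, out)
  ord <- order(m[, 4], m[, 3])  # row-major: south->north then west->east
  m <- m[ord, , drop = FALSE]
  hex <- data.frame(
    hex_id = sprintf("hex_%04d", seq_len(nrow(m))),
    cx = m[, 3], cy = m[, 4]
  )
  attr(hex, "circumradius") <- R
  attr(hex, "width") <- width
  hex
}

#' Vertices of one flat-top hexagon
#'
#' @param cx,cy Hexagon centre (m).
#' @param R Circumradius (m); for a grid from [make_hex_grid()] this is its
#'   `circumradius` attribute.
#' @return 6 x 2 vertex matrix.
#' @export
hex_vertices <- function(cx, cy, R) {
  ang <- (0:5) * pi / 3
  cbind(x = cx + R * cos(ang), y = cy + R * sin(ang))
}

# Index of the hexagon containing each point; boundary ties resolve to the
# lowest hex_id (grid rows are already id-ordered, so first match wins).
#' @keywords internal
.hex_assign <- function(px, py, hexes) {
  R <- attr(hexes, "circumradius")
  idx <- rep(NA_integer_, length(px))
  for (h in seq_len(nrow(hexes))) {
    cand <- which(is.na(idx) & abs(px - hexes$cx[h]) <= R + 1e-9 &
                    abs(py - hexes$cy[h]) <= R + 1e-9)
    if (length(cand)) {
      inside <- .point_in_polygon(px[cand], py[cand],
                                  hex_vertices(hexes$cx[h], hexes$cy[h], R))
      idx[cand[inside]] <- h
    }
  }
  idx
}

#' Aggregate village records onto a hexagonal grid
#'
#' Assigns each village to the single hexagon containing its centroid
#' (boundary ties go to the lowest hexagon id) and computes per-hexagon
#' arithmetic means of PM2.5 and each proxy. Hexagons containing no village
#' are omitted.
#'
#' @param hexes Grid from [make_hex_grid()].
#' @param village_records data.frame with `village_id`, `x`, `y` (centroid,
#'   m), `pm25`, `wrnd`, `em`, `eh` (proxy columns may contain `NA`;
#'   per-hexagon means are over non-missing values).
#' @return data.frame: `hex_id`, `cx`, `cy`, `n_villages`, `mean_pm25`,
#'   `mean_wrnd`, `mean_em`, `mean_eh`; `circumradius` attribute retained.
#' @export
aggregate_to_hex <- function(hexes, village_records) {
  idx <- .hex_assign(village_records$x, village_records$y, hexes)
  if (anyNA(idx))
    stop("village centroid(s) outside the hexagonal grid: ",
         paste(village_records$village_id[is.na(idx)], collapse = ", "))
  g <- split(seq_len(nrow(village_records)), idx)
  rows <- lapply(names(g), function(k) {
    i <- g[[k]]; h <- as.integer(k)
    data.frame(
      hex_id = hexes$hex_id[h], cx = hexes$cx[h], cy = hexes$cy[h],
      n_villages = length(i),
      mean_pm25 = mean(village_records$pm25[i]),
      mean_wrnd = mean(village_records$wrnd[i], na.rm = TRUE),
      mean_em = mean(village_records$em[i], na.rm = TRUE),
      mean_eh = mean(village_records$eh[i], na.rm = TRUE)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$hex_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "circumradius") <- attr(hexes, "circumradius")
  out
}

# Left-closed right-open quantile classes; the last class is closed above.
# All-identical values collapse to class 1.
#' @keywords internal
.quantile_class <- function(v, k) {
  qs <- stats::quantile(v, probs = seq_len(k - 1) / k, na.rm = TRUE, names = FALSE)
  qs <- unique(qs[qs > min(v, na.rm = TRUE)])  # degenerate ties stay class 1
  cls <- rep(1L, length(v))
  for (q in qs) cls <- cls + as.integer(v >= q & !is.na(v))
  cls[is.na(v)] <- NA_integer_
  cls
}

#' Assign bivariate display classes to hexagon aggregates
#'
#' WRND uses the fixed breakpoints 10 and 20 (classes `"0-10"`, `"10-20"`,
#' `">20"`); EM uses 2 and 4 km (`"0-2"`, `"2-4"`, `">4"`); both intervals
#' are left-closed, right-open. EH has no published scheme and uses
#' data-driven terciles of the observed means (index 1-3); PM2.5 uses
#' quintiles (index 1-5, the sequential colour gradient realised as class
#' codes).
#'
#' @param aggregates data.frame from [aggregate_to_hex()].
#' @return `aggregates` with `wrnd_class`, `em_class`, `eh_class`,
#'   `pm25_class` appended.
#' @export
assign_classes <- function(aggregates) {
  if (nrow(aggregates) == 0) stop("no aggregates to classify")
  brk <- function(v, b1, b2, labels) {
    out <- ifelse(v < b1, labels[1], ifelse(v < b2, labels[2], labels[3]))
    out[is.na(v)] <- NA_character_
    out
  }
  aggregates$wrnd_class <- brk(aggregates$mean_wrnd, 10, 20, c("0-10", "10-20", ">20"))
  aggregates$em_class <- brk(aggregates$mean_em, 2, 4, c("0-2", "2-4", ">4"))
  aggregates$eh_class <- .quantile_class(aggregates$mean_eh, 3)
  aggregates$pm25_class <- .quantile_class(aggregates$mean_pm25, 5)
  aggregates
}
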