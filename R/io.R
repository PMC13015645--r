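# Plain-text readers and writers: trace CSV, landscape GeoJSON, population
# grid as Esri ASCII raster.

#' Write monitor traces to CSV
#'
#' Columns: `participant_id`, `timestamp_min`, `x_m`, `y_m`, `pm25_ugm3`,
#' `rh_pct`, `temp_c`, `truth_env` (plus `village_id` when present).
#'
#' @param traces data.frame from [simulate_traces()].
#' @param path Output file path.
#' @export
write_traces_csv <- function(traces, path) {
  out <- data.frame(
    participant_id = traces$participant_id, timestamp_min = traces$t,
    x_m = traces$x, y_m = traces$y, pm25_ugm3 = traces$pm25,
    rh_pct = traces$rh, temp_c = traces$temp, truth_env = traces$truth_env
  )
  if (!is.null(traces$village_id)) out$village_id <- traces$village_id
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read monitor traces from CSV
#'
#' @param path CSV written by [write_traces_csv()].
#' @return data.frame in the internal column layout (`participant_id`, `t`,
#'   `x`, `y`, `pm25`, `rh`, `temp`, `truth_env`, optionally `village_id`).
#' @export
read_traces_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(
    participant_id = d$participant_id, t = d$timestamp_min,
    x = d$x_m, y = d$y_m, pm25 = d$pm25_ugm3, rh = d$rh_pct,
    temp = d$temp_c, truth_env = d$truth_env
  )
  if (!is.null(d$village_id)) out$village_id <- d$village_id
  out
}

#' @keywords internal
.geojson_feature <- function(geometry, properties) {
  list(type = "Feature", properties = properties, geometry = geometry)
}

#' Write landscape vector layers as GeoJSON
#'
#' Writes `roads.geojson` (LineString per road, `class` property),
#' `villages.geojson` (boundary Polygon per village with the centroid in
#' properties) and `buildings.geojson` (Polygon per building) into a
#' directory. Coordinates are in the landscape's metric planar frame.
#'
#' @param landscape An `rp_landscape`.
#' @param dir Output directory (created if needed).
#' @export
write_landscape_geojson <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fc <- function(features) list(type = "FeatureCollection", features = features)
  wj <- function(x, f) jsonlite::write_json(x, file.path(dir, f),
                                            auto_unbox = TRUE, digits = NA)
  roads <- lapply(split(landscape$roads, landscape$roads$road_id), function(r)
    .geojson_feature(
      list(type = "LineString", coordinates = unname(lapply(seq_len(nrow(r)),
           function(i) c(r$x[i], r$y[i])))),
      list(road_id = r$road_id[1], class = r$class[1])))
  wj(fc(unname(roads)), "roads.geojson")
  vill <- lapply(landscape$villages, function(v)
    .geojson_feature(
      list(type = "Polygon", coordinates = list(unname(lapply(
        c(seq_len(nrow(v$boundary)), 1L),
        function(i) c(v$boundary[i, 1], v$boundary[i, 2]))))),
      list(village_id = v$id, centroid_x = v$centroid[[1]],
           centroid_y = v$centroid[[2]])))
  wj(fc(unname(vill)), "villages.geojson")
  bld <- lapply(landscape$buildings, function(b)
    .geojson_feature(
      list(type = "Polygon", coordinates = list(unname(lapply(
        c(seq_len(nrow(b)), 1L), function(i) c(b[i, 1], b[i, 2]))))),
      list(village_id = attr(b, "village_id"))))
  wj(fc(unname(bld)), "buildings.geojson")
  invisible(dir)
}

#' Write a population grid as an Esri ASCII raster
#'
#' Single-band plain-text grid (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value` header followed by rows north to south).
#'
#' @param grid An `rp_popgrid`.
#' @param path Output file path (conventionally `.asc`).
#' @export
write_popgrid_asc <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    "NODATA_value -9999"
  ), con)
  for (r in rev(seq_len(grid$nrows)))  # ASCII grids run north to south
    writeLines(paste(format(grid$counts[r, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  invisible(path)
}

#' Read an Esri ASCII population raster
#'
#' @param path File written by [write_popgrid_asc()] (or any conforming
#'   ASCII grid).
#' @return An `rp_popgrid`.
#' @export
read_popgrid_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  structure(
    list(origin = c(x = hdr$xllcorner, y = hdr$yllcorner),
         cell_size = hdr$cellsize, ncols = as.integer(hdr$ncols),
         nrows = as.integer(hdr$nrows),
         counts = m[rev(seq_len(nrow(m))), , drop = FALSE]),
    class = "rp_popgrid"
  )
}

#' Write hexagon aggregates as GeoJSON
#'
#' @param aggregates data.frame from [aggregate_to_hex()] (the
#'   `circumradius` attribute supplies the hexagon polygons).
#' @param path Output file path.
#' @export
write_hex_geojson <- function(aggregates, path) {
  R <- attr(aggregates, "circumradius")
  feats <- lapply(seq_len(nrow(aggregates)), function(i) {
    v <- hex_vertices(aggregates$cx[i], aggregates$cy[i], R)
    props <- as.list(aggregates[i, setdiff(names(aggregates), c("cx", "cy"))])
    .geojson_feature(
      list(type = "Polygon", coordinates = list(unname(lapply(
        c(seq_len(nrow(v)), 1L), function(k) c(v[k, 1], v[k, 2]))))),
      props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
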