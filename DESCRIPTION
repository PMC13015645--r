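Package: roadproxy
Title: Validation of Road-Traffic Proxies for Personal PM2.5 Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive and validate road-traffic proxy indicators of
    fine particulate matter (PM2.5) exposure in settings with sparse air
    quality monitoring. Implements population-weighted road network density
    (WRND) on a fishnet grid aligned to a gridded population raster,
    Euclidean distances from village centroids to the nearest main road (EM)
    and highway (EH), speed-threshold plus building-footprint classification
    of personal-monitor GPS traces into indoor and outdoor periods,
    aggregation of village-level exposure and proxies onto hexagonal
    tessellations, Spearman rank correlation of proxies against PM2.5, and
    random-forest land-use regression with k-fold cross-validation reporting
    R2, RMSE, MAE, mean bias error and feature importance. A synthetic-data
    module generates landscapes (classed roads, clustered population
    rasters, village polygons, building footprints) and minute-resolution
    personal-monitor traces with known ground truth, so the whole pipeline
    is testable without access to any cohort data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
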