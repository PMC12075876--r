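# End-to-end driver: synthetic region -> three indices -> exposure table ->
# urban classification -> stratified correlation report, with CSV/GeoJSON
# artifacts.

#' Index 2: co-kriged exposure surface summarised per tract
#'
#' Full Index 2 chain: natural-log transform of permitted head (primary
#' variable) and lagoon counts (secondary); empirical direct and cross
#' semivariograms on shared bins; LMC fit (nugget + spherical); co-kriged
#' surface over the tract envelope; per-tract zonal maximum ("worst-case"
#' summary); percent-of-total normalization.
#'
#' @param farms `farm_records`
#' @param tracts `tract_records`
#' @param cfg a [kriging_config()]; a NULL `lag_width` is resolved to
#'   envelope diagonal / (2 * n_lags)
#' @return list with `percent` (named vector summing to 100), `raw_max`
#'   (named vector of zonal maxima), `surface`, `model` (the fitted `lmc`),
#'   and `clouds`
#' @export
idx2_per_tract <- function(farms, tracts, cfg = kriging_config()) {
  stopifnot(inherits(cfg, "kriging_config"))
  if (nrow(farms) < 2L) stop("Index 2 needs at least 2 farms")
  coords <- cbind(farms$x, farms$y)
  dd <- .dedupe_coords(coords, log_transform_heads(farms), farms$lagoon_count)
  z1 <- dd$z1; z2 <- dd$z2
  if (is.null(cfg$lag_width)) {
    bbs <- vapply(tracts$geometry, .mp_bbox, numeric(4L))
    diag_len <- sqrt((max(bbs[3L, ]) - min(bbs[1L, ]))^2 +
                       (max(bbs[4L, ]) - min(bbs[2L, ]))^2)
    cfg$lag_width <- diag_len / (2 * cfg$n_lags)
  }
  clouds <- list(
    primary = empirical_semivariogram(dd$coords, z1, z1, cfg$n_lags, cfg$lag_width),
    secondary = empirical_semivariogram(dd$coords, z2, z2, cfg$n_lags, cfg$lag_width),
    cross = empirical_semivariogram(dd$coords, z1, z2, cfg$n_lags, cfg$lag_width))
  model <- fit_lmc(clouds)
  surface <- predict_surface(list(x = dd$coords[, 1L], y = dd$coords[, 2L]),
                             z1, z2, model, tracts, cfg)
  fallback <- function(s0)
    cokrige_point(s0, dd$coords, z1, z2, model,
                  neighborhood = cfg$neighborhood)$pred
  raw_max <- zonal_max(surface, tracts, fallback_predict = fallback)
  list(percent = percent_of_total(raw_max), raw_max = raw_max,
       surface = surface, model = model, clouds = clouds)
}

#' Assemble the per-tract exposure table
#'
#' Joins the three indices on `tract_id` and attaches geometric-interval
#' class labels (zero class 0, positive classes 1..k) per index.
#'
#' @param idx1 named vector from [idx1_per_tract()]
#' @param idx2_percent named vector from [idx2_per_tract()]
#' @param idx3 named vector from [idx3_per_tract()]
#' @param k_classes positive classes per index for the map legend
#' @return data.frame of class `exposure_table`
#' @export
build_exposure_table <- function(idx1, idx2_percent, idx3, k_classes = 5L) {
  ids <- sort(names(idx1))
  stopifnot(identical(ids, sort(names(idx2_percent))),
            identical(ids, sort(names(idx3))))
  tb <- data.frame(tract_id = ids,
                   idx1_count = as.numeric(idx1[ids]),
                   idx2_percent = as.numeric(idx2_percent[ids]),
                   idx3_density = as.numeric(idx3[ids]),
                   stringsAsFactors = FALSE)
  tb$idx1_class <- assign_classes(tb$idx1_count, geometric_breaks(tb$idx1_count, k_classes))
  tb$idx2_class <- assign_classes(tb$idx2_percent, geometric_breaks(tb$idx2_percent, k_classes))
  tb$idx3_class <- assign_classes(tb$idx3_density, geometric_breaks(tb$idx3_density, k_classes))
  class(tb) <- c("exposure_table", "data.frame")
  tb
}

#' Default end-to-end configuration
#'
#' The default synthetic scene for [run_all()]: a 10 x 10 grid of 4-mile
#' square tracts with a 20 percent urban block, 300 farms, 8,000 addresses,
#' calibrated vulnerability rankings, one-mile buffer, and a 1,000 m
#' co-kriging grid.
#'
#' @param seed global integer seed, expanded to per-stage seeds
#' @param n_farms,n_addresses scene size overrides
#' @return nested list of configuration objects
#' @export
default_config <- function(seed = 1L, n_farms = 300L, n_addresses = 8000L) {
  list(region = region_config(seed = seed),
       farms = farm_gen_config(n_farms = n_farms, seed = seed),
       addresses = address_gen_config(n_addresses = n_addresses, seed = seed),
       vulnerability = vuln_gen_config(seed = seed),
       buffer = buffer_config(),
       kriging = kriging_config())
}

.write_named_csv <- function(v, path, value_col) {
  df <- data.frame(tract_id = names(v), stringsAsFactors = FALSE)
  df[[value_col]] <- .fmt_num(as.numeric(v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full exposure pipeline
#'
#' Chains generation (region, farms, addresses, vulnerability), the three
#' indices, the exposure table with geometric classes, urban classification
#' by city-limit coverage, and the stratified Spearman correlation report.
#' When `out_dir` is given, writes the GeoJSON inputs, `idx1.csv`,
#' `idx2.csv`, `surface.csv`, `idx3.csv`, `exposure.csv`, `corr_all.csv`,
#' `corr_urban.csv`, `corr_rural.csv`, `classes.csv` and `run_log.txt`
#' (all fitted co-kriging parameters echoed for reproducibility).
#'
#' @param config list from [default_config()]
#' @param out_dir output directory (created), or NULL to skip artifacts
#' @return list with `tracts`, `farms`, `addresses`, `exposure`,
#'   `correlations`, `report`, `idx2` (surface/model detail), invisibly
#' @export
run_all <- function(config = default_config(), out_dir = NULL) {
  region <- generate_region(config$region)
  tracts <- region$tracts
  farms <- generate_farms(tracts, config$farms)
  addresses <- generate_addresses(tracts, config$addresses)
  tracts <- generate_vulnerability(tracts, config$vulnerability)

  idx1 <- idx1_per_tract(farms, addresses, tracts, config$buffer)
  i2 <- idx2_per_tract(farms, tracts, config$kriging)
  idx3 <- idx3_per_tract(farms, tracts)
  exposure <- build_exposure_table(idx1, i2$percent, idx3)

  tracts <- classify_urban(tracts, region$city)
  cm <- correlation_matrix(exposure, tracts)
  rep <- filter_report(cm)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(out_dir, f)
    write_farms_geojson(farms, fp("farms.geojson"))
    write_addresses_geojson(addresses, fp("addresses.geojson"))
    write_tracts_geojson(tracts, fp("tracts.geojson"))
    write_polygons_geojson(region$city, fp("city.geojson"))
    .write_named_csv(idx1, fp("idx1.csv"), "idx1_count")
    idx2df <- data.frame(tract_id = names(i2$percent),
                         idx2_raw_max = .fmt_num(as.numeric(i2$raw_max)),
                         idx2_percent = .fmt_num(as.numeric(i2$percent)),
                         stringsAsFactors = FALSE)
    utils::write.csv(idx2df, fp("idx2.csv"), row.names = FALSE, quote = FALSE)
    surf <- i2$surface
    sdf <- data.frame(x = rep(surf$x, times = length(surf$y)),
                      y = rep(surf$y, each = length(surf$x)),
                      prediction = as.numeric(surf$pred),
                      variance = as.numeric(surf$var))
    utils::write.csv(sdf, fp("surface.csv"), row.names = FALSE, quote = FALSE)
    .write_named_csv(idx3, fp("idx3.csv"), "idx3_density")
    write_exposure_table(exposure, fp("exposure.csv"))
    for (s in unique(cm$stratum)) {
      sub <- cm[cm$stratum == s, c("var_a", "var_b", "rho", "rho_rounded", "n_pairs")]
      utils::write.csv(sub, fp(paste0("corr_", s, ".csv")), row.names = FALSE,
                       quote = FALSE)
    }
    cls <- exposure[, c("tract_id", "idx1_class", "idx2_class", "idx3_class")]
    utils::write.csv(cls, fp("classes.csv"), row.names = FALSE, quote = FALSE)
    log <- c(
      sprintf("swinexpo run_all %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      sprintf("tracts: %d (%d urban)", nrow(tracts), sum(tracts$urban, na.rm = TRUE)),
      sprintf("farms: %d  addresses: %d", nrow(farms), nrow(addresses)),
      sprintf("buffer radius: %.6g m  assignment: %s",
              config$buffer$radius, config$buffer$assignment),
      "fitted coregionalization:",
      vapply(i2$model$structures, function(s)
        sprintf("  %s%s B=[%.8g %.8g; %.8g %.8g]", s$family,
                if (is.null(s$range)) "" else sprintf(" range=%.8g m", s$range),
                s$B[1, 1], s$B[1, 2], s$B[2, 1], s$B[2, 2]), ""),
      sprintf("kriging grid cell: %.6g m  n_lags: %d  lag_width: %.8g m",
              config$kriging$grid_cell, config$kriging$n_lags,
              attr(i2$clouds$primary, "lag_width")))
    writeLines(log, fp("run_log.txt"))
  }

  invisible(list(tracts = tracts, farms = farms, addresses = addresses,
                 exposure = exposure, correlations = cm, report = rep,
                 idx2 = i2, city = region$city))
}
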