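## Equal-depth bands of the vertical-offset ribbon have exactly equal area.
geometry_zone_areas_mm2 <- function(geometry) {
  rep(geometry$width * geometry$depth / 6 / 1e6, 6)
}

#' Build the zone sets of a ribbon geometry
#'
#' Constructs the column lines along the pia and white-matter boundaries
#' and the six radial zones of every column.
#'
#' @param geometry a \code{tissue_geometry}.
#' @param n_columns number of vertical columns.
#' @return list with \code{columns} (from \code{\link{build_columns}}) and
#'   \code{zone_sets} (one \code{zone_set} per column).
#' @export
zonate_geometry <- function(geometry, n_columns = 4) {
  pia <- boundary_polyline(geometry, "pia", 257)
  wm <- boundary_polyline(geometry, "wm", 257)
  cols <- build_columns(pia, wm, n_columns)
  zs <- lapply(cols, function(col)
    build_zones(zone_points(col$left), zone_points(col$right)))
  list(columns = cols, zone_sets = zs)
}

#' Assign centroids to zones across the columns of a zonated geometry
#'
#' Applies \code{\link{assign_zone}} column by column; the first matching
#' column wins (columns are disjoint up to shared lines, where the
#' pia-ward/lower-zone tie-break applies within a column).
#'
#' @param centroids data.frame with \code{x}, \code{y} (um).
#' @param zone_sets list of \code{zone_set} objects (one per column).
#' @return integer zone per centroid (1-6 or \code{NA}).
#' @export
assign_zone_multi <- function(centroids, zone_sets) {
  out <- rep(NA_integer_, nrow(as.data.frame(centroids)))
  for (zs in zone_sets) {
    todo <- which(is.na(out))
    if (!length(todo)) break
    out[todo] <- assign_zone(as.data.frame(centroids)[todo, , drop = FALSE],
                             zs)
  }
  out
}

detect_case <- function(cells_case, geometry, det, zone_sets) {
  img <- render_image(cells_case, geometry, seed = cells_case$render_seed[1])
  labels <- detect_nuclei(get_channel(img, "DAPI"), det)
  annuli <- expand_pseudoplasm(labels, det$expansion_distance)
  meas <- measure_cells(labels, annuli, img)
  thr <- det$positivity_thresholds
  thr53 <- if (!is.null(thr) && "53BP1" %in% names(thr)) thr[["53BP1"]]
  else valley_threshold(meas[["nuclear_mean_53BP1"]])
  meas <- classify_positive(meas, "53BP1", thr53)
  meas$zone <- assign_zone_multi(meas[, c("x", "y")], zone_sets)
  meas$case_id <- cells_case$case_id[1]
  meas$condition <- cells_case$condition[1]
  meas
}

#' Run the full analysis pipeline
#'
#' Simulate, (optionally) render and detect, zonate, quantify and analyze a
#' synthetic cohort end to end, writing intermediate artifacts and a report
#' to the configured output directory. With \code{truth_bypass} the
#' statistics run directly on the ground-truth tables (no imaging), which
#' is the fast path for cohort-level statistics; otherwise each case is
#' rendered and re-detected from its images.
#'
#' @param config a \code{pipeline_config}.
#' @return an object of class \code{run_manifest}; the analysis results are
#'   attached as attribute \code{"results"} and written to
#'   \code{config$output_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage %s failed: %s", sQuote(name),
                   conditionMessage(e)), call. = FALSE))
  }
  ## simulate ----------------------------------------------------------------
  all_cells <- stage("simulate", {
    tabs <- lapply(seq_along(config$generator), function(i) {
      g <- config$generator[[i]]
      cells <- simulate_tissue(config$geometry, g,
                               seed = config$seed + g$seed + i)
      cells$render_seed <- config$seed + 1000L + i
      cells
    })
    do.call(rbind, tabs)
  })
  truth_path <- file.path(config$output_dir, "truth_cells.csv")
  utils::write.csv(all_cells, truth_path, row.names = FALSE)
  stages$simulate <- truth_path
  ## zonate ------------------------------------------------------------------
  zon <- stage("zonate", zonate_geometry(config$geometry,
                                         config$zonation$n_columns))
  zone_paths <- character(0)
  for (i in seq_along(zon$zone_sets)) {
    p <- file.path(config$output_dir, sprintf("zones_column%d.geojson", i))
    write_zones_geojson(zon$zone_sets[[i]], p)
    zone_paths <- c(zone_paths, p)
  }
  stages$zonate <- zone_paths
  areas <- geometry_zone_areas_mm2(config$geometry)
  ## detect / quantify -------------------------------------------------------
  if (config$truth_bypass) {
    cells <- all_cells
    cells$zone <- cells$zone_true
    cells$positive_53BP1 <- cells$damage_positive
    cells$nuclear_mean_p16 <- cells$p16_nuclear
    cells$annulus_mean_p16 <- cells$p16_cytoplasmic
  } else {
    cells <- stage("detect", {
      per_case <- split(all_cells, all_cells$case_id)
      meas <- lapply(per_case, detect_case, geometry = config$geometry,
                     det = config$detection, zone_sets = zon$zone_sets)
      do.call(rbind, meas)
    })
  }
  det_path <- file.path(config$output_dir, "detections.csv")
  write_detections(cells, det_path)
  stages$quantify <- det_path
  ## analyze -----------------------------------------------------------------
  results <- stage("analyze", {
    zs <- zone_summary(cells, areas_mm2 = areas)
    res <- list(zone_summary = zs)
    resp <- config$analysis$response
    res$fits <- lapply(split(zs, zs$condition), function(d) {
      lin <- fit_linear(d$zone, d[[resp]])
      quad <- fit_quadratic(d$zone, d[[resp]])
      list(linear = lin, quadratic = quad,
           comparison = compare_models(lin, quad))
    })
    if (length(unique(zs$condition)) >= 2)
      res$anova <- two_way_anova(zs, response = resp)
    x53 <- if ("i53bp1" %in% names(cells)) "i53bp1" else "nuclear_mean_53BP1"
    y16 <- if ("p16_nuclear" %in% names(cells)) "p16_nuclear"
    else "nuclear_mean_p16"
    res$coupling <- lapply(split(cells, cells$condition), function(d)
      coupling_regression(d, per_case_n = config$analysis$per_case_n,
                          seed = config$analysis$coupling_seed,
                          x_col = x53, y_col = y16))
    res$subset_profiles <- list(
      positive_nuclear = subset_intensity_profiles(cells, "positive",
                                                   "nuclear"),
      positive_cytoplasmic = subset_intensity_profiles(cells, "positive",
                                                       "cytoplasmic"),
      negative_nuclear = subset_intensity_profiles(cells, "negative",
                                                   "nuclear"))
    res
  })
  if (!is.null(config$culture)) {
    results$culture <- stage("culture", {
      cc <- config$culture
      cult <- simulate_culture(cc, seed = config$seed + cc$seed)
      p <- file.path(config$output_dir, "culture_cells.csv")
      utils::write.csv(cult, p, row.names = FALSE)
      stages$culture <- p
      culture_fractions(cult)
    })
  }
  ## report ------------------------------------------------------------------
  report_path <- stage("report", write_report(results, config$output_dir))
  stages$report <- report_path
  manifest <- structure(
    list(config_hash = config_hash(config),
         package_version = as.character(utils::packageVersion("cortexlam")),
         seed = config$seed, stages = stages,
         started = t_start,
         finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "results") <- results
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest\n")
  cat(sprintf("  config hash : %s (seed %d)\n", x$config_hash, x$seed))
  cat(sprintf("  package     : cortexlam %s\n", x$package_version))
  cat(sprintf("  stages      : %s\n", paste(names(x$stages), collapse = ", ")))
  invisible(x)
}
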