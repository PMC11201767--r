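## QuPath-dialect detection tables ------------------------------------------

qp_um <- "\u00b5m"

qp_fixed_cols <- function() {
  c(image = "Image",
    x = paste("Centroid X", qp_um),
    y = paste("Centroid Y", qp_um),
    nuclear_area = paste0("Nucleus: Area ", qp_um, "^2"))
}

#' Write a detection table in the QuPath export dialect
#'
#' Columns: \code{Image}, \code{Centroid X um}, \code{Centroid Y um},
#' \code{Nucleus: Area um^2}, \code{Nucleus: <channel> mean},
#' \code{Cytoplasm: <channel> mean} and \code{Class} (the 53BP1
#' classification, when present). Real QuPath exports with these headers
#' read back unchanged.
#'
#' @param cells measurement table (from \code{\link{measure_cells}} /
#'   \code{\link{classify_positive}}).
#' @param path output csv path.
#' @param image image name written to the \code{Image} column.
#' @return \code{path}, invisibly.
#' @export
write_detections <- function(cells, path, image = "synthetic") {
  fx <- qp_fixed_cols()
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    a = if ("image" %in% names(cells)) cells$image
                    else rep(image, nrow(cells)))
  names(out) <- fx[["image"]]
  out[[fx[["x"]]]] <- cells$x
  out[[fx[["y"]]]] <- cells$y
  out[[fx[["nuclear_area"]]]] <- cells$nuclear_area
  for (col in grep("^nuclear_mean_", names(cells), value = TRUE)) {
    ch <- sub("^nuclear_mean_", "", col)
    out[[sprintf("Nucleus: %s mean", ch)]] <- cells[[col]]
  }
  for (col in grep("^annulus_mean_", names(cells), value = TRUE)) {
    ch <- sub("^annulus_mean_", "", col)
    out[[sprintf("Cytoplasm: %s mean", ch)]] <- cells[[col]]
  }
  cls <- rep("", nrow(cells))
  if ("positive_53BP1" %in% names(cells))
    cls <- ifelse(cells$positive_53BP1 %in% TRUE, "53BP1-positive",
                  "53BP1-negative")
  out[["Class"]] <- cls
  handled <- c("image", "x", "y", "nuclear_area",
               grep("^(nuclear|annulus)_mean_", names(cells), value = TRUE),
               "positive_53BP1")
  for (col in setdiff(names(cells), handled)) out[[col]] <- cells[[col]]
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a detection table in the QuPath export dialect
#'
#' Maps the QuPath headers back to the package's internal names
#' (\code{x, y, nuclear_area, nuclear_mean_<ch>, annulus_mean_<ch>}),
#' preserves micrometre units, keeps unknown extra columns untouched, and
#' restores the 53BP1 classification from \code{Class} when present.
#'
#' @param path csv path.
#' @param dialect only \code{"qupath"} is supported.
#' @return typed data.frame of cell records.
#' @export
read_detections <- function(path, dialect = "qupath") {
  dialect <- match.arg(dialect, "qupath")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  fx <- qp_fixed_cols()
  for (col in fx) {
    if (!col %in% names(raw))
      stop(sprintf("missing mandatory column %s", sQuote(col)),
           call. = FALSE)
  }
  to_num <- function(v, col) {
    blank <- !nzchar(trimws(v)) | toupper(trimws(v)) == "NA"
    x <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(x) & !blank)
    if (length(bad))
      stop(sprintf("malformed numeric value %s in column %s, row %d",
                   sQuote(v[bad[1]]), sQuote(col), bad[1]), call. = FALSE)
    x
  }
  out <- data.frame(image = raw[[fx[["image"]]]],
                    x = to_num(raw[[fx[["x"]]]], fx[["x"]]),
                    y = to_num(raw[[fx[["y"]]]], fx[["y"]]),
                    nuclear_area = to_num(raw[[fx[["nuclear_area"]]]],
                                          fx[["nuclear_area"]]),
                    stringsAsFactors = FALSE)
  for (col in names(raw)) {
    nuc <- regmatches(col, regexec("^Nucleus: (.+) mean$", col))[[1]]
    cyt <- regmatches(col, regexec("^Cytoplasm: (.+) mean$", col))[[1]]
    if (length(nuc) == 2) {
      out[[paste0("nuclear_mean_", nuc[2])]] <- to_num(raw[[col]], col)
    } else if (length(cyt) == 2) {
      out[[paste0("annulus_mean_", cyt[2])]] <- to_num(raw[[col]], col)
    }
  }
  if ("Class" %in% names(raw) && any(nzchar(raw$Class)))
    out$positive_53BP1 <- raw$Class == "53BP1-positive"
  known <- c(unname(fx), grep("^(Nucleus|Cytoplasm): .+ mean$",
                              names(raw), value = TRUE), "Class")
  for (col in setdiff(names(raw), known)) {
    v <- raw[[col]]
    x <- suppressWarnings(as.numeric(v))
    if (!anyNA(x[nzchar(trimws(v))])) v <- x
    else if (all(v %in% c("TRUE", "FALSE"))) v <- as.logical(v)
    out[[col]] <- v
  }
  out
}

## Configuration -------------------------------------------------------------

strip_class <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_class)
  } else if (!is.null(names(x)) && is.numeric(x)) as.list(x) else x
}

renum <- function(x) {
  if (is.list(x) && length(x) && all(nzchar(names(x))) &&
      all(vapply(x, function(e) is.numeric(e) && length(e) == 1, TRUE)))
    unlist(x)
  else x
}

#' Assemble a pipeline configuration
#'
#' Bundles the generator, detection, zonation and analysis settings that
#' \code{\link{run_pipeline}} consumes. Round-trips losslessly through the
#' YAML representation of \code{\link{write_config}}.
#'
#' @param generator a \code{generator_config} or a list of them (one per
#'   condition).
#' @param geometry a \code{tissue_geometry}.
#' @param culture optional \code{culture_config}.
#' @param detection a \code{detection_params}.
#' @param zonation list with \code{n_columns}.
#' @param analysis list with \code{response} (\code{"fraction"} or
#'   \code{"density"}), \code{bin_size}, \code{per_case_n},
#'   \code{coupling_seed}.
#' @param truth_bypass run the statistics directly on the ground-truth
#'   tables (no rendering or detection)?
#' @param output_dir directory for pipeline artifacts.
#' @param seed master seed.
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(generator = generator_config("AD"),
                            geometry = make_geometry(),
                            culture = NULL,
                            detection = detection_params(),
                            zonation = list(n_columns = 4),
                            analysis = list(response = "fraction",
                                            bin_size = 100,
                                            per_case_n = 100,
                                            coupling_seed = 1),
                            truth_bypass = TRUE,
                            output_dir = tempfile("cortexlam_run_"),
                            seed = 1L) {
  if (inherits(generator, "generator_config")) generator <- list(generator)
  structure(list(generator = generator, geometry = geometry,
                 culture = culture, detection = detection,
                 zonation = zonation, analysis = analysis,
                 truth_bypass = truth_bypass,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#' @param config a \code{pipeline_config}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(strip_class(unclass(config)), path)
  invisible(path)
}

#' Read a pipeline configuration written by \code{write_config}
#' @param path YAML path.
#' @return a \code{pipeline_config}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gens <- lapply(raw$generator, function(g) {
    g$size_params <- lapply(g$size_params, renum)
    g <- lapply(g, renum)
    do.call(generator_config, g)
  })
  geom <- do.call(make_geometry, raw$geometry)
  cult <- if (!is.null(raw$culture)) {
    cc <- lapply(raw$culture, renum)
    do.call(culture_config, cc)
  }
  det <- do.call(detection_params, lapply(raw$detection, renum))
  pipeline_config(generator = gens, geometry = geom, culture = cult,
                  detection = det, zonation = raw$zonation,
                  analysis = raw$analysis,
                  truth_bypass = raw$truth_bypass,
                  output_dir = raw$output_dir, seed = raw$seed)
}

## Lightweight content fingerprint (polynomial rolling hash, exact in
## double arithmetic) for run manifests.
config_hash <- function(config) {
  s <- jsonlite::toJSON(strip_class(unclass(config)), auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  p <- 67108859
  for (b in bytes) h <- (h * 131 + b) %% p
  sprintf("%08x", h)
}

## Reports -------------------------------------------------------------------

fit_as_list <- function(f) {
  list(coefficients = as.list(f$coefficients), n = f$n, r2 = f$r2,
       adjusted_r2 = f$adj_r2, slope_p = f$slope_p,
       vertex = if (is.finite(f$vertex)) f$vertex else NULL)
}

#' Write analysis results as tidy tables plus a JSON summary
#'
#' Emits one csv per tabular component and a single \code{summary.json}
#' keyed by figure-equivalent names (\code{fig4G}, \code{fig5A_fit_linear},
#' \code{fig5A_fit_quadratic}, \code{fig6E}, \code{fig7B}, ...). The JSON
#' carries no timestamps, so identical results are byte-identical across
#' reruns.
#'
#' @param results a \code{lam_results} list from \code{\link{run_pipeline}}
#'   (or an empty list for a report skeleton).
#' @param path output directory.
#' @return path of the JSON summary, invisibly.
#' @export
write_report <- function(results, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path))
    stop("I/O error: cannot create report directory ", path, call. = FALSE)
  summary <- list()
  if (!is.null(results$zone_summary)) {
    utils::write.csv(results$zone_summary,
                     file.path(path, "zone_summary.csv"), row.names = FALSE)
    by_cond <- split(results$zone_summary, results$zone_summary$condition)
    summary$fig4G <- lapply(by_cond, function(d)
      list(mean_fraction = mean(d$fraction, na.rm = TRUE),
           mean_density = mean(d$density, na.rm = TRUE),
           n_cases = length(unique(d$case_id))))
  }
  if (!is.null(results$fits)) {
    summary$fig5A_fit_linear <- lapply(results$fits, function(f)
      fit_as_list(f$linear))
    summary$fig5A_fit_quadratic <- lapply(results$fits, function(f)
      fit_as_list(f$quadratic))
    summary$fig5A_model_comparison <- lapply(results$fits, function(f)
      list(preferred = f$comparison$preferred, F = f$comparison$F,
           p = f$comparison$p))
  }
  if (!is.null(results$anova)) {
    utils::write.csv(as.data.frame(results$anova),
                     file.path(path, "anova.csv"), row.names = FALSE)
    summary$fig5A_anova <- lapply(seq_len(nrow(results$anova)), function(i)
      as.list(results$anova[i, ]))
  }
  if (!is.null(results$subset_profiles)) {
    summary$fig6B <- fit_as_list(results$subset_profiles$positive_nuclear$fit)
    summary$fig6C <- fit_as_list(
      results$subset_profiles$positive_cytoplasmic$fit)
    summary$fig6D <- fit_as_list(results$subset_profiles$negative_nuclear$fit)
  }
  if (!is.null(results$coupling)) {
    summary$fig6E <- lapply(results$coupling, function(cp)
      list(slope = cp$slope, intercept = cp$intercept, r2 = cp$r2,
           n = cp$n, seed = cp$seed))
  }
  if (!is.null(results$culture)) {
    fr <- results$culture$fractions
    utils::write.csv(fr, file.path(path, "culture_fractions.csv"),
                     row.names = FALSE)
    as_named <- function(marker) {
      s <- fr[fr$marker == marker, ]
      stats::setNames(lapply(seq_len(nrow(s)), function(i)
        list(mean_fraction = s$mean_fraction[i], sem = s$sem[i])),
        s$condition)
    }
    summary$fig7B <- as_named("gh2ax")
    summary$fig7C <- as_named("p27")
    summary$fig7DE <- stats::setNames(
      lapply(seq_len(nrow(results$culture$coupling)), function(i)
        as.list(results$culture$coupling[i, -1])),
      results$culture$coupling$condition)
  }
  out <- file.path(path, "summary.json")
  jsonlite::write_json(summary, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}
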