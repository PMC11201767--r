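first_present <- function(cells, candidates, what) {
  hit <- candidates[candidates %in% names(cells)]
  if (!length(hit))
    stop(sprintf("no %s column found (looked for %s)", what,
                 paste(candidates, collapse = ", ")), call. = FALSE)
  hit[1]
}

#' Per-case, per-zone counts, fractions and densities of positive cells
#'
#' Tallies total and marker-positive cells for every case x zone cell and
#' computes the positive fraction and, when zone areas are supplied, the
#' density of positive cells per mm^2. Cells without a zone assignment are
#' excluded (with a message); zones with no cells yield a record with a
#' missing fraction and a warning.
#'
#' @param cells cell table; needs a zone column (\code{zone} or
#'   \code{zone_true}), a positivity column (\code{positive_53BP1} or
#'   \code{damage_positive}) and \code{case_id}/\code{condition}.
#' @param areas_mm2 optional numeric vector of six zone areas, mm^2.
#' @param zone_col,positive_col optional explicit column names.
#' @return data.frame with columns \code{case_id, condition, zone, n_total,
#'   n_positive, area_mm2, fraction, density}.
#' @export
zone_summary <- function(cells, areas_mm2 = NULL,
                         zone_col = NULL, positive_col = NULL) {
  if (is.null(zone_col))
    zone_col <- first_present(cells, c("zone", "zone_true"), "zone")
  if (is.null(positive_col))
    positive_col <- first_present(cells, c("positive_53BP1", "damage_positive",
                                           "positive"), "positivity")
  zl <- cells[[zone_col]]
  unassigned <- sum(is.na(zl))
  if (unassigned)
    message(sprintf("zone_summary: excluding %d unassigned cell(s)",
                    unassigned))
  cells <- cells[!is.na(zl), , drop = FALSE]
  cases <- unique(cells[, c("case_id", "condition")])
  out <- list()
  for (i in seq_len(nrow(cases))) {
    sub <- cells[cells$case_id == cases$case_id[i], , drop = FALSE]
    for (z in 1:6) {
      sz <- sub[sub[[zone_col]] == z, , drop = FALSE]
      n_tot <- nrow(sz)
      n_pos <- sum(sz[[positive_col]])
      if (n_tot == 0)
        warning(sprintf("zone %d of case %s has no cells", z,
                        cases$case_id[i]), call. = FALSE)
      area <- if (is.null(areas_mm2)) NA_real_ else areas_mm2[z]
      out[[length(out) + 1L]] <- data.frame(
        case_id = cases$case_id[i], condition = cases$condition[i],
        zone = z, n_total = n_tot, n_positive = n_pos,
        area_mm2 = area,
        fraction = if (n_tot > 0) n_pos / n_tot else NA_real_,
        density = if (!is.na(area) && area > 0) n_pos / area else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Two-way condition x zone ANOVA on zone-level summaries
#'
#' Fixed-effects ANOVA with Type II sums of squares (suited to the
#' unbalanced 4-vs-3-case design), with one observation per case x zone.
#'
#' @param records data.frame with \code{condition}, \code{zone},
#'   \code{case_id} and the response column.
#' @param response response column name (e.g. \code{"fraction"} or a mean
#'   intensity).
#' @return an object of class \code{anova_table}: data.frame with rows
#'   condition, zone, interaction, residual and columns \code{ss, df, F, p}.
#' @export
two_way_anova <- function(records, response = "fraction") {
  if (!response %in% names(records))
    stop("response column not found: ", response, call. = FALSE)
  cases_per_cond <- tapply(records$case_id, records$condition,
                           function(x) length(unique(x)))
  if (any(cases_per_cond < 2))
    stop("each condition needs >= 2 cases for residual degrees of freedom",
         call. = FALSE)
  d <- data.frame(y = records[[response]],
                  condition = factor(records$condition),
                  zone = factor(records$zone))
  d <- d[is.finite(d$y), , drop = FALSE]
  terms <- c("condition", "zone", "condition:zone", "Residuals")
  if (stats::var(d$y) == 0) {
    tab <- data.frame(term = c("condition", "zone", "interaction",
                               "residual"),
                      ss = 0, df = NA_integer_, F = NA_real_, p = NA_real_)
    return(structure(tab, class = c("anova_table", "data.frame")))
  }
  fit <- stats::lm(y ~ condition * zone, data = d)
  a <- car::Anova(fit, type = 2)
  m <- match(terms, rownames(a))
  tab <- data.frame(
    term = c("condition", "zone", "interaction", "residual"),
    ss = a[["Sum Sq"]][m], df = a[["Df"]][m],
    F = a[["F value"]][m], p = a[["Pr(>F)"]][m])
  structure(tab, class = c("anova_table", "data.frame"))
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Two-way ANOVA (Type II sums of squares)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Unpaired two-sample t-test
#'
#' Two-sided; pooled (equal-variance) by default, Welch by flag.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param welch use the Welch correction?
#' @return list with \code{t, df, p, mean_a, mean_b}.
#' @export
unpaired_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Size-ranked binned intensity profile
#'
#' Ranks cells by nuclear area (ascending; ties broken by cell id), chunks
#' them into consecutive bins of exactly \code{bin_size} cells (the
#' remainder is dropped), averages the marker intensity per bin, and tests
#' the OLS slope of bin mean intensity against bin rank.
#'
#' @param cells cell table with \code{nuclear_area} and the intensity
#'   column.
#' @param intensity_col marker intensity column (e.g. \code{"i53bp1"}).
#' @param bin_size cells per bin (default 100).
#' @return an object of class \code{binned_profile}: \code{bins}
#'   (data.frame bin, n, mean_area, mean_intensity), \code{slope},
#'   \code{slope_p}, \code{n_dropped}.
#' @export
size_ranked_profile <- function(cells, intensity_col = "i53bp1",
                                bin_size = 100) {
  if (!intensity_col %in% names(cells))
    stop("intensity column not found: ", intensity_col, call. = FALSE)
  id <- if ("cell_id" %in% names(cells)) cells$cell_id else seq_len(nrow(cells))
  ord <- order(cells$nuclear_area, id)
  v <- cells[[intensity_col]][ord]
  a <- cells$nuclear_area[ord]
  nb <- floor(length(v) / bin_size)
  if (nb < 2)
    stop(sprintf("need at least 2 full bins of %d cells (have %d cells)",
                 bin_size, length(v)), call. = FALSE)
  keep <- seq_len(nb * bin_size)
  g <- rep(seq_len(nb), each = bin_size)
  bins <- data.frame(
    bin = seq_len(nb), n = bin_size,
    mean_area = as.vector(tapply(a[keep], g, mean)),
    mean_intensity = as.vector(tapply(v[keep], g, mean)))
  fit <- stats::lm(mean_intensity ~ bin, data = bins)
  cf <- stats::coef(summary(fit))
  structure(list(bins = bins, slope = cf[2, 1], slope_p = cf[2, 4],
                 bin_size = bin_size,
                 n_dropped = length(v) - nb * bin_size),
            class = "binned_profile")
}

#' @export
print.binned_profile <- function(x, ...) {
  cat(sprintf("Size-ranked profile: %d bins of %d cells (%d dropped)\n",
              nrow(x$bins), x$bin_size, x$n_dropped))
  cat(sprintf("  intensity-vs-rank slope %.4g (p = %.4g)\n",
              x$slope, x$slope_p))
  invisible(x)
}

#' Per-cell p16-53BP1 coupling regression
#'
#' Samples up to \code{per_case_n} damage-positive cells per case without
#' replacement (seeded) and regresses nuclear p16 intensity on 53BP1
#' intensity over the pooled sample.
#'
#' @param cells cell table with intensities and a positivity column.
#' @param per_case_n cells sampled per case (default 100).
#' @param seed sampling seed.
#' @param x_col,y_col intensity columns.
#' @param positive_col,case_col classification and case columns.
#' @return an object of class \code{coupling_result}: \code{slope,
#'   intercept, r2, n, sampled_ids, seed}.
#' @export
coupling_regression <- function(cells, per_case_n = 100, seed = 1L,
                                x_col = "i53bp1", y_col = "p16_nuclear",
                                positive_col = NULL, case_col = "case_id") {
  if (is.null(positive_col))
    positive_col <- first_present(cells, c("positive_53BP1",
                                           "damage_positive", "positive"),
                                  "positivity")
  pos <- cells[cells[[positive_col]] %in% TRUE, , drop = FALSE]
  set.seed(seed)
  take <- integer(0)
  for (cs in unique(cells[[case_col]])) {
    rows <- which(pos[[case_col]] == cs)
    if (!length(rows))
      stop(sprintf("case %s has no eligible (positive) cells", cs),
           call. = FALSE)
    if (length(rows) < per_case_n) {
      warning(sprintf("case %s has only %d eligible cells (< %d); using all",
                      cs, length(rows), per_case_n), call. = FALSE)
      take <- c(take, rows)
    } else {
      take <- c(take, sample(rows, per_case_n))
    }
  }
  samp <- pos[take, , drop = FALSE]
  fit <- stats::lm(samp[[y_col]] ~ samp[[x_col]])
  ids <- if ("cell_id" %in% names(samp)) samp$cell_id else take
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = summary(fit)$r.squared,
                 n = nrow(samp), sampled_ids = ids, seed = seed),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("Marker-coupling regression (n = %d, seed %d)\n", x$n, x$seed))
  cat(sprintf("  p16 = %.4g + %.4g x 53BP1, r^2 = %.4f\n",
              x$intercept, x$slope, x$r2))
  invisible(x)
}

#' Per-zone p16 intensity profiles of 53BP1-positive or negative cells
#'
#' Computes the mean p16 intensity of the chosen subset and compartment per
#' case and zone, and fits a linear depth profile (zone index abscissa)
#' through the case x zone means.
#'
#' @param cells cell table with p16 intensities and a positivity column.
#' @param subset \code{"positive"} or \code{"negative"} (53BP1 status).
#' @param compartment \code{"nuclear"} or \code{"cytoplasmic"}.
#' @param value_col override for the intensity column (defaults to
#'   \code{p16_nuclear} / \code{p16_cytoplasmic}).
#' @param positive_col,zone_col optional explicit column names.
#' @return an object of class \code{subset_profile}: \code{means}
#'   (case_id, zone, mean_intensity) and \code{fit} (linear
#'   \code{depth_fit}).
#' @export
subset_intensity_profiles <- function(cells,
                                      subset = c("positive", "negative"),
                                      compartment = c("nuclear",
                                                      "cytoplasmic"),
                                      value_col = NULL,
                                      positive_col = NULL,
                                      zone_col = NULL) {
  subset <- match.arg(subset)
  compartment <- match.arg(compartment)
  if (is.null(positive_col))
    positive_col <- first_present(cells, c("positive_53BP1",
                                           "damage_positive", "positive"),
                                  "positivity")
  if (is.null(zone_col))
    zone_col <- first_present(cells, c("zone", "zone_true"), "zone")
  if (is.null(value_col))
    value_col <- first_present(
      cells,
      if (compartment == "nuclear") c("p16_nuclear", "nuclear_mean_p16")
      else c("p16_cytoplasmic", "annulus_mean_p16"),
      paste(compartment, "p16 intensity"))
  want <- cells[[positive_col]] %in% (subset == "positive")
  sub <- cells[want & !is.na(cells[[zone_col]]), , drop = FALSE]
  out <- list()
  for (cs in unique(cells$case_id)) {
    for (z in 1:6) {
      v <- sub[[value_col]][sub$case_id == cs & sub[[zone_col]] == z]
      v <- v[is.finite(v)]
      if (!length(v))
        message(sprintf("subset_intensity_profiles: no %s cells in zone %d of %s",
                        subset, z, cs))
      out[[length(out) + 1L]] <- data.frame(
        case_id = cs, zone = z,
        mean_intensity = if (length(v)) mean(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  means <- do.call(rbind, out)
  fit <- fit_linear(means$zone, means$mean_intensity)
  structure(list(means = means, fit = fit, subset = subset,
                 compartment = compartment),
            class = "subset_profile")
}

#' @export
print.subset_profile <- function(x, ...) {
  cat(sprintf("p16 %s intensity of 53BP1-%s cells\n",
              x$compartment, x$subset))
  print(x$fit)
  invisible(x)
}

#' Positive fractions and marker coupling in culture data
#'
#' The replicate is the unit of analysis: positive fractions are computed
#' per replicate, aggregated to condition means with SEM, and compared by
#' pairwise unpaired t-tests. The per-cell relation between the senescence
#' marker (p27) and DNA damage (gamma-H2AX) is assessed by an OLS
#' regression within each condition.
#'
#' @param culture table from \code{\link{simulate_culture}} (or equivalent).
#' @return an object of class \code{culture_summary}: \code{fractions}
#'   (condition x marker means with SEM), \code{replicate_fractions},
#'   \code{tests} (pairwise t-tests per marker) and \code{coupling}
#'   (per-condition p27-on-gamma-H2AX regression).
#' @export
culture_fractions <- function(culture) {
  reps <- unique(culture[, c("condition", "replicate_id")])
  nrep <- table(reps$condition)
  if (any(nrep < 2))
    stop("each condition needs >= 2 replicates to estimate the SEM",
         call. = FALSE)
  rf <- do.call(rbind, lapply(seq_len(nrow(reps)), function(i) {
    sub <- culture[culture$replicate_id == reps$replicate_id[i], ]
    data.frame(condition = reps$condition[i],
               replicate_id = reps$replicate_id[i],
               gh2ax_fraction = mean(sub$gh2ax_positive),
               p27_fraction = mean(sub$p27_positive),
               n_cells = nrow(sub), stringsAsFactors = FALSE)
  }))
  conds <- unique(rf$condition)
  agg <- do.call(rbind, lapply(conds, function(cn) {
    s <- rf[rf$condition == cn, ]
    do.call(rbind, lapply(c("gh2ax", "p27"), function(mk) {
      v <- s[[paste0(mk, "_fraction")]]
      data.frame(condition = cn, marker = mk, mean_fraction = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)),
                 n_replicates = length(v), stringsAsFactors = FALSE)
    }))
  }))
  tests <- list()
  if (length(conds) > 1) {
    prs <- utils::combn(conds, 2)
    for (j in seq_len(ncol(prs))) {
      for (mk in c("gh2ax", "p27")) {
        a <- rf[rf$condition == prs[1, j], paste0(mk, "_fraction")]
        b <- rf[rf$condition == prs[2, j], paste0(mk, "_fraction")]
        tt <- unpaired_t(a, b)
        tests[[length(tests) + 1L]] <- data.frame(
          marker = mk, group_a = prs[1, j], group_b = prs[2, j],
          t = tt$t, p = tt$p, stringsAsFactors = FALSE)
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL
  coupling <- do.call(rbind, lapply(conds, function(cn) {
    s <- culture[culture$condition == cn, ]
    fit <- stats::lm(p27_intensity ~ gh2ax_intensity, data = s)
    cf <- stats::coef(summary(fit))
    data.frame(condition = cn, slope = cf[2, 1], slope_p = cf[2, 4],
               r2 = summary(fit)$r.squared, n = nrow(s),
               stringsAsFactors = FALSE)
  }))
  structure(list(fractions = agg, replicate_fractions = rf,
                 tests = tests, coupling = coupling),
            class = "culture_summary")
}

#' @export
print.culture_summary <- function(x, ...) {
  cat("Culture positive fractions (mean over replicates +/- SEM)\n")
  print.data.frame(x$fractions, row.names = FALSE, digits = 4)
  if (!is.null(x$tests)) {
    cat("\nPairwise unpaired t-tests on replicate fractions\n")
    print.data.frame(x$tests, row.names = FALSE, digits = 4)
  }
  cat("\nPer-cell p27 vs gamma-H2AX regression by condition\n")
  print.data.frame(x$coupling, row.names = FALSE, digits = 4)
  invisible(x)
}
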