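#' Configuration of the synthetic-cortex generator
#'
#' Collects every generative parameter for a simulated cohort of cortical
#' sections: the per-zone probability that a cell carries DNA damage
#' (53BP1-positive), a between-case random effect, the neuron/glia
#' nuclear-size mixture, log-normal 53BP1 intensities for negative and
#' positive cells, the linear coupling of nuclear p16 to 53BP1 intensity
#' among damaged cells, depth trends of p16 in undamaged cells and in the
#' perinuclear compartment, and hard-core spacing of nuclei.
#'
#' Condition presets: \code{"AD"} uses 4 cases, a quadratic damage profile
#' with coefficients (0.0201, 0.0955, -0.010612) peaking between zones 4 and
#' 5 (mean fraction about 19.3\%), strong p16--53BP1 coupling
#' (noise ratio 0.62) and a positive p16 depth slope; \code{"UC"} uses 3
#' cases, a flat 5.5\% profile, weak coupling (noise ratio 1.60) and no p16
#' depth trend in undamaged cells.
#'
#' @param condition \code{"AD"} or \code{"UC"}; selects the preset defaults.
#' @param n_cases number of cases (subjects); default 4 for AD, 3 for UC.
#' @param cells_per_case nuclei simulated per case.
#' @param profile_coeffs numeric (a, b, c): positive probability
#'   \code{a + b z + c z^2} of zone index z, clipped to [0, 1].
#' @param case_effect_sd sd of the per-case random effect on the logit of
#'   the positive probability.
#' @param neuron_fraction probability a cell is a neuron (larger nucleus).
#' @param size_params list with components \code{neuron} and \code{glia},
#'   each \code{c(mean_area, sdlog)}: log-normal nuclear-area components
#'   (arithmetic mean area in um^2, log-scale sd).
#' @param intensity_params \code{c(mu_neg, mu_pos, sigma)}: log-scale
#'   53BP1 intensity parameters for negative/positive cells (a.u.).
#' @param size_slope kappa, added 53BP1 intensity per um^2 of nuclear area
#'   above the mixture mean (a.u./um^2).
#' @param coupling_slope,coupling_intercept linear map from 53BP1 intensity
#'   to nuclear p16 intensity among damage-positive cells (a.u.).
#' @param coupling_noise_ratio sd of the coupling noise as a multiple of the
#'   sd of 53BP1 intensity among positives; the population r-squared of the
#'   coupling regression is \code{1 / (1 + ratio^2)} when
#'   \code{coupling_slope = 1}.
#' @param p16_baseline,p16_depth_slope,p16_noise_sd nuclear p16 model for
#'   damage-negative cells: baseline + slope x zone + Gaussian noise (a.u.).
#' @param cytoplasm_params \code{c(baseline, depth_slope, sd)}: perinuclear
#'   (pseudoplasm) p16 model, identical across conditions (a.u.).
#' @param min_spacing hard-core minimum distance between nucleus centroids,
#'   um. Zero disables spacing (fast path for statistical simulations).
#' @param seed default random seed used by the sampling functions.
#' @return an object of class \code{generator_config}.
#' @examples
#' cfg <- generator_config("AD")
#' zone_positive_probability(1:6, cfg$profile_coeffs)
#' @export
generator_config <- function(condition = c("AD", "UC"),
                             n_cases = NULL,
                             cells_per_case = 2000,
                             profile_coeffs = NULL,
                             case_effect_sd = 0.15,
                             neuron_fraction = 0.4,
                             size_params = list(neuron = c(mean_area = 79, sdlog = 0.25),
                                                glia   = c(mean_area = 28, sdlog = 0.25)),
                             intensity_params = c(mu_neg = log(20),
                                                  mu_pos = log(100),
                                                  sigma = 0.3),
                             size_slope = 0.1,
                             coupling_slope = 1,
                             coupling_intercept = 10,
                             coupling_noise_ratio = NULL,
                             p16_baseline = 15,
                             p16_depth_slope = NULL,
                             p16_noise_sd = 5,
                             cytoplasm_params = c(baseline = 12,
                                                  depth_slope = 0.5,
                                                  sd = 4),
                             min_spacing = 8,
                             seed = 1L) {
  condition <- match.arg(condition)
  if (is.null(n_cases)) n_cases <- if (condition == "AD") 4L else 3L
  if (is.null(profile_coeffs))
    profile_coeffs <- if (condition == "AD")
      c(a = 0.0201, b = 0.0955, c = -0.010612) else c(a = 0.055, b = 0, c = 0)
  if (is.null(coupling_noise_ratio))
    coupling_noise_ratio <- if (condition == "AD") 0.62 else 1.60
  if (is.null(p16_depth_slope))
    p16_depth_slope <- if (condition == "AD") 3 else 0
  if (coupling_noise_ratio < 0)
    stop("coupling_noise_ratio must be >= 0", call. = FALSE)
  if (n_cases < 1) stop("n_cases must be >= 1", call. = FALSE)
  if (min_spacing < 0) stop("min_spacing must be >= 0", call. = FALSE)
  if (case_effect_sd < 0) stop("case_effect_sd must be >= 0", call. = FALSE)
  if (neuron_fraction < 0 || neuron_fraction > 1)
    stop("neuron_fraction must be a probability", call. = FALSE)
  pc <- unname(profile_coeffs)
  if (length(pc) != 3) stop("profile_coeffs must have length 3", call. = FALSE)
  structure(
    list(condition = condition, n_cases = as.integer(n_cases),
         cells_per_case = as.integer(cells_per_case),
         profile_coeffs = c(a = pc[1], b = pc[2], c = pc[3]),
         case_effect_sd = case_effect_sd,
         neuron_fraction = neuron_fraction,
         size_params = size_params,
         intensity_params = intensity_params,
         size_slope = size_slope,
         coupling_slope = coupling_slope,
         coupling_intercept = coupling_intercept,
         coupling_noise_ratio = coupling_noise_ratio,
         p16_baseline = p16_baseline,
         p16_depth_slope = p16_depth_slope,
         p16_noise_sd = p16_noise_sd,
         cytoplasm_params = cytoplasm_params,
         min_spacing = min_spacing,
         seed = as.integer(seed)),
    class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Synthetic cortex generator config [%s]\n", x$condition))
  cat(sprintf("  cases x cells      : %d x %d\n", x$n_cases, x$cells_per_case))
  cat(sprintf("  profile (a, b, c)  : %.4g, %.4g, %.4g\n",
              x$profile_coeffs[1], x$profile_coeffs[2], x$profile_coeffs[3]))
  cat(sprintf("  case effect sd     : %g (logit)\n", x$case_effect_sd))
  cat(sprintf("  coupling noise     : %g (population r^2 %.4f)\n",
              x$coupling_noise_ratio, 1 / (1 + x$coupling_noise_ratio^2)))
  cat(sprintf("  min spacing        : %g um, seed %d\n", x$min_spacing, x$seed))
  invisible(x)
}

#' Per-zone probability that a cell is 53BP1-positive
#'
#' Evaluates the quadratic damage profile \code{a + b z + c z^2} at zone
#' index z and clips the result to [0, 1].
#'
#' @param zone integer zone indices in 1..6 (vectorized).
#' @param coeffs numeric (a, b, c).
#' @return probabilities.
#' @export
zone_positive_probability <- function(zone, coeffs) {
  if (any(!(zone %in% 1:6))) stop("zone must be in 1..6", call. = FALSE)
  coeffs <- unname(coeffs)
  p <- coeffs[1] + coeffs[2] * zone + coeffs[3] * zone^2
  pmin(pmax(p, 0), 1)
}

## Hard-core (minimum-spacing) point process in the ribbon.
## Candidates are drawn uniformly, thinned sequentially with a bucket grid
## of cell size = min_spacing so only the 3x3 neighbourhood must be checked.
hardcore_sample <- function(geometry, n, min_spacing) {
  A <- geometry$curvature_amplitude
  ymin <- -A
  ymax <- geometry$depth + A
  if (min_spacing <= 0) {
    ## fast path: independent uniform placement
    xs <- ys <- numeric(0)
    while (length(xs) < n) {
      m <- ceiling((n - length(xs)) * 1.3) + 16
      cx <- stats::runif(m, 0, geometry$width)
      cy <- stats::runif(m, ymin, ymax)
      keep <- in_ribbon(geometry, cx, cy)
      xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
    }
    return(cbind(x = xs[seq_len(n)], y = ys[seq_len(n)]))
  }
  max_attempts <- 50L * n
  s <- min_spacing
  nx <- max(1L, ceiling(geometry$width / s))
  ny <- max(1L, ceiling((ymax - ymin) / s))
  grid <- vector("list", nx * ny)
  px <- numeric(n); py <- numeric(n)
  accepted <- 0L; attempts <- 0L
  batch <- 2048L
  while (accepted < n && attempts < max_attempts) {
    m <- min(batch, max_attempts - attempts)
    cx <- stats::runif(m, 0, geometry$width)
    cy <- stats::runif(m, ymin, ymax)
    ok <- in_ribbon(geometry, cx, cy)
    gx <- pmin(pmax(floor(cx / s), 0), nx - 1)
    gy <- pmin(pmax(floor((cy - ymin) / s), 0), ny - 1)
    for (i in seq_len(m)) {
      attempts <- attempts + 1L
      if (!ok[i]) next
      gi <- gx[i]; gj <- gy[i]
      clash <- FALSE
      for (a in max(0, gi - 1):min(nx - 1, gi + 1)) {
        for (b in max(0, gj - 1):min(ny - 1, gj + 1)) {
          idx <- grid[[a + b * nx + 1L]]
          if (length(idx) &&
              any((px[idx] - cx[i])^2 + (py[idx] - cy[i])^2 < s^2)) {
            clash <- TRUE; break
          }
        }
        if (clash) break
      }
      if (clash) next
      accepted <- accepted + 1L
      px[accepted] <- cx[i]; py[accepted] <- cy[i]
      key <- gi + gj * nx + 1L
      grid[[key]] <- c(grid[[key]], accepted)
      if (accepted == n) break
    }
  }
  if (accepted < n)
    stop(sprintf(
      "packing error: placed %d of %d nuclei at min_spacing %g um (density %.1f/mm^2 requested)",
      accepted, n, s, n / (geometry$width * geometry$depth / 1e6)),
      call. = FALSE)
  cbind(x = px, y = py)
}

#' Place simulated nuclei in a cortical ribbon
#'
#' Draws \code{cells_per_case} nucleus centroids per case by hard-core
#' rejection sampling (all pairwise distances >= \code{min_spacing}),
#' assigns a neuron/glia class and a log-normal nuclear area, computes the
#' true zone from normalized depth, and draws the 53BP1-positive flag from
#' the zone profile shifted by a per-case logit random effect (the drawn
#' effects are centered within the cohort, so they spread cases without
#' moving the cohort-mean fraction).
#'
#' @param geometry a \code{tissue_geometry}.
#' @param config a \code{generator_config}.
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return a data.frame of ground-truth cells (one row per cell) with
#'   columns \code{case_id, condition, x, y, nuclear_area, cell_class,
#'   zone_true, damage_positive}.
#' @export
sample_cells <- function(geometry, config, seed = config$seed) {
  stopifnot(inherits(geometry, "tissue_geometry"),
            inherits(config, "generator_config"))
  set.seed(seed)
  ## per-case logit effects, centered within the cohort so the between-case
  ## spread does not shift the cohort-mean fraction
  u_case <- stats::rnorm(config$n_cases, 0, config$case_effect_sd)
  if (config$n_cases > 1) u_case <- u_case - mean(u_case)
  out <- vector("list", config$n_cases)
  for (k in seq_len(config$n_cases)) {
    n <- config$cells_per_case
    xy <- hardcore_sample(geometry, n, config$min_spacing)
    d <- normalized_depth(geometry, xy[, "x"], xy[, "y"])
    zone <- zone_of_depth(d)
    is_neuron <- stats::runif(n) < config$neuron_fraction
    sp <- config$size_params
    drawn <- function(p, m) {
      ## arithmetic mean m, log-sd s -> meanlog = log(m) - s^2/2
      s <- p[["sdlog"]]
      stats::rlnorm(m, meanlog = log(p[["mean_area"]]) - s^2 / 2, sdlog = s)
    }
    area <- numeric(n)
    area[is_neuron] <- drawn(sp$neuron, sum(is_neuron))
    area[!is_neuron] <- drawn(sp$glia, sum(!is_neuron))
    p <- zone_positive_probability(zone, config$profile_coeffs)
    pshift <- stats::plogis(stats::qlogis(pmin(pmax(p, 1e-9), 1 - 1e-9)) +
                              u_case[k])
    pos <- stats::runif(n) < pshift
    out[[k]] <- data.frame(
      case_id = sprintf("%s_case%02d", config$condition, k),
      condition = config$condition,
      x = xy[, "x"], y = xy[, "y"],
      nuclear_area = area,
      cell_class = ifelse(is_neuron, "neuron", "glia"),
      zone_true = as.integer(zone),
      damage_positive = pos,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Assign marker intensities to simulated cells
#'
#' 53BP1 intensity is log-normal (separate log-means for damage-positive and
#' negative cells) plus a shallow linear size term
#' \code{size_slope * (area - mean area)}. Among damage-positive cells,
#' nuclear p16 is linearly coupled to 53BP1 intensity, with the condition's
#' depth trend (\code{p16_depth_slope * zone}) added on top and Gaussian
#' noise whose sd is \code{coupling_noise_ratio} times the sd of 53BP1
#' intensity in the positive subset (the depth term is small relative to
#' the coupling, so the population r-squared of p16 on 53BP1 stays close
#' to \code{1/(1 + ratio^2)}); among negative cells nuclear p16 follows a
#' baseline plus the same depth slope. Perinuclear (cytoplasmic) p16 follows its own
#' baseline + depth slope, identical across conditions. Intensities are
#' clipped at zero.
#'
#' @param cells truth table from \code{\link{sample_cells}} (needs
#'   \code{damage_positive}, \code{nuclear_area}, \code{zone_true}).
#' @param config a \code{generator_config}.
#' @param seed integer seed.
#' @return \code{cells} with columns \code{i53bp1, p16_nuclear,
#'   p16_cytoplasmic} added.
#' @export
assign_intensities <- function(cells, config, seed = config$seed + 1L) {
  stopifnot(all(c("damage_positive", "nuclear_area", "zone_true") %in%
                  names(cells)))
  if (config$coupling_noise_ratio < 0)
    stop("coupling_noise_ratio must be >= 0", call. = FALSE)
  set.seed(seed)
  n <- nrow(cells)
  ip <- config$intensity_params
  sp <- config$size_params
  mean_area <- config$neuron_fraction * sp$neuron[["mean_area"]] +
    (1 - config$neuron_fraction) * sp$glia[["mean_area"]]
  mu <- ifelse(cells$damage_positive, ip[["mu_pos"]], ip[["mu_neg"]])
  i53 <- stats::rlnorm(n, meanlog = mu, sdlog = ip[["sigma"]]) +
    config$size_slope * (cells$nuclear_area - mean_area)
  i53 <- pmax(i53, 0)
  p16n <- numeric(n)
  pos <- cells$damage_positive
  if (any(pos)) {
    sd53 <- stats::sd(i53[pos])
    if (!is.finite(sd53)) sd53 <- 0
    eps <- stats::rnorm(sum(pos), 0, config$coupling_noise_ratio * sd53)
    p16n[pos] <- config$coupling_intercept +
      config$coupling_slope * i53[pos] +
      config$p16_depth_slope * cells$zone_true[pos] + eps
  }
  if (any(!pos)) {
    p16n[!pos] <- config$p16_baseline +
      config$p16_depth_slope * cells$zone_true[!pos] +
      stats::rnorm(sum(!pos), 0, config$p16_noise_sd)
  }
  cp <- config$cytoplasm_params
  p16c <- cp[["baseline"]] + cp[["depth_slope"]] * cells$zone_true +
    stats::rnorm(n, 0, cp[["sd"]])
  cells$i53bp1 <- i53
  cells$p16_nuclear <- pmax(p16n, 0)
  cells$p16_cytoplasmic <- pmax(p16c, 0)
  cells
}

#' Simulate a full ground-truth tissue cohort
#'
#' Convenience wrapper: \code{\link{sample_cells}} followed by
#' \code{\link{assign_intensities}}.
#'
#' @inheritParams sample_cells
#' @return a complete ground-truth cell table.
#' @export
simulate_tissue <- function(geometry, config, seed = config$seed) {
  cells <- sample_cells(geometry, config, seed = seed)
  assign_intensities(cells, config, seed = seed + 1L)
}
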