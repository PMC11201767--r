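#' Configuration of the etoposide-culture simulation
#'
#' Models DIV14 primary cortical cultures treated for 24 h with etoposide.
#' Each condition has a fixed probability that a cell shows gamma-H2AX
#' (DNA-damage) staining above threshold; the p27 senescence marker is
#' positive with a damage-independent probability, and its intensity is
#' drawn independently of gamma-H2AX intensity.
#'
#' @param n_per_replicate cells per replicate coverslip.
#' @param n_replicates replicates per condition.
#' @param damage_prob named per-condition gamma-H2AX-positive probabilities;
#'   names must be among \code{control}, \code{etop_1uM}, \code{etop_10uM}.
#' @param p27_prob p27-positive probability (all conditions).
#' @param map2_prob probability a cell is MAP2-positive (neuronal).
#' @param gh2ax_threshold,p27_threshold positivity thresholds, a.u.
#' @param intensity_params log-scale (meanlog_neg, meanlog_pos, sdlog_neg,
#'   sdlog_pos) shared by both markers.
#' @param seed default seed.
#' @return an object of class \code{culture_config}.
#' @export
culture_config <- function(n_per_replicate = 500,
                           n_replicates = 3,
                           damage_prob = c(control = 0.05,
                                           etop_1uM = 0.18,
                                           etop_10uM = 0.38),
                           p27_prob = 0.15,
                           map2_prob = 0.9,
                           gh2ax_threshold = 50,
                           p27_threshold = 50,
                           intensity_params = c(meanlog_neg = log(18),
                                                meanlog_pos = log(120),
                                                sdlog_neg = 0.4,
                                                sdlog_pos = 0.35),
                           seed = 1L) {
  valid <- c("control", "etop_1uM", "etop_10uM")
  bad <- setdiff(names(damage_prob), valid)
  if (length(bad) || is.null(names(damage_prob)))
    stop(sprintf("unknown condition label(s) %s; valid labels: %s",
                 paste(sQuote(bad), collapse = ", "),
                 paste(valid, collapse = ", ")), call. = FALSE)
  if (n_per_replicate < 1 || n_replicates < 1)
    stop("cell and replicate counts must be >= 1", call. = FALSE)
  if (any(damage_prob < 0 | damage_prob > 1) || p27_prob < 0 || p27_prob > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(
    list(n_per_replicate = as.integer(n_per_replicate),
         n_replicates = as.integer(n_replicates),
         damage_prob = damage_prob, p27_prob = p27_prob,
         map2_prob = map2_prob,
         gh2ax_threshold = gh2ax_threshold, p27_threshold = p27_threshold,
         intensity_params = intensity_params, seed = as.integer(seed)),
    class = "culture_config")
}

## Truncated log-normal via inverse CDF: positives above thr, negatives below.
rlnorm_side <- function(n, meanlog, sdlog, thr, above) {
  F <- stats::plnorm(thr, meanlog, sdlog)
  u <- if (above) stats::runif(n, F, 1) else stats::runif(n, 0, F)
  stats::qlnorm(u, meanlog, sdlog)
}

#' Simulate an etoposide dose-response culture experiment
#'
#' One row per cell across all conditions and replicates. Positivity flags
#' are drawn first (Bernoulli, per-condition probability for gamma-H2AX,
#' shared probability for p27); intensities are then drawn from log-normal
#' distributions truncated to the correct side of the positivity threshold,
#' so flags and thresholds are always consistent. p27 intensity is
#' independent of gamma-H2AX intensity by construction.
#'
#' @param config a \code{culture_config}.
#' @param seed integer seed.
#' @return a data.frame with columns \code{condition, replicate_id, cell_id,
#'   gh2ax_intensity, p27_intensity, gh2ax_positive, p27_positive,
#'   map2_positive}.
#' @export
simulate_culture <- function(config = culture_config(), seed = config$seed) {
  stopifnot(inherits(config, "culture_config"))
  set.seed(seed)
  ip <- config$intensity_params
  out <- list()
  for (cond in names(config$damage_prob)) {
    for (r in seq_len(config$n_replicates)) {
      n <- config$n_per_replicate
      gpos <- stats::runif(n) < config$damage_prob[[cond]]
      ppos <- stats::runif(n) < config$p27_prob
      gh <- numeric(n); p27 <- numeric(n)
      draw <- function(flags, thr) {
        v <- numeric(length(flags))
        v[flags] <- rlnorm_side(sum(flags), ip[["meanlog_pos"]],
                                ip[["sdlog_pos"]], thr, TRUE)
        v[!flags] <- rlnorm_side(sum(!flags), ip[["meanlog_neg"]],
                                 ip[["sdlog_neg"]], thr, FALSE)
        v
      }
      gh <- draw(gpos, config$gh2ax_threshold)
      p27 <- draw(ppos, config$p27_threshold)
      out[[length(out) + 1L]] <- data.frame(
        condition = cond,
        replicate_id = sprintf("%s_rep%d", cond, r),
        cell_id = seq_len(n),
        gh2ax_intensity = gh,
        p27_intensity = p27,
        gh2ax_positive = gpos,
        p27_positive = ppos,
        map2_positive = stats::runif(n) < config$map2_prob,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
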