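#' Adjusted r-squared
#'
#' \code{1 - (1 - r2) (n - 1) / (n - k - 1)} for a model with k predictors
#' fitted to n observations (k = 2 for the quadratic depth profile).
#'
#' @param r2 coefficient of determination.
#' @param n number of observations.
#' @param k number of predictors (excluding the intercept).
#' @return adjusted r-squared.
#' @examples
#' adjusted_r2(0.71, 24, 2)
#' @export
adjusted_r2 <- function(r2, n, k) {
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

depth_fit_from_lm <- function(fit, x, y, model) {
  s <- summary(fit)
  cf <- stats::coef(s)
  r2 <- if (stats::var(y) == 0) 0 else s$r.squared
  k <- length(stats::coef(fit)) - 1L
  n <- length(y)
  coefs <- stats::coef(fit)
  names(coefs) <- c("a", "b", "c")[seq_along(coefs)]
  se <- cf[, "Std. Error"]
  names(se) <- names(coefs)
  vertex <- NA_real_
  if (model == "quadratic") {
    cc <- coefs[["c"]]
    ## a curvature indistinguishable from zero at the data scale leaves the
    ## vertex undefined
    tol <- 1e-10 * max(abs(y), 1e-300)
    vertex <- if (is.finite(cc) && abs(cc) > tol) -coefs[["b"]] / (2 * cc)
    else NA_real_
  }
  slope_p <- if (stats::var(y) == 0) 1 else cf[2, "Pr(>|t|)"]
  structure(
    list(coefficients = coefs, se = se, n = n,
         r2 = r2, adj_r2 = adjusted_r2(r2, n, k),
         slope_p = slope_p, vertex = vertex,
         df_residual = fit$df.residual,
         rss = sum(stats::resid(fit)^2),
         model = model, x = x, y = y, lm = fit),
    class = "depth_fit")
}

#' Linear depth-profile fit
#'
#' Ordinary least squares of a response (typically the 53BP1-positive
#' fraction per case and zone) on the zone index, with a two-sided t-test
#' of zero slope.
#'
#' @param x zone indices (or any abscissa).
#' @param y response values.
#' @return an object of class \code{depth_fit}.
#' @export
fit_linear <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 3)
    stop("insufficient data: linear fit needs n >= 3", call. = FALSE)
  depth_fit_from_lm(stats::lm(y ~ x), x, y, "linear")
}

#' Quadratic depth-profile fit
#'
#' OLS of the response on (1, z, z^2). The adjusted r-squared uses k = 2
#' predictors, \code{1 - (1 - r2)(n - 1)/(n - 3)}, and the vertex of the
#' fitted parabola is \code{-b/(2c)} (the depth of maximal damage for an
#' inverted-U profile).
#'
#' @inheritParams fit_linear
#' @return an object of class \code{depth_fit}.
#' @export
fit_quadratic <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 4)
    stop("insufficient data: quadratic fit needs n >= 4", call. = FALSE)
  depth_fit_from_lm(stats::lm(y ~ x + I(x^2)), x, y, "quadratic")
}

#' @export
print.depth_fit <- function(x, ...) {
  cat(sprintf("%s depth-profile fit (n = %d)\n",
              if (x$model == "linear") "Linear" else "Quadratic", x$n))
  cat("  coefficients:",
      paste(sprintf("%s = %.6g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  cat(sprintf("  r^2 = %.4f, adjusted r^2 = %.4f\n", x$r2, x$adj_r2))
  if (x$model == "linear")
    cat(sprintf("  zero-slope test: p = %.4g\n", x$slope_p))
  if (x$model == "quadratic" && is.finite(x$vertex))
    cat(sprintf("  vertex at z = %.3f\n", x$vertex))
  invisible(x)
}

#' @export
summary.depth_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying lm summary:\n")
  print(summary(object$lm))
  invisible(object)
}

#' @export
coef.depth_fit <- function(object, ...) object$coefficients

#' @export
residuals.depth_fit <- function(object, ...) stats::resid(object$lm)

#' @export
predict.depth_fit <- function(object, newdata = NULL, ...) {
  z <- if (is.null(newdata)) object$x
  else if (is.list(newdata)) newdata$x else newdata
  b <- object$coefficients
  if (object$model == "linear") b[["a"]] + b[["b"]] * z
  else b[["a"]] + b[["b"]] * z + b[["c"]] * z^2
}

#' @export
plot.depth_fit <- function(x, ...,
                           xlab = "zone", ylab = "response") {
  graphics::plot(x$x, x$y, xlab = xlab, ylab = ylab, pch = 19, ...)
  z <- seq(min(x$x), max(x$x), length.out = 120)
  graphics::lines(z, predict(x, z))
  invisible(x)
}

#' Compare linear and quadratic depth-profile fits
#'
#' Partial F-test for the added quadratic term, with (1, n - 3) degrees of
#' freedom; the preferred model is the one with the higher adjusted
#' r-squared.
#'
#' @param linear a linear \code{depth_fit}.
#' @param quadratic a quadratic \code{depth_fit} on the same data.
#' @return an object of class \code{model_comparison} with elements
#'   \code{preferred}, \code{F}, \code{df}, \code{p}.
#' @export
compare_models <- function(linear, quadratic) {
  stopifnot(inherits(linear, "depth_fit"), inherits(quadratic, "depth_fit"))
  if (linear$model != "linear" || quadratic$model != "quadratic")
    stop("arguments must be a linear and a quadratic depth_fit",
         call. = FALSE)
  if (linear$n != quadratic$n ||
      !isTRUE(all.equal(linear$x, quadratic$x)) ||
      !isTRUE(all.equal(linear$y, quadratic$y)))
    stop("fits must be on identical data", call. = FALSE)
  n <- linear$n
  df2 <- n - 3
  Fstat <- (linear$rss - quadratic$rss) / (quadratic$rss / df2)
  p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  preferred <- if (quadratic$adj_r2 > linear$adj_r2) "quadratic" else "linear"
  structure(list(preferred = preferred, F = Fstat, df = c(1, df2), p = p,
                 linear = linear, quadratic = quadratic),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison: %s preferred (adj r^2 %.4f vs %.4f)\n",
              x$preferred, x$linear$adj_r2, x$quadratic$adj_r2))
  cat(sprintf("  partial F(%d, %d) = %.4g, p = %.4g for the quadratic term\n",
              x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}
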