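#' Construct a synthetic cortical ribbon geometry
#'
#' Defines a strip of gray matter bounded by a pial surface and a
#' white-matter boundary. The pia is a sinusoid of the given amplitude,
#' \code{y_pia(x) = A sin(2 pi x / width)}, and the white-matter boundary is
#' the same curve offset by \code{depth} (so the pia-to-white-matter distance
#' measured along y is constant). Coordinates are in micrometres; y increases
#' with depth (image convention, pia on top).
#'
#' @param width lateral extent of the ribbon, in um.
#' @param depth pia-to-white-matter distance, in um.
#' @param curvature_amplitude amplitude A of the sinusoidal pial surface, um.
#'   Zero gives a rectangular ribbon.
#' @param pixel_size physical size of a rendered pixel, um/px.
#' @return An object of class \code{tissue_geometry}.
#' @examples
#' geom <- make_geometry(1000, 2400, 0, 0.5)
#' geom
#' @export
make_geometry <- function(width = 1000, depth = 2400,
                          curvature_amplitude = 0, pixel_size = 0.5) {
  if (!is.numeric(width) || !is.numeric(depth) || width <= 0 || depth <= 0)
    stop("invalid geometry: width and depth must be positive", call. = FALSE)
  if (pixel_size <= 0)
    stop("invalid geometry: pixel_size must be positive", call. = FALSE)
  if (curvature_amplitude < 0)
    stop("invalid geometry: curvature_amplitude must be >= 0", call. = FALSE)
  if (curvature_amplitude >= depth / 4)
    stop("invalid geometry: curvature_amplitude must be < depth/4",
         call. = FALSE)
  structure(
    list(width = width, depth = depth,
         curvature_amplitude = curvature_amplitude,
         pixel_size = pixel_size),
    class = "tissue_geometry")
}

#' @export
print.tissue_geometry <- function(x, ...) {
  cat("Cortical ribbon geometry\n")
  cat(sprintf("  width x depth : %g x %g um (%.3g mm^2)\n",
              x$width, x$depth, x$width * x$depth / 1e6))
  cat(sprintf("  pia curvature : amplitude %g um\n", x$curvature_amplitude))
  cat(sprintf("  pixel size    : %g um/px\n", x$pixel_size))
  invisible(x)
}

#' Pial surface height at lateral position x
#'
#' @param geometry a \code{tissue_geometry}.
#' @param x lateral positions, um.
#' @return y-offsets of the pia at \code{x}, um.
#' @export
pia_y <- function(geometry, x) {
  geometry$curvature_amplitude * sin(2 * pi * x / geometry$width)
}

#' Sample the pia or white-matter boundary as a polyline
#'
#' @param geometry a \code{tissue_geometry}.
#' @param boundary which boundary to sample.
#' @param n number of vertices.
#' @return an n x 2 matrix of (x, y) coordinates in um, ordered by x.
#' @export
boundary_polyline <- function(geometry, boundary = c("pia", "wm"), n = 129) {
  boundary <- match.arg(boundary)
  x <- seq(0, geometry$width, length.out = n)
  y <- pia_y(geometry, x)
  if (boundary == "wm") y <- y + geometry$depth
  cbind(x = x, y = y)
}

#' Normalized cortical depth of points inside a ribbon
#'
#' Depth 0 lies on the pia, 1 on the white-matter boundary. Points outside
#' the ribbon get values outside [0, 1].
#'
#' @param geometry a \code{tissue_geometry}.
#' @param x,y point coordinates, um.
#' @return normalized depths.
#' @export
normalized_depth <- function(geometry, x, y) {
  (y - pia_y(geometry, x)) / geometry$depth
}

#' Test whether points lie inside the ribbon
#' @inheritParams normalized_depth
#' @return logical vector.
#' @export
in_ribbon <- function(geometry, x, y) {
  d <- normalized_depth(geometry, x, y)
  x >= 0 & x <= geometry$width & d >= 0 & d <= 1
}

#' Radial zone index (1-6) from normalized depth
#'
#' Zones are six equal depth bands; band k covers [(k-1)/6, k/6), with depth
#' 0 assigned to zone 1 and depth 1 to zone 6.
#'
#' @param d normalized depths in [0, 1].
#' @return integer zones 1-6.
#' @export
zone_of_depth <- function(d) {
  as.integer(pmin(pmax(ceiling(6 * d), 1L), 6L))
}
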