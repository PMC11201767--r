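## Polyline helpers ---------------------------------------------------------

cum_arclength <- function(poly) {
  d <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
  c(0, cumsum(d))
}

## Point at arclength fraction f in [0,1] along a polyline.
point_at_fraction <- function(poly, f) {
  s <- cum_arclength(poly)
  L <- s[length(s)]
  if (L <= 0) stop("geometry error: zero-length polyline", call. = FALSE)
  target <- f * L
  i <- findInterval(target, s, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(poly) - 1L)
  t <- (target - s[i]) / (s[i + 1] - s[i])
  cbind(poly[i, 1] + t * (poly[i + 1, 1] - poly[i, 1]),
        poly[i, 2] + t * (poly[i + 1, 2] - poly[i, 2]))
}

## Proper segment intersection (interiors cross); touching endpoints do not
## count.
segments_cross <- function(p1, p2, q1, q2) {
  o <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  d1 <- o(q1, q2, p1); d2 <- o(q1, q2, p2)
  d3 <- o(p1, p2, q1); d4 <- o(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Divide a cortical ribbon into vertical columns
#'
#' Draws \code{n_columns + 1} straight lines from the white matter to the
#' pia; the i-th line connects the point at arclength fraction
#' \code{i/n_columns} along the white-matter boundary to the point at the
#' same fraction along the pia ("evenly spaced" along both boundaries).
#' Consecutive lines bound one column.
#'
#' @param pia,wm boundary polylines (k x 2 matrices of (x, y) um), ordered
#'   in the same lateral direction.
#' @param n_columns number of columns (>= 1).
#' @return list of \code{column_annotation} objects; each holds the
#'   \code{left} and \code{right} bounding lines as 2 x 2 matrices with rows
#'   \code{pia} and \code{wm}.
#' @export
build_columns <- function(pia, wm, n_columns = 4) {
  pia <- as.matrix(pia); wm <- as.matrix(wm)
  if (n_columns < 1) stop("n_columns must be >= 1", call. = FALSE)
  fr <- seq(0, 1, length.out = n_columns + 1)
  pp <- point_at_fraction(pia, fr)
  wp <- point_at_fraction(wm, fr)
  lines <- lapply(seq_along(fr), function(i) {
    m <- rbind(pia = pp[i, ], wm = wp[i, ])
    colnames(m) <- c("x", "y")
    m
  })
  for (i in seq_along(lines)) {
    for (j in seq_along(lines)) {
      if (j <= i) next
      if (segments_cross(lines[[i]]["pia", ], lines[[i]]["wm", ],
                         lines[[j]]["pia", ], lines[[j]]["wm", ]))
        stop(sprintf("geometry error: column lines %d and %d intersect inside the ribbon",
                     i - 1, j - 1), call. = FALSE)
    }
  }
  lapply(seq_len(n_columns), function(k)
    structure(list(left = lines[[k]], right = lines[[k + 1]], index = k),
              class = "column_annotation"))
}

#' Mark the seven zone points on a column line
#'
#' The two endpoints plus five equidistant interior points, splitting the
#' line into six equal parts, ordered from the pia to the white matter. The
#' input may list its endpoints in either order; rows named \code{pia} and
#' \code{wm} identify them.
#'
#' @param line 2 x 2 matrix with rows \code{pia} and \code{wm}.
#' @return 7 x 2 matrix of points, pia first.
#' @export
zone_points <- function(line) {
  if (is.null(rownames(line)) ||
      !all(c("pia", "wm") %in% rownames(line)))
    stop("line must have rows named 'pia' and 'wm'", call. = FALSE)
  p <- line["pia", ]; w <- line["wm", ]
  L <- sqrt(sum((w - p)^2))
  if (L <= 0) stop("geometry error: zero-length column line", call. = FALSE)
  t <- seq(0, 1, by = 1 / 6)
  pts <- cbind(p[1] + t * (w[1] - p[1]), p[2] + t * (w[2] - p[2]))
  colnames(pts) <- c("x", "y")
  rownames(pts) <- NULL
  pts
}

shoelace <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Build the six radial zones of one column
#'
#' Zone k is the quadrilateral bounded by points k and k+1 on the left and
#' right column lines plus the connecting segments; polygons are returned
#' positively oriented (counter-clockwise by the shoelace sign) with areas
#' in mm^2.
#'
#' @param left_points,right_points 7 x 2 matrices from
#'   \code{\link{zone_points}} on the two bounding lines of a column.
#' @return an object of class \code{zone_set}: \code{zones} (list of 6
#'   polygons, 4 x 2 matrices) and \code{areas_mm2}.
#' @export
build_zones <- function(left_points, right_points) {
  stopifnot(nrow(left_points) == 7, nrow(right_points) == 7)
  zones <- vector("list", 6)
  areas <- numeric(6)
  for (k in 1:6) {
    poly <- rbind(left_points[k, ], left_points[k + 1, ],
                  right_points[k + 1, ], right_points[k, ])
    if (segments_cross(poly[1, ], poly[2, ], poly[3, ], poly[4, ]) ||
        segments_cross(poly[2, ], poly[3, ], poly[4, ], poly[1, ]))
      stop(sprintf("geometry error: zone %d polygon is self-intersecting", k),
           call. = FALSE)
    a <- shoelace(poly)
    if (a < 0) {
      poly <- poly[4:1, , drop = FALSE]
      a <- -a
    }
    colnames(poly) <- c("x", "y")
    zones[[k]] <- poly
    areas[k] <- a / 1e6
  }
  structure(list(zones = zones, areas_mm2 = areas), class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat("Zone set: 6 radial zones (1 = pia, 6 = white matter)\n")
  cat("  areas (mm^2):", paste(sprintf("%.4g", x$areas_mm2), collapse = ", "),
      "\n")
  invisible(x)
}

## Even-odd (crossing number) point-in-polygon, vectorized over points.
points_in_polygon <- function(px, py, poly) {
  n <- length(px)
  inside <- rep(FALSE, n)
  m <- nrow(poly)
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## Squared distance from points to a segment, vectorized over points.
dist2_to_segment <- function(px, py, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  L2 <- vx^2 + vy^2
  if (L2 == 0) return((px - a[1])^2 + (py - a[2])^2)
  t <- pmin(pmax(((px - a[1]) * vx + (py - a[2]) * vy) / L2, 0), 1)
  (px - (a[1] + t * vx))^2 + (py - (a[2] + t * vy))^2
}

#' Assign cell centroids to radial zones
#'
#' Point-in-polygon assignment. A centroid exactly on a boundary shared by
#' two zones goes to the lower (pia-ward) index; centroids outside every
#' zone are unassigned (\code{NA}).
#'
#' @param centroids matrix or data.frame with columns \code{x}, \code{y}
#'   (um).
#' @param zone_set a \code{zone_set}.
#' @param tol boundary tolerance, um.
#' @return integer zone per centroid (1-6 or \code{NA}).
#' @export
assign_zone <- function(centroids, zone_set, tol = 1e-9) {
  centroids <- as.matrix(as.data.frame(centroids)[, c("x", "y")])
  px <- centroids[, 1]; py <- centroids[, 2]
  out <- rep(NA_integer_, length(px))
  todo <- rep(TRUE, length(px))
  for (k in 1:6) {
    if (!any(todo)) break
    poly <- zone_set$zones[[k]]
    idx <- which(todo)
    hit <- points_in_polygon(px[idx], py[idx], poly)
    ## boundary pixels: within tol of any edge
    not_hit <- idx[!hit]
    if (length(not_hit)) {
      d2 <- rep(Inf, length(not_hit))
      m <- nrow(poly)
      j <- m
      for (i in seq_len(m)) {
        d2 <- pmin(d2, dist2_to_segment(px[not_hit], py[not_hit],
                                        poly[j, ], poly[i, ]))
        j <- i
      }
      hit[match(not_hit, idx)] <- d2 <= tol^2
    }
    sel <- idx[hit]
    out[sel] <- k
    todo[sel] <- FALSE
  }
  out
}

## GeoJSON -------------------------------------------------------------------

closed_ring <- function(poly) {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

#' Write a zone set as GeoJSON
#'
#' One Polygon feature per zone (coordinates in um) with the zone index and
#' area (mm^2) as properties.
#'
#' @param zone_set a \code{zone_set}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_zones_geojson <- function(zone_set, path) {
  features <- lapply(1:6, function(k) {
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(closed_ring(zone_set$zones[[k]]))),
         properties = list(zone = k, area_mm2 = zone_set$areas_mm2[k]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a zone set from GeoJSON written by \code{write_zones_geojson}
#' @param path GeoJSON path.
#' @return a \code{zone_set}.
#' @export
read_zones_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  zones <- vector("list", 6)
  areas <- numeric(6)
  for (f in g$features) {
    k <- f$properties$zone
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, unlist))
    m <- m[-nrow(m), , drop = FALSE]  # drop closing vertex
    colnames(m) <- c("x", "y")
    zones[[k]] <- m
    areas[k] <- f$properties$area_mm2
  }
  structure(list(zones = zones, areas_mm2 = areas), class = "zone_set")
}

#' Write column lines as GeoJSON LineString features
#' @param columns list of \code{column_annotation} from
#'   \code{\link{build_columns}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_columns_geojson <- function(columns, path) {
  seg_feature <- function(m, role, index) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(c(m["pia", 1], m["pia", 2]),
                                            c(m["wm", 1], m["wm", 2]))),
         properties = list(role = role, column = index))
  }
  features <- list()
  for (col in columns) {
    features <- c(features,
                  list(seg_feature(col$left, "left", col$index),
                       seg_feature(col$right, "right", col$index)))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
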