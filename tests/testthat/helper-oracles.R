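# Independent oracles used by the tests. These deliberately use different
# algorithms from the package implementation.

# Winding-number point-in-polygon: sum of signed angles subtended by the
# polygon edges is +/- 2*pi inside, 0 outside.
wn_inside <- function(px, py, poly) {
  vapply(seq_along(px), function(i) {
    dx <- poly[, 1] - px[i]
    dy <- poly[, 2] - py[i]
    ang <- atan2(dy, dx)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi
  }, TRUE)
}

# Oracle zone assignment: first zone whose polygon contains the point by
# winding number.
wn_assign_zone <- function(centroids, zone_set) {
  px <- centroids$x; py <- centroids$y
  out <- rep(NA_integer_, length(px))
  for (k in 1:6) {
    idx <- which(is.na(out))
    if (!length(idx)) break
    hit <- wn_inside(px[idx], py[idx], zone_set$zones[[k]])
    out[idx[hit]] <- k
  }
  out
}

# Numeric arclength of the sinusoidal pia y = A sin(2 pi x / W) from 0 to x.
sinusoid_arclength <- function(x, A, W) {
  stats::integrate(function(t) sqrt(1 + (A * 2 * pi / W *
                                           cos(2 * pi * t / W))^2),
                   0, x, rel.tol = 1e-10)$value
}

# Render a filled disk (constant amplitude, no blur) as an image matrix.
render_disk <- function(radius_um, pixel_size, value = 100, pad_um = 10,
                        background = 0) {
  n <- ceiling(2 * (radius_um + pad_um) / pixel_size)
  cx <- n / 2
  xs <- (seq_len(n) - cx) * pixel_size
  d2 <- outer(xs^2, xs^2, "+")
  img <- matrix(background, n, n)
  img[d2 <= radius_um^2] <- value
  attr(img, "pixel_size") <- pixel_size
  img
}

# Small default geometry shared across tests.
test_geometry <- function(width = 1000, depth = 2400, amp = 0, px = 0.5) {
  make_geometry(width, depth, amp, px)
}

# Greedy centroid matching of detections to truth within a tolerance;
# returns recall and precision.
match_detections <- function(meas, truth, tol_um = 3) {
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in seq_len(nrow(meas))) {
    d <- sqrt((truth$x - meas$x[i])^2 + (truth$y - meas$y[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol_um) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  list(recall = tp / nrow(truth), precision = tp / nrow(meas))
}
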