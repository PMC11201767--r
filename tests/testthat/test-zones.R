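test_that("columns of a rectangular ribbon are evenly spaced vertical lines", {
  geom <- test_geometry(1000, 2400, 0)
  pia <- boundary_polyline(geom, "pia")
  wm <- boundary_polyline(geom, "wm")
  cols <- build_columns(pia, wm, 4)
  expect_length(cols, 4)
  xs <- c(sapply(cols, function(cc) cc$left["pia", "x"]),
          cols[[4]]$right["pia", "x"])
  expect_equal(xs, c(0, 0.25, 0.5, 0.75, 1) * 1000)
  # n = 1: the whole ribbon is one column
  one <- build_columns(pia, wm, 1)
  expect_length(one, 1)
  expect_equal(one[[1]]$left["pia", "x"], 0)
  expect_equal(one[[1]]$right["pia", "x"], 1000)
})

test_that("curved-ribbon column endpoints sit at equal arclength fractions", {
  A <- 100; W <- 1000
  geom <- make_geometry(W, 2400, A, 0.5)
  pia <- boundary_polyline(geom, "pia", 1025)
  wm <- boundary_polyline(geom, "wm", 1025)
  cols <- build_columns(pia, wm, 4)
  total <- sinusoid_arclength(W, A, W)
  for (i in 1:3) {
    x_end <- cols[[i]]$right["pia", "x"]
    # numeric arclength integration oracle
    expect_equal(sinusoid_arclength(x_end, A, W) / total, i / 4,
                 tolerance = 1e-4)
  }
})

test_that("crossing column lines are rejected with the offending pair named", {
  pia <- cbind(x = c(0, 100), y = c(0, 0))
  wm <- cbind(x = c(100, 0), y = c(50, 50)) # reversed orientation forces crossings
  expect_error(build_columns(pia, wm, 2), "column lines .* intersect")
})

test_that("zone points split a column line into six equal parts, pia first", {
  line <- rbind(pia = c(0, 0), wm = c(0, 6))
  colnames(line) <- c("x", "y")
  pts <- zone_points(line)
  expect_equal(pts[, "y"], 0:6)
  # equal spacing within 1e-9 relative tolerance on an oblique segment
  line2 <- rbind(pia = c(1, 2), wm = c(7.3, -4.1))
  colnames(line2) <- c("x", "y")
  pts2 <- zone_points(line2)
  gaps <- sqrt(diff(pts2[, 1])^2 + diff(pts2[, 2])^2)
  expect_lt(max(abs(gaps - gaps[1])) / gaps[1], 1e-9)
  # reversed row order still yields pia-first points
  pts3 <- zone_points(line2[c("wm", "pia"), ])
  expect_equal(pts3, pts2)
  bad <- rbind(pia = c(1, 1), wm = c(1, 1))
  expect_error(zone_points(bad), "zero-length")
})

test_that("zones of a rectangular column are six equal bands with additive area", {
  left <- zone_points(rbind(pia = c(0, 0), wm = c(0, 2400)))
  right <- zone_points(rbind(pia = c(250, 0), wm = c(250, 2400)))
  zs <- build_zones(left, right)
  expect_equal(zs$areas_mm2, rep(250 * 2400 / 6 / 1e6, 6))
  # additivity against the shoelace of the whole column
  col_area <- 250 * 2400 / 1e6
  expect_lt(abs(sum(zs$areas_mm2) - col_area) / col_area, 1e-6)
  # all polygons positively oriented (counter-clockwise shoelace)
  sl <- function(p) sum(p[, 1] * c(p[-1, 2], p[1, 2]) -
                          c(p[-1, 1], p[1, 1]) * p[, 2]) / 2
  expect_true(all(sapply(zs$zones, sl) > 0))
})

test_that("curved-column zone areas are additive and polygons stay simple", {
  geom <- make_geometry(1000, 2400, 100, 0.5)
  zg <- zonate_geometry(geom, 4)
  poly_area <- function(p) abs(sum(p[, 1] * c(p[-1, 2], p[1, 2]) -
                                     c(p[-1, 1], p[1, 1]) * p[, 2]) / 2)
  for (i in seq_along(zg$zone_sets)) {
    zs <- zg$zone_sets[[i]]
    lp <- zone_points(zg$columns[[i]]$left)
    rp <- zone_points(zg$columns[[i]]$right)
    col_quad <- rbind(lp[1, ], lp[7, ], rp[7, ], rp[1, ])
    expect_lt(abs(sum(zs$areas_mm2) - poly_area(col_quad) / 1e6) /
                sum(zs$areas_mm2), 1e-6)
    # all polygons simple and positively oriented
    sl <- function(p) sum(p[, 1] * c(p[-1, 2], p[1, 2]) -
                            c(p[-1, 1], p[1, 1]) * p[, 2]) / 2
    expect_true(all(sapply(zs$zones, sl) > 0))
  }
})

test_that("zone assignment matches band arithmetic and the tie-break rule", {
  left <- zone_points(rbind(pia = c(0, 0), wm = c(0, 600)))
  right <- zone_points(rbind(pia = c(100, 0), wm = c(100, 600)))
  zs <- build_zones(left, right)
  # depth fraction 0.25 -> band 2
  expect_identical(assign_zone(data.frame(x = 50, y = 150), zs), 2L)
  # exactly on the zone 2/3 boundary -> zone 2 (pia-ward)
  expect_identical(assign_zone(data.frame(x = 50, y = 200), zs), 2L)
  # outside all zones -> unassigned
  expect_identical(assign_zone(data.frame(x = 500, y = 150), zs),
                   NA_integer_)
  # equal-band limit: zone equals ceil(6 d) for interior points
  set.seed(1)
  y <- runif(500, 1e-6, 600 - 1e-6)
  z <- assign_zone(data.frame(x = runif(500, 1e-6, 100 - 1e-6), y = y), zs)
  expect_identical(z, as.integer(pmin(pmax(ceiling(6 * y / 600), 1), 6)))
})

test_that("assignments agree with the winding-number oracle on a curved column", {
  geom <- make_geometry(1000, 2400, 100, 0.5)
  zg <- zonate_geometry(geom, 2)
  zs <- zg$zone_sets[[1]]
  set.seed(2)
  pts <- data.frame(x = runif(2000, -50, 600),
                    y = runif(2000, -150, 2600))
  expect_identical(assign_zone(pts, zs), wn_assign_zone(pts, zs))
})

test_that("assignments are invariant under rigid motion of the whole annotation", {
  left <- zone_points(rbind(pia = c(0, 0), wm = c(30, 600)))
  right <- zone_points(rbind(pia = c(120, -10), wm = c(150, 610)))
  zs <- build_zones(left, right)
  set.seed(3)
  pts <- data.frame(x = runif(400, 0, 150), y = runif(400, -20, 620))
  z0 <- assign_zone(pts, zs)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(m) sweep(as.matrix(m) %*% t(R), 2, c(-55, 98), "+")
  zs_r <- zs
  zs_r$zones <- lapply(zs$zones, function(p) {
    q <- rot(p); colnames(q) <- c("x", "y"); q
  })
  pr <- as.data.frame(rot(pts)); names(pr) <- c("x", "y")
  expect_identical(assign_zone(pr, zs_r), z0)
})

test_that("zone sets round-trip through GeoJSON", {
  geom <- make_geometry(1000, 2400, 100, 0.5)
  zg <- zonate_geometry(geom, 2)
  path <- tempfile(fileext = ".geojson")
  write_zones_geojson(zg$zone_sets[[2]], path)
  back <- read_zones_geojson(path)
  expect_equal(back$areas_mm2, zg$zone_sets[[2]]$areas_mm2)
  for (k in 1:6)
    expect_equal(unname(back$zones[[k]]), unname(zg$zone_sets[[2]]$zones[[k]]))
  write_columns_geojson(zg$columns, tempfile(fileext = ".geojson"))
  succeed()
})
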