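test_that("zone positive probability follows the clipped quadratic profile", {
  uc <- generator_config("UC")
  ad <- generator_config("AD")
  expect_equal(zone_positive_probability(1:6, uc$profile_coeffs),
               rep(0.055, 6))
  p <- zone_positive_probability(1:6, ad$profile_coeffs)
  # near-symmetric about the vertex (-b/2c = 4.4997, i.e. between 4 and 5)
  expect_equal(p[4], p[5], tolerance = 1e-4)
  # direct evaluation of the six polynomial values
  z <- 1:6
  expect_equal(mean(0.0201 + 0.0955 * z - 0.010612 * z^2), 0.1934,
               tolerance = 1e-4)
  expect_equal(mean(p), 0.1934, tolerance = 1e-4)
  # clipping keeps probabilities in [0, 1]
  expect_equal(zone_positive_probability(6, c(2, 0, 0)), 1)
  expect_equal(zone_positive_probability(1, c(-1, 0, 0)), 0)
  expect_error(zone_positive_probability(7, uc$profile_coeffs), "zone")
})

test_that("sample_cells places the requested cells inside the ribbon with hard-core spacing", {
  geom <- test_geometry()
  cfg <- generator_config("UC", n_cases = 1, cells_per_case = 250,
                          min_spacing = 8)
  cells <- sample_cells(geom, cfg, seed = 4)
  expect_equal(nrow(cells), 250)
  expect_true(all(in_ribbon(geom, cells$x, cells$y)))
  # brute-force all-pairs minimum distance oracle
  dmin <- min(dist(cbind(cells$x, cells$y)))
  expect_gte(dmin, 8)
  # zone consistent with normalized depth
  expect_identical(cells$zone_true,
                   zone_of_depth(normalized_depth(geom, cells$x, cells$y)))
  # determinism
  again <- sample_cells(geom, cfg, seed = 4)
  expect_identical(cells, again)
})

test_that("infeasible packing densities raise an informative error", {
  geom <- make_geometry(100, 100, 0, 0.5)
  cfg <- generator_config("UC", n_cases = 1, cells_per_case = 2000,
                          min_spacing = 10)
  expect_error(sample_cells(geom, cfg, seed = 1), "packing error")
})

test_that("marker intensities follow the coupling model", {
  geom <- test_geometry()
  # zero coupling noise: nuclear p16 of positives is an exact line in i53bp1
  # with the depth term silenced, zero noise leaves an exact line
  cfg0 <- generator_config("AD", cells_per_case = 500, min_spacing = 0,
                           coupling_noise_ratio = 0, p16_depth_slope = 0)
  cells0 <- simulate_tissue(geom, cfg0, seed = 5)
  pos0 <- cells0[cells0$damage_positive, ]
  expect_equal(summary(lm(p16_nuclear ~ i53bp1, pos0))$r.squared, 1,
               tolerance = 1e-9)
  expect_error(generator_config("AD", coupling_noise_ratio = -1),
               "coupling_noise_ratio")

  # kappa = 0: no size-intensity trend in expectation
  cfgk <- generator_config("AD", n_cases = 2, cells_per_case = 6000,
                           min_spacing = 0, size_slope = 0)
  cellsk <- simulate_tissue(geom, cfgk, seed = 6)
  neg <- cellsk[!cellsk$damage_positive, ]
  sl <- summary(lm(i53bp1 ~ nuclear_area, neg))$coefficients[2, ]
  expect_lt(abs(sl[["Estimate"]]), 3 * sl[["Std. Error"]])

  # Monte-Carlo check of the closed form r^2 = 1 / (1 + ratio^2)
  cfg <- generator_config("AD", n_cases = 4, cells_per_case = 13000,
                          min_spacing = 0)
  cells <- simulate_tissue(geom, cfg, seed = 7)
  pos <- cells[cells$damage_positive, ]
  expect_gt(nrow(pos), 10000)
  r2 <- summary(lm(p16_nuclear ~ i53bp1, pos))$r.squared
  expect_equal(r2, 1 / (1 + 0.62^2), tolerance = 0.05)
})

test_that("coupling r-squared converges to the closed form at large n", {
  geom <- test_geometry()
  cfg <- generator_config("AD", n_cases = 4, cells_per_case = 65000,
                          min_spacing = 0)
  cells <- simulate_tissue(geom, cfg, seed = 8)
  pos <- cells[cells$damage_positive, ]
  expect_gt(nrow(pos), 50000)
  r2 <- summary(lm(p16_nuclear ~ i53bp1, pos))$r.squared
  expect_lt(abs(r2 - 1 / (1 + 0.62^2)), 0.03)
})

test_that("per-zone empirical positive fractions converge to the profile", {
  geom <- test_geometry()
  cfg <- generator_config("AD", n_cases = 1, cells_per_case = 30000,
                          min_spacing = 0, case_effect_sd = 0)
  cells <- sample_cells(geom, cfg, seed = 9)
  emp <- tapply(cells$damage_positive, cells$zone_true, mean)
  expect_true(all(tapply(cells$zone_true, cells$zone_true, length) > 4000))
  truth <- zone_positive_probability(1:6, cfg$profile_coeffs)
  expect_lt(max(abs(emp - truth)), 0.02)
})

test_that("AD cohorts carry three- to four-fold more damage than UC cohorts", {
  geom <- test_geometry()
  ad <- simulate_tissue(geom, generator_config("AD", cells_per_case = 5000,
                                               min_spacing = 0), seed = 1)
  uc <- simulate_tissue(geom, generator_config("UC", cells_per_case = 5000,
                                               min_spacing = 0), seed = 1)
  fold <- mean(ad$damage_positive) / mean(uc$damage_positive)
  expect_gte(fold, 3)
  expect_lte(fold, 4)
})

test_that("nuclear p16 of damage-negative cells stays below damage-positive cells per zone", {
  geom <- test_geometry()
  cells <- simulate_tissue(geom, generator_config("AD", cells_per_case = 4000,
                                                  min_spacing = 0), seed = 10)
  for (z in 1:6) {
    sub <- cells[cells$zone_true == z, ]
    expect_lt(mean(sub$p16_nuclear[!sub$damage_positive]),
              mean(sub$p16_nuclear[sub$damage_positive]))
  }
})

test_that("culture simulation reproduces the per-condition damage fractions", {
  cfg <- culture_config(n_per_replicate = 4000, n_replicates = 3)
  cu <- simulate_culture(cfg, seed = 11)
  fr <- tapply(cu$gh2ax_positive, cu$condition, mean)
  expect_lt(abs(fr[["control"]] - 0.05), 0.01)
  expect_lt(abs(fr[["etop_10uM"]] - 0.38), 0.015)
  # p27 independent of gamma-H2AX by construction
  for (cond in unique(cu$condition)) {
    s <- cu[cu$condition == cond, ]
    expect_lt(abs(cor(s$p27_intensity, s$gh2ax_intensity)), 0.05)
  }
  # positivity flags consistent with the thresholds
  expect_identical(cu$gh2ax_positive, cu$gh2ax_intensity > cfg$gh2ax_threshold)
  expect_identical(cu$p27_positive, cu$p27_intensity > cfg$p27_threshold)
  # determinism
  expect_identical(cu, simulate_culture(cfg, seed = 11))
  expect_error(culture_config(damage_prob = c(bogus = 0.5)), "bogus")
})
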