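make_cohort <- function(condition = "AD", seed = 1, cells_per_case = 2000,
                        ...) {
  geom <- test_geometry()
  cfg <- generator_config(condition, cells_per_case = cells_per_case,
                          min_spacing = 0, ...)
  simulate_tissue(geom, cfg, seed = seed)
}

test_that("zone summaries tally counts, fractions and densities correctly", {
  cells <- data.frame(case_id = "c1", condition = "UC",
                      zone = rep(1:6, each = 400),
                      positive_53BP1 = rep(FALSE, 2400))
  cells$positive_53BP1[cells$zone == 2][1:20] <- TRUE
  zs <- zone_summary(cells, areas_mm2 = rep(0.4, 6))
  expect_equal(nrow(zs), 6)
  expect_equal(zs$fraction[zs$zone == 2], 0.05)
  expect_equal(zs$density[zs$zone == 2], 20 / 0.4)
  expect_equal(sum(zs$n_total), nrow(cells))
  # saturation
  cells$positive_53BP1 <- TRUE
  expect_true(all(zone_summary(cells)$fraction == 1))
  # unassigned cells excluded with a message; empty zones warned
  cells$zone[1:10] <- NA
  expect_message(zone_summary(cells), "unassigned")
  cells2 <- cells[cells$zone %in% 1:3, ]
  expect_warning(zs2 <- zone_summary(cells2), "no cells")
  expect_true(all(is.na(zs2$fraction[zs2$zone > 3])))
  expect_equal(nrow(zs2), 6)
})

test_that("two-way ANOVA handles the unbalanced design and degenerate input", {
  cells_ad <- make_cohort("AD", seed = 41)
  cells_uc <- make_cohort("UC", seed = 42)
  zs <- rbind(zone_summary(cells_ad), zone_summary(cells_uc))
  tab <- two_way_anova(zs, response = "fraction")
  expect_identical(tab$term, c("condition", "zone", "interaction",
                               "residual"))
  expect_lt(tab$p[tab$term == "condition"], 0.01) # 3.5-fold effect
  expect_equal(tab$df[tab$term == "condition"], 1)
  expect_equal(tab$df[tab$term == "zone"], 5)
  # constant response: zero sums of squares, F reported missing
  zs0 <- zs; zs0$fraction <- 0.1
  tab0 <- two_way_anova(zs0, response = "fraction")
  expect_true(all(tab0$ss == 0))
  expect_true(all(is.na(tab0$F)))
  # a condition with a single case has no residual degrees of freedom
  zs1 <- zs[zs$case_id %in% c("AD_case01", "UC_case01", "UC_case02",
                              "UC_case03"), ]
  expect_error(two_way_anova(zs1), ">= 2 cases")
})

test_that("two-way ANOVA detects a 2-between-case-sd condition shift with high power", {
  cond <- rep(c("AD", "AD", "AD", "AD", "UC", "UC", "UC"), each = 6)
  case <- rep(sprintf("case%d", 1:7), each = 6)
  zone <- rep(1:6, 7)
  set.seed(43)
  hits <- replicate(500, {
    u <- rnorm(7, 0, 1)[rep(1:7, each = 6)]
    y <- u + rnorm(42, 0, 0.3) + 2 * (cond == "AD")
    rec <- data.frame(condition = cond, case_id = case, zone = zone, y = y)
    two_way_anova(rec, response = "y")$p[1] < 0.01
  })
  expect_gte(mean(hits), 0.9)
})

test_that("unpaired t-test matches the hand-computed pooled formula", {
  # identical groups: t = 0, p = 1
  t0 <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)
  # {1,2,3} vs {4,5,6}: pooled sd 1, se = sqrt(2/3), t = -3.674
  tt <- unpaired_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3.674, tolerance = 1e-3)
  # antisymmetry
  rev <- unpaired_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev$t, -tt$t)
  expect_equal(rev$p, tt$p)
  expect_error(unpaired_t(1, c(1, 2)), "n >= 2")
})

test_that("size-ranked binning drops the remainder and detects the size slope", {
  cells <- data.frame(cell_id = 1:250, nuclear_area = runif(250, 10, 100),
                      i53bp1 = rnorm(250, 50, 5))
  bp <- size_ranked_profile(cells, "i53bp1")
  expect_equal(nrow(bp$bins), 2)
  expect_equal(bp$n_dropped, 50)
  expect_true(all(diff(bp$bins$mean_area) > 0))
  expect_error(size_ranked_profile(cells[1:150, ], "i53bp1"), "2 full bins")
  # kappa > 0 defaults: positive slope detected at 12,000 cells
  set.seed(44)
  hits <- replicate(50, {
    cells <- make_cohort("AD", seed = sample.int(1e6, 1), n_cases = 1,
                         cells_per_case = 12000)
    bp <- size_ranked_profile(cells, "i53bp1")
    bp$slope > 0 && bp$slope_p < 0.05
  })
  expect_gte(mean(hits), 0.9)
  # kappa = 0: rejection near the nominal level
  set.seed(45)
  null_hits <- replicate(100, {
    cells <- make_cohort("AD", seed = sample.int(1e6, 1), n_cases = 1,
                         cells_per_case = 6000, size_slope = 0)
    size_ranked_profile(cells, "i53bp1")$slope_p < 0.05
  })
  expect_lt(mean(null_hits), 0.12)
})

test_that("coupling regression samples per case and honors the noise model", {
  cells <- make_cohort("AD", seed = 46)
  cr <- coupling_regression(cells, per_case_n = 100, seed = 2)
  expect_equal(cr$n, 400)
  expect_lt(abs(cr$r2 - 1 / (1 + 0.62^2)), 0.10)
  # zero-noise coupling, no depth term: exact line
  cells0 <- make_cohort("AD", seed = 47, coupling_noise_ratio = 0,
                        p16_depth_slope = 0)
  cr0 <- coupling_regression(cells0, per_case_n = 100, seed = 2)
  expect_equal(cr0$r2, 1, tolerance = 1e-9)
  # shortfall: all eligible cells used with a warning
  pos <- cells[cells$damage_positive, ]
  few <- do.call(rbind, lapply(split(pos, pos$case_id), utils::head, 60))
  expect_warning(cr60 <- coupling_regression(few, per_case_n = 100, seed = 3),
                 "using all")
  expect_equal(cr60$n, 4 * 60)
  # a case with no eligible cells errors with its name
  none <- cells
  none$damage_positive[none$case_id == "AD_case02"] <- FALSE
  expect_error(coupling_regression(none, seed = 1), "AD_case02")
  # determinism per seed
  expect_identical(coupling_regression(cells, seed = 2)$sampled_ids,
                   coupling_regression(cells, seed = 2)$sampled_ids)
})

test_that("subset intensity profiles separate positives from negatives", {
  # identical intensities everywhere: flat fit
  flat <- data.frame(case_id = "c1", condition = "AD",
                     zone = rep(1:6, each = 10),
                     damage_positive = rep(c(TRUE, FALSE), 30),
                     p16_nuclear = 5, p16_cytoplasmic = 2)
  sp <- subset_intensity_profiles(flat, "positive", "nuclear")
  expect_equal(unname(coef(sp$fit)[["b"]]), 0)
  # AD defaults: positive-subset nuclear slope positive and significant
  set.seed(48)
  hits <- replicate(60, {
    cells <- make_cohort("AD", seed = sample.int(1e6, 1))
    f <- subset_intensity_profiles(cells, "positive", "nuclear")$fit
    coef(f)[["b"]] > 0 && f$slope_p < 0.05
  })
  expect_gte(mean(hits), 0.9)
  # negative subset weaker than positive subset in every zone
  cells <- make_cohort("AD", seed = 49)
  mp <- subset_intensity_profiles(cells, "positive", "nuclear")$means
  mn <- subset_intensity_profiles(cells, "negative", "nuclear")$means
  agg <- function(m) tapply(m$mean_intensity, m$zone, mean, na.rm = TRUE)
  expect_true(all(agg(mn) < agg(mp)))
})

test_that("culture fractions aggregate by replicate and keep p27 damage-independent", {
  cu <- simulate_culture(culture_config(n_per_replicate = 1000), seed = 50)
  cf <- culture_fractions(cu)
  expect_equal(nrow(cf$fractions), 6) # 3 conditions x 2 markers
  expect_true(all(cf$fractions$n_replicates == 3))
  # all-negative table gives zero fractions
  cu0 <- cu
  cu0$gh2ax_positive <- FALSE
  cu0$p27_positive <- FALSE
  cf0 <- culture_fractions(cu0)
  expect_true(all(cf0$fractions$mean_fraction == 0))
  # single replicate: no SEM
  expect_error(culture_fractions(cu[cu$replicate_id == "control_rep1", ]),
               ">= 2 replicates")
  # 10 uM vs control strongly separated; p27 slope null respected
  set.seed(51)
  res <- replicate(100, {
    cu <- simulate_culture(culture_config(n_per_replicate = 1000),
                           seed = sample.int(1e6, 1))
    cf <- culture_fractions(cu)
    tt <- cf$tests
    sig <- tt$p[tt$marker == "gh2ax" & tt$group_a == "control" &
                  tt$group_b == "etop_10uM"] < 0.01
    p27_ns <- cf$coupling$slope_p[cf$coupling$condition == "etop_10uM"] > 0.05
    c(sig, p27_ns)
  })
  expect_gte(mean(res[1, ]), 0.95)
  expect_gte(mean(res[2, ]), 0.9)
})
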