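test_that("admin frame honours counts, nesting, and determinism", {
  cfg <- scenario_config(n_districts = 4, n_subdistricts = 10,
                         n_villages = 200, seed = 5)
  fr <- generate_admin_frame(cfg)
  expect_equal(nrow(fr), 200)
  expect_equal(dplyr::n_distinct(fr$district_id), 4)
  expect_equal(dplyr::n_distinct(fr$sub_district_id), 10)
  expect_false(anyDuplicated(fr$village_id) > 0)
  # each sub-district maps to exactly one district
  map <- dplyr::distinct(fr, sub_district_id, district_id)
  expect_equal(nrow(map), 10)
  expect_true(all(fr$area_km2 > 0))
  expect_identical(fr$log_area, log(fr$area_km2))
  expect_true(all(fr$sector %in% c("urban", "rural_estate")))
  expect_identical(fr, generate_admin_frame(cfg))
})

test_that("degenerate single-village hierarchy works", {
  cfg <- scenario_config(n_districts = 1, n_subdistricts = 1, n_villages = 1)
  fr <- generate_admin_frame(cfg)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$district_id, "D001")
  expect_equal(fr$sub_district_id, "S00001")
})

test_that("national-scale frame matches configured counts and urban share", {
  cfg <- scenario_preset("national")
  fr <- memo("national_frame", generate_admin_frame(cfg))
  expect_equal(nrow(fr), 13970)
  expect_equal(dplyr::n_distinct(fr$district_id), 25)
  expect_equal(dplyr::n_distinct(fr$sub_district_id), 331)
  expect_lt(abs(mean(fr$sector == "urban") - 0.092), 0.02)
})

test_that("covariates respect bounds, degenerate specs, and copula correlation", {
  w <- desk_world()
  expect_true(all(w$covars$built_up >= 0 & w$covars$built_up <= 100))
  expect_true(all(w$covars$tree_cover >= 0 & w$covars$tree_cover <= 100))

  # zero-variance marginal gives a constant column
  cfg0 <- scenario_config(
    covariates = list(flat = list(family = "normal", mean = 3, sd = 0)),
    correlation = matrix(1, 1, 1, dimnames = list("flat", "flat")),
    true_beta = c(flat = 0))
  fr0 <- generate_admin_frame(cfg0)
  cv0 <- generate_covariates(fr0, cfg0)
  expect_true(all(cv0$flat == 3))

  # empirical rank correlation approaches the copula-implied value:
  # for Gaussian copula, spearman = (6/pi) asin(r/2)
  cfg2 <- scenario_config(
    n_villages = 10000, n_subdistricts = 50, n_districts = 8,
    urban_fraction = 0,
    covariates = list(a = list(family = "lognormal", meanlog = 0, sdlog = 1),
                      b = list(family = "normal", mean = 0, sd = 1)),
    correlation = matrix(c(1, .6, .6, 1), 2,
                         dimnames = list(c("a", "b"), c("a", "b"))),
    true_beta = c(a = 0, b = 0), seed = 17)
  fr2 <- generate_admin_frame(cfg2)
  cv2 <- generate_covariates(fr2, cfg2)
  implied <- (6 / pi) * asin(0.6 / 2)
  expect_lt(abs(cor(cv2$a, cv2$b, method = "spearman") - implied), 0.05)

  # non-PSD correlation is rejected at validation time
  bad <- matrix(c(1, .99, .99, .99, 1, -.99, .99, -.99, 1), 3)
  dimnames(bad) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_error(
    scenario_config(
      covariates = list(a = list(family = "normal", mean = 0, sd = 1),
                        b = list(family = "normal", mean = 0, sd = 1),
                        c = list(family = "normal", mean = 0, sd = 1)),
      correlation = bad, true_beta = c(a = 0, b = 0, c = 0)),
    class = "bottomup_config_error")
})

test_that("census matches the log-linear mean exactly when noiseless", {
  cfg <- scenario_config(
    n_villages = 50, n_subdistricts = 5, n_districts = 2,
    true_alpha = log(100), true_beta = setNames(rep(0, 5),
                                                names(default_true_beta())),
    true_gamma = c(urban = 0, log_area = 0), district_effect_sd = 0,
    noise = "none")
  fr <- generate_admin_frame(cfg)
  cv <- generate_covariates(fr, cfg)
  cen <- generate_census(fr, cv, cfg)
  expect_equal(cen$mu, rep(100, 50))
  # counts are integers and density is population/area to full precision
  expect_true(all(cen$population == round(cen$population)))
  expect_equal(cen$density, cen$population / fr$area_km2)
  expect_equal(cen$population, as.integer(round(100 * fr$area_km2)))
})

test_that("poisson census noise has the configured mean (Monte-Carlo oracle)", {
  # one village, mu = 500 /km2, area = 2 km2, 2000 replicate censuses
  cfg <- scenario_config(
    n_villages = 1, n_subdistricts = 1, n_districts = 1, urban_fraction = 0,
    area_meanlog = log(2), area_sdlog = 0, area_log_range = c(log(2), log(2)),
    true_alpha = log(500),
    true_beta = setNames(rep(0, 5), names(default_true_beta())),
    true_gamma = c(urban = 0, log_area = 0), district_effect_sd = 0)
  fr <- generate_admin_frame(cfg)
  cv <- generate_covariates(fr, cfg)
  reps <- vapply(seq_len(2000), function(s) {
    generate_census(fr, cv, cfg, seed = s)$density
  }, numeric(1))
  se <- sqrt(500 / (2^2 * 2000) * 2)  # var(density) = mu*area/area^2 = mu/area
  expect_lt(abs(mean(reps) - 500), 3 * se)
})

test_that("default national census densities are right-skewed with sd > mean", {
  cfg <- scenario_preset("national")
  fr <- memo("national_frame", generate_admin_frame(cfg))
  cv <- memo("national_covars", generate_covariates(fr, cfg))
  cen <- memo("national_census", generate_census(fr, cv, cfg))
  expect_gt(sd(cen$density), mean(cen$density))
  expect_gt(mean(cen$density), median(cen$density))  # right skew
  expect_lt(abs(mean(cen$density) - 1400) / 1400, 0.25)
})

test_that("census hierarchy totals are conserved downstream", {
  w <- desk_world()
  by_sub <- tapply(w$census$population, w$frame$sub_district_id, sum)
  expect_equal(sum(by_sub), sum(w$census$population))
  by_dist <- tapply(w$census$population, w$frame$district_id, sum)
  expect_equal(sum(by_dist), sum(w$census$population))
})

test_that("linear-predictor overflow names the offending village", {
  cfg <- scenario_config(n_villages = 10, n_subdistricts = 2, n_districts = 1,
                         true_alpha = 40, noise = "none")
  fr <- generate_admin_frame(cfg)
  cv <- generate_covariates(fr, cfg)
  expect_error(generate_census(fr, cv, cfg), "V0000",
               class = "bottomup_data_error")
})
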