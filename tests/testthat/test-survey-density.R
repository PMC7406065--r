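test_that("full enumeration with share-1 PSUs reproduces census density exactly", {
  cfg <- scenario_config(n_villages = 25, n_subdistricts = 2, n_districts = 1,
                         true_alpha = 4, seed = 3)
  fr <- generate_admin_frame(cfg)
  cv <- generate_covariates(fr, cfg)
  cen <- generate_census(fr, cv, cfg)
  des <- survey_design(sample_fraction = 1, extra_psu_fraction = 0,
                       households_per_psu = 10^6, households_per_block = 10^6)
  s <- draw_survey(fr, cv, cen, des)
  d <- estimate_village_density(s, fr)
  expect_true(all(d$included))
  expect_equal(d$hies_density,
               cen$density[match(d$village_id, cen$village_id)])
  expect_equal(survey_census_concordance(d, cen), 1.0)
})

test_that("the estimator is plain arithmetic: PSU estimate / share / area", {
  # PSU estimate 600 persons, share 0.5, area 2 km2 -> density 600 /km2
  s <- structure(list(
    households = tibble::tibble(
      household_id = c("h1", "h2"), village_id = "v1", psu_id = "v1.P001",
      household_size = c(4L, 2L), design_weight = 100),
    psus = tibble::tibble(
      psu_id = "v1.P001", village_id = "v1", psu_census_population = 600,
      psu_census_share = 0.5, psu_selection_prob = 1),
    villages = tibble::tibble(village_id = "v1", stratum = "D1.rural_estate",
                              pi_village = 1, n_psus_sampled = 1L)
  ), class = "survey_sample")
  fr <- tibble::tibble(village_id = "v1", area_km2 = 2)
  d <- estimate_village_density(s, fr)
  expect_equal(d$hies_density, 600)  # (100*6) / 0.5 / 2

  # doubling the area halves the density (scale equivariance)
  fr2 <- tibble::tibble(village_id = "v1", area_km2 = 4)
  expect_equal(estimate_village_density(s, fr2)$hies_density, 300)
})

test_that("multi-PSU villages are flagged excluded and carry no density", {
  w <- desk_world()
  s <- draw_survey(w$frame, w$covars, w$census,
                   survey_design(extra_psu_fraction = 0.25), seed = 12)
  d <- estimate_village_density(s, w$frame)
  multi <- d[d$n_psus_sampled > 1, ]
  expect_gt(nrow(multi), 0)
  expect_true(all(!multi$included))
  expect_true(all(is.na(multi$hies_density)))
  expect_true(all(d$hies_density[d$included] > 0))
  # excluded fraction equals the multi-PSU fraction in the sample
  expect_equal(mean(!d$included), mean(s$villages$n_psus_sampled > 1))
})

test_that("share and frame errors are raised", {
  s <- structure(list(
    households = tibble::tibble(household_id = "h", village_id = "v1",
                                psu_id = "p", household_size = 4L,
                                design_weight = 1),
    psus = tibble::tibble(psu_id = "p", village_id = "v1",
                          psu_census_population = 4, psu_census_share = 0,
                          psu_selection_prob = 1),
    villages = tibble::tibble(village_id = "v1", stratum = "s",
                              pi_village = 1, n_psus_sampled = 1L)
  ), class = "survey_sample")
  fr <- tibble::tibble(village_id = "v1", area_km2 = 1)
  expect_error(estimate_village_density(s, fr), class = "bottomup_data_error")
  s$psus$psu_census_share <- 0.5
  expect_error(estimate_village_density(s, tibble::tibble(village_id = "zz",
                                                          area_km2 = 1)),
               class = "bottomup_data_error")
})

test_that("concordance matches the analytic attenuation under added noise", {
  # estimates = census + independent noise => rho = sd_y / sqrt(sd_y^2 + sd_e^2)
  withr::with_seed(21, {
    n <- 1000
    y <- rnorm(n, 1000, 300)
    sd_e <- 300
    est <- tibble::tibble(village_id = sprintf("v%04d", 1:n),
                          hies_density = pmax(y + rnorm(n, 0, sd_e), 0.1),
                          n_psus_sampled = 1L, included = TRUE)
    cen <- tibble::tibble(village_id = est$village_id, density = y)
    rho <- survey_census_concordance(est, cen)
    expected <- sd(y) / sqrt(sd(y)^2 + sd_e^2)
    expect_lt(abs(rho - expected), 0.03)
  })
})

test_that("concordance is high under the default two-stage design", {
  w <- desk_world()
  rho <- vapply(1:5, function(r) {
    s <- draw_survey(w$frame, w$covars, w$census, survey_design(),
                     seed = 600 + r)
    survey_census_concordance(estimate_village_density(s, w$frame), w$census)
  }, numeric(1))
  expect_gt(min(rho), 0.85)
})

test_that("concordance input validation works", {
  est <- tibble::tibble(village_id = c("a", "b"), hies_density = c(1, 2),
                        n_psus_sampled = 1L, included = TRUE)
  cen <- tibble::tibble(village_id = c("a", "b"), density = c(1, 2))
  expect_error(survey_census_concordance(est, cen),
               class = "bottomup_data_error")
  est3 <- tibble::tibble(village_id = c("a", "b", "c"),
                         hies_density = c(2, 2, 2),
                         n_psus_sampled = 1L, included = TRUE)
  cen3 <- tibble::tibble(village_id = c("a", "b", "c"), density = c(1, 2, 3))
  expect_error(survey_census_concordance(est3, cen3),
               class = "bottomup_data_error")
})
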