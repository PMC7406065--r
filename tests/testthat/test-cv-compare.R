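test_that("direct CV is zero without dispersion and matches hand arithmetic", {
  fr <- tibble::tibble(village_id = c("a", "b", "c", "d"),
                       sub_district_id = c("s1", "s1", "s2", "s2"))
  est <- tibble::tibble(village_id = fr$village_id,
                        hies_density = c(150, 150, 100, 300),
                        n_psus_sampled = 1L, included = TRUE)
  out <- direct_cv(est, fr)
  expect_equal(out$cv[out$sub_district_id == "s1"], 0)
  # two villages, equal weights, 100 and 300: var = s^2/n = 20000/2
  s2 <- out[out$sub_district_id == "s2", ]
  expect_equal(s2$estimate, 200)
  expect_equal(s2$variance, 10000)
  expect_equal(s2$cv, 50)
})

test_that("single-village sub-districts are flagged undefined", {
  fr <- tibble::tibble(village_id = c("a", "b", "c"),
                       sub_district_id = c("s1", "s2", "s2"))
  est <- tibble::tibble(village_id = fr$village_id,
                        hies_density = c(100, 100, 200),
                        n_psus_sampled = 1L, included = TRUE)
  out <- direct_cv(est, fr)
  expect_false(out$defined[out$sub_district_id == "s1"])
  expect_true(out$defined[out$sub_district_id == "s2"])
})

test_that("direct variances match a survey bootstrap oracle", {
  w <- desk_world()
  s <- draw_survey(w$frame, w$covars, w$census,
                   survey_design(extra_psu_fraction = 0), seed = 5)
  d <- estimate_village_density(s, w$frame)
  vw <- tibble::tibble(village_id = s$villages$village_id,
                       w = 1 / s$villages$pi_village)
  dc <- direct_cv(d, w$frame, vw)
  inc <- d[d$included, ]
  sd_id <- w$frame$sub_district_id[match(inc$village_id, w$frame$village_id)]
  ww <- vw$w[match(inc$village_id, vw$village_id)]
  withr::with_seed(9, {
    boot_var <- vapply(unique(sd_id), function(ss) {
      idx <- which(sd_id == ss)
      n <- length(idx)
      if (n < 2) return(NA_real_)
      reps <- replicate(1000, {
        b <- sample(idx, n, replace = TRUE)
        sum(ww[b] * inc$hies_density[b]) / sum(ww[b])
      })
      var(reps) * n / (n - 1)  # Rao-Wu rescaling
    }, numeric(1))
  })
  ana <- dc$variance[match(unique(sd_id), dc$sub_district_id)]
  ok <- !is.na(boot_var) & !is.na(ana)
  expect_gt(sum(ok), 20)
  expect_lt(abs(sum(ana[ok]) / sum(boot_var[ok]) - 1), 0.15)
  expect_lt(median(abs(ana[ok] - boot_var[ok]) / boot_var[ok]), 0.15)
})

test_that("model CV is zero for a zero covariance and matches the
           intercept-only closed form", {
  n <- 60
  fr <- tibble::tibble(village_id = sprintf("v%02d", 1:n), district_id = "D1",
                       sub_district_id = rep(c("s1", "s2", "s3"), each = n / 3),
                       sector = "rural_estate", area_km2 = 1, log_area = 0)
  y <- withr::with_seed(3, rpois(n, 150))
  fit <- fit_poisson_irls(matrix(nrow = n, ncol = 0), y,
                          cluster = fr$sub_district_id)
  dsg <- structure(list(x = matrix(0, n, 1, dimnames = list(NULL, "z")),
                        village_id = fr$village_id,
                        cluster = fr$sub_district_id),
                   class = "density_design")
  m <- structure(list(coefficients = fit$coefficients, vcov = fit$vcov,
                      selected = character(0)), class = "density_model")
  mc <- model_cv(m, dsg, fr)
  # delta method for exp(a): var = exp(a)^2 var(a); CV = 100 sqrt(var(a))
  expect_equal(mc$cv, rep(100 * sqrt(fit$vcov[1, 1]), 3))

  m0 <- m
  m0$vcov <- matrix(0, 1, 1, dimnames = list("(Intercept)", "(Intercept)"))
  expect_equal(model_cv(m0, dsg, fr)$cv, rep(0, 3))

  m_null <- m
  m_null$vcov <- NULL
  expect_error(model_cv(m_null, dsg, fr), class = "bottomup_usage_error")
})

test_that("model-based precision beats the direct survey estimator on the
           default scenario", {
  run <- desk_run()
  g <- glance(run$cv_report)
  expect_lt(g$mean_model_cv, g$mean_direct_cv)
  expect_gt(g$n_subdistricts, 30)
  # summary mean equals the arithmetic mean over defined sub-districts
  tb <- tibble::as_tibble(run$cv_report)
  usable <- tb[tb$defined & !is.na(tb$model_cv), ]
  expect_equal(g$mean_direct_cv, mean(usable$direct_cv))
  expect_true(all(tb$direct_cv[tb$defined] >= 0))
})
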