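# lambda choice by cross-validation, post-LASSO refit, probit correction

test_that("a single-candidate grid is returned as lambda_star", {
  inst <- tiny_instance(n = 40, p = 3, seed = 1)
  path <- lasso_path(inst$design, inst$y, inst$w, n_lambda = 10)
  cv <- select_lambda_cv(inst$design, inst$y, inst$w, k = 4, seed = 2,
                         path = NULL, lambda = path$lambda[5])
  expect_equal(cv$lambda_star, path$lambda[5])
})

test_that("lambda_star is deterministic and invariant to row order", {
  inst <- tiny_instance(n = 60, p = 4, seed = 3)
  cv1 <- select_lambda_cv(inst$design, inst$y, inst$w, k = 5, seed = 9)
  cv2 <- select_lambda_cv(inst$design, inst$y, inst$w, k = 5, seed = 9)
  expect_equal(cv1$lambda_star, cv2$lambda_star)
  perm <- withr::with_seed(1, sample(length(inst$y)))
  dperm <- subset_design(inst$design, perm)
  cv3 <- select_lambda_cv(dperm, inst$y[perm], inst$w[perm], k = 5, seed = 9,
                          lambda = cv1$path$lambda)
  expect_equal(cv3$lambda_star, cv1$lambda_star)
})

test_that("cross-validation prefers sparser models over the densest fit under
           pure-noise covariates", {
  wins <- 0
  for (r in 1:15) {
    inst <- withr::with_seed(100 + r, {
      n <- 300
      frame <- tibble::tibble(
        village_id = sprintf("v%03d", 1:n),
        district_id = rep(c("D1", "D2"), each = n / 2),
        sub_district_id = sprintf("S%d", rep_len(1:10, n)),
        sector = sample(c("urban", "rural_estate"), n, TRUE),
        area_km2 = exp(rnorm(n, 1, 0.4)))
      frame$log_area <- log(frame$area_km2)
      x <- matrix(rnorm(n * 13), n, 13)
      colnames(x) <- paste0("x", 1:13)
      eta <- 2 + 0.6 * x[, 1] - 0.5 * x[, 2] + 0.4 * x[, 3] -
        0.3 * frame$log_area
      y <- exp(eta + rnorm(n, 0, 0.4))
      covars <- dplyr::bind_cols(tibble::tibble(village_id = frame$village_id),
                                 tibble::as_tibble(x))
      list(design = build_design_matrix(frame, covars), y = y)
    })
    cv <- select_lambda_cv(inst$design, inst$y, k = 5, seed = r,
                           n_lambda = 40)
    rmse_star <- cv$cv$mean_rmse[cv$cv$lambda == cv$lambda_star]
    rmse_min <- cv$cv$mean_rmse[length(cv$path$lambda)]
    wins <- wins + (rmse_star <= rmse_min)
  }
  expect_gte(wins, 12)  # >= 80%
})

test_that("post-LASSO equals the forced-only fit when nothing is selected", {
  inst <- tiny_instance(n = 50, p = 3, seed = 5)
  path <- lasso_path(inst$design, inst$y, inst$w, n_lambda = 5)
  expect_message(
    m <- post_lasso_fit(inst$design, inst$y, inst$w,
                        lambda_star = path$lambda[1], path = path),
    "no covariates")
  forced <- fit_poisson_irls(
    inst$design$x[, !inst$design$penalized, drop = FALSE], inst$y, inst$w)
  expect_equal(coef(m)[names(coef(forced))], coef(forced), tolerance = 1e-9)
  expect_equal(length(m$selected), 0)
})

test_that("post-LASSO coefficients equal the reduced-design IRLS fit exactly", {
  inst <- tiny_instance(n = 60, p = 4, seed = 6)
  cv <- select_lambda_cv(inst$design, inst$y, inst$w, k = 5, seed = 3)
  m <- post_lasso_fit(inst$design, inst$y, inst$w, cv$lambda_star, cv$path)
  reduced <- fit_poisson_irls(
    inst$design$x[, m$support, drop = FALSE], inst$y, inst$w)
  expect_equal(coef(m), coef(reduced))
  # support is selected + forced + intercept, nothing else
  expect_setequal(names(coef(m)),
                  c("(Intercept)", m$selected,
                    names(which(!inst$design$penalized))))
  # lambda_star off the path is an error
  expect_error(post_lasso_fit(inst$design, inst$y, inst$w,
                              lambda_star = 123.4, path = cv$path),
               class = "bottomup_usage_error")
})

test_that("noiseless two-step recovers the truth; raw path coefficients are
           shrunk toward zero", {
  w <- desk_world()
  cfg <- scenario_config(noise = "none")
  cen <- generate_census(w$frame, w$covars, cfg)
  dsg <- build_design_matrix(w$frame, w$covars)
  cv <- select_lambda_cv(dsg, cen$mu, k = 5, seed = 4)
  m <- post_lasso_fit(dsg, cen$mu, lambda_star = cv$lambda_star, path = cv$path)
  truth <- c(cfg$true_beta[cfg$true_beta != 0],
             urban = unname(cfg$true_gamma["urban"]),
             log_area = unname(cfg$true_gamma["log_area"]))
  est <- coef(m)[names(truth)]
  expect_lt(max(abs(est - truth)), 1e-3)
  # shrinkage: raw path coefficients at lambda* sit between 0 and the truth
  idx <- which(cv$path$lambda == cv$lambda_star)
  raw <- cv$path$coefficients[idx, names(cfg$true_beta[cfg$true_beta != 0])]
  tr <- cfg$true_beta[cfg$true_beta != 0]
  expect_true(all(sign(raw) == sign(tr)))
  expect_true(all(abs(raw) <= abs(tr) + 1e-6))
})

test_that("probit selection model recovers generating coefficients", {
  withr::with_seed(31, {
    n <- 5000
    x <- cbind(a = rnorm(n), b = rnorm(n))
    p <- pnorm(-1 + 0.8 * x[, "a"] - 0.5 * x[, "b"])
    ins <- runif(n) < p
    sm <- fit_selection_probit(as.data.frame(x), ins)
    est <- c(sm$eta0, sm$eta1)
    expect_lt(sqrt(mean((est - c(-1, 0.8, -0.5))^2)), 0.1)
    expect_true(all(sm$fitted > 0 & sm$fitted < 1))
  })
})

test_that("probit slopes are null-consistent when selection is uniform", {
  hits <- 0
  for (r in 1:20) {
    withr::with_seed(700 + r, {
      n <- 2000
      x <- cbind(a = rnorm(n))
      ins <- runif(n) < 0.2
      sm <- fit_selection_probit(as.data.frame(x), ins)
      ci <- confint.default(sm$glm_fit)["a", ]
      hits <- hits + (ci[1] <= 0 && 0 <= ci[2])
    })
  }
  expect_gte(hits, 18)  # 95% CI covers 0 in >= 90% of replicates
})

test_that("selection model failure modes raise data errors", {
  expect_error(fit_selection_probit(data.frame(a = rnorm(10)), rep(TRUE, 10)),
               class = "bottomup_data_error")
  # complete separation
  x <- data.frame(a = c(rep(-2, 30), rep(2, 30)))
  ins <- c(rep(FALSE, 30), rep(TRUE, 30))
  expect_error(fit_selection_probit(x, ins), "p_floor",
               class = "bottomup_data_error")
})

test_that("weight schemes follow the printed formulas and the floor", {
  expect_equal(compute_weights(c(v1 = 1), "uniform")$w, 1)
  expect_equal(compute_weights(c(v1 = 500), "inverse_pop")$w, 1 / 500)
  sel <- structure(list(fitted = c(v1 = 0.5, v2 = 0.001)),
                   class = "selection_model")
  w <- compute_weights(c(v1 = 500, v2 = 100), "balance_corrected",
                       selection = sel, p_floor = 0.01)
  expect_equal(w$w, c(1 / (500 * 0.5), 1 / (100 * 0.01)))
  expect_equal(attr(w, "n_floored"), 1L)
  expect_error(compute_weights(c(v1 = 0), "inverse_pop"),
               class = "bottomup_data_error")
  expect_error(compute_weights(c(v1 = 1), "balance_corrected"),
               class = "bottomup_usage_error")
  expect_error(compute_weights(c(v1 = 1), "inverse_pop", selection = sel),
               class = "bottomup_usage_error")
})

test_that("predictions are positive, exact arithmetic, and order-invariant", {
  inst <- tiny_instance(n = 30, p = 2, seed = 15)
  cv <- select_lambda_cv(inst$design, inst$y, k = 5, seed = 1, n_lambda = 20)
  m <- post_lasso_fit(inst$design, inst$y, lambda_star = cv$lambda_star,
                      path = cv$path)
  pred <- predict_density(m, inst$design)
  expect_true(all(pred$density_pred > 0))
  # hand-computed eta for one village
  co <- coef(m)
  eta1 <- co[["(Intercept)"]] +
    sum(co[setdiff(names(co), "(Intercept)")] *
          inst$design$x[1, setdiff(names(co), "(Intercept)")])
  expect_equal(pred$density_pred[1], exp(eta1))
  # row order does not matter
  perm <- rev(seq_len(30))
  pred2 <- predict_density(m, subset_design(inst$design, perm))
  expect_equal(pred2$density_pred, pred$density_pred[perm])
  # missing support column is a schema error
  d_bad <- inst$design
  d_bad$x <- d_bad$x[, setdiff(colnames(d_bad$x), "log_area")]
  expect_error(predict_density(m, d_bad), "log_area",
               class = "bottomup_data_error")
})

test_that("intercept-only model predicts a constant density", {
  m <- structure(list(coefficients = c("(Intercept)" = log(1000))),
                 class = "density_model")
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict_density(m, x)$density_pred, rep(1000, 10))
})
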