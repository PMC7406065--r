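# Shared fixtures, built in code. Heavier objects are memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# a small random regression instance with forced + penalized columns
tiny_instance <- function(n = 40, p = 3, seed = 1, n_districts = 2) {
  withr::with_seed(seed, {
    frame <- tibble::tibble(
      village_id = sprintf("v%03d", seq_len(n)),
      district_id = sprintf("D%d", rep_len(seq_len(n_districts), n)),
      sub_district_id = sprintf("S%d", rep_len(seq_len(max(4, n %/% 5)), n)),
      sector = sample(c("urban", "rural_estate"), n, replace = TRUE),
      area_km2 = exp(rnorm(n, 1, 0.5))
    )
    frame$log_area <- log(frame$area_km2)
    covars <- tibble::as_tibble(
      setNames(as.data.frame(matrix(rnorm(n * p), n, p)),
               paste0("x", seq_len(p))))
    covars <- dplyr::bind_cols(tibble::tibble(village_id = frame$village_id),
                               covars)
    eta <- 1 + 0.5 * covars$x1 - 0.3 * frame$log_area +
      0.4 * (frame$sector == "urban")
    y <- exp(eta + rnorm(n, 0, 0.3))
    w <- runif(n, 0.5, 2)
    list(frame = frame, covars = covars, y = y, w = w,
         design = build_design_matrix(frame, covars))
  })
}

# independent generic-optimizer value for the penalized objective on the
# standardized scale used by lasso_path (BFGS polished, NM from zero)
oracle_pen_objective <- function(design, y, w, lambda_value, path) {
  n <- length(y)
  v <- (w / mean(w)) / n
  pen <- design$penalized
  xs <- design$x
  for (j in which(pen)) {
    m <- sum(v * xs[, j]) / sum(v)
    s <- sqrt(sum(v * (xs[, j] - m)^2))
    xs[, j] <- (xs[, j] - m) / s
  }
  obj <- function(par) {
    eta <- par[1] + drop(xs %*% par[-1])
    -sum(v * (y * eta - exp(pmin(eta, 300)))) +
      lambda_value * sum(abs(par[-1][pen]))
  }
  p <- ncol(xs)
  o_nm <- optim(rep(0, p + 1), obj, method = "Nelder-Mead",
                control = list(maxit = 50000, reltol = 1e-14))
  # polish with BFGS (non-smooth, but fine away from kinks)
  o_bfgs <- tryCatch(
    optim(o_nm$par, obj, method = "BFGS",
          control = list(maxit = 2000, reltol = 1e-14)),
    error = function(e) o_nm)
  min(o_nm$value, o_bfgs$value)
}

# desk-scale scenario shared across files
desk_world <- function() {
  memo("desk_world", {
    cfg <- scenario_config()
    frame <- generate_admin_frame(cfg)
    covars <- generate_covariates(frame, cfg)
    census <- generate_census(frame, covars, cfg)
    list(config = cfg, frame = frame, covars = covars, census = census)
  })
}

desk_run <- function() {
  memo("desk_run", run_experiment(seed = 101))
}
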