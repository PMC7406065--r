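#' Generate the administrative village frame
#'
#' Builds the nested hierarchy district > sub-district > village, assigns
#' each village a sector (urban vs rural/estate, the collapsed two-level
#' coding) and a log-normal area in km2. Every district receives at least
#' one sub-district and every sub-district at least one village; remaining
#' units are allocated at random with equal expected shares.
#'
#' @param config A [scenario_config()].
#' @param seed Optional override of the admin-stage child seed.
#' @return A tibble with columns `village_id`, `district_id`,
#'   `sub_district_id`, `sector` (`"urban"` or `"rural_estate"`),
#'   `area_km2`, `log_area`.
#' @examples
#' frame <- generate_admin_frame(scenario_config(n_villages = 200,
#'                                               n_subdistricts = 10,
#'                                               n_districts = 4))
#' dplyr::count(frame, district_id)
#' @export
generate_admin_frame <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- seed %||% scenario_child_seed(config, "admin")
  nd <- config$n_districts
  ns <- config$n_subdistricts
  nv <- config$n_villages
  withr::with_seed(as.integer(seed), {
    sub_to_dist <- allocate_nested(ns, nd)
    vil_to_sub <- allocate_nested(nv, ns)
    sector <- ifelse(runif(nv) < config$urban_fraction, "urban", "rural_estate")
    # truncated lognormal area via inverse-cdf sampling
    if (config$area_sdlog == 0) {
      area <- rep(exp(config$area_meanlog), nv)
    } else {
      lo <- pnorm(config$area_log_range[1], config$area_meanlog, config$area_sdlog)
      hi <- pnorm(config$area_log_range[2], config$area_meanlog, config$area_sdlog)
      area <- exp(qnorm(lo + runif(nv) * (hi - lo),
                        config$area_meanlog, config$area_sdlog))
    }
    tibble::tibble(
      village_id = sprintf("V%06d", seq_len(nv)),
      district_id = sprintf("D%03d", sub_to_dist[vil_to_sub]),
      sub_district_id = sprintf("S%05d", vil_to_sub),
      sector = sector,
      area_km2 = area,
      log_area = log(area)
    )
  })
}

# assign n children to m parents, each parent non-empty, extras uniform
allocate_nested <- function(n, m) {
  base <- seq_len(m)
  extra <- if (n > m) sample.int(m, n - m, replace = TRUE) else integer(0)
  sort(c(base, extra))
}

#' Generate geospatial covariates via a Gaussian copula
#'
#' One row per village. Each covariate's marginal family is taken from the
#' configuration; dependence follows the configured copula correlation.
#' `logitnormal` covariates are bounded in \[0, 100\] (percent-style layers
#' such as built-up area or tree cover). Urban villages receive the
#' configured latent-scale shifts, so the sector label is informative about
#' the covariate surface.
#'
#' @inheritParams generate_admin_frame
#' @param frame Village frame from [generate_admin_frame()].
#' @return A tibble with `village_id` plus one numeric column per covariate.
#' @export
generate_covariates <- function(frame, config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  check_cols(frame, c("village_id", "sector"), "frame")
  validate_covariate_spec(config$covariates, config$correlation)
  seed <- seed %||% scenario_child_seed(config, "covariates")
  n <- nrow(frame)
  spec <- config$covariates
  p <- length(spec)
  withr::with_seed(as.integer(seed), {
    z <- matrix(rnorm(n * p), n, p)
    # PSD (possibly singular) correlation: use eigen square root
    es <- eigen(config$correlation, symmetric = TRUE)
    rt <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
    z <- z %*% rt
    urban <- frame$sector == "urban"
    out <- tibble::tibble(village_id = frame$village_id)
    for (j in seq_len(p)) {
      nm <- names(spec)[j]
      s <- spec[[j]]
      zj <- z[, j] + (s$urban_shift %||% 0) * urban
      out[[nm]] <- switch(s$family,
        lognormal = exp(s$meanlog + s$sdlog * zj),
        logitnormal = 100 * stats::plogis(s$mu + s$sigma * zj),
        normal = s$mean + s$sd * zj
      )
    }
    out
  })
}

#' Generate a census from the log-linear density model
#'
#' The expected density of village `v` is
#' `mu_v = exp(alpha + beta' x_v + gamma_urban urban_v +
#' gamma_log_area log(area_v) + u_d(v))` with district effects
#' `u_d ~ N(0, district_effect_sd^2)`. The census count is drawn as
#' `Poisson(mu_v * area_v)` (or negative binomial with dispersion `theta`),
#' or deterministically rounded when `noise = "none"`.
#'
#' @inheritParams generate_covariates
#' @param covariates Covariate table from [generate_covariates()].
#' @return A tibble with columns `village_id`, `population` (integer),
#'   `density` (`population / area_km2`), and `mu` (the noiseless expected
#'   density, useful for oracle checks).
#' @export
generate_census <- function(frame, covariates, config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  check_cols(frame, c("village_id", "sector", "area_km2", "log_area"), "frame")
  check_cols(covariates, c("village_id", names(config$true_beta)), "covariates")
  if (!identical(frame$village_id, covariates$village_id)) {
    covariates <- covariates[match(frame$village_id, covariates$village_id), ]
    if (anyNA(covariates$village_id)) {
      abort_data("`covariates` does not cover every village in `frame`.")
    }
  }
  seed <- seed %||% scenario_child_seed(config, "census")
  beta <- config$true_beta
  x <- as.matrix(covariates[names(beta)])
  withr::with_seed(as.integer(seed), {
    u <- rnorm(config$n_districts, 0, config$district_effect_sd)
    names(u) <- sprintf("D%03d", seq_len(config$n_districts))
    eta <- config$true_alpha + drop(x %*% beta) +
      config$true_gamma[["urban"]] * (frame$sector == "urban") +
      config$true_gamma[["log_area"]] * frame$log_area +
      unname(u[frame$district_id])
    bad <- which(abs(eta) > 30)
    if (length(bad)) {
      abort_data(sprintf(
        "Linear predictor overflow (|eta| > 30) for village(s): %s.",
        paste(head(frame$village_id[bad], 5), collapse = ", ")))
    }
    mu <- exp(eta)
    lambda <- mu * frame$area_km2
    pop <- switch(config$noise,
      none = round(lambda),
      poisson = rpois(length(lambda), lambda),
      negbin = rnbinom(length(lambda), size = config$negbin_theta, mu = lambda)
    )
    tibble::tibble(
      village_id = frame$village_id,
      population = as.integer(pop),
      density = pop / frame$area_km2,
      mu = mu
    )
  })
}

#' District effects used by [generate_census()]
#'
#' Recomputes the district random effects for a configuration (they are a
#' deterministic function of the census child seed), so downstream checks
#' can reconstruct the exact generating linear predictor.
#'
#' @inheritParams generate_admin_frame
#' @return Named numeric vector of district effects.
#' @export
true_district_effects <- function(config, seed = NULL) {
  seed <- seed %||% scenario_child_seed(config, "census")
  withr::with_seed(as.integer(seed), {
    u <- rnorm(config$n_districts, 0, config$district_effect_sd)
    names(u) <- sprintf("D%03d", seq_len(config$n_districts))
    u
  })
}
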