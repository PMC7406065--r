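#' Scenario configuration for the synthetic national frame
#'
#' A `scenario_config` bundles everything needed to simulate an admin frame,
#' geospatial covariates, and a census under the log-linear density model
#' `E(density_v) = exp(alpha + beta' x_v + gamma_urban * urban_v +
#' gamma_log_area * log(area_v) + u_district)`. The defaults are sized for
#' desk-scale work (1,000 villages, 50 sub-districts); the `"national"`
#' preset matches a 25-district / 331-sub-district / 13,970-village country
#' with mean density around 1,400 persons per km2 and a 9% urban share.
#'
#' Covariate marginals are specified per column as one of:
#' * `lognormal` — params `meanlog`, `sdlog` (right-skewed, e.g. night lights);
#' * `logitnormal` — params `mu`, `sigma`; values bounded in \[0, 100\]
#'   (e.g. built-up or tree-cover percentages);
#' * `normal` — params `mean`, `sd`.
#'
#' Dependence between covariates is induced by a Gaussian copula with the
#' given correlation matrix. An optional `urban_shift` per covariate moves
#' the latent Gaussian for urban villages, so urban areas are brighter and
#' more built-up than rural ones.
#'
#' @param n_districts,n_subdistricts,n_villages Hierarchy sizes; must satisfy
#'   `n_districts <= n_subdistricts <= n_villages`.
#' @param urban_fraction Expected share of villages labelled urban.
#' @param area_meanlog,area_sdlog Log-normal parameters of village area (km2).
#' @param area_log_range Truncation bounds for log area (defaults to the
#'   observed national range, 0.04-6.35, i.e. about 1 to 570 km2);
#'   truncation keeps implausibly tiny villages out of the density tail.
#' @param covariates Named list of marginal specifications (see Details).
#' @param correlation Correlation matrix of the Gaussian copula (unit
#'   diagonal, positive semi-definite), dimnames matching `covariates`.
#' @param true_alpha Intercept of the log-density model.
#' @param true_beta Named vector of covariate coefficients; names must match
#'   `covariates` exactly.
#' @param true_gamma Named vector with elements `urban` and `log_area`.
#' @param district_effect_sd Standard deviation of mean-zero district effects.
#' @param noise Census noise model: `"poisson"`, `"negbin"` (requires
#'   `negbin_theta > 0`), or `"none"` (deterministic rounding).
#' @param negbin_theta Dispersion parameter for `"negbin"` noise.
#' @param seed Integer seed; all generators derive their streams from it.
#' @return An object of class `scenario_config` (a named list).
#' @seealso [scenario_preset()], [generate_admin_frame()],
#'   [generate_covariates()], [generate_census()]
#' @export
scenario_config <- function(n_districts = 8,
                            n_subdistricts = 50,
                            n_villages = 1000,
                            urban_fraction = 0.09,
                            area_meanlog = 1.25,
                            area_sdlog = 0.81,
                            area_log_range = c(0.04, 6.35),
                            covariates = default_covariate_spec(),
                            correlation = default_covariate_correlation(),
                            true_alpha = 7.77,
                            true_beta = default_true_beta(),
                            true_gamma = c(urban = 1.0, log_area = -0.7),
                            district_effect_sd = 0.3,
                            noise = c("poisson", "negbin", "none"),
                            negbin_theta = NULL,
                            seed = 20120301) {
  n_districts <- check_count(n_districts, "n_districts")
  n_subdistricts <- check_count(n_subdistricts, "n_subdistricts")
  n_villages <- check_count(n_villages, "n_villages")
  if (!(n_districts <= n_subdistricts && n_subdistricts <= n_villages)) {
    abort_config("Counts must satisfy n_districts <= n_subdistricts <= n_villages.")
  }
  urban_fraction <- check_fraction(urban_fraction, "urban_fraction")
  noise <- match.arg(noise)
  if (noise == "negbin") {
    if (is.null(negbin_theta) || !is.numeric(negbin_theta) || negbin_theta <= 0) {
      abort_config("`negbin_theta` must be a positive number when noise = 'negbin'.")
    }
  }
  validate_covariate_spec(covariates, correlation)
  if (!setequal(names(true_beta), names(covariates))) {
    abort_config("`true_beta` names must match covariate names exactly.")
  }
  if (!all(c("urban", "log_area") %in% names(true_gamma))) {
    abort_config("`true_gamma` must contain elements 'urban' and 'log_area'.")
  }
  cfg <- list(
    n_districts = n_districts,
    n_subdistricts = n_subdistricts,
    n_villages = n_villages,
    urban_fraction = urban_fraction,
    area_meanlog = as.numeric(area_meanlog),
    area_sdlog = as.numeric(area_sdlog),
    area_log_range = as.numeric(area_log_range),
    covariates = covariates,
    correlation = correlation,
    true_alpha = as.numeric(true_alpha),
    true_beta = true_beta[names(covariates)],
    true_gamma = true_gamma[c("urban", "log_area")],
    district_effect_sd = as.numeric(district_effect_sd),
    noise = noise,
    negbin_theta = if (noise == "negbin") as.numeric(negbin_theta) else NULL,
    seed = as.integer(seed)
  )
  structure(cfg, class = "scenario_config")
}

#' Preset scenario configurations
#'
#' `"desk"` is the fast default (1,000 villages, 50 sub-districts, 8
#' districts). `"national"` reproduces the emulated country's scale: 25
#' districts, 331 sub-districts, 13,970 villages, 9.2% urban.
#'
#' @param preset One of `"desk"`, `"national"`.
#' @param ... Overrides passed on to [scenario_config()].
#' @return A `scenario_config`.
#' @export
scenario_preset <- function(preset = c("desk", "national"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    desk = list(),
    national = list(n_districts = 25, n_subdistricts = 331,
                   n_villages = 13970, urban_fraction = 0.092)
  )
  do.call(scenario_config, modifyList(args, list(...)))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  hierarchy : %d districts / %d sub-districts / %d villages\n",
              x$n_districts, x$n_subdistricts, x$n_villages))
  cat(sprintf("  urban     : %.1f%%   area ~ lognormal(%.2f, %.2f)\n",
              100 * x$urban_fraction, x$area_meanlog, x$area_sdlog))
  cat(sprintf("  covariates: %s\n", paste(names(x$covariates), collapse = ", ")))
  cat(sprintf("  noise     : %s   seed: %d\n", x$noise, x$seed))
  invisible(x)
}

#' @rdname scenario_config
#' @export
default_covariate_spec <- function() {
  list(
    night_lights = list(family = "lognormal", meanlog = -1.0, sdlog = 1.0,
                        urban_shift = 1.0),
    built_up = list(family = "logitnormal", mu = -2.2, sigma = 1.6,
                    urban_shift = 1.2),
    tree_cover = list(family = "logitnormal", mu = -0.1, sigma = 1.2,
                      urban_shift = -0.8),
    slope = list(family = "normal", mean = 8.7, sd = 5.1),
    elevation = list(family = "lognormal", meanlog = 4.6, sdlog = 1.1)
  )
}

#' @rdname scenario_config
#' @export
default_covariate_correlation <- function() {
  nm <- c("night_lights", "built_up", "tree_cover", "slope", "elevation")
  r <- diag(5)
  dimnames(r) <- list(nm, nm)
  r["night_lights", "built_up"] <- r["built_up", "night_lights"] <- 0.60
  r["night_lights", "tree_cover"] <- r["tree_cover", "night_lights"] <- -0.35
  r["night_lights", "slope"] <- r["slope", "night_lights"] <- -0.20
  r["night_lights", "elevation"] <- r["elevation", "night_lights"] <- -0.15
  r["built_up", "tree_cover"] <- r["tree_cover", "built_up"] <- -0.45
  r["built_up", "slope"] <- r["slope", "built_up"] <- -0.25
  r["built_up", "elevation"] <- r["elevation", "built_up"] <- -0.20
  r["tree_cover", "slope"] <- r["slope", "tree_cover"] <- 0.35
  r["tree_cover", "elevation"] <- r["elevation", "tree_cover"] <- 0.40
  r["slope", "elevation"] <- r["elevation", "slope"] <- 0.50
  r
}

#' @rdname scenario_config
#' @export
default_true_beta <- function() {
  c(night_lights = 0.05, built_up = 0.02, tree_cover = -0.012,
    slope = -0.03, elevation = 0)
}

validate_covariate_spec <- function(covariates, correlation) {
  if (!is.list(covariates) || length(covariates) == 0 ||
      is.null(names(covariates)) || anyDuplicated(names(covariates))) {
    abort_config("`covariates` must be a non-empty uniquely named list.")
  }
  ok_fam <- c("lognormal", "logitnormal", "normal")
  for (nm in names(covariates)) {
    fam <- covariates[[nm]]$family
    if (is.null(fam) || !fam %in% ok_fam) {
      abort_config(sprintf("Covariate '%s' has unknown family '%s'.", nm,
                           fam %||% "<missing>"))
    }
  }
  p <- length(covariates)
  if (!is.matrix(correlation) || any(dim(correlation) != p)) {
    abort_config("`correlation` must be a square matrix matching the covariates.")
  }
  if (max(abs(diag(correlation) - 1)) > 1e-12 ||
      max(abs(correlation - t(correlation))) > 1e-12) {
    abort_config("`correlation` must be symmetric with unit diagonal.")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort_config("`correlation` must be positive semi-definite.")
  }
  if (!is.null(dimnames(correlation)) &&
      !identical(rownames(correlation), names(covariates))) {
    abort_config("`correlation` dimnames must match covariate names (in order).")
  }
  invisible(TRUE)
}

#' Serialize / restore a scenario configuration
#'
#' The configuration round-trips through a flat YAML file without loss
#' (the correlation matrix is stored row-wise).
#'
#' @param config A `scenario_config`.
#' @param path File path.
#' @return `write_scenario_config()` returns `path` invisibly;
#'   `read_scenario_config()` returns a `scenario_config`.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  out <- unclass(config)
  out$correlation <- apply(config$correlation, 1, as.numeric, simplify = FALSE)
  names(out$correlation) <- rownames(config$correlation)
  out$true_beta <- as.list(config$true_beta)
  out$true_gamma <- as.list(config$true_gamma)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  p <- length(raw$covariates)
  corr <- do.call(rbind, lapply(raw$correlation, as.numeric))
  dimnames(corr) <- list(names(raw$covariates), names(raw$covariates))
  scenario_config(
    n_districts = raw$n_districts,
    n_subdistricts = raw$n_subdistricts,
    n_villages = raw$n_villages,
    urban_fraction = raw$urban_fraction,
    area_meanlog = raw$area_meanlog,
    area_sdlog = raw$area_sdlog,
    area_log_range = unlist(raw$area_log_range),
    covariates = raw$covariates,
    correlation = corr,
    true_alpha = raw$true_alpha,
    true_beta = unlist(raw$true_beta),
    true_gamma = unlist(raw$true_gamma),
    district_effect_sd = raw$district_effect_sd,
    noise = raw$noise,
    negbin_theta = raw$negbin_theta,
    seed = raw$seed
  )
}

# documented order of the per-operation child seed streams derived from
# config$seed: 1 admin frame, 2 covariates, 3 census, 4 free/extra
scenario_child_seed <- function(config, stage) {
  stages <- c(admin = 1L, covariates = 2L, census = 3L, extra = 4L)
  spawn_seeds(config$seed, 4L)[stages[[stage]]]
}
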