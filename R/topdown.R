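#' Top-down population redistribution baselines
#'
#' Desk-scale analogues of gridded-population products: a parent unit's
#' (sub-district) census total is redistributed to its child villages
#' either by areal weighting (`redistribute_areal()`, constant density
#' within the parent) or proportionally to a non-negative covariate such
#' as built-up area (`redistribute_covariate()`). Both conserve the parent
#' total exactly; areal redistribution is the covariate rule with the
#' covariate equal to area.
#'
#' @param children Tibble with `parent_id`, `village_id`, `area_km2`, and
#'   (for the covariate rule) the redistribution covariate.
#' @param parents Tibble with `parent_id`, `population` (>= 0).
#' @param covariate Name of the covariate column in `children`.
#' @return Tibble `village_id`, `parent_id`, `count`, `density`.
#' @examples
#' children <- tibble::tibble(parent_id = "s1", village_id = c("a", "b"),
#'                            area_km2 = c(1, 3))
#' parents <- tibble::tibble(parent_id = "s1", population = 1000)
#' redistribute_areal(children, parents)  # counts 250 / 750, density 250
#' @export
redistribute_areal <- function(children, parents) {
  check_cols(children, c("parent_id", "village_id", "area_km2"), "children")
  ch <- children
  ch$.redist <- ch$area_km2
  redistribute_impl(ch, parents, fallback = FALSE)
}

#' @rdname redistribute_areal
#' @export
redistribute_covariate <- function(children, parents, covariate = "built_up") {
  check_cols(children, c("parent_id", "village_id", "area_km2", covariate),
             "children")
  ch <- children
  ch$.redist <- ch[[covariate]]
  if (any(ch$.redist < 0)) {
    abort_data(sprintf("Redistribution covariate '%s' must be non-negative.",
                       covariate))
  }
  redistribute_impl(ch, parents, fallback = TRUE)
}

redistribute_impl <- function(children, parents, fallback) {
  check_cols(parents, c("parent_id", "population"), "parents")
  if (any(parents$population < 0)) abort_data("Parent totals must be >= 0.")
  orphan <- setdiff(children$parent_id, parents$parent_id)
  if (length(orphan)) {
    abort_data(sprintf("Child parent(s) missing from `parents`: %s.",
                       paste(head(orphan, 5), collapse = ", ")))
  }
  parts <- split(seq_len(nrow(children)), children$parent_id)
  ptot <- setNames(parents$population, parents$parent_id)
  out <- purrr::map_dfr(names(parts), function(p) {
    idx <- parts[[p]]
    wgt <- children$.redist[idx]
    if (sum(wgt) <= 0) {
      if (!fallback || sum(children$area_km2[idx]) <= 0) {
        abort_data(sprintf("Parent '%s' has zero total redistribution mass.", p))
      }
      warn(sprintf("Parent '%s': all-zero covariate; falling back to areal weights.", p))
      wgt <- children$area_km2[idx]
    }
    count <- ptot[[p]] * wgt / sum(wgt)
    tibble::tibble(village_id = children$village_id[idx], parent_id = p,
                   count = count,
                   density = count / children$area_km2[idx])
  })
  out[match(children$village_id, out$village_id), ]
}

#' Census-staleness experiment: stale top-down vs current bottom-up
#'
#' Generates a baseline census at time t0, perturbs the spatial population
#' pattern to time t1 (sub-district shares re-weighted by a Dirichlet draw
#' around the t0 shares, times a national growth factor), draws a t1
#' survey, and compares (a) covariate top-down redistribution anchored to
#' the *stale* t0 census against (b) the bottom-up model fit to the t1
#' survey — both evaluated against the t1 census on the identical set of
#' non-surveyed villages.
#'
#' Larger migration (smaller Dirichlet `concentration`) makes the stale
#' anchor worse while leaving the survey-calibrated bottom-up fit current.
#'
#' @param config A [scenario_config()] for the shared frame.
#' @param design A [survey_design()] for the t1 survey.
#' @param concentration Dirichlet concentration for the sub-district share
#'   re-weighting; `sum(alpha) = concentration`, `alpha_s` proportional to
#'   the t0 share. Around 25-100 moves 20-40% of the population across
#'   sub-districts at desk scale.
#' @param growth National population growth factor t0 -> t1.
#' @param covariate Redistribution covariate for the top-down arm.
#' @param seed Integer seed.
#' @return A list: `reports` (tibble of paired [accuracy_report()] rows,
#'   `arm` in `"bottom_up"`/`"topdown_t0"`), `migration_share` (fraction of
#'   t1 population that shifted across sub-districts relative to t0
#'   shares), and the underlying tables.
#' @export
staleness_experiment <- function(config, design, concentration = 50,
                                 growth = 1.0, covariate = "built_up",
                                 seed = 1) {
  stopifnot(inherits(config, "scenario_config"), inherits(design, "survey_design"))
  seeds <- spawn_seeds(seed, 4)
  frame <- generate_admin_frame(config)
  covars <- generate_covariates(frame, config)
  census0 <- generate_census(frame, covars, config)

  # t1: Dirichlet re-weighting of sub-district population shares + growth
  sd_pop0 <- tapply(census0$population, frame$sub_district_id, sum)
  shares0 <- sd_pop0 / sum(sd_pop0)
  shares1 <- withr::with_seed(seeds[1], {
    g <- rgamma(length(shares0), shape = concentration * shares0, rate = 1)
    if (sum(g) == 0) g <- shares0
    g / sum(g)
  })
  mult <- growth * shares1 / shares0
  mult[!is.finite(mult)] <- 0
  mu1 <- census0$mu * mult[match(frame$sub_district_id, names(sd_pop0))]
  census1 <- withr::with_seed(seeds[2], {
    lam <- mu1 * frame$area_km2
    pop <- rpois(length(lam), lam)
    tibble::tibble(village_id = frame$village_id, population = as.integer(pop),
                   density = pop / frame$area_km2, mu = mu1)
  })
  migration_share <- sum(abs(shares1 - shares0)) / 2

  sample1 <- draw_survey(frame, covars, census1, design, seed = seeds[3])
  dens1 <- estimate_village_density(sample1, frame)
  train <- dens1[dens1$included, ]

  dsg <- build_design_matrix(frame, covars)
  tr_idx <- match(train$village_id, dsg$village_id)
  tr_dsg <- subset_design(dsg, tr_idx)
  wts <- compute_weights(setNames(
    pmax(census0$population[match(train$village_id, census0$village_id)], 1),
    train$village_id), "inverse_pop")
  cv <- select_lambda_cv(tr_dsg, train$hies_density, wts, k = 5,
                         seed = seeds[4])
  model <- post_lasso_fit(tr_dsg, train$hies_density, wts, cv$lambda_star,
                          cv$path, cluster = FALSE, scheme = "inverse_pop")

  eval_ids <- setdiff(frame$village_id, train$village_id)
  eval_idx <- match(eval_ids, dsg$village_id)
  bu_pred <- predict_density(model, subset_design(dsg, eval_idx))

  children <- tibble::tibble(
    parent_id = frame$sub_district_id, village_id = frame$village_id,
    area_km2 = frame$area_km2,
    cov = covars[[covariate]][match(frame$village_id, covars$village_id)])
  names(children)[names(children) == "cov"] <- covariate
  parents0 <- tibble::tibble(parent_id = names(sd_pop0),
                             population = as.numeric(sd_pop0))
  td <- redistribute_covariate(children, parents0, covariate)

  truth <- census1$density[match(eval_ids, census1$village_id)]
  td_pred <- td$density[match(eval_ids, td$village_id)]
  reports <- dplyr::bind_rows(
    dplyr::mutate(accuracy_report(truth, bu_pred$density_pred), arm = "bottom_up"),
    dplyr::mutate(accuracy_report(truth, td_pred), arm = "topdown_t0"))
  list(reports = reports, migration_share = migration_share,
       frame = frame, census_t0 = census0, census_t1 = census1,
       model = model, evaluation_villages = eval_ids)
}
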