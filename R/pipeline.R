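#' Run the full bottom-up experiment end to end
#'
#' Simulates the frame, covariates, and census; draws the survey;
#' estimates survey-based village densities; fits the two-step model
#' (penalty path, cross-validated penalty, post-LASSO refit) under the
#' inverse-population and balance-corrected weight schemes; predicts
#' density in non-surveyed villages; and evaluates predictions (density
#' and count scales) against the census along with the direct-vs-model
#' sub-district CV comparison. Every stage consumes its own child seed
#' spawned from `seed`, so reruns with the same configuration are
#' bit-identical.
#'
#' @param config A [scenario_config()].
#' @param design A [survey_design()].
#' @param schemes Weight schemes to fit (subset of `"inverse_pop"`,
#'   `"balance_corrected"`, `"uniform"`).
#' @param k Folds for the penalty choice.
#' @param seed Master seed; stage seeds are spawned from it in the order
#'   scenario, survey, model, evaluation.
#' @param p_floor Probability floor for balance-corrected weights.
#' @return An object of class `bottomup_run`: tables (`frame`,
#'   `covariates`, `census`, `density_estimates`), fitted `models` (one
#'   per scheme), `predictions` (non-surveyed villages), `reports`
#'   (accuracy per scheme and scale), `cv_report`, `concordance`, and a
#'   `manifest` (seeds, sizes, timing, config hash).
#' @export
run_experiment <- function(config = scenario_config(),
                           design = survey_design(),
                           schemes = c("inverse_pop", "balance_corrected"),
                           k = 5, seed = 1, p_floor = 0.01) {
  stopifnot(inherits(config, "scenario_config"), inherits(design, "survey_design"))
  schemes <- match.arg(schemes, c("inverse_pop", "balance_corrected", "uniform"),
                       several.ok = TRUE)
  t0 <- proc.time()[["elapsed"]]
  seeds <- spawn_seeds(seed, 4)
  timing <- numeric()
  tick <- function(stage) {
    now <- proc.time()[["elapsed"]]
    timing[stage] <<- now - t0 - sum(timing)
  }

  cfg <- config
  cfg$seed <- seeds[1]
  frame <- generate_admin_frame(cfg)
  covars <- generate_covariates(frame, cfg)
  census <- generate_census(frame, covars, cfg)
  tick("scenario")

  sample <- draw_survey(frame, covars, census, design, seed = seeds[2])
  dens <- estimate_village_density(sample, frame)
  concordance <- survey_census_concordance(dens, census)
  train <- dens[dens$included, ]
  tick("survey")

  dsg <- build_design_matrix(frame, covars)
  tr_dsg <- subset_design(dsg, match(train$village_id, dsg$village_id))
  y <- train$hies_density
  pop_train <- setNames(census$population[match(train$village_id,
                                                census$village_id)],
                        train$village_id)

  model_seeds <- spawn_seeds(seeds[3], length(schemes) + 1)
  models <- list()
  selection <- NULL
  for (i in seq_along(schemes)) {
    sch <- schemes[i]
    if (sch == "balance_corrected") {
      # probit on the variables selected by the inverse-pop (or first) fit
      base <- models[[1]] %||% fit_two_step(tr_dsg, y,
        compute_weights(pop_train, "inverse_pop"), k, model_seeds[length(schemes) + 1],
        scheme = "inverse_pop")
      sel_vars <- base$selected
      if (length(sel_vars) == 0) sel_vars <- tr_dsg$meta$covariate_cols
      in_survey <- frame$village_id %in% train$village_id
      selection <- fit_selection_probit(
        cbind(tibble::tibble(village_id = frame$village_id),
              tibble::as_tibble(dsg$x[, intersect(sel_vars, colnames(dsg$x)),
                                      drop = FALSE])),
        in_survey)
      wts <- compute_weights(pop_train, "balance_corrected",
                             selection = selection, p_floor = p_floor)
    } else {
      wts <- compute_weights(pop_train, sch)
    }
    models[[sch]] <- fit_two_step(tr_dsg, y, wts, k, model_seeds[i], scheme = sch)
  }
  tick("model")

  eval_ids <- setdiff(frame$village_id, train$village_id)
  eval_dsg <- subset_design(dsg, match(eval_ids, dsg$village_id))
  truth_d <- census$density[match(eval_ids, census$village_id)]
  predictions <- purrr::map_dfr(schemes, function(sch) {
    p <- predict_density(models[[sch]], eval_dsg)
    p$scheme <- sch
    p
  })
  reports <- purrr::map_dfr(schemes, function(sch) {
    p <- predictions[predictions$scheme == sch, ]
    cnt <- density_to_count(p[c("village_id", "density_pred")], frame)
    truth_c <- census$population[match(eval_ids, census$village_id)]
    dplyr::bind_rows(
      dplyr::mutate(accuracy_report(truth_d, p$density_pred, "density"),
                    scheme = sch),
      dplyr::mutate(accuracy_report(truth_c, cnt$count_pred, "count"),
                    scheme = sch))
  })

  vil_w <- tibble::tibble(village_id = sample$villages$village_id,
                          w = 1 / sample$villages$pi_village)
  cvr <- cv_compare(direct_cv(dens, frame, vil_w),
                    model_cv(models[[1]], dsg, frame))
  tick("evaluate")

  manifest <- list(
    config_hash = rlang::hash(list(unclass(config), unclass(design),
                                   schemes, k, p_floor)),
    master_seed = as.integer(seed),
    stage_seeds = setNames(as.integer(seeds),
                           c("scenario", "survey", "model", "evaluation")),
    model_seeds = setNames(as.integer(model_seeds[seq_along(schemes)]), schemes),
    n_villages = nrow(frame),
    n_surveyed = nrow(dens),
    n_train = nrow(train),
    n_evaluated = length(eval_ids),
    package_version = as.character(utils::packageVersion("bottomup")),
    timing_sec = timing
  )
  structure(list(
    frame = frame, covariates = covars, census = census, sample = sample,
    density_estimates = dens, design_matrix = dsg, models = models,
    predictions = predictions, reports = reports, cv_report = cvr,
    concordance = concordance, selection = selection, manifest = manifest,
    inputs = list(config = config, design = design, schemes = schemes,
                  k = k, seed = seed, p_floor = p_floor)
  ), class = "bottomup_run")
}

# path -> cross-validated lambda -> post-LASSO refit
fit_two_step <- function(design, y, weights, k, seed, scheme) {
  cv <- select_lambda_cv(design, y, weights, k = k, seed = seed)
  post_lasso_fit(design, y, weights, cv$lambda_star, cv$path,
                 cluster = TRUE, scheme = scheme, seed = seed)
}

#' @export
print.bottomup_run <- function(x, ...) {
  cat("<bottomup_run>\n")
  m <- x$manifest
  cat(sprintf("  %d villages, %d surveyed (%d single-PSU train), %d evaluated\n",
              m$n_villages, m$n_surveyed, m$n_train, m$n_evaluated))
  cat(sprintf("  survey-census concordance r = %.3f\n", x$concordance))
  rep_d <- x$reports[x$reports$scale == "density", ]
  for (i in seq_len(nrow(rep_d))) {
    cat(sprintf("  [%s] out-of-sample R2 %.3f, SRC %.3f, median RE %.1f%%\n",
                rep_d$scheme[i], rep_d$r2[i], rep_d$spearman[i],
                100 * rep_d$median_re[i]))
  }
  g <- glance(x$cv_report)
  cat(sprintf("  mean sub-district CV: direct %.1f%% vs model %.1f%%\n",
              g$mean_direct_cv, g$mean_model_cv))
  invisible(x)
}

#' @rdname run_experiment
#' @param x A `bottomup_run`.
#' @param ... Unused.
#' @export
glance.bottomup_run <- function(x, ...) {
  rep_d <- x$reports[x$reports$scale == "density", ]
  tibble::tibble(
    scheme = rep_d$scheme, r2 = rep_d$r2, spearman = rep_d$spearman,
    mae = rep_d$mae, median_re = rep_d$median_re,
    concordance = x$concordance,
    mean_direct_cv = attr(x$cv_report, "mean_direct_cv"),
    mean_model_cv = attr(x$cv_report, "mean_model_cv")
  )
}

#' @rdname run_experiment
#' @export
autoplot.bottomup_run <- function(x, ...) {
  p <- x$predictions[x$predictions$scheme == x$inputs$schemes[1], ]
  truth <- x$census$density[match(p$village_id, x$census$village_id)]
  df <- tibble::tibble(census = truth, predicted = p$density_pred)
  ggplot2::ggplot(df, ggplot2::aes(.data$census, .data$predicted)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "census density (persons/km2)",
                  y = "out-of-sample prediction",
                  title = "Bottom-up density predictions, non-surveyed villages") +
    ggplot2::theme_minimal()
}

#' Training-size robustness check
#'
#' Refits the full two-step model on seeded random subsets of the training
#' villages at each fraction, keeping the evaluation set of the base run
#' fixed, and reports the accuracy per fraction (the survey-halving
#' robustness exercise).
#'
#' @param run A [run_experiment()] result.
#' @param fractions Training fractions in (0, 1].
#' @param scheme Weight scheme to refit.
#' @param seed Seed for the subset draws; the fraction-1 fit reuses the
#'   base run's model seed, so it reproduces the base report exactly.
#' @return A tibble: one accuracy row per fraction (density scale), with
#'   `fraction` and `n_train`.
#' @export
subsample_training <- function(run, fractions = c(1, 0.5, 0.25),
                               scheme = "inverse_pop", seed = NULL) {
  stopifnot(inherits(run, "bottomup_run"))
  if (any(fractions <= 0 | fractions > 1)) {
    abort_config("`fractions` must lie in (0, 1].")
  }
  if (!scheme %in% names(run$models)) {
    abort_usage(sprintf("Scheme '%s' was not fitted in the base run.", scheme))
  }
  seed <- seed %||% spawn_seeds(run$inputs$seed, 5)[5]
  train <- run$density_estimates[run$density_estimates$included, ]
  dsg <- run$design_matrix
  census <- run$census
  eval_ids <- setdiff(run$frame$village_id, train$village_id)
  eval_dsg <- subset_design(dsg, match(eval_ids, dsg$village_id))
  truth <- census$density[match(eval_ids, census$village_id)]
  k <- run$inputs$k
  sub_seeds <- spawn_seeds(seed, length(fractions))
  purrr::map_dfr(seq_along(fractions), function(i) {
    f <- fractions[i]
    n_sub <- floor(f * nrow(train))
    if (n_sub < 2 * k) {
      abort_data(sprintf("Fraction %.2f leaves %d rows; too few for %d-fold CV.",
                         f, n_sub, k))
    }
    if (f == 1) {
      model <- run$models[[scheme]]
      n_sub <- nrow(train)
    } else {
      idx <- withr::with_seed(sub_seeds[i], sample.int(nrow(train), n_sub))
      tr <- train[idx, ]
      tr_dsg <- subset_design(dsg, match(tr$village_id, dsg$village_id))
      tr_dsg <- drop_degenerate_columns(tr_dsg)
      pop <- setNames(census$population[match(tr$village_id, census$village_id)],
                      tr$village_id)
      model <- fit_two_step(tr_dsg, tr$hies_density,
                            compute_weights(pop, "inverse_pop"), k,
                            sub_seeds[i], scheme = scheme)
    }
    pred <- predict_density(model, eval_dsg)
    dplyr::mutate(accuracy_report(truth, pred$density_pred, "density"),
                  fraction = f, n_train = n_sub)
  })
}

#' Write the tabular outputs of a run to a directory
#'
#' Writes `villages.csv`, `covariates.csv`, `census.csv`, `survey.csv`
#' (households joined with PSU metadata), `hies_density.csv`,
#' `predictions.csv`, `reports.csv`, `cv_report.csv`, a JSON model file
#' per scheme, and `manifest.json`.
#'
#' @param run A `bottomup_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  stopifnot(inherits(run, "bottomup_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, f) utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  wcsv(run$frame, "villages.csv")
  wcsv(run$covariates, "covariates.csv")
  wcsv(run$census[c("village_id", "population", "density")], "census.csv")
  survey <- dplyr::left_join(run$sample$households, run$sample$psus,
                             by = c("psu_id", "village_id"))
  wcsv(survey, "survey.csv")
  wcsv(run$density_estimates, "hies_density.csv")
  wcsv(run$predictions, "predictions.csv")
  wcsv(run$reports, "reports.csv")
  wcsv(tibble::as_tibble(run$cv_report), "cv_report.csv")
  for (sch in names(run$models)) {
    write_model_json(run$models[[sch]],
                     file.path(dir, sprintf("model_%s.json", sch)))
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Serialize / restore a fitted density model as JSON
#'
#' @param model A `density_model`.
#' @param path JSON file path.
#' @return `read_model_json()` returns a `density_model` sufficient for
#'   [predict_density()].
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "density_model"))
  out <- list(
    coefficients = as.list(model$coefficients),
    selected = model$selected,
    support = model$support,
    lambda_star = model$lambda_star,
    scheme = model$scheme,
    meta = model$meta,
    fold_seed = model$fold_seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  raw <- jsonlite::read_json(path)
  structure(list(
    coefficients = unlist(raw$coefficients),
    selected = as.character(unlist(raw$selected)),
    support = as.character(unlist(raw$support)),
    lambda_star = raw$lambda_star,
    scheme = raw$scheme,
    meta = raw$meta,
    fold_seed = raw$fold_seed
  ), class = "density_model")
}
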