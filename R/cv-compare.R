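#' Direct (survey-based) sub-district CV via the Horvitz-Thompson
#' with-replacement approximation
#'
#' For each sub-district, the direct estimator is the weighted mean of the
#' included survey village densities; its variance uses the
#' with-replacement approximation for a weighted mean with villages as
#' first-stage units,
#' `var = n/(n-1) * sum_i (w_i (y_i - ybar_w) / sum(w))^2`,
#' and `CV = 100 * sqrt(var) / ybar_w`. Sub-districts with a single
#' sampled village have an undefined CV (flagged, excluded from summary
#' means). No finite-population correction is applied — this is the
#' with-replacement approximation, which is slightly conservative at
#' non-trivial sampling fractions.
#'
#' @param estimates [estimate_village_density()] output.
#' @param frame Village frame (for the sub-district mapping).
#' @param weights Optional tibble `village_id`, `w` of village-level
#'   analysis weights (e.g. inverse village inclusion probabilities);
#'   default equal weights.
#' @return A tibble (one row per sub-district with >= 1 included village):
#'   `sub_district_id`, `n`, `estimate`, `variance`, `cv` (percent),
#'   `defined`.
#' @export
direct_cv <- function(estimates, frame, weights = NULL) {
  check_cols(estimates, c("village_id", "hies_density", "included"), "estimates")
  check_cols(frame, c("village_id", "sub_district_id"), "frame")
  inc <- estimates[estimates$included, ]
  sd_id <- frame$sub_district_id[match(inc$village_id, frame$village_id)]
  if (anyNA(sd_id)) abort_data("Some surveyed villages are absent from `frame`.")
  w <- rep(1, nrow(inc))
  if (!is.null(weights)) {
    check_cols(weights, c("village_id", "w"), "weights")
    w <- weights$w[match(inc$village_id, weights$village_id)]
    if (anyNA(w)) abort_data("`weights` must cover every included village.")
  }
  df <- tibble::tibble(sub_district_id = sd_id, y = inc$hies_density, w = w)
  out <- dplyr::summarise(dplyr::group_by(df, .data$sub_district_id),
    n = dplyr::n(),
    estimate = sum(.data$w * .data$y) / sum(.data$w),
    variance = if (dplyr::n() >= 2) {
      dplyr::n() / (dplyr::n() - 1) *
        sum((.data$w * (.data$y - sum(.data$w * .data$y) / sum(.data$w)) /
               sum(.data$w))^2)
    } else NA_real_,
    .groups = "drop")
  out$cv <- ifelse(!is.na(out$variance) & out$estimate > 0,
                   100 * sqrt(out$variance) / out$estimate, NA_real_)
  out$defined <- !is.na(out$cv)
  out
}

#' Model-based sub-district CV via the delta method
#'
#' For each sub-district the model estimate is the mean predicted density
#' over its villages, `gbar = mean_v exp(x_v' theta)`. Its variance uses
#' the delta method with the cluster-robust (sub-district clustered)
#' coefficient covariance: `grad = mean_v (yhat_v x_v)`,
#' `var = grad' V grad`, `CV = 100 sqrt(var) / gbar`.
#'
#' @param model A `density_model` carrying a cluster-robust `vcov`.
#' @param design_all `density_design` for all villages to aggregate over.
#' @param frame Village frame (sub-district mapping).
#' @return Tibble `sub_district_id`, `n`, `estimate`, `variance`, `cv`.
#' @export
model_cv <- function(model, design_all, frame) {
  stopifnot(inherits(design_all, "density_design"))
  if (is.null(model$vcov)) {
    abort_usage("`model` lacks a coefficient covariance; refit with cluster = TRUE.")
  }
  co <- model$coefficients
  terms <- setdiff(names(co), "(Intercept)")
  missing <- setdiff(terms, colnames(design_all$x))
  if (length(missing)) {
    abort_data(sprintf("Design lacks model column(s): %s.",
                       paste(missing, collapse = ", ")))
  }
  x1 <- cbind("(Intercept)" = 1, design_all$x[, terms, drop = FALSE])
  yhat <- exp(pmin(drop(x1 %*% co[c("(Intercept)", terms)]), 300))
  sd_id <- frame$sub_district_id[match(design_all$village_id, frame$village_id)]
  if (anyNA(sd_id)) abort_data("Some design villages are absent from `frame`.")
  v <- model$vcov[c("(Intercept)", terms), c("(Intercept)", terms)]
  groups <- split(seq_along(yhat), sd_id)
  out <- purrr::map_dfr(names(groups), function(s) {
    idx <- groups[[s]]
    gbar <- mean(yhat[idx])
    grad <- colMeans(yhat[idx] * x1[idx, , drop = FALSE])
    varg <- drop(t(grad) %*% v %*% grad)
    tibble::tibble(sub_district_id = s, n = length(idx), estimate = gbar,
                   variance = varg,
                   cv = if (gbar > 0) 100 * sqrt(max(varg, 0)) / gbar else NA_real_)
  })
  out
}

#' Compare direct and model-based sub-district CVs
#'
#' Joins [direct_cv()] and [model_cv()] on sub-district and summarizes the
#' mean CVs over sub-districts where the direct CV is defined — the
#' precision comparison between the survey-only estimator and the
#' model-based predictions.
#'
#' @param direct Output of [direct_cv()].
#' @param model_based Output of [model_cv()].
#' @return A tibble of class `cv_report` with per-sub-district
#'   `direct_cv`/`model_cv`; attributes `mean_direct_cv`, `mean_model_cv`,
#'   `n_subdistricts` hold the summary (also via [glance()]).
#' @export
cv_compare <- function(direct, model_based) {
  joined <- dplyr::inner_join(
    dplyr::select(direct, "sub_district_id", n_sampled = "n",
                  direct_estimate = "estimate", direct_cv = "cv",
                  "defined"),
    dplyr::select(model_based, "sub_district_id",
                  model_estimate = "estimate", model_cv = "cv"),
    by = "sub_district_id")
  usable <- joined[joined$defined & !is.na(joined$model_cv), ]
  out <- joined
  class(out) <- c("cv_report", class(out))
  attr(out, "mean_direct_cv") <- mean(usable$direct_cv)
  attr(out, "mean_model_cv") <- mean(usable$model_cv)
  attr(out, "n_subdistricts") <- nrow(usable)
  out
}

#' @rdname cv_compare
#' @param x A `cv_report`.
#' @param ... Unused.
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    mean_direct_cv = attr(x, "mean_direct_cv"),
    mean_model_cv = attr(x, "mean_model_cv"),
    cv_reduction = 1 - attr(x, "mean_model_cv") / attr(x, "mean_direct_cv"),
    n_subdistricts = attr(x, "n_subdistricts")
  )
}

#' @rdname cv_compare
#' @export
autoplot.cv_report <- function(x, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), "sub_district_id",
                  direct = "direct_cv", model = "model_cv"),
    c("direct", "model"), names_to = "estimator", values_to = "cv")
  ggplot2::ggplot(df[!is.na(df$cv), ],
                  ggplot2::aes(x = .data$estimator, y = .data$cv)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "sub-district CV (%)", x = NULL,
                  title = "Direct survey vs model-based precision") +
    ggplot2::theme_minimal()
}
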