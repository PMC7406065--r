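#' Accuracy report for density or count predictions
#'
#' Computes the accuracy surface used throughout: R-squared (squared
#' Pearson correlation by default, with the 1 - SSE/SST variant stored as
#' `r2_ss`), Spearman rank correlation, MAE, RMSE, and the mean and median
#' relative error `|pred - truth| / truth` over strictly positive truths
#' (the number of excluded zero-truth rows is recorded). Relative errors
#' are identical whether computed on densities or on counts, since the two
#' differ only by the village-area factor.
#'
#' @param y_true,y_pred Equal-length numeric vectors (n >= 3).
#' @param scale Label: `"density"` or `"count"`.
#' @return A one-row tibble of class `accuracy_report`.
#' @examples
#' accuracy_report(c(100, 200, 400), c(110, 190, 440))
#' @export
accuracy_report <- function(y_true, y_pred, scale = c("density", "count")) {
  scale <- match.arg(scale)
  if (length(y_true) != length(y_pred)) {
    abort_data("`y_true` and `y_pred` must have equal length.")
  }
  if (length(y_true) < 3) abort_data("Need at least 3 observations.")
  if (anyNA(y_true) || anyNA(y_pred)) abort_data("Inputs must be complete.")
  if (sd(y_true) == 0 || sd(y_pred) == 0) {
    abort_data("Correlation-based metrics undefined: zero variance input.")
  }
  err <- y_pred - y_true
  pos <- y_true > 0
  re <- abs(err[pos]) / y_true[pos]
  out <- tibble::tibble(
    r2 = cor(y_true, y_pred)^2,
    r2_ss = 1 - sum(err^2) / sum((y_true - mean(y_true))^2),
    spearman = cor(y_true, y_pred, method = "spearman"),
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    mean_re = mean(re),
    median_re = median(re),
    n = length(y_true),
    n_zero_truth = sum(!pos),
    scale = scale
  )
  class(out) <- c("accuracy_report", class(out))
  out
}

#' Convert density predictions to population counts
#'
#' `count_v = density_v * area_v`. Relative errors of counts equal the
#' relative errors of the densities village by village.
#'
#' @param density_pred Tibble with `village_id`, `density_pred` (or a
#'   numeric vector aligned with `frame`).
#' @param frame Village frame with `village_id`, `area_km2`.
#' @return A tibble `village_id`, `count_pred`.
#' @export
density_to_count <- function(density_pred, frame) {
  check_cols(frame, c("village_id", "area_km2"), "frame")
  if (is.data.frame(density_pred)) {
    check_cols(density_pred, c("village_id", "density_pred"), "density_pred")
    area <- frame$area_km2[match(density_pred$village_id, frame$village_id)]
    if (anyNA(area)) {
      abort_data(sprintf("Village(s) missing from `frame`: %s.",
                         paste(head(density_pred$village_id[is.na(area)], 5),
                               collapse = ", ")))
    }
    tibble::tibble(village_id = density_pred$village_id,
                   count_pred = density_pred$density_pred * area)
  } else {
    if (length(density_pred) != nrow(frame)) {
      abort_data("Density vector length does not match `frame`.")
    }
    tibble::tibble(village_id = frame$village_id,
                   count_pred = as.numeric(density_pred) * frame$area_km2)
  }
}

#' Out-of-sample R-squared by k-fold cross-validation of the full pipeline
#'
#' Runs the complete two-step procedure — penalty path, cross-validated
#' penalty choice, post-LASSO refit — inside each training fold, collects
#' the held-out predictions, and reports the R-squared (squared Pearson,
#' plus the 1 - SSE/SST variant) of the pooled held-out predictions
#' against the truth.
#'
#' @inheritParams select_lambda_cv
#' @param inner_k Folds for the penalty choice inside each training fold.
#' @return A list: `r2`, `r2_ss`, `predictions` (tibble of village, truth,
#'   held-out prediction, fold).
#' @export
crossfold_r2 <- function(design, y, weights = NULL, k = 5, seed = 1,
                         inner_k = 5, ...) {
  stopifnot(inherits(design, "density_design"))
  n <- nrow(design$x)
  if (n < 2 * k) abort_data("Need at least 2k observations for k-fold CV.")
  w <- resolve_weights(weights, n)
  folds <- fold_assignment(design$village_id, k, seed)
  inner_seeds <- spawn_seeds(seed, k)
  preds <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    hold <- folds == f
    tr <- subset_design(design, !hold)
    tr <- drop_degenerate_columns(tr, warn_fold = f)
    cv <- select_lambda_cv(tr, y[!hold], w[!hold], k = inner_k,
                           seed = inner_seeds[f], ...)
    model <- post_lasso_fit(tr, y[!hold], w[!hold], cv$lambda_star, cv$path,
                            cluster = FALSE)
    ho <- subset_design(design, hold)
    ho$x <- ho$x[, colnames(tr$x), drop = FALSE]
    preds[hold] <- predict_density(model, ho)$density_pred
  }
  list(
    r2 = cor(y, preds)^2,
    r2_ss = 1 - sum((y - preds)^2) / sum((y - mean(y))^2),
    predictions = tibble::tibble(village_id = design$village_id,
                                 y_true = y, y_pred = preds, fold = folds)
  )
}
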