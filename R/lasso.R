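#' L1-penalized weighted Poisson regularization path
#'
#' Solves, for a decreasing grid of penalty levels,
#' `min -(1/N) sum w (y eta - exp(eta)) + lambda * sum_penalized |tau_j|`
#' by iteratively reweighted cyclic coordinate descent with
#' soft-thresholding. Penalized columns are standardized to weighted mean
#' zero and unit weighted variance before thresholding; forced columns
#' (district dummies, urban, log area) and the intercept are never
#' penalized nor thresholded. Coefficients are returned on the original
#' covariate scale. The grid starts at `lambda_max`, the smallest penalty
#' at which every penalized coefficient is exactly zero (computed from the
#' score of the forced-only fit), and descends geometrically to
#' `lambda_max * lambda_min_ratio`.
#'
#' @inheritParams fit_poisson_irls
#' @param n_lambda Grid length (default 100).
#' @param lambda_min_ratio Ratio `lambda_min / lambda_max` (default 1e-4).
#' @param lambda Optional explicit decreasing grid of positive penalties
#'   (overrides the automatic grid). Zero or negative entries are a
#'   validation error; the unpenalized fit is [fit_poisson_irls()].
#' @param tol_cd Inner sweep tolerance on the maximum (standardized-scale)
#'   coefficient change.
#' @param max_sweeps Maximum cyclic sweeps per IRLS step.
#' @return An object of class `lasso_path`: `lambda`, `coefficients`
#'   (grid x columns, original scale, intercept first), `objective`
#'   (penalized, standardized scale), `df` (nonzero penalized count),
#'   `kkt_max_violation`, plus standardization bookkeeping.
#' @export
lasso_path <- function(design, y, weights = NULL, n_lambda = 100,
                       lambda_min_ratio = 1e-4, lambda = NULL,
                       tol = 1e-8, tol_cd = 1e-10, max_sweeps = 1000,
                       max_iter = 100) {
  stopifnot(inherits(design, "density_design"))
  x <- design$x
  pen <- design$penalized
  if (!any(pen)) abort_config("The design has no penalized columns.")
  n <- nrow(x)
  if (length(y) != n) abort_data("`y` length does not match the design.")
  w <- resolve_weights(weights, n)
  v <- w / n

  std <- standardize_penalized(x, pen, v)
  xs <- std$x

  # null (forced-only) fit gives the score that defines lambda_max
  forced_fit <- fit_poisson_irls(x[, !pen, drop = FALSE], y, w,
                                 tol = tol, max_iter = max_iter)
  mu0 <- forced_fit$fitted
  score0 <- drop(crossprod(xs[, pen, drop = FALSE], v * (y - mu0)))
  # nudge above the analytic boundary so the first grid point sits strictly
  # in the all-zero region (KKT equality is numerically fragile)
  lambda_max <- max(abs(score0)) * (1 + 1e-6)
  if (is.null(lambda)) {
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = n_lambda))
  } else {
    lambda <- as.numeric(lambda)
    if (any(lambda <= 0)) {
      abort_config("All `lambda` values must be strictly positive; use fit_poisson_irls() for lambda = 0.")
    }
    lambda <- sort(lambda, decreasing = TRUE)
  }

  fit <- cd_poisson_path(xs, y, v, pen, lambda,
                         alpha_start = log(max(wtd_mean(y, w), 1e-8)),
                         tol_irls = tol, tol_cd = tol_cd,
                         max_sweeps = max_sweeps, max_irls = max_iter)
  if (!all(fit$converged)) {
    warn(sprintf("Coordinate descent did not fully converge at %d of %d lambda value(s).",
                 sum(!fit$converged), length(lambda)))
  }

  beta_std <- fit$beta                # p x nl, standardized penalized scale
  kkt <- kkt_violations(xs, y, v, pen, lambda, beta_std, fit$alpha)

  # de-standardize
  beta <- beta_std
  beta[pen, ] <- beta_std[pen, , drop = FALSE] / std$scale[pen]
  alpha <- fit$alpha -
    colSums(beta_std[pen, , drop = FALSE] * (std$center[pen] / std$scale[pen]))
  coefs <- t(rbind("(Intercept)" = alpha, beta))
  colnames(coefs) <- c("(Intercept)", colnames(x))

  structure(list(
    lambda = lambda,
    coefficients = coefs,
    coefficients_std = beta_std,
    alpha_std = fit$alpha,
    objective = fit$objective,
    df = colSums(beta_std[pen, , drop = FALSE] != 0),
    converged = fit$converged,
    kkt_max_violation = kkt,
    penalized = pen,
    center = std$center,
    scale = std$scale,
    lambda_max = lambda_max,
    weights = w
  ), class = "lasso_path")
}

standardize_penalized <- function(x, pen, v) {
  center <- setNames(rep(0, ncol(x)), colnames(x))
  scale <- setNames(rep(1, ncol(x)), colnames(x))
  xs <- x
  for (j in which(pen)) {
    m <- sum(v * x[, j])
    s <- sqrt(sum(v * (x[, j] - m)^2))
    if (s <= 0) abort_data(sprintf("Penalized column '%s' is constant.",
                                   colnames(x)[j]))
    center[j] <- m
    scale[j] <- s
    xs[, j] <- (x[, j] - m) / s
  }
  list(x = xs, center = center, scale = scale)
}

# max KKT subgradient violation per lambda, standardized scale:
#   zero coefficients:     |score_j| <= lambda
#   nonzero coefficients:  score_j = lambda * sign(tau_j)
kkt_violations <- function(xs, y, v, pen, lambda, beta_std, alpha_std) {
  vapply(seq_along(lambda), function(l) {
    eta <- drop(xs %*% beta_std[, l]) + alpha_std[l]
    score <- drop(crossprod(xs[, pen, drop = FALSE],
                            v * (y - exp(pmin(eta, 300)))))
    b <- beta_std[pen, l]
    viol_zero <- pmax(abs(score[b == 0]) - lambda[l], 0)
    viol_nz <- abs(score[b != 0] - lambda[l] * sign(b[b != 0]))
    max(c(viol_zero, viol_nz, 0))
  }, numeric(1))
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("<lasso_path> %d lambda values in [%.3g, %.3g]; df %d..%d\n",
              length(x$lambda), min(x$lambda), max(x$lambda),
              min(x$df), max(x$df)))
  invisible(x)
}

#' @rdname lasso_path
#' @param x A `lasso_path`.
#' @param ... Unused.
#' @export
tidy.lasso_path <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(
    lambda = rep(x$lambda, times = ncol(co)),
    term = rep(colnames(co), each = nrow(co)),
    estimate = as.numeric(co),
    penalized = rep(c(FALSE, unname(x$penalized)), each = nrow(co))
  )
}

#' @rdname lasso_path
#' @export
autoplot.lasso_path <- function(x, ...) {
  df <- tidy(x)
  df <- df[df$penalized, ]
  ggplot2::ggplot(df, ggplot2::aes(x = log(.data$lambda), y = .data$estimate,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log(lambda)", y = "coefficient (original scale)",
                  colour = NULL,
                  title = "Penalized Poisson coefficient paths") +
    ggplot2::theme_minimal()
}

#' Choose the penalty by k-fold cross-validated RMSE
#'
#' Villages are assigned to folds by a seeded permutation of their sorted
#' ids (so the assignment is invariant to row order). For each fold the
#' path is refit on the training villages over the same penalty grid and
#' the held-out root-mean-squared error of `exp(eta)` against `y` is
#' recorded; `lambda_star` minimizes the mean fold RMSE, with ties broken
#' toward the larger (sparser) penalty.
#'
#' @inheritParams lasso_path
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param path Optional precomputed [lasso_path()] on the full data (its
#'   grid is reused).
#' @return A list: `lambda_star`, `cv` (tibble of lambda, mean and per-fold
#'   RMSE), `folds` (named fold assignment), and the full-data `path`.
#' @export
select_lambda_cv <- function(design, y, weights = NULL, k = 5, seed = 1,
                             path = NULL, ...) {
  stopifnot(inherits(design, "density_design"))
  n <- nrow(design$x)
  if (n < 2 * k) abort_data("Need at least 2k observations for k-fold CV.")
  w <- resolve_weights(weights, n)
  dots <- list(...)
  if (is.null(path)) {
    path <- do.call(lasso_path, c(list(design, y, w), dots))
  }
  # fold refits reuse the full-data grid; grid-shaping args must not recur
  dots[c("lambda", "n_lambda", "lambda_min_ratio")] <- NULL
  lambda <- path$lambda
  folds <- fold_assignment(design$village_id, k, seed)
  rmse <- matrix(NA_real_, length(lambda), k)
  for (f in seq_len(k)) {
    hold <- folds == f
    tr_design <- subset_design(design, !hold)
    tr_design <- drop_degenerate_columns(tr_design, warn_fold = f)
    fold_path <- do.call(lasso_path,
                         c(list(tr_design, y[!hold], w[!hold], lambda = lambda),
                           dots))
    xh <- cbind(1, design$x[hold, colnames(tr_design$x), drop = FALSE])
    pred <- exp(pmin(xh %*% t(fold_path$coefficients), 300))
    rmse[, f] <- sqrt(colMeans((pred - y[hold])^2))
  }
  mean_rmse <- rowMeans(rmse)
  best <- which(mean_rmse <= min(mean_rmse) + 1e-12)[1]  # largest lambda wins ties
  list(
    lambda_star = lambda[best],
    cv = tibble::tibble(lambda = lambda, mean_rmse = mean_rmse,
                        fold_rmse = asplit(rmse, 1)),
    folds = setNames(folds, design$village_id),
    path = path
  )
}

# seeded fold assignment keyed to sorted village ids (row-order invariant)
fold_assignment <- function(ids, k, seed) {
  ord_ids <- sort(ids)
  f <- withr::with_seed(as.integer(seed),
                        sample(rep_len(seq_len(k), length(ids))))
  f[match(ids, ord_ids)]
}

# drop columns that became constant/collinear inside a training fold
drop_degenerate_columns <- function(design, warn_fold = NULL) {
  x <- design$x
  keep <- apply(x, 2, function(col) max(col) > min(col))
  qr_x <- qr(cbind(1, x[, keep, drop = FALSE]))
  if (qr_x$rank < sum(keep) + 1) {
    drop_idx <- qr_x$pivot[(qr_x$rank + 1):(sum(keep) + 1)] - 1
    drop_idx <- drop_idx[drop_idx > 0]
    keep[which(keep)[drop_idx]] <- FALSE
  }
  if (!all(keep)) {
    warn(sprintf("Dropping degenerate column(s)%s: %s.",
                 if (is.null(warn_fold)) "" else sprintf(" in fold %d", warn_fold),
                 paste(colnames(x)[!keep], collapse = ", ")))
    design <- select_columns(design, which(keep))
  }
  design
}

#' Post-LASSO refit on the selected support
#'
#' Refits the unpenalized weighted Poisson pseudo-likelihood on the
#' penalized columns with nonzero path coefficients at `lambda_star` plus
#' all forced columns, removing the shrinkage bias of the raw path
#' coefficients. An empty selection is not an error: the model reduces to
#' the forced-only fit (with a message).
#'
#' @inheritParams select_lambda_cv
#' @param lambda_star A value on the computed path.
#' @param path A [lasso_path()] containing `lambda_star`.
#' @param cluster Clusters for the sandwich covariance (default the
#'   design's sub-districts).
#' @param scheme Weight scheme label stored with the fit.
#' @return An object of class `density_model`.
#' @export
post_lasso_fit <- function(design, y, weights = NULL, lambda_star, path,
                           cluster = TRUE, scheme = "uniform", seed = NA) {
  stopifnot(inherits(design, "density_design"), inherits(path, "lasso_path"))
  idx <- which(abs(path$lambda - lambda_star) <=
                 1e-10 * max(path$lambda, 1))
  if (length(idx) == 0) abort_usage("`lambda_star` is not on the computed path.")
  idx <- idx[1]
  beta <- path$coefficients[idx, -1]
  selected <- names(which(path$penalized & beta != 0))
  if (length(selected) == 0) {
    rlang::inform("LASSO selected no covariates; model reduces to the forced-only fit.")
  }
  support <- c(selected, names(which(!path$penalized)))
  support <- intersect(colnames(design$x), support)
  fit <- fit_poisson_irls(select_columns(design, support), y, weights,
                          cluster = cluster)
  structure(list(
    coefficients = fit$coefficients,
    selected = selected,
    lambda_star = lambda_star,
    shrunk_coefficients = path$coefficients[idx, c("(Intercept)", support)],
    scheme = scheme,
    vcov = fit$vcov,
    objective = fit$objective,
    fitted = fit$fitted,
    village_id = design$village_id,
    support = support,
    meta = design$meta,
    fold_seed = seed,
    path_summary = list(lambda_max = path$lambda_max,
                        n_lambda = length(path$lambda),
                        df = path$df[idx])
  ), class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat("<density_model> weighted Poisson post-LASSO fit\n")
  cat(sprintf("  lambda*  : %.4g (%d covariate(s) selected)\n",
              x$lambda_star, length(x$selected)))
  cat(sprintf("  selected : %s\n",
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none)"))
  cat(sprintf("  weights  : %s\n", x$scheme))
  invisible(x)
}

#' @export
coef.density_model <- function(object, ...) object$coefficients

#' @export
vcov.density_model <- function(object, ...) object$vcov

#' @rdname post_lasso_fit
#' @param x,object A `density_model`.
#' @param ... Unused.
#' @export
tidy.density_model <- function(x, ...) {
  out <- tibble::tibble(term = names(x$coefficients),
                        estimate = as.numeric(x$coefficients),
                        selected = names(x$coefficients) %in% x$selected)
  if (!is.null(x$vcov)) {
    out$std.error <- sqrt(diag(x$vcov))
    out$statistic <- out$estimate / out$std.error
    out$p.value <- 2 * pnorm(-abs(out$statistic))
  }
  out
}

#' @rdname post_lasso_fit
#' @export
glance.density_model <- function(x, ...) {
  tibble::tibble(
    lambda_star = x$lambda_star,
    n_selected = length(x$selected),
    scheme = x$scheme,
    objective = x$objective,
    n_train = length(x$fitted)
  )
}

#' @rdname post_lasso_fit
#' @export
autoplot.density_model <- function(x, ...) {
  df <- tidy(x)
  df <- df[df$term != "(Intercept)" & !grepl("^district", df$term), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term, .data$estimate),
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "post-LASSO coefficient", y = NULL, fill = "selected",
                  title = "Density model coefficients") +
    ggplot2::theme_minimal()
}

#' Predict population density
#'
#' Evaluates `exp(alpha + x' theta)` for new villages; predictions are
#' strictly positive by construction.
#'
#' @param model A `density_model` (or `poisson_fit`).
#' @param design_new A `density_design` for the new villages (or a numeric
#'   matrix with named columns covering the model support).
#' @return A tibble `village_id`, `density_pred`.
#' @export
predict_density <- function(model, design_new) {
  co <- model$coefficients
  terms <- setdiff(names(co), "(Intercept)")
  if (inherits(design_new, "density_design")) {
    x <- design_new$x
    ids <- design_new$village_id
  } else {
    x <- as.matrix(design_new)
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  }
  missing <- setdiff(terms, colnames(x))
  if (length(missing)) {
    abort_data(sprintf("New design lacks model column(s): %s.",
                       paste(missing, collapse = ", ")))
  }
  eta <- drop(x[, terms, drop = FALSE] %*% co[terms]) + co[["(Intercept)"]]
  tibble::tibble(village_id = ids, density_pred = exp(pmin(eta, 300)))
}
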