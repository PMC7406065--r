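#' Weighted Poisson pseudo-likelihood fit (IRLS)
#'
#' Maximizes the weighted Poisson pseudo-log-likelihood
#' `sum_v w_v (y_v eta_v - exp(eta_v))` with `eta = alpha + x' theta`.
#' The response may be any non-negative real (population density is
#' continuous); the estimator solves the quasi-Poisson score equations, so
#' no integrality is assumed. Weights are normalized to mean 1 internally,
#' making the fit invariant to the weight scale.
#'
#' This is also the `lambda = 0` limit of the penalized path in
#' [lasso_path()].
#'
#' @param design A `density_design` (or a bare numeric matrix).
#' @param y Non-negative response vector.
#' @param weights Positive observation weights (default uniform). May be a
#'   `weight_vector` from [compute_weights()].
#' @param cluster Optional cluster labels for a sandwich (cluster-robust)
#'   covariance; `TRUE` uses the design's sub-district labels.
#' @param tol Relative-objective convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `poisson_fit`: coefficients (intercept
#'   first), fitted values, the minimized objective
#'   `-(1/N) sum w (y eta - exp(eta))`, its iteration trace, and optional
#'   cluster-robust covariance `vcov`.
#' @export
fit_poisson_irls <- function(design, y, weights = NULL, cluster = NULL,
                             tol = 1e-8, max_iter = 100) {
  x <- if (inherits(design, "density_design")) design$x else as.matrix(design)
  n <- nrow(x)
  if (length(y) != n) abort_data("`y` length does not match the design.")
  if (any(y < 0) || anyNA(y)) abort_data("`y` must be non-negative and complete.")
  w <- resolve_weights(weights, n)
  cl <- NULL
  if (isTRUE(cluster)) {
    if (!inherits(design, "density_design")) {
      abort_usage("`cluster = TRUE` requires a `density_design` with cluster labels.")
    }
    cl <- design$cluster
  } else if (!is.null(cluster) && !isFALSE(cluster)) {
    cl <- cluster
  }

  x1 <- cbind("(Intercept)" = 1, x)
  qr_x <- qr(sqrt(w) * x1)
  if (qr_x$rank < ncol(x1)) {
    bad <- colnames(x1)[qr_x$pivot[(qr_x$rank + 1):ncol(x1)]]
    abort_data(sprintf("Design is rank deficient; collinear column(s): %s.",
                       paste(bad, collapse = ", ")))
  }

  beta <- c(log(max(wtd_mean(y, w), 1e-8)), rep(0, ncol(x)))
  eta <- drop(x1 %*% beta)
  obj <- poisson_objective(eta, y, w)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- exp(pmin(pmax(eta, -30), 30))
    v <- w * mu
    z <- eta + (y - mu) / mu
    fit <- lm.wfit(x1, z, v)
    beta_new <- fit$coefficients
    eta_new <- drop(x1 %*% beta_new)
    obj_new <- poisson_objective(eta_new, y, w)
    # step-halving keeps IRLS monotone on hard instances
    step <- 1
    while (obj_new > obj + 1e-12 && step > 1e-4) {
      step <- step / 2
      beta_new <- beta + step * (fit$coefficients - beta)
      eta_new <- drop(x1 %*% beta_new)
      obj_new <- poisson_objective(eta_new, y, w)
    }
    delta <- abs(obj - obj_new) / (abs(obj) + 1e-10)
    beta <- beta_new
    eta <- eta_new
    obj <- obj_new
    trace <- c(trace, obj)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    cond <- rlang::error_cnd(class = "bottomup_convergence_error",
                             message = sprintf(
                               "IRLS did not converge in %d iterations (last objective %.8g).",
                               max_iter, obj),
                             trace_objective = trace)
    rlang::cnd_signal(cond)
  }
  mu <- exp(pmin(pmax(eta, -30), 30))
  vc <- NULL
  if (!is.null(cl)) vc <- cluster_sandwich(x1, y, mu, w, cl)
  structure(list(
    coefficients = setNames(as.numeric(beta), colnames(x1)),
    fitted = mu,
    objective = obj,
    trace = trace,
    iterations = it,
    weights = w,
    vcov = vc,
    cluster = if (!is.null(cl)) "supplied" else NULL,
    terms = colnames(x1)
  ), class = "poisson_fit")
}

# -(1/N) sum w_i (y_i eta_i - exp(eta_i)); w already mean-1
poisson_objective <- function(eta, y, w) {
  -mean(w * (y * eta - exp(pmin(eta, 300))))
}

resolve_weights <- function(weights, n) {
  if (is.null(weights)) {
    w <- rep(1, n)
  } else if (inherits(weights, "weight_vector") || is.data.frame(weights)) {
    w <- weights$w
  } else {
    w <- as.numeric(weights)
  }
  if (length(w) != n) abort_data("Weight length does not match the data.")
  if (any(!is.finite(w)) || any(w <= 0)) {
    abort_data("All weights must be positive and finite.")
  }
  w / mean(w)
}

# cluster-robust sandwich for the Poisson pseudo-likelihood
cluster_sandwich <- function(x1, y, mu, w, cluster) {
  a <- crossprod(x1, (w * mu) * x1)
  s <- (w * (y - mu)) * x1
  sc <- rowsum(s, group = cluster)
  b <- crossprod(as.matrix(sc))
  ainv <- solve(a)
  g <- nrow(sc)
  # small-sample factor g/(g-1), the usual CR1-style correction
  v <- ainv %*% b %*% ainv * g / max(g - 1, 1)
  dimnames(v) <- list(colnames(x1), colnames(x1))
  v
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf("<poisson_fit> %d terms, objective %.6g (%d IRLS iterations)\n",
              length(x$coefficients), x$objective, x$iterations))
  invisible(x)
}

#' @export
coef.poisson_fit <- function(object, ...) object$coefficients

#' @export
vcov.poisson_fit <- function(object, ...) object$vcov

#' @rdname fit_poisson_irls
#' @param x,object A `poisson_fit`.
#' @param ... Unused.
#' @export
tidy.poisson_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$coefficients),
                        estimate = as.numeric(x$coefficients))
  if (!is.null(x$vcov)) {
    out$std.error <- sqrt(diag(x$vcov))
    out$statistic <- out$estimate / out$std.error
    out$p.value <- 2 * pnorm(-abs(out$statistic))
  }
  out
}

#' @rdname fit_poisson_irls
#' @export
glance.poisson_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, iterations = x$iterations,
                 n_terms = length(x$coefficients))
}
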