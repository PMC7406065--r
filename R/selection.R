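#' Probit model for village selection into the survey
#'
#' Fits a maximum-likelihood probit of the survey-inclusion indicator on
#' the LASSO-selected covariates (plus an intercept) over every village in
#' the frame, yielding the predicted selection probabilities used by the
#' balance-corrected weights `1 / (pop_v * INhat_v)`.
#'
#' @param covars_selected Data frame or matrix of the selected covariates
#'   for all villages (numeric columns only), or a tibble with
#'   `village_id` plus covariates.
#' @param in_survey Logical (or 0/1) vector: is the village in the survey?
#' @return An object of class `selection_model` with `eta0` (intercept),
#'   `eta1` (slopes), and `fitted` probabilities strictly inside (0, 1).
#' @export
fit_selection_probit <- function(covars_selected, in_survey) {
  ids <- NULL
  if (is.data.frame(covars_selected) && "village_id" %in% names(covars_selected)) {
    ids <- covars_selected$village_id
    covars_selected <- covars_selected[setdiff(names(covars_selected), "village_id")]
  }
  x <- as.matrix(covars_selected)
  yy <- as.numeric(in_survey)
  if (length(yy) != nrow(x)) abort_data("`in_survey` length does not match the covariates.")
  if (length(unique(yy)) < 2) {
    abort_data("`in_survey` has a single class; the probit cannot be fit.")
  }
  qr_x <- qr(cbind(1, x))
  if (qr_x$rank < ncol(x) + 1) {
    abort_data("Selected-covariate matrix is rank deficient.")
  }
  df <- data.frame(.in = yy, x)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.in ~ ., data = df, family = binomial(link = "probit")),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  # near-zero deviance = perfect classification; extreme-probability
  # warnings alone are tolerated (strong gradients produce them honestly)
  # unless the slopes are running away
  if (fit$deviance < 1e-6 || (sep && max(abs(coef(fit)[-1])) > 20)) {
    abort_data(paste(
      "Complete (or quasi-complete) separation in the selection probit;",
      "consider relying on the probability floor (p_floor) or fewer covariates."))
  }
  p <- pmin(pmax(as.numeric(fit$fitted.values), 1e-12), 1 - 1e-12)
  structure(list(
    eta0 = unname(coef(fit)[1]),
    eta1 = coef(fit)[-1],
    fitted = if (is.null(ids)) p else setNames(p, ids),
    village_id = ids,
    glm_fit = fit
  ), class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf("<selection_model> probit on %d covariate(s); fitted range [%.3g, %.3g]\n",
              length(x$eta1), min(x$fitted), max(x$fitted)))
  invisible(x)
}

#' @rdname fit_selection_probit
#' @param x A `selection_model`.
#' @param ... Unused.
#' @export
tidy.selection_model <- function(x, ...) {
  s <- summary(x$glm_fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' Observation weights for the survey-based density model
#'
#' `inverse_pop` uses `w_v = 1 / pop_v` (survey-based fits weight down
#' large villages whose survey densities are comparatively noisy in the
#' emulated design). `balance_corrected` additionally divides by the
#' probit-predicted selection probability, `w_v = 1 / (pop_v * INhat_v)`,
#' with probabilities clipped from below at `p_floor` so weights stay
#' bounded. `uniform` gives `w_v = 1`.
#'
#' @param pop Positive village populations (optionally named by village).
#' @param scheme One of `"uniform"`, `"inverse_pop"`, `"balance_corrected"`.
#' @param selection A [fit_selection_probit()] model; required (and only
#'   allowed) for `"balance_corrected"`. Probabilities are matched by name
#'   when both `pop` and the selection model carry village ids.
#' @param p_floor Lower clip for predicted selection probabilities
#'   (default 0.01).
#' @return A tibble of class `weight_vector` with columns `village_id`
#'   (if available), `w`, and `scheme`; attribute `n_floored` counts
#'   probabilities raised to the floor.
#' @export
compute_weights <- function(pop, scheme = c("uniform", "inverse_pop",
                                            "balance_corrected"),
                            selection = NULL, p_floor = 0.01) {
  scheme <- match.arg(scheme)
  pop <- if (is.data.frame(pop)) setNames(pop$population, pop$village_id) else pop
  if (any(!is.finite(pop)) || any(pop <= 0)) {
    abort_data("`pop` must be strictly positive and finite.")
  }
  if (scheme == "balance_corrected" && is.null(selection)) {
    abort_usage("`balance_corrected` weights require a selection model.")
  }
  if (scheme != "balance_corrected" && !is.null(selection)) {
    abort_usage("A selection model is only used with scheme = 'balance_corrected'.")
  }
  n_floored <- 0L
  w <- switch(scheme,
    uniform = rep(1, length(pop)),
    inverse_pop = 1 / pop,
    balance_corrected = {
      p <- selection$fitted
      if (!is.null(names(pop)) && !is.null(names(p))) {
        p <- p[names(pop)]
        if (anyNA(p)) abort_data("Selection model lacks probabilities for some villages.")
      } else if (length(p) != length(pop)) {
        abort_data("Selection probabilities do not align with `pop`.")
      }
      n_floored <- sum(p < p_floor)
      1 / (pop * pmax(p, p_floor))
    }
  )
  out <- tibble::tibble(village_id = names(pop) %||% NA_character_,
                        w = as.numeric(w), scheme = scheme)
  class(out) <- c("weight_vector", class(out))
  attr(out, "n_floored") <- n_floored
  attr(out, "p_floor") <- p_floor
  out
}
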