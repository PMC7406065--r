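#' Internal validators
#'
#' Small assertion helpers shared across the package. They raise classed
#' conditions so callers (and tests) can distinguish configuration errors
#' from data errors.
#'
#' @name bottomup-validators
#' @keywords internal
NULL

abort_config <- function(msg) abort(msg, class = "bottomup_config_error")
abort_data <- function(msg) abort(msg, class = "bottomup_data_error")
abort_usage <- function(msg) abort(msg, class = "bottomup_usage_error")

check_count <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x)) {
    abort_config(sprintf("`%s` must be a single positive integer.", name))
  }
  as.integer(x)
}

check_fraction <- function(x, name, open_left = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x > 1 ||
      (open_left && x <= 0) || (!open_left && x < 0)) {
    abort_config(sprintf("`%s` must be a single number in %s.", name,
                         if (open_left) "(0, 1]" else "[0, 1]"))
  }
  as.numeric(x)
}

check_cols <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_data(sprintf("`%s` is missing required column(s): %s.",
                       name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Derive independent child seeds from one master seed
#'
#' Each pipeline stage consumes its own seed so that stages are individually
#' reproducible.  Children are drawn from a short generator stream seeded by
#' the master seed and kept below 2^31.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @keywords internal
spawn_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# weighted mean/variance with weights summing to anything positive
wtd_mean <- function(x, w) sum(w * x) / sum(w)
wtd_var <- function(x, w) {
  m <- wtd_mean(x, w)
  sum(w * (x - m)^2) / sum(w)
}
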