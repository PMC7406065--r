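#' Build the model design matrix
#'
#' Assembles the village-level design used by all density models: a
#' penalized block of geospatial covariates and a forced (never-penalized)
#' block of district dummies (reference coding, lexicographically first
#' district dropped), the urban indicator, and log village area. Constant
#' columns (e.g. the urban dummy in an all-rural frame) are dropped with a
#' warning so the design never carries a constant column after the
#' reference drop.
#'
#' @param frame Village frame with `village_id`, `district_id`,
#'   `sub_district_id`, `sector`, `log_area`.
#' @param covariates Covariate table (`village_id` + numeric columns).
#' @param covariate_cols Which covariate columns to penalize; default all
#'   non-id columns.
#' @param district_levels Optional fixed district level set (used when
#'   building a prediction design that must match a training design).
#' @return An object of class `density_design`: list with the numeric
#'   matrix `x` (no intercept column), logical `penalized` per column,
#'   `village_id`, `cluster` (sub-district), and `meta` (term bookkeeping).
#' @export
build_design_matrix <- function(frame, covariates,
                                covariate_cols = NULL,
                                district_levels = NULL) {
  check_cols(frame, c("village_id", "district_id", "sub_district_id",
                      "sector", "log_area"), "frame")
  check_cols(covariates, "village_id", "covariates")
  covariate_cols <- covariate_cols %||% setdiff(names(covariates), "village_id")
  if (length(covariate_cols) == 0) {
    abort_config("At least one penalized covariate column is required.")
  }
  check_cols(covariates, covariate_cols, "covariates")
  cv <- covariates[match(frame$village_id, covariates$village_id),
                   covariate_cols, drop = FALSE]
  if (anyNA(cv)) abort_data("`covariates` must cover every village in `frame`.")
  xpen <- as.matrix(cv)

  district_levels <- district_levels %||% sort(unique(frame$district_id))
  if (!all(frame$district_id %in% district_levels)) {
    abort_data("`frame` contains districts outside `district_levels`.")
  }
  ref <- district_levels[1]
  dums <- lapply(setdiff(district_levels, ref), function(d) {
    as.numeric(frame$district_id == d)
  })
  if (length(dums)) {
    names(dums) <- paste0("district", setdiff(district_levels, ref))
  }
  zf <- cbind(
    if (length(dums)) do.call(cbind, dums),
    urban = as.numeric(frame$sector == "urban"),
    log_area = frame$log_area
  )
  x <- cbind(xpen, zf)
  penalized <- c(rep(TRUE, ncol(xpen)), rep(FALSE, ncol(zf)))
  names(penalized) <- colnames(x)
  keep <- apply(x, 2, function(col) max(col) > min(col))
  if (!all(keep)) {
    warn(sprintf("Dropping constant column(s): %s.",
                 paste(colnames(x)[!keep], collapse = ", ")))
    x <- x[, keep, drop = FALSE]
    penalized <- penalized[keep]
  }
  structure(list(
    x = x,
    penalized = penalized,
    village_id = frame$village_id,
    cluster = frame$sub_district_id,
    meta = list(covariate_cols = covariate_cols,
                district_levels = district_levels,
                reference_district = ref)
  ), class = "density_design")
}

#' @export
print.density_design <- function(x, ...) {
  cat(sprintf("<density_design> %d villages, %d penalized + %d forced columns\n",
              nrow(x$x), sum(x$penalized), sum(!x$penalized)))
  invisible(x)
}

#' Row-subset a density design
#' @param design A `density_design`.
#' @param rows Integer or logical row index.
#' @return A `density_design` on the selected rows.
#' @export
subset_design <- function(design, rows) {
  stopifnot(inherits(design, "density_design"))
  out <- design
  out$x <- design$x[rows, , drop = FALSE]
  out$village_id <- design$village_id[rows]
  out$cluster <- design$cluster[rows]
  out
}

# column-subset (keeps the penalized flags of the retained columns)
select_columns <- function(design, cols) {
  out <- design
  out$x <- design$x[, cols, drop = FALSE]
  out$penalized <- design$penalized[cols]
  out
}
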