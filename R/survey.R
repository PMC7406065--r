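#' Specify the two-stage stratified household survey design
#'
#' The design emulates a national income/expenditure survey: villages are
#' selected within district-by-sector strata, one census block (PSU) is
#' drawn per selected village (occasionally two, controlled by
#' `extra_psu_fraction`), and a fixed number of households is enumerated
#' within the block. All inclusion probabilities are exact, so design
#' weights are exact inverse inclusion probabilities.
#'
#' Village selection is equal-probability (fixed-size simple random
#' sampling without replacement within each stratum) when
#' `selection_tilt` is `NULL` or all-zero. With a non-zero tilt the
#' village inclusion probability becomes a probit function of the tilted
#' standardized covariate index,
#' `pi_v = Phi(qnorm(f_h) + tilt' x_v)` with `f_h` the stratum base
#' sampling fraction, and villages enter independently (Bernoulli
#' sampling). This makes a probit selection model on the same covariates
#' the correctly specified correction.
#'
#' @param sample_fraction Fraction of (populated) villages to sample when
#'   `n_villages` is `NULL`. The default 0.17 mirrors a survey covering
#'   about 17% of villages.
#' @param n_villages Optional total number of villages to sample
#'   (proportionally allocated across strata), or a named vector of
#'   per-stratum counts (names `"district.sector"`).
#' @param psus_per_village Number of PSUs drawn per selected village
#'   (default 1).
#' @param extra_psu_fraction Probability that a selected village with at
#'   least two blocks receives one additional sampled PSU. Villages with
#'   more than one sampled PSU are excluded from density estimation; the
#'   default 0.03 reproduces the "97% of surveyed villages contain exactly
#'   one PSU" situation. Set to 0 for a strictly single-PSU design.
#' @param households_per_psu Households enumerated per sampled PSU
#'   (default 10; if the block is smaller, the whole block is taken).
#' @param households_per_block Number of households per census block used
#'   to partition a village into PSUs (default 80).
#' @param mean_household_size Mean household size used to partition the
#'   census population into households (default 4).
#' @param selection_tilt Named numeric vector over covariate columns; zero
#'   or `NULL` means uniform sampling.
#' @param seed Integer seed for the survey draw.
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(sample_fraction = 0.17,
                          n_villages = NULL,
                          psus_per_village = 1,
                          extra_psu_fraction = 0.03,
                          households_per_psu = 10,
                          households_per_block = 80,
                          mean_household_size = 4,
                          selection_tilt = NULL,
                          seed = 4102) {
  if (is.null(n_villages)) {
    sample_fraction <- check_fraction(sample_fraction, "sample_fraction",
                                      open_left = TRUE)
  }
  psus_per_village <- check_count(psus_per_village, "psus_per_village")
  extra_psu_fraction <- check_fraction(extra_psu_fraction, "extra_psu_fraction")
  households_per_psu <- check_count(households_per_psu, "households_per_psu")
  households_per_block <- check_count(households_per_block, "households_per_block")
  if (!is.null(selection_tilt)) {
    if (!is.numeric(selection_tilt) || is.null(names(selection_tilt))) {
      abort_config("`selection_tilt` must be a named numeric vector.")
    }
    if (all(selection_tilt == 0)) selection_tilt <- NULL
  }
  structure(list(
    sample_fraction = if (is.null(n_villages)) sample_fraction else NULL,
    n_villages = n_villages,
    psus_per_village = psus_per_village,
    extra_psu_fraction = extra_psu_fraction,
    households_per_psu = households_per_psu,
    households_per_block = households_per_block,
    mean_household_size = check_count(mean_household_size, "mean_household_size"),
    selection_tilt = selection_tilt,
    seed = as.integer(seed)
  ), class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("<survey_design>\n")
  if (!is.null(x$sample_fraction)) {
    cat(sprintf("  village stage : %.1f%% of populated villages per stratum\n",
                100 * x$sample_fraction))
  } else {
    cat(sprintf("  village stage : %s villages\n",
                paste(x$n_villages, collapse = "+")))
  }
  cat(sprintf("  psu stage     : %d block(s)/village (extra-PSU prob %.2f), %d hh/PSU\n",
              x$psus_per_village, x$extra_psu_fraction, x$households_per_psu))
  cat(sprintf("  tilt          : %s\n",
              if (is.null(x$selection_tilt)) "none (uniform)" else
                paste(names(x$selection_tilt), round(x$selection_tilt, 2),
                      collapse = ", ")))
  invisible(x)
}

#' Draw a two-stage stratified household survey
#'
#' Samples villages within district-by-sector strata, partitions each
#' selected village's census population into households and census blocks
#' (PSUs), draws `psus_per_village` blocks (plus occasionally one extra,
#' see [survey_design()]), and enumerates households within the sampled
#' blocks. Villages with zero census population are not part of the survey
#' frame (they contain no households to list).
#'
#' Each household's `design_weight` is the exact inverse of its overall
#' inclusion probability, so the weighted total
#' `sum(design_weight * household_size)` is design-unbiased for the census
#' population of the survey frame.
#'
#' @param frame Village frame ([generate_admin_frame()]).
#' @param covariates Covariate table; only needed when the design has a
#'   selection tilt.
#' @param census Census table ([generate_census()]).
#' @param design A [survey_design()].
#' @param seed Optional override of `design$seed`.
#' @return An object of class `survey_sample`: a list of tibbles
#'   `households` (`household_id`, `village_id`, `psu_id`,
#'   `household_size`, `design_weight`), `psus` (`psu_id`, `village_id`,
#'   `psu_census_population`, `psu_census_share`, `psu_selection_prob`),
#'   and `villages` (`village_id`, `stratum`, `pi_village`,
#'   `n_psus_sampled`).
#' @export
draw_survey <- function(frame, covariates = NULL, census, design, seed = NULL) {
  stopifnot(inherits(design, "survey_design"))
  check_cols(frame, c("village_id", "district_id", "sector", "area_km2"), "frame")
  check_cols(census, c("village_id", "population"), "census")
  seed <- seed %||% design$seed
  pop <- census$population[match(frame$village_id, census$village_id)]
  if (anyNA(pop)) abort_data("`census` does not cover every village in `frame`.")
  eligible <- pop > 0
  fr <- frame[eligible, ]
  pop <- pop[eligible]
  fr$stratum <- paste(fr$district_id, fr$sector, sep = ".")

  tilt <- design$selection_tilt
  tilt_index <- NULL
  if (!is.null(tilt)) {
    if (is.null(covariates)) {
      abort_usage("`covariates` must be supplied when the design has a selection tilt.")
    }
    check_cols(covariates, c("village_id", names(tilt)), "covariates")
    xm <- as.matrix(covariates[match(fr$village_id, covariates$village_id),
                               names(tilt), drop = FALSE])
    xm <- scale(xm)
    tilt_index <- drop(xm %*% tilt)
  }

  withr::with_seed(as.integer(seed), {
    strata <- split(seq_len(nrow(fr)), fr$stratum)
    n_by_stratum <- stratum_allocation(design, lengths(strata))
    sel <- logical(nrow(fr))
    pi_v <- numeric(nrow(fr))
    for (h in names(strata)) {
      idx <- strata[[h]]
      n_h <- n_by_stratum[[h]]
      if (n_h > length(idx)) {
        abort_config(sprintf(
          "Requested %d villages from stratum '%s' of size %d.",
          n_h, h, length(idx)))
      }
      if (is.null(tilt)) {
        pi_v[idx] <- n_h / length(idx)
        if (n_h > 0) sel[idx[sample.int(length(idx), n_h)]] <- TRUE
      } else {
        base <- min(max(n_h / length(idx), 1e-6), 1 - 1e-9)
        p <- pnorm(qnorm(base) + tilt_index[idx])
        p <- pmin(pmax(p, 1e-6), 1)
        pi_v[idx] <- p
        sel[idx] <- runif(length(idx)) < p
      }
    }

    sampled <- which(sel)
    hh_rows <- vector("list", length(sampled))
    psu_rows <- vector("list", length(sampled))
    vil_rows <- vector("list", length(sampled))
    for (k in seq_along(sampled)) {
      i <- sampled[k]
      parts <- partition_village(pop[i], design)
      b <- length(parts$block_pop)
      extra_ok <- design$extra_psu_fraction > 0 && b > design$psus_per_village
      n_draw <- min(design$psus_per_village, b) +
        (extra_ok && runif(1) < design$extra_psu_fraction)
      # marginal block inclusion probability given the village is selected
      pi_b <- if (b <= design$psus_per_village) 1 else
        (design$psus_per_village +
           (if (extra_ok) design$extra_psu_fraction else 0)) / b
      blocks <- sample.int(b, n_draw)
      vid <- fr$village_id[i]
      psu_ids <- sprintf("%s.P%03d", vid, blocks)
      hh_list <- vector("list", n_draw)
      for (j in seq_len(n_draw)) {
        bl <- blocks[j]
        sizes <- parts$hh_sizes[parts$hh_block == bl]
        m <- min(design$households_per_psu, length(sizes))
        take <- sample.int(length(sizes), m)
        hh_list[[j]] <- tibble::tibble(
          household_id = sprintf("%s.H%04d", psu_ids[j], take),
          village_id = vid,
          psu_id = psu_ids[j],
          household_size = sizes[take],
          design_weight = 1 / (pi_v[i] * pi_b * (m / length(sizes)))
        )
      }
      hh_rows[[k]] <- dplyr::bind_rows(hh_list)
      psu_pop <- vapply(blocks, function(bl) {
        sum(parts$hh_sizes[parts$hh_block == bl])
      }, numeric(1))
      psu_rows[[k]] <- tibble::tibble(
        psu_id = psu_ids,
        village_id = vid,
        psu_census_population = psu_pop,
        psu_census_share = psu_pop / pop[i],
        psu_selection_prob = pi_v[i] * pi_b
      )
      vil_rows[[k]] <- tibble::tibble(
        village_id = vid,
        stratum = fr$stratum[i],
        pi_village = pi_v[i],
        n_psus_sampled = n_draw
      )
    }
    structure(list(
      households = dplyr::bind_rows(hh_rows),
      psus = dplyr::bind_rows(psu_rows),
      villages = dplyr::bind_rows(vil_rows)
    ), class = "survey_sample")
  })
}

#' @export
print.survey_sample <- function(x, ...) {
  cat("<survey_sample>\n")
  cat(sprintf("  %d households in %d PSUs across %d villages\n",
              nrow(x$households), nrow(x$psus), nrow(x$villages)))
  multi <- mean(x$villages$n_psus_sampled > 1)
  cat(sprintf("  multi-PSU villages: %.1f%%\n", 100 * multi))
  invisible(x)
}

# proportional (largest remainder) allocation of the total sample across
# strata, honouring per-stratum overrides
stratum_allocation <- function(design, stratum_sizes) {
  if (!is.null(design$n_villages) && !is.null(names(design$n_villages))) {
    unknown <- setdiff(names(design$n_villages), names(stratum_sizes))
    if (length(unknown)) {
      abort_config(sprintf("Unknown or empty stratum in allocation: %s.",
                           paste(unknown, collapse = ", ")))
    }
    out <- setNames(rep(0L, length(stratum_sizes)), names(stratum_sizes))
    out[names(design$n_villages)] <- as.integer(design$n_villages)
    return(as.list(out))
  }
  total <- if (!is.null(design$n_villages)) {
    as.integer(design$n_villages)
  } else {
    max(1L, round(design$sample_fraction * sum(stratum_sizes)))
  }
  if (total > sum(stratum_sizes)) {
    abort_config("Requested sample exceeds the number of populated villages.")
  }
  quota <- total * stratum_sizes / sum(stratum_sizes)
  n <- pmin(floor(quota), stratum_sizes)
  rem <- total - sum(n)
  if (rem > 0) {
    room <- stratum_sizes - n
    frac <- quota - floor(quota)
    ord <- order(frac, decreasing = TRUE)
    for (i in ord) {
      if (rem == 0) break
      add <- min(room[i], 1)
      n[i] <- n[i] + add
      rem <- rem - add
    }
    # still short (rare): fill wherever room remains
    if (rem > 0) {
      for (i in order(stratum_sizes - n, decreasing = TRUE)) {
        if (rem == 0) break
        add <- min(stratum_sizes[i] - n[i], rem)
        n[i] <- n[i] + add
        rem <- rem - add
      }
    }
  }
  as.list(setNames(as.integer(n), names(stratum_sizes)))
}

# partition a village's census population into households with dispersed
# sizes (1 + Poisson around the design mean) and the households into
# roughly equal census blocks
partition_village <- function(population, design) {
  m <- design$mean_household_size
  n_guess <- max(1L, as.integer(ceiling(1.5 * population / m)))
  draws <- 1L + rpois(n_guess, max(m - 1, 0))
  cum <- cumsum(draws)
  while (cum[length(cum)] < population) {
    draws <- c(draws, 1L + rpois(n_guess, max(m - 1, 0)))
    cum <- cumsum(draws)
  }
  n_hh <- which(cum >= population)[1]
  sizes <- draws[seq_len(n_hh)]
  sizes[n_hh] <- sizes[n_hh] - (cum[n_hh] - population)
  if (sizes[n_hh] == 0L) {
    n_hh <- n_hh - 1L
    sizes <- sizes[seq_len(n_hh)]
    if (n_hh == 0L) {
      n_hh <- 1L
      sizes <- population
    }
  }
  n_blocks <- max(1L, as.integer(round(n_hh / design$households_per_block)))
  block <- sort(rep(seq_len(n_blocks), length.out = n_hh))
  list(hh_sizes = sizes, hh_block = block,
       block_pop = vapply(split(sizes, block), sum, numeric(1)))
}
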