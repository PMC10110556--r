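#' Log response ratio and its within-study variance
#'
#' The effect size is `lnRR = ln(mean_T / mean_C)`; its within-study variance
#' is `SE_T^2 / mean_T^2 + SE_C^2 / mean_C^2`. The between-study variance tau2
#' is a property of the analysis set, not the row, and is added later during
#' pooling.
#'
#' @param mean_t,se_t Treatment-arm mean and standard error.
#' @param mean_c,se_c Control-arm mean and standard error.
#' @return A list with numeric vectors `ln_rr` and `v_within`.
#' @examples
#' log_response_ratio(0.30, 0.03, 0.25, 0.05)
#' @export
log_response_ratio <- function(mean_t, se_t, mean_c, se_c) {
  if (any(mean_t <= 0 | mean_c <= 0)) {
    abort("Group means must be positive for the log response ratio.")
  }
  list(
    ln_rr = log(mean_t / mean_c),
    v_within = se_t^2 / mean_t^2 + se_c^2 / mean_c^2
  )
}

#' Back-transform a pooled log ratio to percentage change
#'
#' `percentage_change(x) = (exp(x) - 1) * 100`; the inverse is
#' `ln(1 + pct / 100)`.
#'
#' @param pooled_ln Numeric vector on the log-ratio scale.
#' @return Percentage change.
#' @export
percentage_change <- function(pooled_ln) {
  (exp(pooled_ln) - 1) * 100
}

#' Build the per-observation effect-size table
#'
#' Takes validated observations ([read_observations]) and computes, per row:
#' the log response ratio `ln_rr` and within-study variance `v_within`
#' (standard-error based, before tau2); the standardized treatment magnitude
#' `delta` and the sensitivity pair `ln_sens = ln_rr / delta`,
#' `v_sens_within = v_within / delta^2` for single-factor rows; the ambient
#' conductance moderator `ambient_gs` (the control-arm mean); and the count of
#' factors `n_factors`.
#'
#' @param observations Tibble from [read_observations] (or any tibble with the
#'   canonical columns).
#' @return The input with effect-size columns appended, one row per
#'   observation.
#' @export
effect_sizes <- function(observations) {
  obs <- as_tibble(observations)
  es <- log_response_ratio(obs$mean_T, obs$se_T, obs$mean_C, obs$se_C)
  first_factor <- sub("\\+.*$", "", obs$factors)
  n_factors <- lengths(strsplit(obs$factors, "\\+"))
  delta <- ifelse(n_factors == 1,
                  standardize_magnitude(first_factor, obs$magnitude_1),
                  NA_real_)
  obs %>%
    mutate(
      n_factors = n_factors,
      ln_rr = es$ln_rr,
      v_within = es$v_within,
      delta = delta,
      ln_sens = .data$ln_rr / delta,
      v_sens_within = .data$v_within / delta^2,
      ambient_gs = .data$mean_C
    )
}

#' Standardized sensitivity from an effect size
#'
#' Divides a log response ratio by the standardized treatment magnitude:
#' `ln_sens = ln_rr / delta`, `v_sens = v / delta^2`. Exact by construction:
#' `ln_sens * delta == ln_rr` and `v_sens * delta^2 == v`.
#'
#' @param ln_rr,v Effect size and its variance (with or without tau2 —
#'   whichever scale the caller is working on).
#' @param delta Standardized magnitude, positive.
#' @return List with `ln_sens` and `v_sens`.
#' @export
sensitivity <- function(ln_rr, v, delta) {
  if (any(delta <= 0)) abort("Standardized magnitude delta must be positive.")
  list(ln_sens = ln_rr / delta, v_sens = v / delta^2)
}

#' Adjusted weights for non-independent observations
#'
#' Observations of the same species at the same site (within one factor set)
#' are non-independent; the "shifting the unit of analysis" adjustment divides
#' each raw weight `w = 1/v` by `n_ob`, the size of its
#' (site, species, factor set) group, so each species-by-site unit carries one
#' unit of total weight regardless of how many rows it contributed.
#'
#' @param effects Tibble with columns `site_id`, `species`, `factors` and a
#'   variance column.
#' @param tau2 Between-study variance folded into the variance before
#'   weighting.
#' @param var_col Name of the within-study variance column
#'   (default `"v_within"`).
#' @param max_weight Cap applied to raw weights when `v_within + tau2`
#'   underflows toward zero (rounded-to-zero reported SEs with tau2 = 0).
#' @return The input with `v`, `w`, `n_ob`, `w_star` columns appended.
#' @export
adjusted_weights <- function(effects, tau2, var_col = "v_within",
                             max_weight = 1e8) {
  if (nrow(effects) == 0) {
    return(mutate(effects, v = numeric(0), w = numeric(0),
                  n_ob = integer(0), w_star = numeric(0)))
  }
  effects %>%
    mutate(
      v = .data[[var_col]] + tau2,
      w = pmin(1 / .data$v, max_weight)
    ) %>%
    group_by(.data$site_id, .data$species, .data$factors) %>%
    mutate(n_ob = n(), w_star = .data$w / .data$n_ob) %>%
    ungroup()
}
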