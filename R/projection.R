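#' Project end-of-century stomatal-conductance change per biome
#'
#' Multiplies pooled standardized sensitivities by projected forcing
#' magnitudes: the ln-scale prediction is `mean_ln * delta`, its 95% interval
#' is obtained by multiplying the ln-scale CI bounds by `delta` (the forcing
#' is treated as known; the sensitivity is the only uncertain term), and both
#' are back-transformed to percentage change. Cells whose sensitivity CI spans
#' zero are flagged insignificant; biome-factor cells without a pooled
#' sensitivity are returned with `no_data = TRUE` rather than erroring.
#'
#' A warning is emitted when a projected `delta` exceeds the largest
#' standardized treatment magnitude that generated the sensitivity
#' (extrapolation beyond the experimental range).
#'
#' @param sensitivities Tibble of pooled sensitivities per standardized unit:
#'   columns `factors`, `mean_ln`, `ci_low`, `ci_high`, and optionally `biome`
#'   (e.g. bind `tidy(pool(eff, "sens", by = "biome"))` per factor).
#' @param forcing Tibble of projected changes in native units: columns
#'   `scenario`, `factors`, `change` (non-negative; decreases are positive
#'   magnitudes under the `dP` code), optionally `biome`.
#' @param observed_max Optional named numeric vector of the maximum observed
#'   standardized magnitude per factor, for the extrapolation guard (see
#'   [observed_delta_range]).
#' @return Tibble keyed by scenario (x biome) x factor with `delta`,
#'   ln-scale prediction and bounds, `pct`, `pct_low`, `pct_high`,
#'   `significant`, `extrapolated`, `no_data`.
#' @export
project_gs <- function(sensitivities, forcing, observed_max = NULL) {
  if (any(forcing$change < 0, na.rm = TRUE)) {
    abort("Forcing changes must be non-negative; code decreases via the factor (dP).")
  }
  keys <- intersect(c("biome", "factors"), intersect(names(sensitivities),
                                                     names(forcing)))
  out <- forcing %>%
    left_join(sensitivities, by = keys) %>%
    mutate(
      delta = ifelse(.data$change == 0, 0,
                     standardize_magnitude(.data$factors, .data$change)),
      no_data = is.na(.data$mean_ln),
      ln_pred = .data$mean_ln * .data$delta,
      ln_low = .data$ci_low * .data$delta,
      ln_high = .data$ci_high * .data$delta,
      pct = percentage_change(.data$ln_pred),
      pct_low = percentage_change(pmin(.data$ln_low, .data$ln_high)),
      pct_high = percentage_change(pmax(.data$ln_low, .data$ln_high)),
      significant = !.data$no_data & (.data$ci_low > 0 | .data$ci_high < 0)
    )
  if (!is.null(observed_max)) {
    out$extrapolated <- !out$no_data &
      out$delta > (observed_max[out$factors] %||% Inf)
    out$extrapolated[is.na(out$extrapolated)] <- FALSE
    if (any(out$extrapolated)) {
      warn(paste0(
        "Projected forcing exceeds the experimental range for: ",
        paste(unique(out$factors[out$extrapolated]), collapse = ", "),
        "; sensitivities are extrapolated."))
    }
  } else {
    out$extrapolated <- NA
  }
  out
}

#' Largest standardized treatment magnitude per factor
#'
#' Convenience helper for the extrapolation guard of [project_gs]: the maximum
#' `delta` observed per single factor in an effect table.
#'
#' @param effects Effect-size tibble from [effect_sizes].
#' @return Named numeric vector, one entry per factor present.
#' @export
observed_delta_range <- function(effects) {
  eff <- effects %>% filter(.data$n_factors == 1, is.finite(.data$delta))
  c(tapply(eff$delta, eff$factors, max))
}
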