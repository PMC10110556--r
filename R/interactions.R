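fe_collapse <- function(y, v) {
  # fixed-effect summary of replicate observations of one experimental arm
  w <- 1 / pmax(v, 1e-12)
  list(y = sum(w * y) / sum(w), v = 1 / sum(w))
}

#' Match factorial experiments into interaction triples
#'
#' Scans the effect-size table for two-factor rows whose two single-factor
#' arms are present in the same study, site, and species, and assembles one
#' triple per complete factorial: the combined effect `ln_rr_ab`, the two
#' single-factor effects, their sum `ln_sum = ln_rr_a + ln_rr_b` with variance
#' `v_a + v_b`, and the additivity contrast `d = ln_rr_ab - ln_sum` with
#' variance `v_d = v_ab + v_a + v_b` (arms treated as independent; the shared
#' control makes this slightly conservative). Replicate observations of one
#' arm are first collapsed by inverse-variance averaging. Incomplete
#' factorials are skipped and listed in `attr(, "skipped")`.
#'
#' @param effects Effect-size tibble from [effect_sizes].
#' @param classify Attach the interaction classification column
#'   ([classify_interaction])?
#' @return Tibble with one row per triple: keys, `pair`, effects, variances,
#'   `ln_sum`, `v_sum`, `d`, `v_d`, and `classification`.
#' @export
build_triples <- function(effects, classify = TRUE) {
  eff <- effects
  combined <- eff %>% filter(.data$n_factors == 2)
  singles <- eff %>%
    filter(.data$n_factors == 1) %>%
    group_by(.data$study_id, .data$site_id, .data$species, .data$factors) %>%
    summarise(ln = fe_collapse(.data$ln_rr, .data$v_within)$y,
              v = fe_collapse(.data$ln_rr, .data$v_within)$v,
              .groups = "drop")
  comb <- combined %>%
    group_by(.data$study_id, .data$site_id, .data$species, .data$factors) %>%
    summarise(ln_rr_ab = fe_collapse(.data$ln_rr, .data$v_within)$y,
              v_ab = fe_collapse(.data$ln_rr, .data$v_within)$v,
              .groups = "drop") %>%
    tidyr::separate_wider_delim("factors", "+",
                                names = c("factor_a", "factor_b"),
                                cols_remove = FALSE)
  out <- comb %>%
    left_join(rename(singles, factor_a = "factors", ln_rr_a = "ln",
                     v_a = "v"),
              by = c("study_id", "site_id", "species", "factor_a")) %>%
    left_join(rename(singles, factor_b = "factors", ln_rr_b = "ln",
                     v_b = "v"),
              by = c("study_id", "site_id", "species", "factor_b"))
  skipped <- out %>% filter(is.na(.data$ln_rr_a) | is.na(.data$ln_rr_b))
  out <- out %>%
    filter(!is.na(.data$ln_rr_a), !is.na(.data$ln_rr_b)) %>%
    mutate(
      pair = .data$factors,
      ln_sum = .data$ln_rr_a + .data$ln_rr_b,
      v_sum = .data$v_a + .data$v_b,
      d = .data$ln_rr_ab - .data$ln_sum,
      v_d = .data$v_ab + .data$v_a + .data$v_b
    )
  if (classify && nrow(out) > 0) {
    out$classification <- classify_interaction(out$ln_rr_ab, out$v_ab,
                                               out$ln_sum, out$v_sum)
  }
  if (nrow(skipped) > 0) {
    inform(paste0(nrow(skipped),
                  " incomplete factorial(s) skipped (missing single-factor arm)."))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Classify a two-factor interaction against the additive expectation
#'
#' The combined effect is compared with the sum of the single-factor effects
#' via `d = ln_rr_ab - ln_sum` and a two-sided z-test on `d` using
#' `v_d = v_ab + v_sum`. A non-significant `d` is additive (the point sits on
#' the 1:1 line up to sampling error). A significant `d` is synergistic when
#' it pushes the combined effect further in the direction of the sum (above
#' the 1:1 line for positive sums, below it for negative sums) and
#' antagonistic when it pulls it back toward zero. When the sum itself is not
#' distinguishable from zero its direction is undefined, so a significant `d`
#' is reported as indeterminate.
#'
#' @param ln_rr_ab,v_ab Combined-treatment effect and variance.
#' @param ln_sum,v_sum Summed single-factor effects and variance.
#' @return Character vector: `"additive"`, `"synergistic"`, `"antagonistic"`,
#'   or `"indeterminate"`.
#' @export
classify_interaction <- function(ln_rr_ab, v_ab, ln_sum, v_sum) {
  d <- ln_rr_ab - ln_sum
  v_d <- v_ab + v_sum
  sig_d <- abs(d) > 1.96 * sqrt(v_d)
  sum_sig <- abs(ln_sum) > 1.96 * sqrt(v_sum)
  dplyr::case_when(
    !sig_d ~ "additive",
    !sum_sig ~ "indeterminate",
    sign(d) == sign(ln_sum) ~ "synergistic",
    TRUE ~ "antagonistic"
  )
}

#' Trend of combined effects against summed single-factor effects
#'
#' Regresses the combined effect `ln_rr_ab` on the summed single-factor
#' effects `ln_sum` (weighted by `1 / v_d` by default). Under additivity the
#' slope is 1 with intercept 0; a slope below 1 indicates attenuation —
#' interactions that grow more antagonistic as effect sizes grow.
#'
#' @param triples Tibble from [build_triples].
#' @param weighted Weight by inverse `v_d` (default) or fit unweighted.
#' @return A `gs_metareg`-classed fit with moderator `ln_sum`; its slope CI is
#'   `estimate +/- 1.96 se` in `tidy()`.
#' @export
interaction_trend <- function(triples, weighted = TRUE) {
  if (nrow(triples) < 3) {
    abort("At least 3 complete triples are needed for the interaction trend.")
  }
  x <- triples$ln_sum
  y <- triples$ln_rr_ab
  w <- if (weighted) 1 / triples$v_d else rep(1, nrow(triples))
  X <- cbind("(Intercept)" = 1, ln_sum = x)
  fit <- wls_meta(X, y, w)
  slope_p <- 2 * pnorm(-abs(fit$coef[2] / fit$se[2]))
  new_metareg("rr", "ln_sum", "linear", fit, X, NULL,
              r2 = NA_real_, p_slope = slope_p,
              tau2_model = NA_real_, tau2_null = NA_real_,
              data = tibble(x = x, y = y, v = triples$v_d, w_star = w))
}
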