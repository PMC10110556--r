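#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar geom_hline
#'   geom_abline geom_line geom_ribbon labs theme_minimal geom_vline
#'   geom_errorbarh position_dodge geom_col facet_wrap coord_flip
NULL

#' @export
ggplot2::autoplot

#' Forest-style plot of subgroup pooled estimates
#'
#' Percentage change (or sensitivity) per group with 95% intervals; filled
#' points are significantly different from zero.
#'
#' @param object A `gs_subgroup` from [pool].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gs_subgroup <- function(object, ...) {
  d <- tidy(object) %>%
    mutate(group = .data[[object$by]], sig = .data$p < 0.05)
  ggplot(d, aes(x = .data$pct, y = .data$group)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$pct_low, xmax = .data$pct_high),
                   height = 0.2) +
    geom_point(aes(fill = .data$sig), shape = 21, size = 3) +
    labs(x = ifelse(object$metric == "sens",
                    "% change per standardized unit", "% change"),
         y = object$by, fill = "p < 0.05") +
    theme_minimal()
}

#' Scatter-and-fit plot of a meta-regression
#'
#' Effect sizes against the moderator, point area proportional to the
#' adjusted weight, with the fitted line and its 95% band.
#'
#' @param object A `gs_metareg` from [meta_regress].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gs_metareg <- function(object, ...) {
  grid <- seq(min(object$data$x), max(object$data$x), length.out = 200)
  pred <- predict(object, grid)
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    geom_point(aes(size = .data$w_star), alpha = 0.4) +
    geom_ribbon(data = pred, aes(x = .data$x, ymin = .data$ci_low,
                                 ymax = .data$ci_high),
                inherit.aes = FALSE, alpha = 0.2) +
    geom_line(data = pred, aes(x = .data$x, y = .data$fit),
              inherit.aes = FALSE) +
    labs(x = object$moderator,
         y = ifelse(object$response == "rr", "lnRR", "lnSens"),
         size = "w*") +
    theme_minimal()
}

#' Funnel plot of effects against precision
#'
#' @param effects Effect-size tibble or the output of [funnel_data].
#' @param metric `"rr"` or `"sens"`.
#' @return A ggplot of effect size versus precision (`1/sqrt(v)`).
#' @export
plot_funnel <- function(effects, metric = "rr") {
  d <- if ("precision" %in% names(effects)) effects
       else funnel_data(effects, metric)
  centre <- sum(d$ln_value / d$v) / sum(1 / d$v)
  ggplot(d, aes(x = .data$ln_value, y = .data$precision)) +
    geom_point(alpha = 0.5) +
    geom_vline(xintercept = centre, linetype = 2) +
    labs(x = "effect size (ln scale)", y = "precision (1/SE)") +
    theme_minimal()
}

#' Combined versus summed effects with the 1:1 additivity line
#'
#' @param triples Tibble from [build_triples].
#' @return A ggplot; points coloured by interaction classification, the
#'   dashed line marking exact additivity.
#' @export
plot_interaction <- function(triples) {
  ggplot(triples, aes(x = .data$ln_sum, y = .data$ln_rr_ab,
                      colour = .data$classification)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    geom_point(alpha = 0.7) +
    labs(x = "sum of single-factor lnRR", y = "combined lnRR",
         colour = NULL) +
    theme_minimal()
}

#' Bar chart of projected percentage change per biome and scenario
#'
#' @param projection Tibble from [project_gs].
#' @return A ggplot; insignificant cells are shown hollow.
#' @export
plot_projection <- function(projection) {
  d <- filter(projection, !.data$no_data)
  d$y_axis <- if ("biome" %in% names(d)) d$biome else d$factors
  ggplot(d, aes(x = .data$pct, y = .data$y_axis,
                fill = .data$scenario)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7,
             aes(alpha = .data$significant)) +
    geom_errorbarh(aes(xmin = .data$pct_low, xmax = .data$pct_high),
                   position = position_dodge(width = 0.8), height = 0.2) +
    facet_wrap(~factors, scales = "free_x") +
    labs(x = "projected % change in g_s", y = NULL) +
    theme_minimal()
}
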