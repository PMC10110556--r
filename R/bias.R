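#' Funnel-plot data
#'
#' Pure projection of an effect table to the (effect, precision) pairs a
#' funnel plot displays, precision being `1 / sqrt(v)`.
#'
#' @param effects Effect-size tibble from [effect_sizes].
#' @param metric `"rr"` or `"sens"`.
#' @return Tibble with columns `ln_value`, `v`, `precision`, plus the key
#'   columns `study_id`, `site_id`, `species`, `factors`.
#' @export
funnel_data <- function(effects, metric = c("rr", "sens")) {
  metric <- match.arg(metric)
  cols <- metric_columns(metric)
  effects %>%
    filter(is.finite(.data[[cols["value"]]]), is.finite(.data[[cols["var"]]])) %>%
    transmute(.data$study_id, .data$site_id, .data$species, .data$factors,
              ln_value = .data[[cols["value"]]],
              v = .data[[cols["var"]]],
              precision = 1 / sqrt(.data$v))
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' Classic Egger test: the standardized effect `y / sqrt(v)` is regressed on
#' precision `1 / sqrt(v)` by ordinary least squares, and the intercept is
#' tested against zero with a t-test on `k - 2` degrees of freedom. A
#' symmetric funnel gives an intercept near zero; small-study effects
#' (publication bias) shift it away.
#'
#' @param effects Effect-size tibble, or a tibble from [funnel_data].
#' @param metric `"rr"` or `"sens"` (ignored when `effects` already carries
#'   `ln_value`/`v` columns).
#' @return A `gs_egger` object with `tidy()`/`glance()` methods: intercept
#'   estimate, SE, t, p, slope, and `k`.
#' @export
egger_test <- function(effects, metric = c("rr", "sens")) {
  dat <- if (all(c("ln_value", "v") %in% names(effects))) {
    effects
  } else {
    funnel_data(effects, metric)
  }
  k <- nrow(dat)
  if (k < 3) abort("Egger's test needs at least 3 effects.")
  z <- dat$ln_value / sqrt(dat$v)
  prec <- 1 / sqrt(dat$v)
  fit <- stats::lm(z ~ prec)
  sm <- summary(fit)$coefficients
  structure(
    list(intercept = sm[1, 1], se = sm[1, 2], t = sm[1, 3],
         p = 2 * pt(-abs(sm[1, 3]), df = k - 2),
         slope = sm[2, 1], k = k),
    class = "gs_egger"
  )
}

#' @export
print.gs_egger <- function(x, ...) {
  cat(sprintf(
    "Egger's regression (k = %d): intercept %.3f (SE %.3f), t = %.2f, p = %.3g\n",
    x$k, x$intercept, x$se, x$t, x$p))
  invisible(x)
}

#' Tidy an Egger test
#'
#' @param x A `gs_egger` object.
#' @param ... Unused.
#' @return One-row tibble with the intercept test and slope.
#' @export
tidy.gs_egger <- function(x, ...) {
  tibble(intercept = x$intercept, se = x$se, t = x$t, p = x$p,
         slope = x$slope, k = x$k)
}

#' @rdname tidy.gs_egger
#' @export
glance.gs_egger <- function(x, ...) tidy(x)
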