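#' Restricted cubic spline basis (Harrell parameterisation)
#'
#' Builds the natural cubic spline basis that is linear beyond the outer
#' knots: the moderator itself plus `length(knots) - 2` nonlinear terms, each
#' scaled by the squared outer-knot span so coefficients stay on a comparable
#' scale.
#'
#' @param x Numeric vector.
#' @param knots Numeric vector of at least 3 distinct knot locations.
#' @return Matrix with `length(knots) - 1` columns; knots kept as attribute.
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(unique(knots))
  k <- length(knots)
  if (k < 3) abort("A restricted cubic spline needs at least 3 knots.")
  pos3 <- function(u) pmax(u, 0)^3
  scale <- (knots[k] - knots[1])^2
  nl <- vapply(seq_len(k - 2), function(j) {
    (pos3(x - knots[j]) -
       pos3(x - knots[k - 1]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
       pos3(x - knots[k]) * (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])) /
      scale
  }, numeric(length(x)))
  out <- cbind(x, matrix(nl, nrow = length(x)))
  colnames(out) <- c("x", paste0("x'", seq_len(k - 2)))
  attr(out, "knots") <- knots
  out
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

# Weighted least squares with meta-analytic (inverse-variance) covariance.
wls_meta <- function(X, y, w) {
  if (qr(X * sqrt(w))$rank < ncol(X)) {
    abort("rank-deficient design")
  }
  A <- crossprod(X, X * w)
  Ainv <- solve(A)
  b <- as.vector(Ainv %*% crossprod(X, y * w))
  se <- sqrt(diag(Ainv))
  list(coef = b, se = se, vcov = Ainv)
}

new_metareg <- function(response, moderator, form, fit, X, knots, r2, p_slope,
                        tau2_model, tau2_null, data) {
  terms <- colnames(X)
  structure(
    list(
      response = response, moderator = moderator, form = form,
      coefficients = tibble(
        term = terms, estimate = fit$coef, se = fit$se,
        z = fit$coef / fit$se, p = 2 * pnorm(-abs(fit$coef / fit$se))
      ),
      vcov = fit$vcov, knots = knots, r2 = r2, p_slope = p_slope,
      k = nrow(data), tau2_model = tau2_model, tau2_null = tau2_null,
      data = data
    ),
    class = "gs_metareg"
  )
}

#' Weighted meta-regression of effect sizes on a moderator
#'
#' Regresses log response ratios or sensitivities on a single moderator by
#' weighted least squares with the adjusted weights `w*`, where the residual
#' between-study variance tau2 of the moderator model is estimated by REML and
#' folded into each weight. The moderator enters either linearly or through a
#' restricted cubic spline ([rcs_basis]) with knots at weighted quantiles.
#' `form = "auto"` fits both and keeps the one accounting for more
#' heterogeneity ([select_form]).
#'
#' The model's `r2` is the proportional reduction in tau2 relative to the
#' intercept-only model, clamped at zero; `p_slope` is the Wald chi-squared
#' test of all moderator terms jointly.
#'
#' @param effects Effect-size tibble from [effect_sizes].
#' @param moderator Column name of the moderator (`"delta"`, `"ambient_gs"`,
#'   `"duration"`, `"mat"`, `"ai"`, `"vpd"`, ...). Rows with missing moderator
#'   are dropped.
#' @param response `"rr"` or `"sens"`.
#' @param form `"linear"`, `"rcs"`, or `"auto"`.
#' @param n_knots Number of spline knots (default 4, at the weighted
#'   5/35/65/95 percentiles; 3 knots use 10/50/90).
#' @param tau2_method Passed to [estimate_tau2].
#' @return A `gs_metareg` object with `tidy()`, `glance()`, `predict()` and
#'   `autoplot()` methods.
#' @export
meta_regress <- function(effects, moderator, response = c("rr", "sens"),
                         form = c("linear", "rcs", "auto"), n_knots = 4,
                         tau2_method = c("reml", "dl")) {
  response <- match.arg(response)
  form <- match.arg(form)
  tau2_method <- match.arg(tau2_method)
  cols <- metric_columns(response)
  eff <- effects %>%
    filter(is.finite(.data[[cols["value"]]]), is.finite(.data[[cols["var"]]]),
           is.finite(.data[[moderator]]))
  y <- eff[[cols["value"]]]
  v <- eff[[cols["var"]]]
  x <- eff[[moderator]]
  if (length(unique(x)) < 2) {
    abort(paste0("rank-deficient design: moderator '", moderator,
                 "' is constant"))
  }
  tau2_null <- estimate_tau2(y, v, method = tau2_method)

  fit_one <- function(frm) {
    if (frm == "linear") {
      X <- cbind("(Intercept)" = 1, x)
      colnames(X) <- c("(Intercept)", moderator)
      knots <- NULL
    } else {
      probs <- if (n_knots >= 4) {
        c(0.05, seq(0.35, 0.65, length.out = n_knots - 2), 0.95)
      } else c(0.1, 0.5, 0.9)
      knots <- weighted_quantile(x, 1 / v, probs)
      if (length(unique(knots)) < 3) abort("degenerate knots")
      basis <- rcs_basis(x, knots)
      knots <- attr(basis, "knots")
      X <- cbind("(Intercept)" = 1, basis)
      colnames(X) <- c("(Intercept)", paste0(moderator, colnames(basis) |>
                                               sub("^x", "", x = _)))
    }
    if (length(y) <= ncol(X)) abort("more coefficients than observations")
    tau2_model <- estimate_tau2(y, v, X = X, method = tau2_method)
    effw <- adjusted_weights(eff, tau2_model, var_col = cols[["var"]])
    fit <- wls_meta(X, y, effw$w_star)
    idx <- setdiff(seq_along(fit$coef), 1)
    chi <- tryCatch(
      drop(t(fit$coef[idx]) %*%
             solve(fit$vcov[idx, idx, drop = FALSE], fit$coef[idx])),
      error = function(e) NA_real_)
    p_slope <- pchisq(chi, df = length(idx), lower.tail = FALSE)
    r2 <- if (tau2_null > 0) max(0, 1 - tau2_model / tau2_null) else 0
    new_metareg(response, moderator, frm, fit, X, knots, r2, p_slope,
                tau2_model, tau2_null,
                tibble(x = x, y = y, v = v, w_star = effw$w_star))
  }

  if (form == "auto") {
    lin <- fit_one("linear")
    rcs <- tryCatch(fit_one("rcs"), error = function(e) NULL)
    select_form(lin, rcs)
  } else {
    fit_one(form)
  }
}

#' Choose between a linear and a spline meta-regression
#'
#' Keeps the fit that accounts for more residual heterogeneity (higher `r2`);
#' ties go to the linear model for parsimony, and a missing/failed spline fit
#' falls back to the linear one with a warning.
#'
#' @param fit_linear,fit_rcs `gs_metareg` objects fitted to the same data
#'   (`fit_rcs` may be `NULL` if the spline fit failed).
#' @return The chosen `gs_metareg`.
#' @export
select_form <- function(fit_linear, fit_rcs) {
  if (is.null(fit_rcs)) {
    warn("Spline fit unavailable; reporting the linear model.")
    return(fit_linear)
  }
  if (fit_rcs$r2 > fit_linear$r2) fit_rcs else fit_linear
}

#' @export
print.gs_metareg <- function(x, ...) {
  cat(sprintf("Meta-regression of %s on %s (%s), k = %d\n",
              ifelse(x$response == "rr", "lnRR", "lnSens"),
              x$moderator, x$form, x$k))
  print(as.data.frame(x$coefficients), digits = 4)
  cat(sprintf("R2 = %.3f (tau2 %.4g -> %.4g), moderator p = %.3g\n",
              x$r2, x$tau2_null, x$tau2_model, x$p_slope))
  invisible(x)
}

#' Predictions from a meta-regression fit
#'
#' @param object A `gs_metareg` object.
#' @param newdata Numeric vector of moderator values (defaults to the data).
#' @param ... Unused.
#' @return Tibble with `x`, `fit`, `se`, and 95% interval bounds.
#' @export
predict.gs_metareg <- function(object, newdata = NULL, ...) {
  x <- newdata %||% object$data$x
  X <- if (object$form == "linear") {
    cbind(1, x)
  } else {
    cbind(1, rcs_basis(x, object$knots))
  }
  fit <- as.vector(X %*% object$coefficients$estimate)
  se <- sqrt(rowSums((X %*% object$vcov) * X))
  tibble(x = x, fit = fit, se = se,
         ci_low = fit - 1.96 * se, ci_high = fit + 1.96 * se)
}

#' Tidy a meta-regression fit
#'
#' @param x A `gs_metareg` object.
#' @param ... Unused.
#' @return `tidy()`: coefficient table; `glance()`: one row with form, `r2`,
#'   residual tau2, moderator p-value, and `k`.
#' @export
tidy.gs_metareg <- function(x, ...) x$coefficients

#' @rdname tidy.gs_metareg
#' @export
glance.gs_metareg <- function(x, ...) {
  tibble(response = x$response, moderator = x$moderator, form = x$form,
         r2 = x$r2, tau2_model = x$tau2_model, tau2_null = x$tau2_null,
         p_slope = x$p_slope, k = x$k)
}
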