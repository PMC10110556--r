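metric_columns <- function(metric) {
  switch(metric,
    rr = c(value = "ln_rr", var = "v_within"),
    sens = c(value = "ln_sens", var = "v_sens_within"),
    abort("metric must be 'rr' or 'sens'")
  )
}

pool_core <- function(eff, value_col) {
  y <- eff[[value_col]]
  sw <- sum(eff$w_star)
  mean_ln <- sum(eff$w_star * y) / sw
  se <- sqrt(1 / sw)
  ci_low <- mean_ln - 1.96 * se
  ci_high <- mean_ln + 1.96 * se
  tibble(
    mean_ln = mean_ln, se = se, ci_low = ci_low, ci_high = ci_high,
    pct = percentage_change(mean_ln),
    pct_low = percentage_change(ci_low),
    pct_high = percentage_change(ci_high),
    p = 2 * pnorm(-abs(mean_ln / se)),
    n_sp = dplyr::n_distinct(eff$species),
    n_ob = nrow(eff),
    m = nrow(eff)
  )
}

#' Pool effect sizes or sensitivities with the random-effects model
#'
#' Estimates the between-study variance tau2, folds it into each observation's
#' variance, applies the adjusted weights `w* = w / n_ob` for non-independent
#' (same site, same species) observations, and computes the weighted mean with
#' its standard error `sqrt(1 / sum(w*))`, 95% confidence interval
#' (`+/- 1.96 SE`), two-sided normal p-value, and back-transformed percentage
#' change.
#'
#' With `by`, a subgroup (mixed-effects) analysis is run instead: tau2 is by
#' default common across groups (estimated with group membership as a
#' moderator), each group is pooled separately, and the between-group
#' heterogeneity statistic `Q_B = sum_g W_g (theta_g - theta)^2` is tested
#' against a chi-squared distribution on `groups - 1` degrees of freedom.
#'
#' @param effects Effect-size tibble from [effect_sizes] (optionally
#'   filtered). Sensitivities exist only for single-factor rows; two-factor
#'   rows are dropped for `metric = "sens"`.
#' @param metric `"rr"` pools log response ratios, `"sens"` pools standardized
#'   sensitivities.
#' @param by Optional grouping column name (`"biome"`, `"pft"`, `"setting"`,
#'   `"factors"`, ...) for a subgroup analysis.
#' @param tau2_method `"reml"` (default) or `"dl"`, see [estimate_tau2].
#' @param tau2_scope For subgroup analyses: `"common"` (one tau2 across
#'   groups, the default) or `"within"` (one per group).
#' @param tau2 Optional fixed between-study variance; skips estimation
#'   (useful for audits and sensitivity checks).
#' @return A `gs_pooled` object, or a `gs_subgroup` object when `by` is given.
#'   Both have [tidy()] and [glance()] methods; `gs_pooled` also prints the
#'   percentage change with its interval.
#' @export
pool <- function(effects, metric = c("rr", "sens"), by = NULL,
                 tau2_method = c("reml", "dl"),
                 tau2_scope = c("common", "within"), tau2 = NULL) {
  metric <- match.arg(metric)
  tau2_method <- match.arg(tau2_method)
  tau2_scope <- match.arg(tau2_scope)
  cols <- metric_columns(metric)
  eff <- effects %>% filter(is.finite(.data[[cols["value"]]]),
                            is.finite(.data[[cols["var"]]]))
  if (nrow(eff) == 0) abort("No effects to pool.")

  if (!is.null(by)) {
    return(subgroup_pool(eff, cols, by, tau2_method, tau2_scope, metric,
                         tau2_fixed = tau2))
  }
  if (is.null(tau2)) {
    tau2 <- if (nrow(eff) >= 2) {
      estimate_tau2(eff[[cols["value"]]], eff[[cols["var"]]],
                    method = tau2_method)
    } else 0
  }
  eff <- adjusted_weights(eff, tau2, var_col = cols[["var"]])
  out <- pool_core(eff, cols[["value"]])
  structure(
    list(estimate = mutate(out, tau2 = tau2), metric = metric,
         tau2 = tau2, tau2_method = tau2_method, effects = eff),
    class = "gs_pooled"
  )
}

subgroup_pool <- function(eff, cols, by, tau2_method, tau2_scope, metric,
                          tau2_fixed = NULL) {
  if (!by %in% names(eff)) abort(paste0("Grouping column '", by, "' not found."))
  eff <- eff %>% filter(!is.na(.data[[by]]))
  groups <- unique(eff[[by]])
  sizes <- table(eff[[by]])
  if (any(sizes == 0)) warn("Empty subgroup dropped.")
  if (length(groups) < 2) {
    abort("Subgroup analysis needs at least two non-empty groups.")
  }
  y <- eff[[cols["value"]]]
  v <- eff[[cols["var"]]]
  if (!is.null(tau2_fixed)) {
    tau2_by <- setNames(rep(tau2_fixed, length(groups)), groups)
  } else if (tau2_scope == "common") {
    X <- stats::model.matrix(~ factor(eff[[by]]))
    tau2_all <- estimate_tau2(y, v, X = X, method = tau2_method)
    tau2_by <- setNames(rep(tau2_all, length(groups)), groups)
  } else {
    tau2_by <- vapply(groups, function(g) {
      idx <- eff[[by]] == g
      if (sum(idx) >= 2) estimate_tau2(y[idx], v[idx], method = tau2_method)
      else 0
    }, numeric(1))
    names(tau2_by) <- groups
  }
  per_group <- purrr::map_dfr(groups, function(g) {
    sub <- eff[eff[[by]] == g, , drop = FALSE]
    sub <- adjusted_weights(sub, tau2_by[[g]], var_col = cols[["var"]])
    pool_core(sub, cols[["value"]]) %>%
      mutate(group = g, tau2 = tau2_by[[g]], W_g = sum(sub$w_star),
             .before = 1)
  })
  theta <- sum(per_group$W_g * per_group$mean_ln) / sum(per_group$W_g)
  q_b <- sum(per_group$W_g * (per_group$mean_ln - theta)^2)
  df <- nrow(per_group) - 1
  structure(
    list(groups = rename(per_group, !!by := "group"),
         by = by, metric = metric,
         q_b = q_b, df = df, p_qb = pchisq(q_b, df, lower.tail = FALSE),
         tau2_scope = tau2_scope, overall_mean = theta),
    class = "gs_subgroup"
  )
}

#' @export
print.gs_pooled <- function(x, ...) {
  e <- x$estimate
  cat(sprintf(
    "Pooled %s: %.4f [%.4f, %.4f] (ln scale)\n  %% change: %.2f%% [%.2f%%, %.2f%%]\n  tau2 = %.4g, p = %.3g, n_sp = %d, n_ob = %d\n",
    ifelse(x$metric == "rr", "lnRR", "lnSens"),
    e$mean_ln, e$ci_low, e$ci_high, e$pct, e$pct_low, e$pct_high,
    x$tau2, e$p, e$n_sp, e$n_ob))
  invisible(x)
}

#' @export
print.gs_subgroup <- function(x, ...) {
  cat(sprintf("Subgroup analysis by %s (%s)\n", x$by, x$metric))
  print(as.data.frame(x$groups[, c(x$by, "mean_ln", "ci_low", "ci_high",
                                   "pct", "n_sp", "n_ob")]), digits = 4)
  cat(sprintf("Q_B = %.3f on %d df, p = %.3g\n", x$q_b, x$df, x$p_qb))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pooled estimate
#'
#' @param x A `gs_pooled` object from [pool].
#' @param ... Unused.
#' @return One-row tibble with the pooled mean, SE, interval, percentage
#'   change, tau2, p-value and counts.
#' @export
tidy.gs_pooled <- function(x, ...) x$estimate

#' @rdname tidy.gs_pooled
#' @export
glance.gs_pooled <- function(x, ...) {
  tibble(metric = x$metric, tau2 = x$tau2, tau2_method = x$tau2_method,
         n_ob = x$estimate$n_ob, n_sp = x$estimate$n_sp)
}

#' Tidy a subgroup analysis
#'
#' @param x A `gs_subgroup` object from [pool] with `by`.
#' @param ... Unused.
#' @return `tidy()`: one row per group with pooled estimates; `glance()`: one
#'   row with `Q_B`, its degrees of freedom and p-value.
#' @export
tidy.gs_subgroup <- function(x, ...) x$groups

#' @rdname tidy.gs_subgroup
#' @export
glance.gs_subgroup <- function(x, ...) {
  tibble(by = x$by, metric = x$metric, q_b = x$q_b, df = x$df,
         p_qb = x$p_qb, tau2_scope = x$tau2_scope)
}
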