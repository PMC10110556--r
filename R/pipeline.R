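#' Run the full meta-analysis pipeline
#'
#' Orchestrates every stage on one observation table: validation, effect
#' sizes, per-factor pooling of responses and sensitivities, biome and
#' plant-functional-type subgroup analyses (outdoor studies only, since indoor
#' plants do not experience the site climate), the indoor/outdoor setting
#' comparison, moderator meta-regressions, interaction triples with their
#' trend, Egger bias tests per factor set, and — when forcing values are
#' supplied — biome-level projections.
#'
#' @param observations Raw observation table (path, data frame, or validated
#'   tibble); passed through [read_observations].
#' @param schema Optional column-name schema for [read_observations].
#' @param moderators Moderator columns for the meta-regression stage.
#' @param forcing Optional forcing tibble for [project_gs] (columns
#'   `scenario`, `factors`, `change`, optionally `biome`).
#' @param tau2_method Passed to all pooling stages.
#' @param min_group Minimum effects for a factor or subgroup to be analysed.
#' @return A list of class `gs_pipeline`: tibbles `effects`,
#'   `pooled_by_factor`, `sens_by_biome`, `sens_by_pft`, `setting_comparison`,
#'   `meta_regressions`, `triples`, `interaction_trends`, `bias`,
#'   `projection` (NULL without forcing), and `manifest` (row counts per
#'   stage, package version, options).
#' @export
run_pipeline <- function(observations, schema = NULL,
                         moderators = c("delta", "ambient_gs", "duration",
                                        "mat", "ai", "vpd"),
                         forcing = NULL,
                         tau2_method = c("reml", "dl"),
                         min_group = 3) {
  tau2_method <- match.arg(tau2_method)
  obs <- read_observations(observations, schema = schema, quiet = TRUE)
  if (nrow(obs) == 0) abort("ingest: no valid observations in input.")
  eff <- effect_sizes(obs)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0(name, ": ", conditionMessage(e)))
    })
  }

  factor_sets <- eff %>% count(.data$factors) %>%
    filter(.data$n >= min_group) %>% pull(.data$factors)
  single <- factor_sets[!grepl("\\+", factor_sets)]

  pooled_by_factor <- stage("pooling", purrr::map_dfr(factor_sets, function(f) {
    sub <- filter(eff, .data$factors == f)
    rr <- tidy(pool(sub, "rr", tau2_method = tau2_method)) %>%
      mutate(factors = f, metric = "rr", .before = 1)
    sens <- if (!grepl("\\+", f)) {
      tidy(pool(sub, "sens", tau2_method = tau2_method)) %>%
        mutate(factors = f, metric = "sens", .before = 1)
    } else NULL
    bind_rows(rr, sens)
  }))

  outdoor <- filter(eff, .data$setting == "outdoor", !is.na(.data$biome))
  subgroup_table <- function(by) {
    purrr::map_dfr(single, function(f) {
      sub <- filter(outdoor, .data$factors == f)
      counts <- table(sub[[by]])
      sub <- sub[sub[[by]] %in% names(counts)[counts >= min_group], ]
      if (nrow(sub) < 2 * min_group || n_distinct(sub[[by]]) < 2) return(NULL)
      sg <- pool(sub, "sens", by = by, tau2_method = tau2_method)
      tidy(sg) %>%
        mutate(factors = f, .before = 1) %>%
        mutate(q_b = sg$q_b, df_qb = sg$df, p_qb = sg$p_qb)
    })
  }
  sens_by_biome <- stage("subgroup-biome", subgroup_table("biome"))
  sens_by_pft <- stage("subgroup-pft", subgroup_table("pft"))

  setting_comparison <- stage("subgroup-setting", purrr::map_dfr(single, function(f) {
    sub <- filter(eff, .data$factors == f, !is.na(.data$setting))
    if (n_distinct(sub$setting) < 2 ||
        min(table(sub$setting)) < min_group) return(NULL)
    sg <- pool(sub, "sens", by = "setting", tau2_method = tau2_method)
    tidy(sg) %>% mutate(factors = f, .before = 1) %>%
      mutate(q_b = sg$q_b, p_qb = sg$p_qb)
  }))

  meta_regressions <- stage("metareg", purrr::map_dfr(single, function(f) {
    sub <- filter(eff, .data$factors == f)
    purrr::map_dfr(moderators, function(m) {
      if (!m %in% names(sub)) return(NULL)
      ok <- sum(is.finite(sub[[m]]) & is.finite(sub$ln_rr))
      if (ok < 10 || n_distinct(sub[[m]][is.finite(sub[[m]])]) < 5) return(NULL)
      fit <- tryCatch(meta_regress(sub, m, response = "rr", form = "auto"),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      glance(fit) %>% mutate(factors = f, .before = 1)
    })
  }))

  triples <- stage("interactions", build_triples(eff))
  interaction_trends <- if (nrow(triples) >= 3) {
    stage("interactions", {
      triples %>%
        group_by(.data$pair) %>%
        filter(n() >= 3) %>%
        group_map(~ glance_trend(interaction_trend(.x), .y$pair)) %>%
        bind_rows()
    })
  } else NULL

  bias <- stage("bias", purrr::map_dfr(factor_sets, function(f) {
    sub <- filter(eff, .data$factors == f)
    if (nrow(sub) < 3) return(NULL)
    tidy(egger_test(sub, "rr")) %>% mutate(factors = f, .before = 1)
  }))

  projection <- NULL
  if (!is.null(forcing) && !is.null(sens_by_biome) && nrow(sens_by_biome) > 0) {
    projection <- stage("projection", project_gs(
      sens_by_biome %>%
        select("factors", "biome", "mean_ln", "ci_low", "ci_high", "p"),
      forcing, observed_max = observed_delta_range(eff)))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gsmeta")),
    tau2_method = tau2_method,
    n_input = nrow(obs) + nrow(attr(obs, "rejections") %||% tibble()),
    n_valid = nrow(obs),
    n_rejected = nrow(attr(obs, "rejections") %||% tibble()),
    n_effects = nrow(eff),
    n_factor_sets = length(factor_sets),
    n_triples = nrow(triples),
    outputs = c("effects", "pooled_by_factor", "sens_by_biome", "sens_by_pft",
                "setting_comparison", "meta_regressions", "triples",
                "interaction_trends", "bias",
                if (!is.null(projection)) "projection")
  )
  structure(
    list(effects = eff, pooled_by_factor = pooled_by_factor,
         sens_by_biome = sens_by_biome, sens_by_pft = sens_by_pft,
         setting_comparison = setting_comparison,
         meta_regressions = meta_regressions,
         triples = triples, interaction_trends = interaction_trends,
         bias = bias, projection = projection, manifest = manifest),
    class = "gs_pipeline"
  )
}

glance_trend <- function(fit, pair) {
  co <- fit$coefficients
  tibble(
    pair = pair,
    intercept = co$estimate[1], intercept_se = co$se[1],
    slope = co$estimate[2], slope_se = co$se[2],
    slope_low = co$estimate[2] - 1.96 * co$se[2],
    slope_high = co$estimate[2] + 1.96 * co$se[2],
    p_slope = fit$p_slope, k = fit$k
  )
}

#' @export
print.gs_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("g_s meta-analysis pipeline run\n")
  cat(sprintf("  observations: %d valid (%d rejected), %d factor sets, %d triples\n",
              m$n_valid, m$n_rejected, m$n_factor_sets, m$n_triples))
  cat("  outputs:", paste(m$outputs, collapse = ", "), "\n")
  invisible(x)
}
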