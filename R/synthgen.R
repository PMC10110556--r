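# Synthetic observation tables with known ground truth, emulating the
# structure of a multi-factor global-change manipulation dataset: studies
# nested in sites, several species per site, replicated observations per
# species (the non-independent unit), between-study heterogeneity, and
# measurement error consistent with the reported standard errors.

default_factor_table <- function() {
  tibble(
    factor   = c("eCO2", "eT", "iP", "dP", "eN", "eO3"),
    # true mean sensitivities, ln per standardized unit; defaults are the
    # magnitudes typical of published g_s syntheses (reductions under eCO2,
    # warming, drought and ozone; increases under added water and nitrogen)
    mean_sens = c(-0.0866, -0.0151, 0.0208, -0.0356, 0.0080, -0.0212),
    tau2      = rep(0.02, 6),
    # native-unit treatment-magnitude ranges typical of the experiments:
    # +200..400 ppm CO2, +1..5 C, 20..60 % precipitation change,
    # 2..15 g N m-2 yr-1, 20..80 ppb O3
    mag_min   = c(200, 1, 20, 20, 2, 20),
    mag_max   = c(400, 5, 60, 60, 15, 80),
    n_studies = rep(30L, 6)
  )
}

BIOME_MAT <- c(boreal_forest = -2, temperate_forest = 8,
               subtropical_forest = 18, tropical_forest = 25,
               temperate_grassland = 6, mediterranean_woodland = 15,
               desert = 20, cropland = 12)
BIOME_AI <- c(boreal_forest = 0.9, temperate_forest = 1.0,
              subtropical_forest = 1.2, tropical_forest = 1.6,
              temperate_grassland = 0.45, mediterranean_woodland = 0.4,
              desert = 0.15, cropland = 0.7)

#' Configuration for the synthetic observation generator
#'
#' Collects and validates every ground-truth parameter used by
#' [generate_observations]. The defaults emulate the structure of the
#' compiled experimental literature: six factors, tens of studies per factor,
#' two species per site with two replicate observations each, between-study
#' heterogeneity on the sensitivity scale, control conductances around
#' 0.25 mol m-2 s-1, and standard errors from a constant coefficient of
#' variation.
#'
#' @param seed Integer RNG seed; identical configurations generate identical
#'   tables.
#' @param factors Tibble with columns `factor`, `mean_sens` (true mean
#'   sensitivity, ln per standardized unit), `tau2` (between-study variance on
#'   the heterogeneity scale), `mag_min`, `mag_max` (native-unit magnitude
#'   range, uniform), `n_studies`.
#' @param species_per_study,obs_per_species Replication structure; each study
#'   is one site.
#' @param heterogeneity `"sens"` (random effects on the per-unit sensitivity
#'   scale, default) or `"rr"` (on the log response-ratio scale).
#' @param gs_median,gs_sdlog Log-normal distribution of control-arm mean
#'   conductance (mol m-2 s-1).
#' @param se_cv Coefficient of variation generating reported standard errors
#'   (`SE = se_cv * mean / sqrt(n)`).
#' @param n_range Integer range replicate counts are drawn from (min 3).
#' @param outdoor_prob Probability a study is an outdoor experiment; indoor
#'   studies carry no biome label.
#' @param biome_offsets Optional named numeric: additive shift of `mean_sens`
#'   per biome (creates real between-biome differences).
#' @param plateau Optional named numeric, per factor: standardized magnitude
#'   beyond which the mean response stops growing (a saturating
#'   dose-response).
#' @param interaction `NULL`, or a list with `pairs` (character, e.g.
#'   `"eCO2+eT"`), `n_triples` per pair, and `lambda` (combined effect =
#'   `lambda` times the sum of the single-factor effects; 1 = additive).
#' @param suppress Small-study suppression switch for publication-bias tests:
#'   if `TRUE`, generated rows whose effect falls below the factor's true mean
#'   while their variance is above the median are censored.
#' @return A validated `gs_synth_config` list.
#' @export
synth_config <- function(seed = 42L,
                         factors = default_factor_table(),
                         species_per_study = 2L,
                         obs_per_species = 2L,
                         heterogeneity = c("sens", "rr"),
                         gs_median = 0.25, gs_sdlog = 0.5,
                         se_cv = 0.15,
                         n_range = c(3L, 10L),
                         outdoor_prob = 0.85,
                         biome_offsets = NULL,
                         plateau = NULL,
                         interaction = NULL,
                         suppress = FALSE) {
  heterogeneity <- match.arg(heterogeneity)
  stopifnot(is.numeric(seed), length(seed) == 1)
  need <- c("factor", "mean_sens", "tau2", "mag_min", "mag_max", "n_studies")
  if (!all(need %in% names(factors))) {
    abort(paste0("factors table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  if (!all(factors$factor %in% GCF_CODES)) abort("Unknown factor code in config.")
  if (any(factors$tau2 < 0)) abort("tau2 must be non-negative.")
  if (any(factors$mag_min <= 0 | factors$mag_max < factors$mag_min)) {
    abort("Magnitude ranges must be positive with mag_max >= mag_min.")
  }
  if (species_per_study < 1 || obs_per_species < 1 ||
      any(factors$n_studies < 1)) {
    abort("Counts must be at least 1.")
  }
  if (n_range[1] < 3) abort("Replicate counts must satisfy n >= 3.")
  if (se_cv < 0 || gs_median <= 0) abort("Dispersion parameters must be positive.")
  if (!is.null(interaction)) {
    if (!all(c("pairs", "n_triples", "lambda") %in% names(interaction))) {
      abort("interaction needs elements pairs, n_triples, lambda.")
    }
    if (interaction$lambda <= 0 || interaction$lambda > 1.5) {
      abort("interaction lambda must lie in (0, 1.5].")
    }
    pr <- strsplit(interaction$pairs, "\\+")
    if (!all(vapply(pr, function(p)
      length(p) == 2 && all(p %in% factors$factor), logical(1)))) {
      abort("Each interaction pair must name two configured factors.")
    }
  }
  structure(
    list(seed = as.integer(seed), factors = factors,
         species_per_study = as.integer(species_per_study),
         obs_per_species = as.integer(obs_per_species),
         heterogeneity = heterogeneity,
         gs_median = gs_median, gs_sdlog = gs_sdlog, se_cv = se_cv,
         n_range = as.integer(n_range), outdoor_prob = outdoor_prob,
         biome_offsets = biome_offsets, plateau = plateau,
         interaction = interaction, suppress = suppress),
    class = "gs_synth_config"
  )
}

sample_biomes <- function(n) {
  sample(BIOME_LEVELS, n, replace = TRUE,
         prob = c(0.06, 0.3, 0.08, 0.04, 0.18, 0.06, 0.06, 0.22))
}

make_arm <- function(cfg, ln_rr_true, n_t, n_c, mean_c) {
  v_within <- cfg$se_cv^2 / n_t + cfg$se_cv^2 / n_c
  ln_obs <- ln_rr_true + rnorm(length(ln_rr_true), 0, sqrt(v_within))
  mean_t <- mean_c * exp(ln_obs)
  tibble(
    mean_T = mean_t, se_T = cfg$se_cv * mean_t / sqrt(n_t), n_T = n_t,
    mean_C = mean_c, se_C = cfg$se_cv * mean_c / sqrt(n_c), n_C = n_c
  )
}

#' Generate a synthetic observation table with known ground truth
#'
#' Draws an observation table satisfying every validation rule of
#' [read_observations] from the model in [synth_config]: per study one site
#' and one treatment magnitude; per species a unit-level random effect with
#' the configured between-study variance; per observation a measurement error
#' whose variance matches the reported standard errors, so the computed
#' `v_within` is the true noise variance. Two-factor configurations add
#' complete factorial triples obeying
#' `ln_rr_ab = lambda * (ln_rr_a + ln_rr_b) + noise`.
#'
#' @param config A `gs_synth_config` from [synth_config].
#' @return A list with `observations` (tibble in canonical columns) and
#'   `truth` (the generating parameters: per-factor mean sensitivity and tau2,
#'   interaction lambda, counts).
#' @export
generate_observations <- function(config) {
  if (!inherits(config, "gs_synth_config")) {
    abort("config must come from synth_config().")
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(config$seed)
  cfg <- config

  per_factor <- purrr::pmap_dfr(cfg$factors, function(factor, mean_sens, tau2,
                                                      mag_min, mag_max,
                                                      n_studies) {
    rows <- tidyr::expand_grid(
      study = seq_len(n_studies),
      sp = seq_len(cfg$species_per_study),
      rep = seq_len(cfg$obs_per_species)
    )
    study_mag <- runif(n_studies, mag_min, mag_max)
    study_biome <- sample_biomes(n_studies)
    study_outdoor <- runif(n_studies) < cfg$outdoor_prob
    raw_mag <- study_mag[rows$study]
    delta <- standardize_magnitude(factor, raw_mag)
    mu <- mean_sens +
      (cfg$biome_offsets[study_biome[rows$study]] %||% 0)
    mu[is.na(mu)] <- mean_sens
    eff_delta <- if (!is.null(cfg$plateau) && factor %in% names(cfg$plateau)) {
      pmin(delta, cfg$plateau[[factor]])
    } else delta
    # unit-level random effect shared by replicate obs of a species
    unit <- interaction(rows$study, rows$sp, drop = TRUE)
    u <- rnorm(nlevels(unit), 0, sqrt(tau2))[as.integer(unit)]
    ln_rr_true <- if (cfg$heterogeneity == "sens") {
      (mu + u) * eff_delta
    } else {
      mu * eff_delta + u
    }
    n_t <- sample(cfg$n_range[1]:cfg$n_range[2], nrow(rows), replace = TRUE)
    n_c <- sample(cfg$n_range[1]:cfg$n_range[2], nrow(rows), replace = TRUE)
    mean_c <- cfg$gs_median * exp(rnorm(nrow(rows), 0, cfg$gs_sdlog))
    arm <- make_arm(cfg, ln_rr_true, n_t, n_c, mean_c)
    biome <- ifelse(study_outdoor[rows$study], study_biome[rows$study],
                    NA_character_)
    mt <- BIOME_MAT[study_biome[rows$study]] + rnorm(nrow(rows), 0, 1.5)
    tibble(
      study_id = paste0(factor, "_S", rows$study),
      site_id = paste0(factor, "_site", rows$study),
      species = paste0(factor, "_S", rows$study, "_sp", rows$sp),
      biome = biome,
      pft = sample(PFT_LEVELS, nrow(rows), replace = TRUE),
      factors = factor,
      magnitude_1 = raw_mag, magnitude_2 = NA_real_
    ) %>%
      bind_cols(arm) %>%
      mutate(
        setting = ifelse(study_outdoor[rows$study], "outdoor", "indoor"),
        duration = round(runif(nrow(rows), 30, 365)),
        mat = mt,
        ai = pmax(0.05, BIOME_AI[study_biome[rows$study]] +
                    rnorm(nrow(rows), 0, 0.1)),
        monthly_temp = mt + 8,
        vp = 0.6 * 0.611 * exp(17.502 * (mt + 8) / (240.97 + mt + 8))
      )
  })

  inter_rows <- NULL
  if (!is.null(cfg$interaction)) {
    ft <- cfg$factors
    inter_rows <- purrr::map_dfr(cfg$interaction$pairs, function(pair) {
      fac <- strsplit(pair, "\\+")[[1]]
      fa <- ft[ft$factor == fac[1], ]
      fb <- ft[ft$factor == fac[2], ]
      nt <- cfg$interaction$n_triples
      mag_a <- runif(nt, fa$mag_min, fa$mag_max)
      mag_b <- runif(nt, fb$mag_min, fb$mag_max)
      da <- standardize_magnitude(fac[1], mag_a)
      db <- standardize_magnitude(fac[2], mag_b)
      ua <- rnorm(nt, 0, sqrt(fa$tau2))
      ub <- rnorm(nt, 0, sqrt(fb$tau2))
      ln_a <- if (cfg$heterogeneity == "sens") (fa$mean_sens + ua) * da
              else fa$mean_sens * da + ua
      ln_b <- if (cfg$heterogeneity == "sens") (fb$mean_sens + ub) * db
              else fb$mean_sens * db + ub
      ln_ab <- cfg$interaction$lambda * (ln_a + ln_b)
      biome <- sample_biomes(nt)
      purrr::map_dfr(seq_len(nt), function(i) {
        keys <- tibble(
          study_id = paste0("I_", pair, "_", i),
          site_id = paste0("I_", pair, "_site", i),
          species = paste0("I_", pair, "_", i, "_sp1"),
          biome = biome[i], pft = sample(PFT_LEVELS, 1)
        )
        arms <- tibble(
          factors = c(fac[1], fac[2], paste(fac, collapse = "+")),
          magnitude_1 = c(mag_a[i], mag_b[i], mag_a[i]),
          magnitude_2 = c(NA, NA, mag_b[i]),
          ln_true = c(ln_a[i], ln_b[i], ln_ab[i])
        )
        n_t <- sample(cfg$n_range[1]:cfg$n_range[2], 3, replace = TRUE)
        n_c <- sample(cfg$n_range[1]:cfg$n_range[2], 3, replace = TRUE)
        mean_c <- cfg$gs_median * exp(rnorm(3, 0, cfg$gs_sdlog))
        bind_cols(keys[rep(1, 3), ], arms[, 1:3],
                  make_arm(cfg, arms$ln_true, n_t, n_c, mean_c)) %>%
          mutate(setting = "outdoor",
                 duration = round(runif(3, 30, 365)),
                 mat = BIOME_MAT[biome[i]], ai = BIOME_AI[biome[i]],
                 monthly_temp = NA_real_, vp = NA_real_)
      })
    })
  }

  obs <- bind_rows(per_factor, inter_rows)
  if (isTRUE(cfg$suppress)) {
    v_rel <- cfg$se_cv^2 / obs$n_T + cfg$se_cv^2 / obs$n_C
    ln_obs <- log(obs$mean_T / obs$mean_C)
    fac1 <- sub("\\+.*$", "", obs$factors)
    ft <- cfg$factors
    mu_ln <- ft$mean_sens[match(fac1, ft$factor)] *
      standardize_magnitude(fac1, obs$magnitude_1)
    drop <- ln_obs < mu_ln & v_rel > stats::median(v_rel)
    obs <- obs[!drop, , drop = FALSE]
  }
  obs <- obs[OBS_COLUMNS]

  truth <- list(
    factors = cfg$factors[c("factor", "mean_sens", "tau2")],
    heterogeneity = cfg$heterogeneity,
    lambda = cfg$interaction$lambda %||% NA_real_,
    suppress = cfg$suppress,
    n_obs = nrow(obs)
  )
  list(observations = as_tibble(obs), truth = truth)
}
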