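# Builders for minimal in-memory tables and independent brute-force oracles.

make_effects <- function(ln_rr, v_within,
                         site = paste0("site", seq_along(ln_rr)),
                         species = paste0("sp", seq_along(ln_rr)),
                         factors = "eCO2", delta = 3,
                         biome = "temperate_forest", setting = "outdoor") {
  k <- length(ln_rr)
  tibble::tibble(
    study_id = paste0("study", seq_len(k)),
    site_id = rep_len(site, k),
    species = rep_len(species, k),
    biome = rep_len(biome, k),
    pft = "conifer",
    factors = rep_len(factors, k),
    n_factors = 1L,
    setting = rep_len(setting, k),
    ln_rr = ln_rr,
    v_within = v_within,
    delta = rep_len(delta, k),
    ln_sens = ln_rr / rep_len(delta, k),
    v_sens_within = v_within / rep_len(delta, k)^2,
    ambient_gs = 0.25
  )
}

# Brute-force random-effects pooling: plain loops over the defining sums,
# given a fixed tau2 and externally supplied group sizes.
brute_pool <- function(ln_rr, v_within, tau2, n_ob) {
  stopifnot(length(ln_rr) == length(v_within), length(ln_rr) == length(n_ob))
  num <- 0; den <- 0
  for (i in seq_along(ln_rr)) {
    w <- 1 / (v_within[i] + tau2)
    ws <- w / n_ob[i]
    num <- num + ws * ln_rr[i]
    den <- den + ws
  }
  mean_ln <- num / den
  se <- sqrt(1 / den)
  list(mean_ln = mean_ln, se = se,
       ci_low = mean_ln - 1.96 * se, ci_high = mean_ln + 1.96 * se,
       pct = (exp(mean_ln) - 1) * 100)
}

# A well-formed raw observation row in the canonical CSV layout.
make_obs_rows <- function(n = 5, mean_C = 0.25, mean_T = 0.2, n_T = 5, n_C = 5,
                          factors = "eCO2", magnitude_1 = 300) {
  tibble::tibble(
    study_id = paste0("s", seq_len(n)), site_id = paste0("site", seq_len(n)),
    species = paste0("sp", seq_len(n)), biome = "temperate_forest",
    pft = "conifer", factors = factors,
    magnitude_1 = magnitude_1, magnitude_2 = NA_real_,
    mean_T = mean_T, se_T = 0.02, n_T = n_T,
    mean_C = mean_C, se_C = 0.02, n_C = n_C,
    setting = "outdoor", duration = 100, mat = 10, ai = 0.8,
    monthly_temp = 18, vp = 1.2
  )
}
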