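test_that("a constant moderator raises a rank-deficiency error naming it", {
  eff <- make_effects(rnorm(10), runif(10, 0.01, 0.05))
  eff$duration <- 100
  expect_error(meta_regress(eff, "duration"), "duration")
})

test_that("equal weights reduce the linear fit to ordinary least squares", {
  set.seed(21)
  eff <- make_effects(rnorm(40, 0.1, 0.3), rep(0.02, 40))
  eff$mat <- runif(40, -5, 25)
  fit <- meta_regress(eff, "mat", form = "linear")
  ols <- stats::lm(eff$ln_rr ~ eff$mat)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-10)
})

test_that("the slope is equivariant under moderator rescaling", {
  set.seed(22)
  eff <- make_effects(rnorm(50, 0, 0.3), runif(50, 0.01, 0.08))
  eff$mat <- runif(50, 0, 10)
  f1 <- meta_regress(eff, "mat", form = "linear")
  eff2 <- eff
  eff2$mat <- eff$mat * 4
  f2 <- meta_regress(eff2, "mat", form = "linear")
  expect_equal(f2$coefficients$estimate[2], f1$coefficients$estimate[2] / 4,
               tolerance = 1e-8)
  expect_equal(f2$p_slope, f1$p_slope, tolerance = 1e-8)
})

test_that("the spline basis is linear beyond the outer knots", {
  knots <- c(1, 2, 4, 6)
  x <- seq(7, 12, by = 0.25)         # entirely beyond the last knot
  B <- rcs_basis(x, knots)
  for (j in seq_len(ncol(B))) {
    expect_equal(diff(diff(B[, j])), rep(0, length(x) - 2), tolerance = 1e-10)
  }
  expect_error(rcs_basis(1:10, c(1, 2)), "3 knots")
})

test_that("a generated linear dose response is recovered with its slope", {
  cfg <- synth_config(
    seed = 99,
    factors = tibble::tibble(factor = "eT", mean_sens = -0.1, tau2 = 0.01,
                             mag_min = 1, mag_max = 5, n_studies = 150L),
    species_per_study = 2L, obs_per_species = 1L, heterogeneity = "rr")
  eff <- effect_sizes(generate_observations(cfg)$observations)
  fit <- meta_regress(eff, "delta", response = "rr", form = "linear")
  slope <- fit$coefficients$estimate[2]
  expect_gt(slope, -0.12)
  expect_lt(slope, -0.08)
  expect_lt(fit$p_slope, 0.001)
  expect_gt(fit$r2, 0.5)   # the dose term explains most heterogeneity
})

test_that("a saturating dose response prefers the spline form", {
  wins <- vapply(1:40, function(s) {
    cfg <- synth_config(
      seed = 1000 + s,
      factors = tibble::tibble(factor = "eCO2", mean_sens = -0.12,
                               tau2 = 0.01, mag_min = 50, mag_max = 600,
                               n_studies = 100L),
      species_per_study = 2L, obs_per_species = 1L,
      heterogeneity = "rr", plateau = c(eCO2 = 3))
    eff <- effect_sizes(generate_observations(cfg)$observations)
    lin <- meta_regress(eff, "delta", form = "linear")
    rcs <- meta_regress(eff, "delta", form = "rcs")
    sel <- select_form(lin, rcs)
    sel$form == "rcs" && rcs$r2 > lin$r2
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("form selection prefers higher r2 with ties and failures to linear", {
  lin <- structure(list(form = "linear", r2 = 0.10), class = "gs_metareg")
  rcs <- structure(list(form = "rcs", r2 = 0.25), class = "gs_metareg")
  expect_identical(select_form(lin, rcs)$form, "rcs")
  rcs$r2 <- 0.10
  expect_identical(select_form(lin, rcs)$form, "linear")
  expect_warning(out <- select_form(lin, NULL), "linear")
  expect_identical(out$form, "linear")
})

test_that("predict and autoplot operate on a fitted meta-regression", {
  set.seed(33)
  eff <- make_effects(rnorm(60, 0, 0.3), runif(60, 0.01, 0.05))
  eff$mat <- runif(60, 0, 20)
  eff$ln_rr <- -0.02 * eff$mat + eff$ln_rr
  fit <- meta_regress(eff, "mat", form = "auto")
  pr <- predict(fit, c(5, 10))
  expect_equal(nrow(pr), 2)
  expect_true(all(pr$ci_low < pr$fit & pr$fit < pr$ci_high))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_equal(glance(fit)$k, 60)
})
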