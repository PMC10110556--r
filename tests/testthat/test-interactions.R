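factorial_rows <- function(species = "sp1", ln_a = -0.2, ln_b = -0.1,
                           ln_ab = -0.3, drop_arm = NULL) {
  rows <- make_obs_rows(3)
  rows$study_id <- "s1"; rows$site_id <- "siteA"; rows$species <- species
  rows$factors <- c("eCO2", "eT", "eCO2+eT")
  rows$magnitude_1 <- c(300, 2, 300)
  rows$magnitude_2 <- c(NA, NA, 2)
  rows$mean_C <- 0.25
  rows$mean_T <- 0.25 * exp(c(ln_a, ln_b, ln_ab))
  if (!is.null(drop_arm)) rows <- rows[rows$factors != drop_arm, ]
  rows
}

test_that("complete factorials yield one triple per species", {
  obs <- read_observations(factorial_rows(), quiet = TRUE)
  tr <- build_triples(effect_sizes(obs))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$pair, "eCO2+eT")
  expect_equal(tr$ln_sum, tr$ln_rr_a + tr$ln_rr_b)
  expect_equal(tr$v_d, tr$v_ab + tr$v_a + tr$v_b)

  two_sp <- dplyr::bind_rows(factorial_rows("sp1"), factorial_rows("sp2"))
  tr2 <- build_triples(effect_sizes(read_observations(two_sp, quiet = TRUE)))
  expect_equal(nrow(tr2), 2)
})

test_that("incomplete factorials are skipped and logged, not errors", {
  obs <- read_observations(factorial_rows(drop_arm = "eT"), quiet = TRUE)
  expect_message(tr <- build_triples(effect_sizes(obs)), "skipped")
  expect_equal(nrow(tr), 0)
  expect_equal(nrow(attr(tr, "skipped")), 1)
})

test_that("replicate arm observations are collapsed before matching", {
  dup <- dplyr::bind_rows(factorial_rows(), factorial_rows()[1, ])
  tr <- build_triples(effect_sizes(read_observations(dup, quiet = TRUE)))
  expect_equal(nrow(tr), 1)
  # two equal-variance replicates of arm a halve its variance
  one <- build_triples(effect_sizes(read_observations(factorial_rows(),
                                                      quiet = TRUE)))
  expect_equal(tr$v_a, one$v_a / 2)
})

test_that("interactions classify by the 1:1 line rule on both sides of zero", {
  v <- 1e-4
  # on the line: additive
  expect_equal(classify_interaction(-0.3, v, -0.3, v), "additive")
  # negative sum, combined less negative -> antagonistic
  expect_equal(classify_interaction(-0.2, v, -0.6, v), "antagonistic")
  # negative sum, combined more negative -> synergistic
  expect_equal(classify_interaction(-0.9, v, -0.6, v), "synergistic")
  # positive sum, combined above the line -> synergistic
  expect_equal(classify_interaction(0.9, v, 0.4, v), "synergistic")
  # positive sum, combined pulled back -> antagonistic
  expect_equal(classify_interaction(0.1, v, 0.4, v), "antagonistic")
  # sum indistinguishable from zero but d significant -> indeterminate
  expect_equal(classify_interaction(0.5, v, 0.001, 0.01), "indeterminate")
  # large uncertainty swallows the difference -> additive
  expect_equal(classify_interaction(-0.2, 0.2, -0.6, 0.2), "additive")
})

test_that("classification is symmetric in the factor order", {
  set.seed(55)
  for (i in 1:20) {
    a <- rnorm(1, 0, 0.4); b <- rnorm(1, 0, 0.4)
    ab <- rnorm(1, a + b, 0.2)
    va <- runif(1, 1e-4, 0.05); vb <- runif(1, 1e-4, 0.05)
    vab <- runif(1, 1e-4, 0.05)
    expect_identical(classify_interaction(ab, vab, a + b, va + vb),
                     classify_interaction(ab, vab, b + a, vb + va))
  }
})

test_that("the trend slope is one under exact additivity and errors degenerate", {
  x <- seq(-0.8, 0.8, length.out = 12)
  tr <- tibble::tibble(ln_sum = x, ln_rr_ab = x, v_d = 0.01)
  fit <- interaction_trend(tr)
  expect_equal(fit$coefficients$estimate, c(0, 1), tolerance = 1e-10)

  expect_error(interaction_trend(tr[1:2, ]), "3 complete triples")
  origin <- tibble::tibble(ln_sum = rep(0, 5), ln_rr_ab = rep(0, 5), v_d = 0.01)
  expect_error(interaction_trend(origin), "rank-deficient")
})
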