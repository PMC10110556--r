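test_that("log response ratio and within-study variance match hand values", {
  expect_equal(log_response_ratio(0.2, 0.05, 0.2, 0.03)$ln_rr, 0)
  no_se <- log_response_ratio(0.5, 0, 0.25, 0)
  expect_equal(no_se$ln_rr, log(2))
  expect_equal(no_se$v_within, 0)
  ex <- log_response_ratio(0.30, 0.03, 0.25, 0.05)
  expect_equal(ex$ln_rr, log(1.2))
  expect_equal(ex$v_within, (0.03 / 0.30)^2 + (0.05 / 0.25)^2)
  expect_equal(ex$v_within, 0.05)
  expect_error(log_response_ratio(0, 0.1, 0.2, 0.1), "positive")
})

test_that("lnRR is antisymmetric and scale invariant", {
  set.seed(101)
  for (i in 1:25) {
    m_t <- runif(1, 0.05, 0.8); m_c <- runif(1, 0.05, 0.8)
    s_t <- runif(1, 0, 0.1); s_c <- runif(1, 0, 0.1)
    fwd <- log_response_ratio(m_t, s_t, m_c, s_c)
    rev <- log_response_ratio(m_c, s_c, m_t, s_t)
    expect_equal(fwd$ln_rr, -rev$ln_rr)
    expect_equal(fwd$v_within, rev$v_within)
    c0 <- runif(1, 0.1, 10)
    scl <- log_response_ratio(c0 * m_t, c0 * s_t, c0 * m_c, c0 * s_c)
    expect_equal(scl$ln_rr, fwd$ln_rr)
    expect_equal(scl$v_within, fwd$v_within)
  }
})

test_that("adjusted weights divide by the site-species group size", {
  # four observations of one species at one site, equal weights
  eff <- make_effects(rep(0.1, 4), rep(1 / 8, 4), site = "A", species = "x")
  w <- adjusted_weights(eff, tau2 = 0)
  expect_equal(w$n_ob, rep(4L, 4))
  expect_equal(w$w_star, rep(2, 4))
  expect_equal(w$w_star * w$n_ob, w$w)

  # different species at one site stay independent
  eff2 <- make_effects(c(0.1, 0.2), c(0.5, 0.5), site = "A",
                       species = c("x", "y"))
  w2 <- adjusted_weights(eff2, tau2 = 0)
  expect_equal(w2$n_ob, c(1L, 1L))
  expect_equal(w2$w_star, w2$w)

  # unequal weights within a group of three: element-wise w / 3
  eff3 <- make_effects(rep(0, 3), 1 / c(6, 3, 3), site = "A", species = "x")
  w3 <- adjusted_weights(eff3, tau2 = 0)
  expect_equal(w3$w_star, c(2, 1, 1))

  # a single- and a two-factor observation of one species never share n_ob
  eff4 <- make_effects(c(0.1, 0.1), c(0.2, 0.2), site = "A", species = "x")
  eff4$factors[2] <- "eCO2+eT"
  w4 <- adjusted_weights(eff4, tau2 = 0)
  expect_equal(w4$n_ob, c(1L, 1L))

  empty <- adjusted_weights(make_effects(numeric(0), numeric(0)), tau2 = 0)
  expect_equal(nrow(empty), 0)
})

test_that("sensitivity is the exact ratio by delta and its square", {
  s <- sensitivity(-0.30, 0.04, 3)
  expect_equal(s$ln_sens, -0.10)
  expect_equal(s$v_sens, 0.04 / 9)
  expect_identical(s$ln_sens * 3, -0.30)
  expect_equal(sensitivity(0.25, 0.01, 1), list(ln_sens = 0.25, v_sens = 0.01))
  expect_equal(sensitivity(0, 0.02, 7)$ln_sens, 0)
  expect_error(sensitivity(0.1, 0.01, 0), "positive")
})

test_that("percentage change back-transforms and round-trips exactly", {
  expect_equal(percentage_change(0), 0)
  expect_equal(percentage_change(log(2)), 100)
  expect_equal(percentage_change(-0.0866), -8.29, tolerance = 1e-3)
  set.seed(7)
  x <- rnorm(50, 0, 0.5)
  expect_equal(log(1 + percentage_change(x) / 100), x)
})

test_that("effect_sizes fills effect and sensitivity columns per row", {
  raw <- make_obs_rows(3, mean_T = 0.30, mean_C = 0.25)
  raw$se_T <- 0.03; raw$se_C <- 0.05
  eff <- effect_sizes(read_observations(raw, quiet = TRUE))
  expect_equal(eff$ln_rr, rep(log(1.2), 3))
  expect_equal(eff$v_within, rep(0.05, 3))
  expect_equal(eff$delta, rep(3, 3))
  expect_equal(eff$ln_sens * eff$delta, eff$ln_rr)
  expect_equal(eff$v_sens_within * eff$delta^2, eff$v_within)
  expect_equal(eff$ambient_gs, eff$mean_C)

  # two-factor rows carry no single-factor sensitivity
  raw$factors[1] <- "eCO2+eT"; raw$magnitude_2[1] <- 2
  eff2 <- effect_sizes(read_observations(raw, quiet = TRUE))
  expect_true(is.na(eff2$ln_sens[eff2$n_factors == 2]))
})
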