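test_that("tau2 estimators handle degenerate and closed-form cases", {
  # no excess heterogeneity: identical effects with equal variances
  expect_equal(estimate_tau2(rep(0.2, 10), rep(0.02, 10)), 0)
  expect_equal(estimate_tau2(rep(0.2, 10), rep(0.02, 10), method = "dl"), 0)

  # two effects: DL closed form max(0, (Q - 1) / C), hand-computed
  y <- c(0.1, 0.5); v <- c(0.02, 0.05)
  w <- 1 / v
  yb <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yb)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  expect_equal(estimate_tau2(y, v, method = "dl"), max(0, (Q - 1) / C))

  expect_error(estimate_tau2(0.1, 0.01), "two effects")
})

test_that("REML tau2 agrees with metafor with and without moderators", {
  set.seed(31)
  for (i in 1:5) {
    k <- sample(20:80, 1)
    v <- runif(k, 0.005, 0.05)
    x <- runif(k, 0, 5)
    y <- 0.1 - 0.05 * x + rnorm(k, 0, sqrt(v + 0.03))
    expect_equal(estimate_tau2(y, v),
                 metafor::rma(yi = y, vi = v, method = "REML",
                              control = list(tol = 1e-10))$tau2,
                 tolerance = 1e-4)
    expect_equal(estimate_tau2(y, v, X = cbind(1, x)),
                 metafor::rma(yi = y, vi = v, mods = ~x, method = "REML",
                              control = list(tol = 1e-10))$tau2,
                 tolerance = 1e-4)
    expect_equal(estimate_tau2(y, v, method = "dl"),
                 metafor::rma(yi = y, vi = v, method = "DL")$tau2,
                 tolerance = 1e-10)
  }
})

test_that("REML recovers a known tau2 at large k", {
  set.seed(11)
  y <- rnorm(500, 0.1, sqrt(0.01 + 0.05))
  t2 <- estimate_tau2(y, rep(0.01, 500))
  expect_gt(t2, 0.035)
  expect_lt(t2, 0.065)
})

test_that("pool reproduces single- and two-effect hand computations", {
  one <- pool(make_effects(0.2, 0.04), tau2 = 0)
  expect_equal(one$estimate$mean_ln, 0.2)
  expect_equal(one$estimate$se, sqrt(0.04))

  two <- pool(make_effects(c(0.1, 0.3), c(1, 1 / 3)), tau2 = 0)
  expect_equal(two$estimate$mean_ln, 0.25)
  expect_equal(two$estimate$se, 0.5)
  expect_equal(two$estimate$n_sp, 2L)

  zero <- pool(make_effects(c(0, 0), c(0.1, 0.2)), tau2 = 0)
  expect_equal(zero$estimate$pct, 0)
  expect_equal(zero$estimate$ci_low, -zero$estimate$ci_high)
})

test_that("confidence bounds obey the 1.96 SE identity and ordering", {
  set.seed(5)
  eff <- make_effects(rnorm(12, 0.1, 0.3), runif(12, 0.01, 0.1),
                      site = sample(c("A", "B"), 12, TRUE),
                      species = sample(c("x", "y", "z"), 12, TRUE))
  p <- tidy(pool(eff))
  expect_equal(p$ci_high - p$ci_low, 2 * 1.96 * p$se)
  expect_true(p$ci_low <= p$mean_ln && p$mean_ln <= p$ci_high)
  expect_equal(p$pct, percentage_change(p$mean_ln))
  expect_true(p$pct_low < p$pct && p$pct < p$pct_high)
})

test_that("pooled mean is invariant to uniform weight rescaling", {
  set.seed(9)
  eff <- make_effects(rnorm(8, 0, 0.3), runif(8, 0.01, 0.1))
  base <- pool(eff, tau2 = 0.02)$estimate
  scaled <- eff
  scaled$v_within <- eff$v_within * 4   # w scales by 1/4 uniformly
  resc <- pool(scaled, tau2 = 0.08)$estimate
  expect_equal(resc$mean_ln, base$mean_ln)
  expect_equal(resc$se, 2 * base$se)
})

test_that("pool matches a brute-force oracle on small hand-built panels", {
  set.seed(42)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    site <- sample(c("A", "B"), k, TRUE)
    species <- sample(c("x", "y"), k, TRUE)
    eff <- make_effects(rnorm(k, 0, 0.4), runif(k, 0.01, 0.2),
                        site = site, species = species)
    tau2 <- runif(1, 0, 0.05)
    got <- pool(eff, tau2 = tau2)$estimate
    key <- paste(site, species)
    n_ob <- as.vector(table(key)[key])
    want <- brute_pool(eff$ln_rr, eff$v_within, tau2, n_ob)
    expect_equal(got$mean_ln, want$mean_ln, tolerance = 1e-12)
    expect_equal(got$se, want$se, tolerance = 1e-12)
    expect_equal(got$ci_low, want$ci_low, tolerance = 1e-12)
    expect_equal(got$ci_high, want$ci_high, tolerance = 1e-12)
  }
})

test_that("subgroup analysis computes Q_B and flags real separation", {
  # identical pooled means -> Q_B = 0
  eff <- dplyr::bind_rows(
    make_effects(c(0.2, 0.2), c(0.05, 0.05), biome = "desert"),
    make_effects(c(0.2, 0.2), c(0.05, 0.05), biome = "cropland")
  )
  eff$site_id <- paste0(eff$site_id, eff$biome)
  sg <- pool(eff, by = "biome", tau2 = 0)
  expect_equal(sg$q_b, 0, tolerance = 1e-12)

  # strong separation: power ~ 1
  set.seed(13)
  eff2 <- dplyr::bind_rows(
    make_effects(rnorm(30, 0, 0.05), rep(0.002, 30), biome = "desert",
                 site = paste0("d", 1:30)),
    make_effects(rnorm(30, 0.5, 0.05), rep(0.002, 30), biome = "cropland",
                 site = paste0("c", 1:30))
  )
  sg2 <- pool(eff2, by = "biome")
  expect_lt(sg2$p_qb, 0.001)
  expect_equal(sg2$df, 1)
  expect_equal(nrow(tidy(sg2)), 2)
  expect_true(all(c("q_b", "p_qb") %in% names(glance(sg2))))

  # a single group cannot be tested
  expect_error(pool(make_effects(rnorm(5), runif(5, 0.01, 0.05)),
                    by = "biome"),
               "two non-empty groups")
})
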