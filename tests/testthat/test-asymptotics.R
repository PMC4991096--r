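test_that("mixture moments follow the moment algebra", {
  expect_equal(unname(mixture_moments(dist_mixture2(0.5, 0, 1, 0, 1))),
               c(0, 1))
  m <- mixture_moments(dist_mixture2(0.5, 0, 1, 2 * sqrt(2), 1))
  expect_equal(m[["mean"]], sqrt(2), tolerance = 1e-12)
  expect_equal(m[["var"]], 3, tolerance = 1e-12)
  # tau2 -> 1 recovers the second component's moments
  m2 <- mixture_moments(dist_mixture2(1e-9, 0, 1, 5, 2))
  expect_equal(m2[["mean"]], 5, tolerance = 1e-6)
  expect_equal(m2[["var"]], 2, tolerance = 1e-6)
})

test_that("subsample-t interval has the closed-form center and width", {
  m <- two_group_model(dist_normal(1, 1))
  ci <- t_ci(m, 1, 1, n = 400, alpha = 0.05)
  expect_equal(ci$half_width, qnorm(0.975) * sqrt(2 / 400), tolerance = 1e-9)
  expect_equal(ci$center, sqrt(2) * 1 / sqrt(4), tolerance = 1e-12)
  expect_equal(ci$upper - ci$lower, 2 * ci$half_width)

  # null model centers at zero whatever the variances
  m0 <- two_group_model(dist_normal(0, 7), dist_normal(0, 0.3))
  expect_equal(t_ci(m0, 2, 3, 100)$center, 0)

  # the width depends only on (a, b, n, alpha)
  wide <- two_group_model(dist_mixture2(0.3, -2, 4, 5, 9))
  expect_equal(t_ci(wide, 2, 3, 100)$half_width,
               t_ci(m0, 2, 3, 100)$half_width)
})

test_that("calibrated homo and hetero models share the same t interval", {
  for (sit in c("I", "II", "III")) {
    mods <- situation_models(sit)
    ci_h <- t_ci(mods$homo, 1, 10, 200)
    ci_x <- t_ci(mods$hetero, 1, 10, 200)
    expect_equal(ci_h$center, ci_x$center, tolerance = 1e-10, info = sit)
    expect_equal(ci_h$half_width, ci_x$half_width, info = sit)
  }
})

test_that("sign-sum moments reduce to closed forms", {
  # F1 = F0 (continuous): exchangeability gives 1/2
  null <- two_group_model(dist_normal(0, 1))
  expect_equal(signsum_moments(null, 1, 1)[["e_us"]], 0.5, tolerance = 1e-8)
  expect_equal(signsum_moments(null, 2, 3)[["e_us"]], 0.5, tolerance = 1e-8)

  # a=b=1 normal case: Phi(dmu / sqrt(s1^2 + s0^2))
  for (par in list(c(1, 1, 1), c(0.5, 2, 1), c(-0.7, 1, 3))) {
    m <- two_group_model(dist_normal(par[1], par[2]), dist_normal(0, par[3]))
    expect_equal(signsum_moments(m, 1, 1)[["e_us"]],
                 pnorm(par[1] / sqrt(par[2] + par[3])), tolerance = 1e-8)
  }
})

test_that("sign-sum moments agree with a simulation oracle, variance nonnegative", {
  set.seed(77)
  for (sit in c("I", "III")) {
    model <- situation_models(sit)$hetero
    for (b in c(1, 10)) {
      mom <- signsum_moments(model, 1, b)
      oracle <- mc_signsum_mean(model, 1, b, n_draws = 2e5)
      expect_lt(abs(mom[["e_us"]] - oracle[["mean"]]), 4 * oracle[["se"]])
      expect_gte(mom[["sigma_tilde_sq"]], 0)
    }
  }
  # a > 1 exercises the mixture convolution of the W distributions
  model <- situation_models("I")$hetero
  mom <- signsum_moments(model, 3, 2)
  oracle <- mc_signsum_mean(model, 3, 2, n_draws = 2e5)
  expect_lt(abs(mom[["e_us"]] - oracle[["mean"]]), 4 * oracle[["se"]])

  # complete separation: G_y(V_y) is a.s. constant, so sigma_tilde^2 ~ 0
  sep <- two_group_model(dist_normal(100, 1))
  msep <- signsum_moments(sep, 1, 1)
  expect_equal(msep[["e_us"]], 1, tolerance = 1e-8)
  expect_lt(msep[["sigma_tilde_sq"]], 1e-8)
})

test_that("sign-sum interval scales as theory dictates", {
  m <- situation_models("I")$homo
  nearly_sure <- signsum_ci(m, 1, 5, 200, alpha = 0.9999)
  expect_lt(nearly_sure$half_width, 1e-3)
  ci_n <- signsum_ci(m, 1, 5, 250)
  ci_4n <- signsum_ci(m, 1, 5, 1000)
  expect_equal(ci_4n$half_width, ci_n$half_width / 2, tolerance = 1e-10)
  expect_equal(ci_4n$center, ci_n$center, tolerance = 1e-10)
})

test_that("the asymptotic interval covers the sampling distribution of U^S", {
  # homo model of Situation I, a=1, b=10, n=1000: empirical coverage of the
  # 95% interval over simulated replicates stays above 90%
  m <- situation_models("I")$homo
  ci <- signsum_ci(m, 1, 10, 1000)
  set.seed(12)
  inside <- replicate(250, {
    es <- one_gene_es(rnorm(500), rnorm(500, 1, 1))
    u <- sign_sum(es, subsample_scheme(1, 10, "monte_carlo", n_draws = 25000,
                                       seed = sample.int(1e6, 1)))$score
    u >= ci$lower && u <= ci$upper
  })
  expect_gte(mean(inside), 0.90)
})

test_that("UCL differences are positive and ordered in (a, b) under calibration", {
  mods <- situation_models("I")
  expect_equal(ucl_difference(mods$homo, mods$homo, 1, 10, 200), 0)

  d_b1 <- ucl_difference(mods$homo, mods$hetero, 1, 1, 200)
  d_b5 <- ucl_difference(mods$homo, mods$hetero, 1, 5, 200)
  d_b10 <- ucl_difference(mods$homo, mods$hetero, 1, 10, 200)
  expect_gt(d_b10, 0)
  expect_gte(d_b10, d_b1)
  expect_gte(d_b10, ucl_difference(mods$homo, mods$hetero, 5, 10, 200))

  grid <- asymptotics_grid(mods$homo, mods$hetero, a = 1, b = c(1, 5, 10),
                           n = 200)
  expect_equal(grid$ucl_diff, c(d_b1, d_b5, d_b10), tolerance = 1e-10)
})
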