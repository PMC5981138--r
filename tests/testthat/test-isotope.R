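test_that("rayleigh_delta honours its closed form and domain", {
  expect_identical(rayleigh_delta(-5.2, -8.67, 1), -5.2)
  expect_identical(rayleigh_delta(-5.2, 0, c(1, 0.7, 0.3)), rep(-5.2, 3))
  # hand evaluation: -5.2 + (-8.67) * ln(0.9) = -4.28652
  expect_equal(rayleigh_delta(-5.2, -8.67, 0.9), -4.286524, tolerance = 1e-6)
  expect_error(rayleigh_delta(-5.2, -8.67, 0), "f must be")
  expect_error(rayleigh_delta(-5.2, -8.67, -0.1), "f must be")
})

test_that("residual DIC grows enriched as f falls (negative epsilon)", {
  f <- seq(1, 0.5, by = -0.05)
  d <- rayleigh_delta(-5, -8, f)
  expect_true(all(diff(d) > 0))
  d_pos <- rayleigh_delta(-5, 8, f)
  expect_true(all(diff(d_pos) < 0))
})

test_that("the linearised and exact Rayleigh forms agree closely here", {
  # over the observed fractionation and DIC-loss range the two differ by
  # well under 0.05 per mil
  f <- seq(1, 0.8, by = -0.01)
  d_lin <- rayleigh_delta(-5.2, -8.67, f)
  d_ex <- rayleigh_delta(-5.2, -8.67, f, exact = TRUE)
  expect_lt(max(abs(d_lin - d_ex)), 0.05)
})

test_that("fit_epsilon recovers epsilon exactly from noiseless series", {
  set.seed(404)
  for (i in 1:50) {
    eps <- runif(1, -30, 0)
    d0 <- runif(1, -30, 10)
    n <- sample(3:100, 1)
    f <- sort(runif(n, 0.3, 1), decreasing = TRUE)
    fit <- fit_epsilon(f, rayleigh_delta(d0, eps, f))
    expect_equal(fit$epsilon, eps, tolerance = 1e-8)
    expect_equal(fit$intercept, d0, tolerance = 1e-8)
    expect_gte(fit$r_squared, 1 - 1e-10)
  }
})

test_that("exclusion masks are explicit and change the fit", {
  ex <- generate_degassing_experiment(
    degassing_experiment_spec(noise_sd = list(dic_mM = 0, d13c = 0)))
  f <- dic_fraction_remaining(ex$dic_mM)
  masked <- fit_epsilon(f, ex$d13c_permil, exclude = 1:6)
  unmasked <- fit_epsilon(f, ex$d13c_permil)
  expect_equal(masked$n_excluded, 6L)
  expect_equal(masked$epsilon, -8.67, tolerance = 1e-6)
  # the incompletely mixed early points steepen the unmasked slope
  expect_lt(unmasked$epsilon, masked$epsilon)
  expect_error(fit_epsilon(f, ex$d13c_permil,
                           exclude = rep(TRUE, length(f))),
               "at least 2")
  expect_error(fit_epsilon(rep(0.9, 5), rnorm(5)), "constant")
})

test_that("expected DIC delta13C is a pure shift by the enrichment factor", {
  expect_identical(expected_dic_delta(-1.2), -2.2)
  expect_identical(expected_dic_delta(c(-2.2, -0.2)), c(-3.2, -1.2))
  expect_identical(
    expected_dic_delta(0.7, isotope_config(calcite_bicarbonate_enrichment = 0)),
    0.7)
  # distributes over the mean
  x <- c(-2.2, -1.7, -0.9, -0.2)
  expect_equal(mean(expected_dic_delta(x)), expected_dic_delta(mean(x)))
})

test_that("DIC fractions divide through by the first value", {
  expect_equal(dic_fraction_remaining(c(15.7, 14.9, 13.7, 12.8)),
               c(1, 0.94904459, 0.87261146, 0.81528662), tolerance = 1e-7)
  expect_identical(dic_fraction_remaining(rep(3.2, 4)), rep(1, 4))
  expect_equal(dic_fraction_remaining(c(14.7, 13.5))[2], 0.9183673,
               tolerance = 1e-6)
  expect_error(dic_fraction_remaining(c(14.7, 0)), "> 0")
  expect_error(dic_fraction_remaining(c(-1, 2)), "> 0")
})

test_that("the stream fractionation is internally consistent with the transect", {
  # Rayleigh prediction at the outflow DIC fraction, from the source value
  # and the stream fractionation, lands close to the measured outflow DIC
  # delta13C (-3.1 per mil)
  pred <- rayleigh_delta(-4.8, -7.80, 12.8 / 15.7)
  expect_lt(abs(pred - (-3.1)), 0.3)
})
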