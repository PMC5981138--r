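noise_free <- list(dic_mM = 0, d13c = 0, temperature_C = 0, ph = 0,
                   ions_mM = 0)

test_that("noise-free transect endpoints reproduce the printed analyses", {
  tr <- generate_transect(transect_spec(noise_sd = noise_free))
  expect_equal(nrow(tr), 4L)
  expect_identical(tr$dic_mM[c(1, 4)], c(15.7, 12.8))
  expect_equal(tr$temperature_C[c(1, 4)], c(81.2, 70.7), tolerance = 1e-9)
  expect_equal(tr$pH[c(1, 4)], c(6.70, 7.45), tolerance = 0.1)
  expect_equal(tr$d13c_dic_permil[1], -4.8)
  # cooler and more alkaline downstream
  expect_true(all(diff(tr$temperature_C) < 0))
  expect_true(all(diff(tr$pH) > 0))
})

test_that("noise-free transect is a fixed point of the epsilon estimator", {
  spec <- transect_spec(noise_sd = noise_free)
  tr <- generate_transect(spec)
  fit <- fit_epsilon(dic_fraction_remaining(tr$dic_mM), tr$d13c_dic_permil)
  expect_equal(fit$epsilon, spec$epsilon, tolerance = 1e-8)
})

test_that("generated samples satisfy the water-sample invariants", {
  tr <- generate_transect(transect_spec(seed = 7))
  samples <- water_samples_from_df(tr)
  for (s in samples) {
    expect_s3_class(s, "water_sample")
    expect_true(s$temperature_C >= 0 && s$temperature_C <= 100)
    expect_true(s$pH >= 0 && s$pH <= 14)
    expect_true(all(unlist(s[c("dic", "ca", "na", "k", "cl", "so4", "f",
                               "sio2")]) >= 0))
  }
})

test_that("generation is seeded: same seed identical, different seeds differ", {
  a <- generate_transect(transect_spec(seed = 11))
  b <- generate_transect(transect_spec(seed = 11))
  c <- generate_transect(transect_spec(seed = 12))
  expect_identical(a, b)
  expect_false(identical(a, c))
  e1 <- generate_degassing_experiment(degassing_experiment_spec(seed = 5))
  e2 <- generate_degassing_experiment(degassing_experiment_spec(seed = 5))
  e3 <- generate_degassing_experiment(degassing_experiment_spec(seed = 6))
  expect_identical(e1, e2)
  expect_false(identical(e1, e3))
  # generators must not disturb the global RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_transect(transect_spec(seed = 3)))
  expect_identical(rnorm(1), before)
})

test_that("noise-free experiment reproduces the printed endpoints and epsilon", {
  spec <- degassing_experiment_spec(noise_sd = list(dic_mM = 0, d13c = 0))
  ex <- generate_degassing_experiment(spec)
  expect_equal(nrow(ex), 31L)
  expect_identical(ex$dic_mM[1], 14.7)
  expect_equal(ex$dic_mM[31], 13.5, tolerance = 1e-12)
  expect_identical(ex$d13c_permil[1], -5.2)
  # the depleted early points put the last sample near the printed -3.3
  expect_equal(ex$d13c_permil[31], -3.3, tolerance = 0.1)
  fit <- fit_epsilon(dic_fraction_remaining(ex$dic_mM), ex$d13c_permil,
                     exclude = seq_len(spec$n_unmixed))
  expect_equal(fit$epsilon, spec$epsilon, tolerance = 0.1)
})

test_that("epsilon recovery does not depend on the DIC decline shape", {
  for (shape in c("exponential", "linear")) {
    spec <- degassing_experiment_spec(dic_decline = shape,
                                      noise_sd = list(dic_mM = 0, d13c = 0))
    ex <- generate_degassing_experiment(spec)
    expect_identical(ex$dic_mM[1], 14.7)
    expect_equal(ex$dic_mM[31], 13.5, tolerance = 1e-12)
    fit <- fit_epsilon(dic_fraction_remaining(ex$dic_mM), ex$d13c_permil,
                       exclude = 1:6)
    expect_equal(fit$epsilon, spec$epsilon, tolerance = 1e-8)
  }
})

test_that("unmixing perturbation has the injected sign and magnitude", {
  spec <- degassing_experiment_spec(noise_sd = list(dic_mM = 0, d13c = 0))
  ex <- generate_degassing_experiment(spec)
  line <- rayleigh_delta(spec$delta_initial + spec$unmixed_amplitude,
                         spec$epsilon, dic_fraction_remaining(ex$dic_mM))
  dev <- ex$d13c_permil - line
  expect_equal(dev[1], -spec$unmixed_amplitude)           # full depletion
  expect_true(all(dev[1:6] < 0))                          # toward depletion
  expect_true(all(abs(dev[7:31]) < 1e-12))                # later points on-line
  expect_true(all(diff(dev[1:7]) > 0))                    # linear decay
})

test_that("median recovered epsilon at analytical precision is accurate", {
  # 200 seeded replicates at the stated replicate precision
  # (DIC +/-0.3 mM, delta13C +/-0.5 per mil)
  eps_hat <- vapply(1:200, function(s) {
    tr <- generate_transect(transect_spec(seed = s))
    fit_epsilon(dic_fraction_remaining(tr$dic_mM),
                tr$d13c_dic_permil)$epsilon
  }, numeric(1))
  expect_lt(abs(median(eps_hat) - (-7.80)), 0.5)
})

test_that("spec validation rejects degenerate designs", {
  expect_error(degassing_experiment_spec(duration_s = 120, interval_s = 30),
               "at least 8")
  expect_error(degassing_experiment_spec(n_unmixed = 40), "n_unmixed")
  expect_error(transect_spec(n_sites = 1), "n_sites")
  expect_error(transect_spec(noise_sd = list(d13c = -1)), "noise")
})
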