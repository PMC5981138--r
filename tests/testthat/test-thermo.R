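test_that("equilibrium constants reproduce their published 25 degC values", {
  tc <- thermo_constants(25)
  # Plummer & Busenberg (1982) report pK1 = 6.352, pK2 = 10.329,
  # log10 Ksp(calcite) = -8.480 at 25 degC
  expect_equal(-log10(tc$K1), 6.352, tolerance = 1e-3)
  expect_equal(-log10(tc$K2), 10.329, tolerance = 1e-3)
  expect_equal(log10(tc$Ksp_calcite), -8.480, tolerance = 1e-3)
  # pure-water ion product
  expect_equal(-log10(tc$Kw), 13.995, tolerance = 1e-3)
  # amorphous silica solubility, hand-evaluated:
  # 10^(4.52 - 731/298.15) = 117.0 mg/kg -> / 60.0843 g/mol = 1.947e-3 mol/kg
  expect_equal(tc$csat_amSiO2, 1.947e-3, tolerance = 1e-3)
})

test_that("constants are positive and trend correctly with temperature", {
  temps <- seq(0, 100, by = 5)
  for (t in temps) {
    tc <- thermo_constants(t)
    expect_true(all(unlist(tc[c("K1", "K2", "Kw", "Ksp_calcite",
                                "csat_amSiO2")]) > 0))
  }
  ksp <- vapply(seq(25, 85, by = 5),
                function(t) thermo_constants(t)$Ksp_calcite, numeric(1))
  expect_true(all(diff(ksp) < 0))   # calcite less soluble when hotter
  csat <- vapply(seq(25, 85, by = 5),
                 function(t) thermo_constants(t)$csat_amSiO2, numeric(1))
  expect_true(all(diff(csat) > 0))  # amorphous silica more soluble when hotter
})

test_that("out-of-range temperature and unknown correlations are rejected", {
  expect_error(thermo_constants(-5), "temperature")
  expect_error(thermo_constants(150), "temperature")
  expect_error(thermo_registry(k1 = "nope"), "unknown correlation")
})

test_that("Davies activity coefficients honour their limits and a hand value", {
  # infinite-dilution limit for every charge
  for (z in 0:3) {
    expect_equal(activity_coefficient(z, 0, 25), 1)
  }
  # charge symmetry
  expect_identical(activity_coefficient(1, 0.05, 60),
                   activity_coefficient(-1, 0.05, 60))
  # hand evaluation: A(25) = 0.5116, z = 2, I = 0.025:
  # log10 gamma = -0.5116 * 4 * (0.15811/1.15811 - 0.0075) = -0.2641
  expect_equal(activity_coefficient(2, 0.025, 25), 0.5445, tolerance = 1e-3)
  # bounded on (0, 1.2] over a broad sweep
  g <- activity_coefficient(2, seq(0, 0.5, by = 0.01), 80)
  expect_true(all(g > 0 & g <= 1.2))
  expect_error(activity_coefficient(1, -0.1), "ionic_strength")
})

test_that("gamma tends to 1 as ionic strength tends to 0", {
  for (z in 1:3) {
    g <- activity_coefficient(z, 10^seq(-2, -10), 40)
    expect_true(all(diff(g) > 0))
    expect_equal(g[length(g)], 1, tolerance = 1e-3)
  }
})

test_that("registry can be loaded from the packaged YAML", {
  reg <- read_thermo_registry(system.file("extdata", "thermo_registry.yaml",
                                          package = "springsat"))
  expect_s3_class(reg, "thermo_registry")
  expect_equal(thermo_constants(40, reg)$K1, thermo_constants(40)$K1)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("k1: plummer_busenberg_1982\nquartz: foo", bad)
  expect_error(read_thermo_registry(bad), "unknown thermodynamic registry")
})
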