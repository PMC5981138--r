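test_that("zero-extent processes leave the water unchanged", {
  tr <- degassing_trajectory(site1, 0, n_steps = 10, epsilon_co2_dic = -7.8)
  expect_equal(nrow(tr$points), 1L)
  expect_identical(tr$points$pH, site1$pH)
  expect_identical(tr$points$dic, site1$dic)
  expect_identical(tr$points$delta13c_dic, site1$delta13c_dic)

  ev <- evaporation_trajectory(site1, max_evaporated_fraction = 0)
  expect_equal(ev$points$omega_calcite[1],
               saturation(site1)$omega_calcite, tolerance = 1e-9)

  co <- cooling_trajectory(site1, t_end_C = site1$temperature_C)
  expect_equal(nrow(co$points), 1L)
  expect_equal(co$points$pH, site1$pH, tolerance = 1e-9)
})

test_that("degassing holds alkalinity fixed while pH and omega rise", {
  tr <- degassing_trajectory(site1, 0.5, n_steps = 100,
                             epsilon_co2_dic = -7.80)
  pts <- tr$points
  alk0 <- pts$carbonate_alkalinity[1]
  expect_true(all(abs(pts$carbonate_alkalinity - alk0) < 1e-10))
  expect_true(all(diff(pts$pH) > 0))
  expect_true(all(diff(pts$omega_calcite) > 0))
  # silica saturation is untouched by degassing
  expect_true(all(pts$omega_amSiO2 == pts$omega_amSiO2[1]))
  # spot-check against independent per-point solves
  for (i in c(25, 50, 100)) {
    r <- pts$extent[i]
    pH_i <- solve_ph(alk0, site1$dic * (1 - r), site1$temperature_C,
                     pts$ionic_strength[i])
    expect_equal(pts$pH[i], pH_i, tolerance = 1e-9)
    expect_equal(pts$delta13c_dic[i],
                 rayleigh_delta(site1$delta13c_dic, -7.80, 1 - r))
  }
})

test_that("evaporation concentrates conservatively and omegas never decrease", {
  ev <- evaporation_trajectory(site1, 81.2, 0.95, 100)
  pts <- ev$points
  # mass per original kg of water is invariant
  expect_equal(pts$dic * (1 - pts$extent), rep(site1$dic, nrow(pts)),
               tolerance = 1e-12)
  # closed form for the neutral silica species
  expect_equal(pts$omega_amSiO2,
               pts$omega_amSiO2[1] / (1 - pts$extent), tolerance = 1e-12)
  expect_true(all(diff(pts$omega_calcite) > 0))
  expect_true(all(diff(pts$omega_amSiO2) > 0))
})

test_that("hot evaporation strongly favours calcite; cool evaporation is even", {
  hot <- evaporation_trajectory(site1, 81.2, 0.8, 100)$points
  cool <- evaporation_trajectory(site1, 25, 0.8, 100)$points
  i_hot <- which(hot$omega_amSiO2 >= 1)[1]
  expect_gt(hot$omega_calcite[i_hot] / hot$omega_amSiO2[i_hot], 10)
  i_cool <- which(cool$omega_amSiO2 >= 1)[1]
  ratio_cool <- cool$omega_calcite[i_cool] / cool$omega_amSiO2[i_cool]
  expect_lt(ratio_cool, hot$omega_calcite[i_hot] / hot$omega_amSiO2[i_hot])
})

test_that("cooling alone cannot saturate amorphous silica", {
  co <- cooling_trajectory(site1, 81.2, 25, 100)
  expect_true(all(co$points$omega_amSiO2 < 1))
  # silica saturation rises monotonically as the water cools
  expect_true(all(diff(co$points$omega_amSiO2) > 0))
  # hand value at 25 degC: 1.49e-3 / 1.9473e-3 mol/kg
  expect_equal(co$points$omega_amSiO2[nrow(co$points)], 0.7651,
               tolerance = 1e-3)
})

test_that("trajectories are bitwise deterministic and grid-insensitive", {
  a <- degassing_trajectory(site1, 0.4, 100, -7.8)
  b <- degassing_trajectory(site1, 0.4, 100, -7.8)
  expect_identical(a, b)
  x200 <- first_crossing(evaporation_trajectory(site1, 81.2, 0.95, 200),
                         "amSiO2")
  x400 <- first_crossing(evaporation_trajectory(site1, 81.2, 0.95, 400),
                         "amSiO2")
  expect_lt(abs(x400 - x200) / x200, 0.005)
})

test_that("the staged growth scenario reports the expected crossings", {
  gs <- growth_scenario(site1)
  expect_identical(gs$crossings$degassing$calcite, 0)     # already saturated
  expect_true(is.na(gs$crossings$degassing$amSiO2))       # degassing: never
  expect_false(is.na(gs$crossings$evaporation$amSiO2))    # splash stage: yes
  # stage-2 silica threshold agrees with a standalone evaporation run of the
  # same end-member water
  last <- gs$stages$degassing$points[nrow(gs$stages$degassing$points), ]
  end_member <- water_sample(site1$temperature_C, last$pH, dic = last$dic,
                             ca = site1$ca, na = site1$na, k = site1$k,
                             cl = site1$cl, so4 = site1$so4, f = site1$f,
                             sio2 = site1$sio2)
  standalone <- evaporation_trajectory(end_member, 25, 0.95, 200)
  expect_equal(gs$crossings$evaporation$amSiO2,
               first_crossing(standalone, "amSiO2"), tolerance = 1e-9)
})

test_that("zero-extent scenario stages report no crossings", {
  gs <- growth_scenario(site1,
                        flowpath_config = list(max_dic_removed_fraction = 0),
                        splash_config = list(max_evaporated_fraction = 0))
  expect_true(all(is.na(unlist(gs$crossings))))
})
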