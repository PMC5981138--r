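# Shared fixtures: the packaged transect waters and a random-sample factory.

lhc <- lhc_site_waters()

site1 <- lhc[[1]]
site4 <- lhc[[4]]

# a random valid water sample; concentrations mol/kg
random_sample <- function() {
  water_sample(
    temperature_C = runif(1, 5, 95),
    pH = runif(1, 4, 11),
    dic = runif(1, 0.1e-3, 50e-3),
    ca = runif(1, 0, 5e-3), na = runif(1, 0, 30e-3),
    k = runif(1, 0, 2e-3), cl = runif(1, 0, 20e-3),
    so4 = runif(1, 0, 3e-3), f = runif(1, 0, 1e-3),
    sio2 = runif(1, 0, 3e-3)
  )
}

# independent alkalinity oracle: the carbonate alkalinity at a given pH,
# written out from first principles (alpha fractions + water self-ionisation)
# without going through speciate()/solve_ph()
alkalinity_oracle <- function(pH, dic, temperature_C, I) {
  TK <- temperature_C + 273.15
  K1 <- 10^(-356.3094 - 0.06091964 * TK + 21834.37 / TK +
              126.8339 * log10(TK) - 1684915 / TK^2)
  K2 <- 10^(-107.8871 - 0.03252849 * TK + 5151.79 / TK +
              38.92561 * log10(TK) - 563713.9 / TK^2)
  Kw <- exp(148.9802 - 13847.26 / TK - 23.6521 * log(TK))
  eps <- 87.740 - 0.40008 * temperature_C + 9.398e-4 * temperature_C^2 -
    1.410e-6 * temperature_C^3
  A <- 1.824829238e6 * (eps * TK)^(-1.5)
  gam <- function(z) 10^(-A * z^2 * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I))
  aH <- 10^(-pH)
  r1 <- K1 / (gam(1) * aH)
  r2 <- K2 * gam(1) / (gam(2) * aH)
  a0 <- 1 / (1 + r1 + r1 * r2)
  dic * (a0 * r1 + 2 * a0 * r1 * r2) + Kw / aH / gam(1) - aH / gam(1)
}
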