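# Carbonate-system speciation at fixed pH is closed-form: at proton activity
# aH the molal concentration ratios are
#   [HCO3-]/[CO2(aq)] = K1 / (gamma1 * aH)        (gamma0 = 1 for CO2(aq))
#   [CO3--]/[HCO3-]   = K2 * gamma1 / (gamma2 * aH)
# giving the usual alpha fractions of DIC.

.alpha_fractions <- function(aH, K1, K2, g1, g2) {
  r1 <- K1 / (g1 * aH)
  r2 <- K2 * g1 / (g2 * aH)
  a0 <- 1 / (1 + r1 + r1 * r2)
  c(co2 = a0, hco3 = a0 * r1, co3 = a0 * r1 * r2)
}

#' Speciate the carbonate system of a water sample
#'
#' Partitions the sample's DIC among CO2(aq), HCO3- and CO3-- at the sample's
#' pH using activity-corrected equilibrium constants (closed-form alpha
#' fractions), and computes H+/OH-, ionic strength, and the carbonate
#' alkalinity \[HCO3-\] + 2\[CO3--\] + \[OH-\] - \[H+\].
#'
#' @param sample a [water_sample()] with `pH` set (required when `dic > 0`).
#' @param registry a [thermo_registry()].
#' @return An object of class `speciation_result`: molalities `co2_aq`,
#'   `hco3`, `co3`, `h`, `oh` (mol/kg), matching activities in `activities`,
#'   `ionic_strength` (mol/kg) and `carbonate_alkalinity` (eq/kg).
#' @export
#' @examples
#' s <- water_sample(70.7, 7.45, dic = 12.8, ca = 1.0, na = 17.3, k = 0.8,
#'                   cl = 5.1, so4 = 1.1, f = 0.5, units = "mM")
#' sp <- speciate(s)
#' sp$hco3 / s$dic    # bicarbonate fraction, ~0.9
speciate <- function(sample, registry = thermo_registry()) {
  stopifnot(inherits(sample, "water_sample"))
  if (is.na(sample$pH)) {
    stop("sample pH is unset; speciation requires pH (see solve_ph to ",
         "derive it from alkalinity)", call. = FALSE)
  }
  tc <- thermo_constants(sample$temperature_C, registry)
  I <- ionic_strength(sample)
  g1 <- activity_coefficient(1, I, sample$temperature_C)
  g2 <- activity_coefficient(2, I, sample$temperature_C)
  aH <- 10^(-sample$pH)
  alpha <- .alpha_fractions(aH, tc$K1, tc$K2, g1, g2)
  m <- sample$dic * alpha
  m_h <- aH / g1
  a_oh <- tc$Kw / aH
  m_oh <- a_oh / g1
  out <- list(
    co2_aq = unname(m["co2"]), hco3 = unname(m["hco3"]),
    co3 = unname(m["co3"]), h = m_h, oh = m_oh,
    activities = c(co2_aq = unname(m["co2"]),   # neutral species: gamma = 1
                   hco3 = unname(g1 * m["hco3"]),
                   co3 = unname(g2 * m["co3"]),
                   h = aH, oh = a_oh),
    ionic_strength = I,
    carbonate_alkalinity =
      unname(m["hco3"] + 2 * m["co3"]) + m_oh - m_h,
    constants = tc
  )
  class(out) <- "speciation_result"
  out
}

#' @export
print.speciation_result <- function(x, ...) {
  cat(sprintf("Carbonate speciation (I = %.4f mol/kg)\n", x$ionic_strength))
  cat(sprintf("  CO2(aq) %.3e  HCO3- %.3e  CO3-- %.3e mol/kg\n",
              x$co2_aq, x$hco3, x$co3))
  cat(sprintf("  carbonate alkalinity %.4e eq/kg\n", x$carbonate_alkalinity))
  invisible(x)
}

# alkalinity (eq/kg) as a function of pH at fixed dic, T, I -- strictly
# increasing in pH, which guarantees a unique root for solve_ph
.alkalinity_at_ph <- function(pH, dic, tc, g1, g2) {
  aH <- 10^(-pH)
  alpha <- .alpha_fractions(aH, tc$K1, tc$K2, g1, g2)
  unname(dic * (alpha["hco3"] + 2 * alpha["co3"])) +
    tc$Kw / aH / g1 - aH / g1
}

#' Solve for the pH that reproduces a carbonate alkalinity
#'
#' Finds the unique pH in \[0, 14\] at which a water of the given DIC,
#' temperature and ionic strength has the given carbonate alkalinity.  The
#' alkalinity is strictly increasing in pH at fixed DIC, so a bracketed root
#' solve is used (absolute residual tolerance 1e-12 eq/kg).  This is the
#' workhorse of the constant-alkalinity degassing model: CO2 loss lowers DIC
#' without changing alkalinity, so the pH must rise.
#'
#' @param carbonate_alkalinity target carbonate alkalinity, eq/kg.
#' @param dic total dissolved inorganic carbon, mol/kg; must be > 0.
#' @param temperature_C temperature, degrees Celsius.
#' @param ionic_strength ionic strength, mol/kg (default 0).
#' @param registry a [thermo_registry()].
#' @return pH (scalar).
#' @export
#' @examples
#' s <- water_sample(81.2, 6.70, dic = 15.7e-3)
#' alk <- speciate(s)$carbonate_alkalinity
#' solve_ph(alk, s$dic, 81.2)        # recovers 6.70
#' solve_ph(alk, 0.8 * s$dic, 81.2)  # less DIC, same alkalinity -> higher pH
solve_ph <- function(carbonate_alkalinity, dic, temperature_C,
                     ionic_strength = 0, registry = thermo_registry()) {
  stopifnot(is.numeric(carbonate_alkalinity), length(carbonate_alkalinity) == 1L,
            is.numeric(dic), length(dic) == 1L)
  if (!is.finite(dic) || dic <= 0) {
    stop("dic must be > 0", call. = FALSE)
  }
  tc <- thermo_constants(temperature_C, registry)
  g1 <- activity_coefficient(1, ionic_strength, temperature_C)
  g2 <- activity_coefficient(2, ionic_strength, temperature_C)
  resid <- function(pH) {
    .alkalinity_at_ph(pH, dic, tc, g1, g2) - carbonate_alkalinity
  }
  lo <- resid(0); hi <- resid(14)
  if (lo > 0 || hi < 0) {
    stop(sprintf(paste0("alkalinity %.6g eq/kg is not attainable at dic = %.6g",
                        " mol/kg, T = %.6g degC; attainable range is",
                        " [%.6g, %.6g] eq/kg"),
                 carbonate_alkalinity, dic, temperature_C,
                 carbonate_alkalinity + lo, carbonate_alkalinity + hi),
         call. = FALSE)
  }
  root <- stats::uniroot(resid, interval = c(0, 14), tol = 1e-13,
                         f.lower = lo, f.upper = hi, maxiter = 1000L)
  root$root
}

#' Mineral saturation states
#'
#' Saturation ratio (Omega = ion activity product / solubility product) and
#' saturation index (SI = log10 Omega) for calcite and amorphous silica:
#' Omega_calcite = a(Ca++) a(CO3--) / Ksp; Omega_amSiO2 = m(SiO2(aq)) / csat,
#' treating dissolved silica as a neutral species with unit activity
#' coefficient.  Omega > 1 means precipitation is thermodynamically favoured.
#'
#' @param sample a [water_sample()].
#' @param speciation a [speciate()] result for `sample` (computed if omitted).
#' @return An object of class `saturation_state` with `omega_calcite`,
#'   `si_calcite`, `omega_amSiO2`, `si_amSiO2`.
#' @export
#' @examples
#' s <- water_sample(81.2, 6.70, dic = 15.7, ca = 1.3, na = 16.8, k = 0.7,
#'                   cl = 5.0, so4 = 1.1, f = 0.5, sio2 = 1.49, units = "mM")
#' saturation(s)   # calcite supersaturated, amorphous silica undersaturated
saturation <- function(sample, speciation = speciate(sample)) {
  stopifnot(inherits(sample, "water_sample"),
            inherits(speciation, "speciation_result"))
  tc <- speciation$constants
  g2 <- activity_coefficient(2, speciation$ionic_strength,
                             sample$temperature_C)
  a_ca <- g2 * sample$ca
  omega_cc <- a_ca * speciation$activities[["co3"]] / tc$Ksp_calcite
  omega_si <- sample$sio2 / tc$csat_amSiO2
  out <- list(
    omega_calcite = omega_cc,
    si_calcite    = log10(omega_cc),
    omega_amSiO2  = omega_si,
    si_amSiO2     = log10(omega_si)
  )
  class(out) <- "saturation_state"
  out
}

#' @export
print.saturation_state <- function(x, ...) {
  cat(sprintf("Omega(calcite) = %.3g (SI %.2f);  Omega(am. SiO2) = %.3g (SI %.2f)\n",
              x$omega_calcite, x$si_calcite, x$omega_amSiO2, x$si_amSiO2))
  invisible(x)
}
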