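#' Thermodynamic correlation registry
#'
#' The equilibrium constants and solubilities used throughout the package are
#' evaluated from empirical temperature correlations.  The registry maps each
#' constant to a named correlation so the thermodynamic basis is explicit and
#' swappable.  Available correlations:
#'
#' * `k1`, `k2`, `ksp_calcite`: `"plummer_busenberg_1982"` — the analytic
#'   expressions of Plummer & Busenberg (1982, Geochim. Cosmochim. Acta 46,
#'   1011-1040) for the carbonic acid dissociation constants and the calcite
#'   solubility product (25 °C values: pK1 = 6.352, pK2 = 10.329,
#'   log10 Ksp = -8.480).
#' * `kw`: `"millero_1995"` — pure-water ion product,
#'   ln Kw = 148.9802 - 13847.26/T - 23.6521 ln T (pKw = 13.995 at 25 °C).
#' * `csat_amsio2`: `"fournier_1977"` — amorphous silica solubility,
#'   log10 C(mg/kg SiO2) = 4.52 - 731/T(K), converted to mol/kg with a molar
#'   mass of 60.0843 g/mol.
#'
#' @param k1,k2,kw,ksp_calcite,csat_amsio2 correlation names (character).
#' @return An object of class `thermo_registry`: a named list of correlation
#'   functions of absolute temperature (K).
#' @seealso [thermo_constants()], [read_thermo_registry()]
#' @export
#' @examples
#' reg <- thermo_registry()
#' thermo_constants(25, registry = reg)
thermo_registry <- function(k1 = "plummer_busenberg_1982",
                            k2 = "plummer_busenberg_1982",
                            kw = "millero_1995",
                            ksp_calcite = "plummer_busenberg_1982",
                            csat_amsio2 = "fournier_1977") {
  pick <- function(constant, name) {
    avail <- .thermo_correlations[[constant]]
    if (!name %in% names(avail)) {
      stop(sprintf("unknown correlation '%s' for constant '%s'; available: %s",
                   name, constant, paste(names(avail), collapse = ", ")),
           call. = FALSE)
    }
    avail[[name]]
  }
  reg <- list(
    k1          = pick("k1", k1),
    k2          = pick("k2", k2),
    kw          = pick("kw", kw),
    ksp_calcite = pick("ksp_calcite", ksp_calcite),
    csat_amsio2 = pick("csat_amsio2", csat_amsio2)
  )
  attr(reg, "names_chosen") <- c(k1 = k1, k2 = k2, kw = kw,
                                 ksp_calcite = ksp_calcite,
                                 csat_amsio2 = csat_amsio2)
  class(reg) <- "thermo_registry"
  reg
}

# molar mass of SiO2, g/mol
.M_SIO2 <- 60.0843

# Correlation library; every function takes absolute temperature (K) and
# returns the constant on the activity (molal) scale.
.thermo_correlations <- list(
  k1 = list(
    plummer_busenberg_1982 = function(TK) {
      10^(-356.3094 - 0.06091964 * TK + 21834.37 / TK +
            126.8339 * log10(TK) - 1684915 / TK^2)
    }
  ),
  k2 = list(
    plummer_busenberg_1982 = function(TK) {
      10^(-107.8871 - 0.03252849 * TK + 5151.79 / TK +
            38.92561 * log10(TK) - 563713.9 / TK^2)
    }
  ),
  kw = list(
    millero_1995 = function(TK) {
      exp(148.9802 - 13847.26 / TK - 23.6521 * log(TK))
    }
  ),
  ksp_calcite = list(
    plummer_busenberg_1982 = function(TK) {
      10^(-171.9065 - 0.077993 * TK + 2839.319 / TK + 71.595 * log10(TK))
    }
  ),
  csat_amsio2 = list(
    fournier_1977 = function(TK) {
      10^(4.52 - 731 / TK) / .M_SIO2 * 1e-3   # mg/kg -> mol/kg
    }
  )
)

#' Evaluate the thermodynamic constants at a temperature
#'
#' @param temperature_C temperature in degrees Celsius, in \[0, 100\].
#' @param registry a [thermo_registry()] selecting the correlations.
#' @return An object of class `thermo_constants` with elements `K1`, `K2`
#'   (carbonic acid dissociation constants), `Kw` (water ion product),
#'   `Ksp_calcite` (calcite solubility product) — all on the activity scale —
#'   and `csat_amSiO2` (amorphous silica solubility, mol/kg water), plus the
#'   temperature they were evaluated at.
#' @export
#' @examples
#' tc <- thermo_constants(81.2)
#' -log10(tc$K1)   # pK1 at the spring source temperature
thermo_constants <- function(temperature_C, registry = thermo_registry()) {
  stopifnot(is.numeric(temperature_C), length(temperature_C) == 1L,
            is.finite(temperature_C))
  if (temperature_C < 0 || temperature_C > 100) {
    stop("temperature_C must be in [0, 100] (liquid water at 1 atm), got ",
         temperature_C, call. = FALSE)
  }
  TK <- temperature_C + 273.15
  out <- list(
    temperature_C = temperature_C,
    K1            = registry$k1(TK),
    K2            = registry$k2(TK),
    Kw            = registry$kw(TK),
    Ksp_calcite   = registry$ksp_calcite(TK),
    csat_amSiO2   = registry$csat_amsio2(TK)
  )
  class(out) <- "thermo_constants"
  out
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat(sprintf("Thermodynamic constants at %.1f degC\n", x$temperature_C))
  cat(sprintf("  pK1 = %.3f  pK2 = %.3f  pKw = %.3f\n",
              -log10(x$K1), -log10(x$K2), -log10(x$Kw)))
  cat(sprintf("  log10 Ksp(calcite) = %.3f\n", log10(x$Ksp_calcite)))
  cat(sprintf("  csat(am. SiO2) = %.3e mol/kg\n", x$csat_amSiO2))
  invisible(x)
}

#' Debye-Hueckel limiting slope A
#'
#' Computed from the Malmberg & Maryott (1956) dielectric constant of water
#' with unit solvent density; A = 0.511 at 25 °C.
#'
#' @param temperature_C temperature, degrees Celsius.
#' @return A in (kg/mol)^(1/2).
#' @keywords internal
debye_huckel_A <- function(temperature_C) {
  eps <- 87.740 - 0.40008 * temperature_C + 9.398e-4 * temperature_C^2 -
    1.410e-6 * temperature_C^3
  TK <- temperature_C + 273.15
  1.824829238e6 * (eps * TK)^(-1.5)
}

#' Single-ion activity coefficient (Davies equation)
#'
#' log10 gamma = -A z^2 (sqrt(I)/(1 + sqrt(I)) - 0.3 I), with the
#' temperature-dependent Debye-Hueckel slope A.  Neutral species (charge 0)
#' are assigned gamma = 1.  The Davies form is adequate for the dilute
#' (I ~ 0.025 mol/kg) waters this package targets; it degrades above
#' I ~ 0.5 mol/kg, which the trajectory models flag.
#'
#' @param charge integer ionic charge (sign is immaterial).
#' @param ionic_strength ionic strength, mol/kg water; must be >= 0.
#' @param temperature_C temperature, degrees Celsius.
#' @return activity coefficient (unitless).
#' @export
#' @examples
#' activity_coefficient(2, 0.025, 25)   # ~0.54
activity_coefficient <- function(charge, ionic_strength, temperature_C = 25) {
  if (any(ionic_strength < 0)) {
    stop("ionic_strength must be >= 0", call. = FALSE)
  }
  A <- debye_huckel_A(temperature_C)
  sI <- sqrt(ionic_strength)
  10^(-A * charge^2 * (sI / (1 + sI) - 0.3 * ionic_strength))
}
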