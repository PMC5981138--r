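#' Construct a water sample
#'
#' A single water analysis: temperature, pH (NBS scale; the proton activity is
#' taken as 10^-pH), total dissolved inorganic carbon, major ion totals,
#' dissolved silica, and optionally the carbon isotope composition of the DIC.
#' All concentrations are molal (mol per kg of water); `units = "mM"` converts
#' from mmol/L assuming a solution density of 1.0 kg/L (dilute waters).
#'
#' @param temperature_C temperature, degrees Celsius, in \[0, 100\].
#' @param pH pH on the NBS scale, in \[0, 14\]; may be `NA` when only
#'   composition is known.
#' @param dic total dissolved inorganic carbon.
#' @param ca,na,k,cl,so4,f major ion totals (calcium, sodium, potassium,
#'   chloride, sulfate, fluoride).
#' @param sio2 total dissolved silica as SiO2.
#' @param delta13c_dic carbon isotope composition of the DIC, per mil VPDB
#'   (optional).
#' @param site_id optional sample label carried through reports.
#' @param units `"mol_kg"` (default) or `"mM"`.
#' @return An object of class `water_sample`.
#' @export
#' @examples
#' # spring source water
#' src <- water_sample(81.2, 6.70, dic = 15.7, ca = 1.3, na = 16.8, k = 0.7,
#'                     cl = 5.0, so4 = 1.1, f = 0.5, sio2 = 1.49,
#'                     delta13c_dic = -4.8, units = "mM")
#' src
water_sample <- function(temperature_C, pH = NA_real_, dic = 0,
                         ca = 0, na = 0, k = 0, cl = 0, so4 = 0, f = 0,
                         sio2 = 0, delta13c_dic = NA_real_,
                         site_id = NA_character_,
                         units = c("mol_kg", "mM")) {
  units <- match.arg(units)
  conc <- c(dic = dic, ca = ca, na = na, k = k, cl = cl, so4 = so4,
            f = f, sio2 = sio2)
  if (units == "mM") conc <- conc * 1e-3
  if (!is.finite(temperature_C) || temperature_C < 0 || temperature_C > 100) {
    stop("temperature_C must be finite and in [0, 100]", call. = FALSE)
  }
  if (!is.na(pH) && (pH < 0 || pH > 14)) {
    stop("pH must be in [0, 14] (or NA)", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    bad <- names(conc)[!is.finite(conc) | conc < 0]
    stop("concentrations must be finite and >= 0; offending field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- c(list(temperature_C = temperature_C, pH = as.numeric(pH)),
           as.list(conc),
           list(delta13c_dic = as.numeric(delta13c_dic),
                site_id = site_id))
  class(out) <- "water_sample"
  out
}

#' @export
print.water_sample <- function(x, ...) {
  id <- if (is.na(x$site_id)) "" else paste0(" [", x$site_id, "]")
  cat(sprintf("Water sample%s: %.1f degC, pH %s\n", id, x$temperature_C,
              ifelse(is.na(x$pH), "NA", sprintf("%.2f", x$pH))))
  cat(sprintf("  DIC %.3g mM, Ca %.3g, Na %.3g, K %.3g, Cl %.3g, SO4 %.3g, F %.3g, SiO2 %.3g mM\n",
              x$dic * 1e3, x$ca * 1e3, x$na * 1e3, x$k * 1e3, x$cl * 1e3,
              x$so4 * 1e3, x$f * 1e3, x$sio2 * 1e3))
  if (!is.na(x$delta13c_dic)) {
    cat(sprintf("  d13C(DIC) %.2f permil VPDB\n", x$delta13c_dic))
  }
  invisible(x)
}

#' Ionic strength from analytical totals
#'
#' I = 1/2 sum(m_i z_i^2) over the major ions, treating each as fully
#' dissociated at its analytical total.  DIC is counted once as a monovalent
#' contribution (these waters are bicarbonate-dominated); the ionic strength
#' is computed from the totals and not iterated with speciation, a
#' second-order simplification at I ~ 0.025 mol/kg.
#'
#' @param sample a [water_sample()].
#' @return ionic strength, mol/kg water.
#' @export
ionic_strength <- function(sample) {
  stopifnot(inherits(sample, "water_sample"))
  0.5 * (sample$na + sample$k + 4 * sample$ca +
           sample$cl + sample$f + 4 * sample$so4 + sample$dic)
}

#' Charge-balance diagnostic
#'
#' Reports the charge imbalance of the analytical totals (cation minus anion
#' equivalents, carbonate alkalinity counted on the anion side).  The
#' imbalance is diagnostic only; analyses are never adjusted.
#'
#' @param sample a [water_sample()] with pH set.
#' @param speciation optional precomputed [speciate()] result.
#' @return list with `cation_eq`, `anion_eq`, `imbalance_eq` (eq/kg) and
#'   `imbalance_percent` (relative to the mean of the two sums).
#' @export
charge_balance <- function(sample, speciation = speciate(sample)) {
  cat_eq <- sample$na + sample$k + 2 * sample$ca + speciation$h
  an_eq <- sample$cl + sample$f + 2 * sample$so4 +
    speciation$hco3 + 2 * speciation$co3 + speciation$oh
  imb <- cat_eq - an_eq
  list(cation_eq = cat_eq, anion_eq = an_eq, imbalance_eq = imb,
       imbalance_percent = 100 * imb / ((cat_eq + an_eq) / 2))
}

# internal: derive a modified copy of a sample
.update_sample <- function(sample, ...) {
  mods <- list(...)
  for (nm in names(mods)) sample[[nm]] <- mods[[nm]]
  sample
}
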