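# Seeded generators of synthetic datasets with the statistical structure the
# analysis chain assumes: a downstream spring transect whose chemistry
# evolves by constant-ish-alkalinity CO2 degassing, and a stirred-container
# degassing experiment time series whose first few samples sit off the
# Rayleigh line (incomplete mixing).  With zero noise every generated dataset
# is an exact fixed point of the estimators, which is what makes them useful
# as end-to-end oracles.

# run code with a temporary RNG seed, restoring global state afterwards
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Specification of a synthetic spring transect
#'
#' Defaults reproduce the studied spring: a 4-site downstream transect whose
#' source is the packaged Site 1 water (81.2 °C, pH 6.70, DIC 15.7 mM,
#' delta13C_DIC -4.8 per mil) evolving to the Site 4 end-member (70.7 °C, pH
#' 7.45, DIC 12.8 mM), with the stream fractionation epsilon = -7.80 per mil
#' and measurement noise at the stated analytical precision (DIC +/-0.3 mM,
#' delta13C +/-0.5 per mil).
#'
#' @param n_sites number of sites (>= 2; default 4).
#' @param source source [water_sample()] (default: packaged Site 1).
#' @param end end-member [water_sample()] (default: packaged Site 4).
#' @param epsilon per-mil fractionation for the Rayleigh delta13C profile
#'   (default -7.80).
#' @param source_delta13c delta13C of the source DIC, per mil (default -4.8).
#' @param noise_sd list of Gaussian noise standard deviations applied to the
#'   reported values: `dic_mM` (0.3), `d13c` (0.5), `temperature_C` (0),
#'   `ph` (0), `ions_mM` (0).
#' @param seed integer seed fixing the output bitwise (default 1).
#' @return list of class `transect_spec`.
#' @export
transect_spec <- function(n_sites = 4,
                          source = lhc_site_waters()[[1]],
                          end = lhc_site_waters()[[4]],
                          epsilon = -7.80,
                          source_delta13c = -4.8,
                          noise_sd = list(),
                          seed = 1L) {
  stopifnot(n_sites >= 2, inherits(source, "water_sample"),
            inherits(end, "water_sample"))
  ns <- utils::modifyList(list(dic_mM = 0.3, d13c = 0.5, temperature_C = 0,
                               ph = 0, ions_mM = 0), noise_sd)
  if (any(unlist(ns) < 0)) stop("noise sd must be >= 0", call. = FALSE)
  structure(list(n_sites = as.integer(n_sites), source = source, end = end,
                 epsilon = epsilon, source_delta13c = source_delta13c,
                 noise_sd = ns, seed = seed),
            class = "transect_spec")
}

#' Generate a synthetic spring transect
#'
#' Site chemistry is interpolated linearly in site index between the source
#' and end-member samples: temperature, conservative ions, silica and DIC.
#' delta13C_DIC follows the Rayleigh law at each site's fraction of source
#' DIC remaining.  pH is solved from a carbonate-alkalinity profile
#' interpolated between the alkalinities implied by the two endpoint
#' (pH, DIC, T) pairs — alkalinity is nearly conserved along the flow path
#' (CO2 degassing carries none), and anchoring both ends to the printed
#' analyses reproduces the endpoint pH values exactly.  Gaussian measurement
#' noise is then added to the reported columns; the pH/alkalinity structure
#' is generated from the noise-free truth.
#'
#' @param spec a [transect_spec()].
#' @return A data.frame in the water-chemistry CSV schema (`site_id`,
#'   `temperature_C`, `pH`, `dic_mM`, ..., `d13c_dic_permil`), one row per
#'   site, accepted by [read_water_csv()]/[water_samples_from_df()].
#' @export
#' @examples
#' tr <- generate_transect(transect_spec(noise_sd = list(dic_mM = 0, d13c = 0)))
#' tr[, c("site_id", "temperature_C", "pH", "dic_mM", "d13c_dic_permil")]
generate_transect <- function(spec) {
  stopifnot(inherits(spec, "transect_spec"))
  src <- spec$source; end <- spec$end
  n <- spec$n_sites
  w <- (seq_len(n) - 1) / (n - 1)
  lerp <- function(a, b) a + w * (b - a)
  temperature <- lerp(src$temperature_C, end$temperature_C)
  dic <- lerp(src$dic, end$dic)
  ions <- lapply(c(ca = "ca", na = "na", k = "k", cl = "cl", so4 = "so4",
                   f = "f", sio2 = "sio2"),
                 function(fld) lerp(src[[fld]], end[[fld]]))
  alk <- lerp(speciate(src)$carbonate_alkalinity,
              speciate(end)$carbonate_alkalinity)
  pH <- numeric(n)
  for (i in seq_len(n)) {
    s_i <- water_sample(temperature[i], dic = dic[i], ca = ions$ca[i],
                        na = ions$na[i], k = ions$k[i], cl = ions$cl[i],
                        so4 = ions$so4[i], f = ions$f[i], sio2 = ions$sio2[i])
    pH[i] <- solve_ph(alk[i], dic[i], temperature[i], ionic_strength(s_i))
  }
  d13c <- rayleigh_delta(spec$source_delta13c, spec$epsilon, dic / dic[1])
  ns <- spec$noise_sd
  .with_seed(spec$seed, {
    out <- data.frame(
      site_id = paste0("S", seq_len(n)),
      temperature_C = temperature + stats::rnorm(n, 0, ns$temperature_C),
      pH = pH + stats::rnorm(n, 0, ns$ph),
      dic_mM = pmax(dic * 1e3 + stats::rnorm(n, 0, ns$dic_mM), 0),
      ca_mM = pmax(ions$ca * 1e3 + stats::rnorm(n, 0, ns$ions_mM), 0),
      na_mM = pmax(ions$na * 1e3 + stats::rnorm(n, 0, ns$ions_mM), 0),
      k_mM = pmax(ions$k * 1e3 + stats::rnorm(n, 0, ns$ions_mM), 0),
      cl_mM = pmax(ions$cl * 1e3 + stats::rnorm(n, 0, ns$ions_mM), 0),
      so4_mM = pmax(ions$so4 * 1e3 + stats::rnorm(n, 0, ns$ions_mM), 0),
      f_mM = pmax(ions$f * 1e3 + stats::rnorm(n, 0, ns$ions_mM), 0),
      sio2_mM = pmax(ions$sio2 * 1e3 + stats::rnorm(n, 0, ns$ions_mM), 0),
      d13c_dic_permil = d13c + stats::rnorm(n, 0, ns$d13c)
    )
    out
  })
}

#' Specification of a synthetic degassing experiment
#'
#' Defaults reproduce the on-site stirred-container experiment: a 15-minute
#' run sampled at 30-s intervals (31 points), DIC declining from 14.7 to
#' 13.5 mM, fractionation epsilon = -8.67 per mil, first measured delta13C
#' -5.2 per mil, and the first 6 samples perturbed off the Rayleigh line by
#' incomplete mixing of the stirred vessel.  The perturbation is toward
#' depletion (the early samples under-read the vessel's enriching residue)
#' with amplitude decaying linearly to zero after `n_unmixed` points; the
#' default amplitude of 1.2 per mil places the underlying Rayleigh intercept
#' at -4.0 per mil, so the noise-free series ends near -3.3 per mil while a
#' fit masking the unmixed points recovers epsilon exactly.
#'
#' @param duration_s experiment duration, seconds (default 900).
#' @param interval_s sampling interval, seconds (default 30).
#' @param dic_initial_mM,dic_final_mM initial/final DIC, mM (14.7, 13.5).
#' @param epsilon per-mil fractionation (default -8.67).
#' @param delta_initial first measured delta13C, per mil (default -5.2).
#' @param n_unmixed number of initial incompletely mixed samples (default 6).
#' @param unmixed_amplitude per-mil depletion of the first sample relative to
#'   the Rayleigh line (default 1.2), decaying linearly to zero at sample
#'   `n_unmixed + 1`.
#' @param dic_decline `"exponential"` (default) or `"linear"` decline of DIC
#'   in time; endpoints are exact either way.
#' @param noise_sd list with `dic_mM` (default 0.3) and `d13c` (default 0.5)
#'   Gaussian measurement noise.
#' @param seed integer seed (default 1).
#' @return list of class `degassing_experiment_spec`.
#' @export
degassing_experiment_spec <- function(duration_s = 900, interval_s = 30,
                                      dic_initial_mM = 14.7,
                                      dic_final_mM = 13.5,
                                      epsilon = -8.67,
                                      delta_initial = -5.2,
                                      n_unmixed = 6,
                                      unmixed_amplitude = 1.2,
                                      dic_decline = c("exponential", "linear"),
                                      noise_sd = list(),
                                      seed = 1L) {
  dic_decline <- match.arg(dic_decline)
  n_points <- floor(duration_s / interval_s) + 1L
  if (n_points < 8L) {
    stop("duration/interval must yield at least 8 sampling points",
         call. = FALSE)
  }
  if (n_unmixed >= n_points) {
    stop("n_unmixed must be smaller than the number of points", call. = FALSE)
  }
  stopifnot(dic_initial_mM > 0, dic_final_mM > 0,
            dic_final_mM <= dic_initial_mM)
  ns <- utils::modifyList(list(dic_mM = 0.3, d13c = 0.5), noise_sd)
  if (any(unlist(ns) < 0)) stop("noise sd must be >= 0", call. = FALSE)
  structure(list(duration_s = duration_s, interval_s = interval_s,
                 dic_initial_mM = dic_initial_mM, dic_final_mM = dic_final_mM,
                 epsilon = epsilon, delta_initial = delta_initial,
                 n_unmixed = as.integer(n_unmixed),
                 unmixed_amplitude = unmixed_amplitude,
                 dic_decline = dic_decline, noise_sd = ns, seed = seed),
            class = "degassing_experiment_spec")
}

#' Generate a synthetic degassing-experiment time series
#'
#' @param spec a [degassing_experiment_spec()].
#' @return A data.frame with columns `time_s`, `dic_mM`, `d13c_permil`,
#'   accepted by [read_series_csv()].
#' @export
#' @examples
#' ex <- generate_degassing_experiment(
#'   degassing_experiment_spec(noise_sd = list(dic_mM = 0, d13c = 0)))
#' fit_epsilon(dic_fraction_remaining(ex$dic_mM), ex$d13c_permil,
#'             exclude = 1:6)   # recovers -8.67
generate_degassing_experiment <- function(spec) {
  stopifnot(inherits(spec, "degassing_experiment_spec"))
  t <- seq(0, spec$duration_s, by = spec$interval_s)
  u <- t / spec$duration_s
  dic <- if (spec$dic_decline == "exponential") {
    spec$dic_initial_mM * (spec$dic_final_mM / spec$dic_initial_mM)^u
  } else {
    spec$dic_initial_mM + u * (spec$dic_final_mM - spec$dic_initial_mM)
  }
  f <- dic / dic[1]
  # underlying Rayleigh line: intercept offset so the perturbed first sample
  # reads delta_initial
  delta_line <- rayleigh_delta(spec$delta_initial + spec$unmixed_amplitude,
                               spec$epsilon, f)
  offset <- numeric(length(t))
  if (spec$n_unmixed > 0) {
    i <- seq_len(spec$n_unmixed)
    offset[i] <- -spec$unmixed_amplitude * (1 - (i - 1) / spec$n_unmixed)
  }
  d13c <- delta_line + offset
  n <- length(t)
  .with_seed(spec$seed, {
    data.frame(
      time_s = t,
      dic_mM = pmax(dic + stats::rnorm(n, 0, spec$noise_sd$dic_mM), 0),
      d13c_permil = d13c + stats::rnorm(n, 0, spec$noise_sd$d13c)
    )
  })
}
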