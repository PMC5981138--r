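# Process trajectory models: CO2 degassing at constant alkalinity,
# evaporation at fixed temperature, and cooling at fixed composition.  These
# are saturation-potential curves -- Omega is tracked without precipitating
# mass back out of solution -- mirroring how reaction-path modelling is used
# to ask whether a process *can* drive a mineral to supersaturation.

.trajectory_row <- function(extent, sample, speciation, sat, delta13c) {
  data.frame(
    extent = extent,
    temperature_C = sample$temperature_C,
    pH = sample$pH,
    dic = sample$dic,
    carbonate_alkalinity = speciation$carbonate_alkalinity,
    ionic_strength = speciation$ionic_strength,
    omega_calcite = sat$omega_calcite,
    si_calcite = sat$si_calcite,
    omega_amSiO2 = sat$omega_amSiO2,
    si_amSiO2 = sat$si_amSiO2,
    delta13c_dic = delta13c,
    davies_ok = speciation$ionic_strength <= 0.5
  )
}

.new_trajectory <- function(process, points, sample, config) {
  structure(list(process = process, points = points,
                 sample = sample, config = config),
            class = "process_trajectory")
}

#' @export
print.process_trajectory <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf("%s trajectory: %d points, extent %.4g -> %.4g\n",
              x$process, n, x$points$extent[1], x$points$extent[n]))
  cat(sprintf("  Omega(calcite) %.3g -> %.3g;  Omega(am. SiO2) %.3g -> %.3g\n",
              x$points$omega_calcite[1], x$points$omega_calcite[n],
              x$points$omega_amSiO2[1], x$points$omega_amSiO2[n]))
  invisible(x)
}

#' @export
as.data.frame.process_trajectory <- function(x, ...) x$points

#' CO2 degassing trajectory at constant alkalinity
#'
#' Models progressive CO2 loss from a water: at each step the DIC is reduced,
#' the carbonate alkalinity is held at its initial value (degassing removes
#' CO2, which carries no alkalinity), the pH is re-solved, and the saturation
#' states recomputed.  The carbon isotope composition of the residual DIC
#' follows the Rayleigh law delta = delta0 + epsilon ln(f) with f the
#' fraction of DIC remaining.  Degassing raises pH and the calcite saturation
#' state while leaving silica saturation untouched.
#'
#' @param sample a fully specified [water_sample()] (pH and `delta13c_dic`
#'   set; the isotope column is `NA` if `delta13c_dic` is missing).
#' @param max_dic_removed_fraction largest fraction of DIC removed, in
#'   \[0, 1).
#' @param n_steps number of increments (the trajectory has `n_steps + 1`
#'   points; default 200).
#' @param epsilon_co2_dic fractionation factor between the escaping CO2 and
#'   the residual DIC, per mil (negative: the gas is depleted, the residue
#'   enriched).
#' @param registry a [thermo_registry()].
#' @return A `process_trajectory`; `$points` has one row per extent with pH,
#'   DIC, alkalinity, saturation states, and delta13C of the DIC.
#' @export
#' @examples
#' src <- water_sample(81.2, 6.70, dic = 15.7, ca = 1.3, na = 16.8, k = 0.7,
#'                     cl = 5.0, so4 = 1.1, f = 0.5, sio2 = 1.49,
#'                     delta13c_dic = -4.8, units = "mM")
#' tr <- degassing_trajectory(src, max_dic_removed_fraction = 0.4,
#'                            n_steps = 50, epsilon_co2_dic = -7.80)
#' tr
degassing_trajectory <- function(sample, max_dic_removed_fraction = 0.5,
                                 n_steps = 200, epsilon_co2_dic = -8.67,
                                 registry = thermo_registry()) {
  stopifnot(inherits(sample, "water_sample"), !is.na(sample$pH),
            sample$dic > 0,
            max_dic_removed_fraction >= 0, max_dic_removed_fraction < 1)
  removed <- unique(seq(0, max_dic_removed_fraction, length.out = n_steps + 1))
  sp0 <- speciate(sample, registry)
  alk0 <- sp0$carbonate_alkalinity
  delta0 <- sample$delta13c_dic
  rows <- vector("list", length(removed))
  for (i in seq_along(removed)) {
    r <- removed[i]
    if (r == 0) {
      s_i <- sample
      sp_i <- sp0
    } else {
      s_i <- .update_sample(sample, dic = sample$dic * (1 - r))
      pH_i <- tryCatch(
        solve_ph(alk0, s_i$dic, s_i$temperature_C, ionic_strength(s_i),
                 registry),
        error = function(e) {
          warning("degassing trajectory truncated at removed fraction ",
                  signif(r, 4), ": ", conditionMessage(e), call. = FALSE)
          NA_real_
        })
      if (is.na(pH_i)) break
      s_i <- .update_sample(s_i, pH = pH_i)
      sp_i <- speciate(s_i, registry)
    }
    d_i <- if (is.na(delta0)) NA_real_ else
      rayleigh_delta(delta0, epsilon_co2_dic, 1 - r)
    rows[[i]] <- .trajectory_row(r, s_i, sp_i, saturation(s_i, sp_i), d_i)
  }
  points <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(points) <- NULL
  .new_trajectory("degassing", points, sample,
                  list(max_dic_removed_fraction = max_dic_removed_fraction,
                       n_steps = n_steps, epsilon_co2_dic = epsilon_co2_dic))
}

#' Evaporation trajectory at fixed temperature
#'
#' Conservative concentration: at evaporated fraction x every solute total
#' (ions, DIC, silica) and the carbonate alkalinity are multiplied by
#' 1/(1-x); temperature is held at the scenario value and the pH re-solved at
#' each step.  The system is closed to gas exchange (evaporation "alone");
#' because dissolved silica is neutral with unit activity coefficient,
#' Omega_amSiO2(x) = Omega_amSiO2(0)/(1-x) exactly.  Points with ionic
#' strength beyond the Davies validity limit (I > 0.5 mol/kg) are flagged in
#' the `davies_ok` column.
#'
#' @param sample a [water_sample()] with pH set.
#' @param temperature_C_scenario temperature at which the evaporating water
#'   is held (default: the sample's own temperature).  A cooler scenario
#'   models splash water that has cooled before evaporating; the x = 0 point
#'   is then the cooled (re-equilibrated) water.
#' @param max_evaporated_fraction largest evaporated fraction x, in \[0, 1).
#' @param n_steps number of increments (default 200).
#' @param registry a [thermo_registry()].
#' @return A `process_trajectory` with extent = evaporated fraction x.
#' @export
evaporation_trajectory <- function(sample,
                                   temperature_C_scenario = sample$temperature_C,
                                   max_evaporated_fraction = 0.95,
                                   n_steps = 200,
                                   registry = thermo_registry()) {
  stopifnot(inherits(sample, "water_sample"), !is.na(sample$pH),
            max_evaporated_fraction >= 0, max_evaporated_fraction < 1)
  xs <- unique(seq(0, max_evaporated_fraction, length.out = n_steps + 1))
  alk0 <- speciate(sample, registry)$carbonate_alkalinity
  rows <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    x <- xs[i]
    cf <- 1 / (1 - x)
    s_i <- .update_sample(sample,
                          temperature_C = temperature_C_scenario,
                          dic = sample$dic * cf, ca = sample$ca * cf,
                          na = sample$na * cf, k = sample$k * cf,
                          cl = sample$cl * cf, so4 = sample$so4 * cf,
                          f = sample$f * cf, sio2 = sample$sio2 * cf)
    pH_i <- solve_ph(alk0 * cf, s_i$dic, temperature_C_scenario,
                     ionic_strength(s_i), registry)
    s_i <- .update_sample(s_i, pH = pH_i)
    sp_i <- speciate(s_i, registry)
    rows[[i]] <- .trajectory_row(x, s_i, sp_i, saturation(s_i, sp_i),
                                 NA_real_)
  }
  points <- do.call(rbind, rows)
  rownames(points) <- NULL
  if (any(!points$davies_ok)) {
    warning("ionic strength exceeds Davies validity (I > 0.5 mol/kg) for ",
            sum(!points$davies_ok), " point(s); see the davies_ok column",
            call. = FALSE)
  }
  .new_trajectory("evaporation", points, sample,
                  list(temperature_C_scenario = temperature_C_scenario,
                       max_evaporated_fraction = max_evaporated_fraction,
                       n_steps = n_steps))
}

#' Cooling trajectory at fixed composition
#'
#' Lowers the temperature from `t_start_C` to `t_end_C` with all solute
#' totals fixed (closed system: DIC and carbonate alkalinity are conserved);
#' the equilibrium constants, activity coefficients and hence the pH and
#' saturation states are re-evaluated at each temperature.  Cooling raises
#' amorphous-silica saturation only through the temperature dependence of its
#' solubility.
#'
#' @param sample a [water_sample()] with pH set; its temperature is taken as
#'   the start unless `t_start_C` is given.
#' @param t_start_C,t_end_C start and end temperatures, degrees Celsius
#'   (`t_end_C < t_start_C`).
#' @param n_steps number of increments (default 100).
#' @param registry a [thermo_registry()].
#' @return A `process_trajectory` with extent = temperature (decreasing).
#' @export
cooling_trajectory <- function(sample, t_start_C = sample$temperature_C,
                               t_end_C = 25, n_steps = 100,
                               registry = thermo_registry()) {
  stopifnot(inherits(sample, "water_sample"), !is.na(sample$pH))
  if (t_end_C > t_start_C) {
    stop("t_end_C must not exceed t_start_C for a cooling trajectory",
         call. = FALSE)
  }
  temps <- unique(seq(t_start_C, t_end_C, length.out = n_steps + 1))
  s0 <- .update_sample(sample, temperature_C = t_start_C)
  alk0 <- speciate(s0, registry)$carbonate_alkalinity
  rows <- vector("list", length(temps))
  for (i in seq_along(temps)) {
    s_i <- .update_sample(sample, temperature_C = temps[i])
    pH_i <- solve_ph(alk0, s_i$dic, temps[i], ionic_strength(s_i), registry)
    s_i <- .update_sample(s_i, pH = pH_i)
    sp_i <- speciate(s_i, registry)
    rows[[i]] <- .trajectory_row(temps[i], s_i, sp_i, saturation(s_i, sp_i),
                                 NA_real_)
  }
  points <- do.call(rbind, rows)
  rownames(points) <- NULL
  .new_trajectory("cooling", points, sample,
                  list(t_start_C = t_start_C, t_end_C = t_end_C,
                       n_steps = n_steps))
}

#' First saturation-threshold crossing along a trajectory
#'
#' Linear interpolation between the bracketing grid points of the first
#' upward crossing of `omega >= threshold`, making the reported extent
#' insensitive to grid resolution.  If the trajectory starts at or above the
#' threshold the first extent is returned.
#'
#' @param trajectory a `process_trajectory`.
#' @param mineral `"calcite"` or `"amSiO2"`.
#' @param threshold saturation ratio threshold (default 1).
#' @return the extent of first crossing, or `NA` if never reached.
#' @export
first_crossing <- function(trajectory, mineral = c("calcite", "amSiO2"),
                           threshold = 1) {
  mineral <- match.arg(mineral)
  pts <- trajectory$points
  omega <- pts[[paste0("omega_", mineral)]]
  extent <- pts$extent
  if (omega[1] >= threshold) return(extent[1])
  above <- which(omega >= threshold)
  if (length(above) == 0L) return(NA_real_)
  i <- above[1]
  w <- (threshold - omega[i - 1]) / (omega[i] - omega[i - 1])
  extent[i - 1] + w * (extent[i] - extent[i - 1])
}

#' Staged growth scenario: degassing flow path, then splash evaporation
#'
#' Chains the two stages of the precipitate growth model: (1) CO2 degassing
#' at constant alkalinity along the flow path drives calcite towards and past
#' saturation; (2) the degassed end-member water splashes onto the emergent
#' structure, cools to the splash temperature and evaporates, driving
#' amorphous silica to saturation.  Each stage reports which minerals reach
#' Omega >= 1 and at what extent (interpolated).  A zero-extent stage models
#' no process and reports no crossings.
#'
#' @param source a fully specified [water_sample()].
#' @param flowpath_config list overriding `max_dic_removed_fraction` (0.5),
#'   `n_steps` (200), `epsilon_co2_dic` (-7.80).
#' @param splash_config list overriding `temperature_C` (25),
#'   `max_evaporated_fraction` (0.95), `n_steps` (200).
#' @param registry a [thermo_registry()].
#' @return An object of class `growth_scenario`: `stages` (named
#'   `process_trajectory` list) and `crossings` (per stage, per mineral
#'   extents of first Omega >= 1 crossing, `NA` if not reached).
#' @export
growth_scenario <- function(source, flowpath_config = list(),
                            splash_config = list(),
                            registry = thermo_registry()) {
  fp <- utils::modifyList(list(max_dic_removed_fraction = 0.5, n_steps = 200,
                               epsilon_co2_dic = -7.80), flowpath_config)
  sp <- utils::modifyList(list(temperature_C = 25,
                               max_evaporated_fraction = 0.95, n_steps = 200),
                          splash_config)
  stage1 <- degassing_trajectory(source, fp$max_dic_removed_fraction,
                                 fp$n_steps, fp$epsilon_co2_dic, registry)
  last <- stage1$points[nrow(stage1$points), ]
  end_member <- .update_sample(source, dic = last$dic, pH = last$pH,
                               delta13c_dic = last$delta13c_dic)
  stage2 <- evaporation_trajectory(end_member, sp$temperature_C,
                                   sp$max_evaporated_fraction, sp$n_steps,
                                   registry)
  crossings_of <- function(tr) {
    if (nrow(tr$points) < 2L) {
      return(list(calcite = NA_real_, amSiO2 = NA_real_))
    }
    list(calcite = first_crossing(tr, "calcite"),
         amSiO2 = first_crossing(tr, "amSiO2"))
  }
  cr <- list(degassing = crossings_of(stage1),
             evaporation = crossings_of(stage2))
  structure(list(stages = list(degassing = stage1, evaporation = stage2),
                 crossings = cr, source = source,
                 config = list(flowpath = fp, splash = sp)),
            class = "growth_scenario")
}

#' @export
print.growth_scenario <- function(x, ...) {
  cat("Staged growth scenario\n")
  for (stage in names(x$crossings)) {
    cr <- x$crossings[[stage]]
    reached <- names(cr)[!vapply(cr, is.na, logical(1))]
    cat(sprintf("  %-12s Omega >= 1 reached by: %s\n", stage,
                if (length(reached)) paste(reached, collapse = ", ")
                else "none"))
    for (m in reached) {
      cat(sprintf("      %s at extent %.3g\n", m, cr[[m]]))
    }
  }
  invisible(x)
}
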