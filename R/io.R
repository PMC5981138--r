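# CSV / YAML / JSON interfaces and the full-analysis report.

.WATER_COLS_REQUIRED <- c("site_id", "temperature_C", "pH", "dic_mM",
                          "ca_mM", "na_mM", "k_mM", "cl_mM", "so4_mM",
                          "f_mM")
.WATER_COLS_OPTIONAL <- c("sio2_mM", "d13c_dic_permil")

.parse_numeric_col <- function(chr, col, rows_label = seq_along(chr)) {
  chr <- trimws(chr)
  out <- suppressWarnings(as.numeric(chr))
  bad <- which(!is.na(chr) & nzchar(chr) & is.na(out))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                 chr[bad[1]], col, rows_label[bad[1]]), call. = FALSE)
  }
  out[!nzchar(chr)] <- NA_real_
  out
}

#' Read a water-chemistry CSV
#'
#' One row per sample; header must be exactly `site_id, temperature_C, pH,
#' dic_mM, ca_mM, na_mM, k_mM, cl_mM, so4_mM, f_mM` with optional trailing
#' `sio2_mM` and `d13c_dic_permil` columns (empty cells allowed in the
#' optional columns).  Concentrations are in mmol/L and converted to mol/kg
#' water assuming unit density.  Unknown columns, non-numeric cells and
#' negative concentrations are rejected with the offending row and column
#' named.
#'
#' @param path path to the CSV file.
#' @return A list of [water_sample()] objects, named by `site_id`.
#' @export
#' @examples
#' path <- system.file("extdata", "lhc_table1.csv", package = "springsat")
#' waters <- read_water_csv(path)
#' waters[["1"]]
read_water_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  water_samples_from_df(df)
}

#' Build water samples from a data.frame in the CSV schema
#'
#' @param df data.frame with the [read_water_csv()] columns (numeric or
#'   character).
#' @return A list of [water_sample()] objects, named by `site_id`.
#' @export
water_samples_from_df <- function(df) {
  unknown <- setdiff(names(df), c(.WATER_COLS_REQUIRED, .WATER_COLS_OPTIONAL))
  if (length(unknown)) {
    stop("unknown column(s) in water-chemistry table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(.WATER_COLS_REQUIRED, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(df)
  num <- list()
  for (col in setdiff(c(.WATER_COLS_REQUIRED, .WATER_COLS_OPTIONAL),
                      "site_id")) {
    num[[col]] <- if (col %in% names(df)) {
      .parse_numeric_col(as.character(df[[col]]), col)
    } else {
      rep(NA_real_, n)
    }
  }
  conc_cols <- c("dic_mM", "ca_mM", "na_mM", "k_mM", "cl_mM", "so4_mM",
                 "f_mM", "sio2_mM")
  for (col in conc_cols) {
    neg <- which(!is.na(num[[col]]) & num[[col]] < 0)
    if (length(neg)) {
      stop(sprintf("negative concentration in column '%s', row %d",
                   col, neg[1]), call. = FALSE)
    }
  }
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    g <- function(col) {
      v <- num[[col]][i]
      if (is.na(v)) 0 else v
    }
    samples[[i]] <- water_sample(
      temperature_C = num$temperature_C[i], pH = num$pH[i],
      dic = g("dic_mM"), ca = g("ca_mM"), na = g("na_mM"), k = g("k_mM"),
      cl = g("cl_mM"), so4 = g("so4_mM"), f = g("f_mM"), sio2 = g("sio2_mM"),
      delta13c_dic = num$d13c_dic_permil[i],
      site_id = as.character(df$site_id[i]), units = "mM")
  }
  names(samples) <- as.character(df$site_id)
  samples
}

#' Convert water samples to a data.frame in the CSV schema
#'
#' @param samples list of [water_sample()] objects.
#' @return data.frame with the [read_water_csv()] columns (mM units).
#' @export
water_samples_to_df <- function(samples) {
  if (inherits(samples, "water_sample")) samples <- list(samples)
  do.call(rbind, lapply(samples, function(s) {
    data.frame(site_id = s$site_id, temperature_C = s$temperature_C,
               pH = s$pH, dic_mM = s$dic * 1e3, ca_mM = s$ca * 1e3,
               na_mM = s$na * 1e3, k_mM = s$k * 1e3, cl_mM = s$cl * 1e3,
               so4_mM = s$so4 * 1e3, f_mM = s$f * 1e3,
               sio2_mM = s$sio2 * 1e3,
               d13c_dic_permil = s$delta13c_dic)
  })) -> df
  rownames(df) <- NULL
  df
}

#' Write a water-chemistry CSV
#'
#' @param samples list of [water_sample()] objects, or a data.frame already
#'   in the CSV schema.
#' @param path output path.
#' @export
write_water_csv <- function(samples, path) {
  df <- if (is.data.frame(samples)) samples else water_samples_to_df(samples)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a degassing time-series CSV
#'
#' Columns: `time_s` (optional), `dic_mM`, `d13c_permil`.
#'
#' @param path path to the CSV file.
#' @return data.frame with `time_s`, `dic_mM`, `d13c_permil`.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  unknown <- setdiff(names(df), c("time_s", "dic_mM", "d13c_permil"))
  if (length(unknown)) {
    stop("unknown column(s) in series table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(c("dic_mM", "d13c_permil"), names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    time_s = if ("time_s" %in% names(df)) {
      .parse_numeric_col(df$time_s, "time_s")
    } else {
      rep(NA_real_, nrow(df))
    },
    dic_mM = .parse_numeric_col(df$dic_mM, "dic_mM"),
    d13c_permil = .parse_numeric_col(df$d13c_permil, "d13c_permil")
  )
  out
}

#' Packaged spring-transect water analyses
#'
#' The four-site downstream transect of the studied spring (source 81.2 °C,
#' pH 6.70, DIC 15.7 mM; outflow 70.7 °C, pH 7.45, DIC 12.8 mM), with
#' dissolved silica and delta13C_DIC where reported (sites 1 and 4).
#'
#' @return A named list of four [water_sample()] objects.
#' @export
#' @examples
#' saturation(lhc_site_waters()[[1]])
lhc_site_waters <- function() {
  read_water_csv(system.file("extdata", "lhc_table1.csv",
                             package = "springsat", mustWork = TRUE))
}

#' Read a thermodynamic-correlation registry from YAML
#'
#' The YAML file maps constant names (`k1`, `k2`, `kw`, `ksp_calcite`,
#' `csat_amsio2`) to correlation names; see [thermo_registry()] for the
#' available correlations.  Unknown keys are rejected.
#'
#' @param path path to the YAML file.
#' @return a [thermo_registry()].
#' @export
read_thermo_registry <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("k1", "k2", "kw", "ksp_calcite", "csat_amsio2")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown thermodynamic registry key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(thermo_registry, cfg)
}

.CONFIG_KEYS <- c("water_csv", "series_csv", "carbonate_delta13c",
                  "source_site", "exclude_first", "degassing", "evaporation",
                  "cooling", "isotope", "registry", "seed", "verbosity")

#' Build and validate a run configuration
#'
#' @param water_csv path to the water-chemistry CSV (required).
#' @param series_csv optional path to a degassing time-series CSV; when
#'   given, a fractionation fit is included in the report.
#' @param carbonate_delta13c optional numeric vector of measured carbonate
#'   delta13C values (per mil); when given, expected DIC values are reported.
#' @param source_site index or site_id of the sample used as the source for
#'   trajectory models (default 1, the first row).
#' @param exclude_first number of initial series points excluded from the
#'   fractionation fit (default 0).
#' @param degassing,evaporation,cooling,isotope lists overriding the model
#'   parameters (see [degassing_trajectory()], [evaporation_trajectory()],
#'   [cooling_trajectory()], [isotope_config()]).  `evaporation$temperatures_C`
#'   defaults to the source temperature and 25 °C.
#' @param registry optional path to a YAML correlation registry, or a
#'   [thermo_registry()].
#' @param seed integer seed recorded in provenance (the analysis itself is
#'   deterministic; the seed feeds any synthetic-data generation done with
#'   the same config).
#' @param verbosity 0 (quiet) or 1 (log correlation set, tolerances and
#'   exclusions via `message()`).
#' @return list of class `run_config`.
#' @export
run_config <- function(water_csv, series_csv = NULL,
                       carbonate_delta13c = NULL, source_site = 1L,
                       exclude_first = 0L, degassing = list(),
                       evaporation = list(), cooling = list(),
                       isotope = list(), registry = NULL, seed = 1L,
                       verbosity = 1L) {
  stopifnot(is.character(water_csv), length(water_csv) == 1L)
  reg <- if (is.null(registry)) {
    thermo_registry()
  } else if (inherits(registry, "thermo_registry")) {
    registry
  } else {
    read_thermo_registry(registry)
  }
  cfg <- list(
    water_csv = water_csv, series_csv = series_csv,
    carbonate_delta13c = carbonate_delta13c, source_site = source_site,
    exclude_first = as.integer(exclude_first),
    degassing = utils::modifyList(
      list(max_dic_removed_fraction = 0.5, n_steps = 200,
           epsilon_co2_dic = -7.80), degassing),
    evaporation = utils::modifyList(
      list(temperatures_C = NULL, max_evaporated_fraction = 0.95,
           n_steps = 200), evaporation),
    cooling = utils::modifyList(list(t_end_C = 25, n_steps = 100), cooling),
    isotope = do.call(isotope_config, isotope),
    registry = reg, seed = as.integer(seed), verbosity = verbosity
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Accepts the [run_config()] arguments as YAML keys; unknown keys are
#' rejected.
#'
#' @param path path to the YAML file.
#' @return a `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, cfg)
}

.config_hash <- function(config) {
  stripped <- unclass(config)
  stripped$registry <- attr(config$registry, "names_chosen")
  stripped$isotope <- unclass(config$isotope)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(stripped, auto_unbox = TRUE,
                                           digits = NA, null = "null")), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis chain
#'
#' Executes, per site: carbonate speciation and calcite / amorphous-silica
#' saturation.  From the source sample: a constant-alkalinity degassing
#' trajectory, evaporation trajectories at the configured temperature
#' scenarios, and a cooling trajectory.  If a time series is configured, the
#' Rayleigh fractionation fit (with the configured initial exclusions); if
#' carbonate delta13C values are configured, the expected DIC delta13C table.
#' The report carries a provenance block (package version, seed, config hash)
#' and regenerating it from the same configuration is bitwise reproducible.
#'
#' @param config a [run_config()].
#' @return An object of class `analysis_report` with elements `sites`
#'   (per-site data.frame), `trajectories` (named `process_trajectory` list),
#'   `crossings`, `fits`, `expected_dic`, `provenance`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  reg <- config$registry
  log1 <- function(...) if (config$verbosity >= 1) message(sprintf(...))
  log1("thermodynamic correlations: %s",
       paste(names(attr(reg, "names_chosen")),
             attr(reg, "names_chosen"), sep = "=", collapse = ", "))
  log1("pH solver: bracketed on [0, 14], alkalinity residual tol 1e-12 eq/kg")

  samples <- read_water_csv(config$water_csv)
  site_rows <- lapply(samples, function(s) {
    sp <- speciate(s, reg)
    sat <- saturation(s, sp)
    data.frame(site_id = s$site_id, temperature_C = s$temperature_C,
               pH = s$pH, dic_mM = s$dic * 1e3,
               ionic_strength = sp$ionic_strength,
               carbonate_alkalinity = sp$carbonate_alkalinity,
               hco3_fraction = sp$hco3 / max(s$dic, .Machine$double.xmin),
               omega_calcite = sat$omega_calcite,
               si_calcite = sat$si_calcite,
               omega_amSiO2 = sat$omega_amSiO2,
               si_amSiO2 = sat$si_amSiO2,
               d13c_dic_permil = s$delta13c_dic)
  })
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL

  src <- if (is.character(config$source_site)) {
    samples[[config$source_site]]
  } else {
    samples[[as.integer(config$source_site)]]
  }
  dg <- config$degassing
  trajectories <- list(
    degassing = degassing_trajectory(src, dg$max_dic_removed_fraction,
                                     dg$n_steps, dg$epsilon_co2_dic, reg)
  )
  ev <- config$evaporation
  ev_temps <- if (is.null(ev$temperatures_C)) {
    c(src$temperature_C, 25)
  } else {
    ev$temperatures_C
  }
  for (tC in ev_temps) {
    trajectories[[sprintf("evaporation_%gC", tC)]] <-
      evaporation_trajectory(src, tC, ev$max_evaporated_fraction,
                             ev$n_steps, reg)
  }
  co <- config$cooling
  trajectories$cooling <- cooling_trajectory(src, src$temperature_C,
                                             co$t_end_C, co$n_steps, reg)
  crossings <- lapply(trajectories, function(tr) {
    list(calcite = first_crossing(tr, "calcite"),
         amSiO2 = first_crossing(tr, "amSiO2"))
  })

  fits <- list()
  d13c <- vapply(samples, function(s) s$delta13c_dic, numeric(1))
  have <- !is.na(d13c)
  if (sum(have) >= 2) {
    dic <- vapply(samples, function(s) s$dic, numeric(1))
    fits$transect <- fit_epsilon(dic_fraction_remaining(dic)[have],
                                 d13c[have])
    log1("transect fit: %d sites with d13C, 0 excluded", sum(have))
  }
  if (!is.null(config$series_csv)) {
    ser <- read_series_csv(config$series_csv)
    excl <- seq_len(config$exclude_first)
    fits$series <- fit_epsilon(dic_fraction_remaining(ser$dic_mM),
                               ser$d13c_permil,
                               exclude = if (length(excl)) excl else NULL)
    log1("series fit: excluded first %d point(s)", config$exclude_first)
  }

  expected_dic <- NULL
  if (!is.null(config$carbonate_delta13c)) {
    expected_dic <- data.frame(
      d13c_carb_permil = config$carbonate_delta13c,
      d13c_exp_permil = expected_dic_delta(config$carbonate_delta13c,
                                           config$isotope))
  }

  report <- list(
    sites = sites,
    trajectories = trajectories,
    crossings = crossings,
    fits = fits,
    expected_dic = expected_dic,
    provenance = list(
      package = "springsat",
      version = as.character(utils::packageVersion("springsat")),
      seed = config$seed,
      config_hash = .config_hash(config),
      correlations = as.list(attr(reg, "names_chosen")),
      source_site = src$site_id
    )
  )
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (", x$provenance$package, " ",
      x$provenance$version, ")\n", sep = "")
  cat(sprintf("  %d site(s); Omega(calcite) %s\n", nrow(x$sites),
              paste(signif(x$sites$omega_calcite, 3), collapse = ", ")))
  for (nm in names(x$fits)) {
    cat(sprintf("  %s epsilon = %.3f permil (n = %d)\n", nm,
                x$fits[[nm]]$epsilon, x$fits[[nm]]$n_used))
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (everything, machine-readable) plus companion CSV
#' tables: `sites.csv`, one `trajectory_<name>.csv` per trajectory, and
#' `expected_dic.csv` when present.
#'
#' @param report an [run_full_analysis()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$sites, file.path(dir, "sites.csv"),
                   row.names = FALSE, na = "")
  for (nm in names(report$trajectories)) {
    utils::write.csv(report$trajectories[[nm]]$points,
                     file.path(dir, paste0("trajectory_", nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  if (!is.null(report$expected_dic)) {
    utils::write.csv(report$expected_dic,
                     file.path(dir, "expected_dic.csv"),
                     row.names = FALSE, na = "")
  }
  json <- list(
    sites = report$sites,
    crossings = report$crossings,
    fits = lapply(report$fits, unclass),
    expected_dic = report$expected_dic,
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(dir)
}
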