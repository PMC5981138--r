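# Rayleigh distillation of the carbon isotope composition of DIC during CO2
# degassing, and the least-squares estimator of the fractionation factor.

#' Rayleigh evolution of delta13C with DIC loss
#'
#' Linearised Rayleigh law: delta = delta0 + epsilon * ln(f), where f is the
#' fraction of DIC remaining and epsilon the per-mil fractionation between
#' the escaping CO2 and the residual DIC (negative for degassing: the gas is
#' depleted, so the residue grows enriched as f falls).  The exact form
#' delta = (delta0 + 1000) f^(epsilon/1000) - 1000 is available via
#' `exact = TRUE`; at the fractionations and DIC losses typical of hot-spring
#' outflows the two differ by < 0.05 per mil.
#'
#' @param delta0 initial delta13C of the DIC, per mil VPDB.
#' @param epsilon fractionation factor, per mil.
#' @param f fraction of DIC remaining, in (0, 1\]; vectorised.
#' @param exact use the exact Rayleigh form instead of the linearisation.
#' @return delta13C of the residual DIC, per mil VPDB.
#' @export
#' @examples
#' rayleigh_delta(-5.2, -8.67, 0.9)
rayleigh_delta <- function(delta0, epsilon, f, exact = FALSE) {
  if (any(!is.finite(f)) || any(f <= 0) || any(f > 1)) {
    stop("f must be in (0, 1]", call. = FALSE)
  }
  if (exact) {
    (delta0 + 1000) * f^(epsilon / 1000) - 1000
  } else {
    delta0 + epsilon * log(f)
  }
}

#' Fraction of DIC remaining along a series
#'
#' Normalises a DIC concentration series by its first value, so the first
#' point is f = 1 by convention.
#'
#' @param dic DIC concentrations (any consistent unit); all values must be
#'   > 0.
#' @return f, the fraction of the initial DIC remaining.
#' @export
#' @examples
#' dic_fraction_remaining(c(15.7, 14.9, 13.7, 12.8))
dic_fraction_remaining <- function(dic) {
  if (length(dic) < 1L || any(!is.finite(dic)) || any(dic <= 0)) {
    stop("dic values must all be finite and > 0", call. = FALSE)
  }
  dic / dic[1]
}

#' Construct a Rayleigh series
#'
#' A (f, delta13C) series with an optional exclusion mask for points not to
#' be used in regression (e.g. early samples taken before a stirred vessel
#' was fully mixed).  Exclusion is always explicit — there is no automatic
#' outlier rejection — and the fit records how many points were excluded.
#'
#' @param f fraction of DIC remaining; must be > 0 (measurement noise may
#'   nudge a point slightly above 1).
#' @param delta13c delta13C of the DIC, per mil VPDB; same length as `f`.
#' @param exclude points to exclude from fitting: a logical mask of the same
#'   length, or integer indices.
#' @return An object of class `rayleigh_series`.
#' @export
rayleigh_series <- function(f, delta13c, exclude = NULL) {
  if (length(f) != length(delta13c)) {
    stop("f and delta13c must have the same length", call. = FALSE)
  }
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("f must be > 0", call. = FALSE)
  }
  mask <- rep(FALSE, length(f))
  if (!is.null(exclude)) {
    if (is.logical(exclude)) {
      stopifnot(length(exclude) == length(f))
      mask <- exclude
    } else {
      mask[as.integer(exclude)] <- TRUE
    }
  }
  structure(list(f = as.numeric(f), delta13c = as.numeric(delta13c),
                 excluded = mask),
            class = "rayleigh_series")
}

#' Estimate the fractionation factor from a Rayleigh series
#'
#' Ordinary least squares of delta13C on ln(f) over the unmasked points; the
#' slope estimates the per-mil fractionation epsilon between the lost product
#' and the reactant DIC, and the intercept is the delta13C at f = 1.  A
#' t-based confidence interval on the slope is reported from the OLS standard
#' error.
#'
#' @param f a `rayleigh_series`, or a numeric vector of DIC fractions
#'   remaining (then `delta13c` is required).
#' @param delta13c delta13C values, per mil VPDB (when `f` is numeric).
#' @param exclude as in [rayleigh_series()] (when `f` is numeric).
#' @param conf_level confidence level for the slope interval (default 0.95).
#' @return An object of class `fractionation_fit`: `epsilon`, `intercept`,
#'   `r_squared`, `se_epsilon`, `conf_int`, `n_used`, `n_excluded`.
#' @export
#' @examples
#' f <- c(1, 0.95, 0.9, 0.85)
#' fit_epsilon(f, rayleigh_delta(-5.2, -8.67, f))
fit_epsilon <- function(f, delta13c = NULL, exclude = NULL,
                        conf_level = 0.95) {
  series <- if (inherits(f, "rayleigh_series")) f else
    rayleigh_series(f, delta13c, exclude)
  use <- !series$excluded
  x <- log(series$f[use])
  y <- series$delta13c[use]
  if (sum(use) < 2L) {
    stop("need at least 2 unmasked points to fit epsilon", call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("f is constant over the unmasked points; epsilon is unidentifiable",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  est <- stats::coef(fit)[["x"]]
  res <- stats::residuals(fit)
  ssr <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1    # flat noiseless series
  # slope standard error computed directly (avoids summary.lm's warning on
  # the zero-residual oracle series)
  se <- if (fit$df.residual > 0) {
    sqrt(ssr / fit$df.residual / sum((x - mean(x))^2))
  } else {
    NA_real_
  }
  ci <- if (!is.na(se)) {
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
    c(est - tq * se, est + tq * se)
  } else {
    c(NA_real_, NA_real_)
  }
  out <- list(
    epsilon = est,
    intercept = stats::coef(fit)[["(Intercept)"]],
    r_squared = r2,
    se_epsilon = se,
    conf_int = ci,
    conf_level = conf_level,
    n_used = sum(use),
    n_excluded = sum(!use)
  )
  class(out) <- "fractionation_fit"
  out
}

#' @export
print.fractionation_fit <- function(x, ...) {
  cat(sprintf("Rayleigh fractionation fit: epsilon = %.3f permil", x$epsilon))
  if (!is.na(x$se_epsilon)) {
    cat(sprintf(" (%d%% CI [%.3f, %.3f])", round(100 * x$conf_level),
                x$conf_int[1], x$conf_int[2]))
  }
  cat(sprintf("\n  intercept %.3f permil, R^2 = %.4f, n = %d used, %d excluded\n",
              x$intercept, x$r_squared, x$n_used, x$n_excluded))
  invisible(x)
}

#' Isotope model configuration
#'
#' @param calcite_bicarbonate_enrichment equilibrium per-mil enrichment of
#'   calcite over bicarbonate (default 1.0).
#' @param epsilon_co2_dic per-mil fractionation between escaping CO2 and
#'   residual DIC during degassing (default -8.67).
#' @return list of class `isotope_config`.
#' @export
isotope_config <- function(calcite_bicarbonate_enrichment = 1.0,
                           epsilon_co2_dic = -8.67) {
  stopifnot(is.finite(calcite_bicarbonate_enrichment),
            is.finite(epsilon_co2_dic))
  structure(list(
    calcite_bicarbonate_enrichment = calcite_bicarbonate_enrichment,
    epsilon_co2_dic = epsilon_co2_dic
  ), class = "isotope_config")
}

#' Expected DIC delta13C from a measured carbonate
#'
#' Back-calculates the delta13C a water's DIC must have had for its
#' equilibrium calcite to match a measured carbonate value, given a fixed
#' calcite-bicarbonate enrichment: delta13C_EXP = delta13C_carb - enrichment.
#'
#' @param delta13c_carb measured carbonate delta13C, per mil VPDB;
#'   vectorised.
#' @param config an [isotope_config()].
#' @return expected DIC delta13C, per mil VPDB.
#' @export
#' @examples
#' expected_dic_delta(c(-2.2, -1.2, -0.2))
expected_dic_delta <- function(delta13c_carb, config = isotope_config()) {
  stopifnot(all(is.finite(delta13c_carb)))
  delta13c_carb - config$calcite_bicarbonate_enrichment
}
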