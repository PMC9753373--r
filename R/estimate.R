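#' Estimate penetrance from per-state variant frequencies
#'
#' Runs the full estimation pipeline: (1) compute the observed state rate
#' from the weighted per-state variant frequencies ([observed_rate()]), with
#' a delta-method confidence interval when standard errors are supplied;
#' (2) tabulate the expected rate against penetrance at the given residual
#' risk and sibship size ([build_lookup()]); (3) invert the observed rate to
#' an uncorrected estimate ([invert_rate()]); (4) correct the estimate for
#' the bias induced by the sibship-size distribution via simulation-based
#' calibration ([fit_error_model()], [adjust_estimate()]). Confidence bounds
#' on the rate, when available, are passed through steps 3-4 with the same
#' lookup table and error model.
#'
#' The residual risk `g` may be supplied directly, set to zero, or derived
#' from the frequencies and disease context by Bayes' theorem
#' ([residual_risk()]; the default). For rare diseases the derived `g` is
#' near zero and has negligible influence on the estimate.
#'
#' @inheritParams observed_rate
#' @param N Average sibship size of the sampled population (e.g. a Total
#'   Fertility Rate).
#' @param g Residual non-carrier risk: `"auto"` (derive via Bayes; falls back
#'   to 0 with a warning if the lifetime risk is missing), `"zero"`, or a
#'   number in `[0, 1)`.
#' @param rate_state Designated state `X`; see [state_combination()].
#' @param correct_bias Apply the simulation-based correction (step 4)?
#'   Disable to obtain the raw lookup inverse only.
#' @param lookup_step Grid spacing of the lookup table.
#' @param n_families,calibration_grid,max_degree,sibship_dist Calibration
#'   settings forwarded to [fit_error_model()].
#' @param seed Optional integer seed for the calibration simulations.
#'
#' @return An object of class `"penetrance_estimate"`: list with
#'   `f_unadjusted`, `f_adjusted`, `ci_lower`, `ci_upper` (adjusted bounds,
#'   `NA` without standard errors), the interval bounds before correction
#'   (`ci_lower_unadjusted`, `ci_upper_unadjusted`), the `observed_rate`
#'   record, `g`, `g_source`, `N`, `combo`, the `error_fit` (or `NULL`) and
#'   the call `settings`.
#' @examples
#' \donttest{
#' fr <- variant_frequencies(F = variant_frequency(0.300, se = 0.025),
#'                           S = variant_frequency(0.015, se = 0.00255),
#'                           U = 0)
#' ctx <- disease_context(lifetime_risk = 1 / 400, familiality = 0.05)
#' est <- estimate_penetrance(fr, ctx, N = 1.823, states = c("F", "S"),
#'                            n_families = 2000,
#'                            calibration_grid = seq(0, 1, 0.1), seed = 1)
#' est
#' }
#' @export
estimate_penetrance <- function(freqs, context, N, g = "auto", states = NULL,
                                rate_state = NULL, conf_level = 0.95,
                                correct_bias = TRUE, lookup_step = 1e-4,
                                n_families = 50000,
                                calibration_grid = seq(0, 1, by = 0.02),
                                max_degree = 3, sibship_dist = "poisson",
                                seed = NULL) {
  stopifnot(inherits(freqs, "variant_frequency_set"))
  if (is.null(states)) states <- setdiff(names(freqs), "U")
  combo <- as_state_combination(states, rate_state)
  obs <- observed_rate(freqs, combo, context, conf_level)

  if (identical(g, "auto")) {
    if (is.null(context$lifetime_risk)) {
      warning("lifetime risk unavailable; assuming residual risk g = 0")
      g_val <- 0; g_source <- "default-zero"
    } else {
      g_val <- residual_risk(freqs, context)$g; g_source <- "derived"
    }
  } else if (identical(g, "zero")) {
    g_val <- 0; g_source <- "zero"
  } else if (is.numeric(g) && length(g) == 1L) {
    g_val <- g; g_source <- "fixed"
  } else stop("g must be \"auto\", \"zero\", or a single number")

  lut <- build_lookup(combo, g = g_val, N = N, step = lookup_step)
  f_un <- invert_rate(lut, obs$rate)

  fit <- NULL
  f_adj <- f_un
  if (correct_bias) {
    fit <- fit_error_model(combo, g = g_val, N = N, grid = calibration_grid,
                           n_families = n_families, max_degree = max_degree,
                           sibship_dist = sibship_dist, seed = seed,
                           lookup = lut)
    f_adj <- adjust_estimate(f_un, fit)
  }

  ci_un <- ci_adj <- c(NA_real_, NA_real_)
  if (!is.na(obs$se)) {
    bounds <- suppressWarnings(invert_rate(lut, c(obs$ci_lower, obs$ci_upper)))
    ci_un <- sort(bounds)
    ci_adj <- if (correct_bias) sort(adjust_estimate(ci_un, fit)) else ci_un
  }

  structure(list(f_unadjusted = f_un, f_adjusted = f_adj,
                 ci_lower = ci_adj[1], ci_upper = ci_adj[2],
                 ci_lower_unadjusted = ci_un[1],
                 ci_upper_unadjusted = ci_un[2],
                 observed_rate = obs, g = g_val, g_source = g_source,
                 N = N, combo = combo, error_fit = fit,
                 settings = list(conf_level = conf_level,
                                 correct_bias = correct_bias,
                                 lookup_step = lookup_step,
                                 n_families = n_families,
                                 calibration_grid = calibration_grid,
                                 max_degree = max_degree,
                                 sibship_dist = sibship_dist, seed = seed)),
            class = "penetrance_estimate")
}

#' @export
print.penetrance_estimate <- function(x, digits = 3, ...) {
  cat("Penetrance estimate over {",
      paste(unclass(x$combo), collapse = ","), "}\n", sep = "")
  cat(sprintf("  observed rate of %s: %.*f", rate_state_of(x$combo),
              digits, x$observed_rate$rate))
  if (!is.na(x$observed_rate$se))
    cat(sprintf(" (%g%% CI %.*f-%.*f)", 100 * x$observed_rate$conf_level,
                digits, x$observed_rate$ci_lower,
                digits, x$observed_rate$ci_upper))
  cat("\n")
  cat(sprintf("  residual risk g = %.4g (%s); sibship size N = %.4g\n",
              x$g, x$g_source, x$N))
  cat(sprintf("  penetrance f = %.*f (uncorrected %.*f)", digits,
              x$f_adjusted, digits, x$f_unadjusted))
  if (!is.na(x$ci_lower))
    cat(sprintf(", %g%% CI %.*f-%.*f", 100 * x$settings$conf_level,
                digits, x$ci_lower, digits, x$ci_upper))
  cat("\n")
  invisible(x)
}
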