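#' Calibrate the estimation error of lookup inversion
#'
#' The lookup curve assumes every family has exactly `N` siblings, while real
#' (and simulated) populations have a distribution of integer sibship sizes
#' around that mean. Inverting a rate computed on such a population through
#' the fixed-`N` curve is therefore systematically biased. This function
#' quantifies that bias by simulation: for each true penetrance on a
#' calibration grid it simulates a population of families
#' ([simulate_families()]), computes the simulated state rate, inverts it
#' through the lookup table, and records the error `true - estimated`. A
#' polynomial regression of the error on the estimated penetrance is then
#' fitted, with the degree chosen among `1..max_degree` by adjusted R-squared
#' and demoted if the implied corrected estimate would not be monotone in the
#' uncorrected one.
#'
#' Calibration points at which no simulated family falls in the modelled
#' states (e.g. true `f = 0` with `g = 0` over `{F,S}`) are dropped; rates
#' falling outside the span of the lookup curve are clamped to its endpoint.
#'
#' @inheritParams build_lookup
#' @param grid True penetrance values to calibrate at (default 0 to 1 in
#'   steps of 0.02).
#' @param n_families Families simulated per grid point (default 50,000,
#'   keeping per-point Monte-Carlo noise below about 0.005).
#' @param max_degree Highest polynomial degree considered (default 3).
#' @param sibship_dist Sibship-size distribution, as in
#'   [simulate_families()].
#' @param seed Optional integer seed making the fit reproducible.
#' @param lookup Optional pre-built [build_lookup()] table for the same
#'   combination, `g` and `N` (built on demand otherwise).
#'
#' @return An object of class `"error_fit"`: list with the fitted `model`
#'   (an `lm`), chosen `degree`, `adj_r_squared`, the `calibration` data
#'   frame (`f_true`, `rate_sim`, `f_est`, `error`) and the simulation
#'   `settings`.
#' @examples
#' \donttest{
#' fit <- fit_error_model(c("F", "S"), g = 0, N = 1.8, n_families = 2000,
#'                        grid = seq(0, 1, 0.1), seed = 1)
#' fit$degree
#' }
#' @export
fit_error_model <- function(states, g = 0, N, rate_state = NULL,
                            grid = seq(0, 1, by = 0.02),
                            n_families = 50000, max_degree = 3,
                            sibship_dist = "poisson", seed = NULL,
                            lookup = NULL) {
  combo <- as_state_combination(states, rate_state)
  if (is.null(lookup)) lookup <- build_lookup(combo, g = g, N = N)
  if (!is.null(seed)) set.seed(seed)
  rate_sim <- vapply(grid, function(ft) {
    pop <- simulate_families(ft, g = g, mean_sibship = N,
                             n_families = n_families,
                             sibship_dist = sibship_dist)
    tryCatch(simulated_state_rate(pop, combo), error = function(e) NA_real_)
  }, numeric(1))
  keep <- !is.na(rate_sim)
  f_est <- rep(NA_real_, length(grid))
  f_est[keep] <- suppressWarnings(invert_rate(lookup, rate_sim[keep]))
  calib <- data.frame(f_true = grid, rate_sim = rate_sim, f_est = f_est,
                      error = grid - f_est)
  fit_data <- calib[keep, ]
  if (nrow(fit_data) < max_degree + 2L)
    stop("too few usable calibration points to fit an error model")
  if (length(unique(fit_data$f_est)) < 2L)
    stop("degenerate calibration grid: all inverted estimates identical")
  degrees <- seq_len(min(max_degree, length(unique(fit_data$f_est)) - 1L))
  fits <- lapply(degrees, function(d)
    stats::lm(error ~ poly(f_est, d, raw = TRUE), data = fit_data))
  adj <- vapply(fits, function(m) summary(m)$adj.r.squared, numeric(1))
  probe <- data.frame(f_est = seq(0, 1, by = 0.001))
  monotone <- vapply(fits, function(m) {
    adj_f <- probe$f_est + stats::predict(m, probe)
    all(diff(adj_f) >= -1e-8)
  }, logical(1))
  order_pref <- order(-adj)
  pick <- order_pref[match(TRUE, monotone[order_pref])]
  if (is.na(pick)) pick <- 1L  # fall back to linear if nothing is monotone
  structure(list(model = fits[[pick]], degree = degrees[[pick]],
                 adj_r_squared = adj[[pick]], calibration = calib,
                 settings = list(combo = combo, g = g, N = N, grid = grid,
                                 n_families = n_families,
                                 max_degree = max_degree,
                                 sibship_dist = sibship_dist, seed = seed)),
            class = "error_fit")
}

#' @export
print.error_fit <- function(x, ...) {
  s <- x$settings
  cat(sprintf(paste0("Error calibration for state %s over {%s} ",
                     "(g = %.4g, N = %.4g)\n"),
              rate_state_of(s$combo), paste(unclass(s$combo), collapse = ","),
              s$g, s$N))
  cat(sprintf("  polynomial degree %d (adj. R-squared %.4f), %d x %d %s\n",
              x$degree, x$adj_r_squared, length(s$grid), s$n_families,
              paste0(s$sibship_dist, "-sibship families")))
  invisible(x)
}

#' Apply a fitted bias correction to a penetrance estimate
#'
#' Adds the error predicted by an [fit_error_model()] calibration to an
#' uncorrected (lookup-inverted) estimate and clamps the result to `[0, 1]`.
#' A zero-coefficient model is the identity.
#'
#' @param f_unadjusted Uncorrected penetrance estimate(s) in `[0, 1]`.
#' @param model An `"error_fit"` object.
#' @return Bias-corrected estimate(s) in `[0, 1]`.
#' @examples
#' \donttest{
#' fit <- fit_error_model(c("F", "S"), g = 0, N = 1.8, n_families = 2000,
#'                        grid = seq(0, 1, 0.1), seed = 1)
#' adjust_estimate(0.75, fit)
#' }
#' @export
adjust_estimate <- function(f_unadjusted, model) {
  stopifnot(inherits(model, "error_fit"))
  if (anyNA(f_unadjusted) || any(f_unadjusted < 0) || any(f_unadjusted > 1))
    stop("estimates to adjust must lie in [0, 1]")
  pred <- unname(stats::predict(model$model,
                                data.frame(f_est = as.numeric(f_unadjusted))))
  pmin(pmax(f_unadjusted + pred, 0), 1)
}
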