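#' Build a penetrance lookup table
#'
#' Tabulates the expected state rate [expected_rate()] on a regular grid of
#' penetrance values `f` spanning `[0, 1]` for fixed residual risk `g` and
#' sibship size `N`. The curve must be monotone in `f` (in either direction)
#' for inversion to be meaningful; this is verified at build time and a
#' non-monotone curve is an error.
#'
#' @inheritParams expected_rate
#' @param step Grid spacing (default `1e-4`, i.e. 10,001 points — finer than
#'   the three decimals at which estimates are reported).
#' @return A data frame of class `"penetrance_lookup"` with columns `f` and
#'   `rate`, carrying the combination, `g`, `N`, `step` and monotonicity
#'   direction as attributes.
#' @examples
#' lut <- build_lookup(c("F", "S"), g = 0, N = 2, step = 0.001)
#' head(lut)
#' @export
build_lookup <- function(states, g = 0, N, step = 1e-4, rate_state = NULL) {
  combo <- as_state_combination(states, rate_state)
  if (!is.numeric(step) || step <= 0 || step > 0.5)
    stop("step must be a small positive grid spacing")
  npts <- round(1 / step) + 1L
  fgrid <- seq(0, 1, length.out = npts)
  rate <- expected_rate(fgrid, g = g, N = N, states = combo)
  d <- diff(rate)
  increasing <- all(d >= -1e-9)
  decreasing <- all(d <= 1e-9)
  if (!increasing && !decreasing)
    stop("expected-rate curve is not monotone in f for this state ",
         "combination; inversion is not defined")
  out <- data.frame(f = fgrid, rate = rate)
  structure(out, combo = combo, g = g, N = N, step = step,
            direction = if (increasing) "increasing" else "decreasing",
            class = c("penetrance_lookup", "data.frame"))
}

#' Invert an observed rate through a lookup table
#'
#' Returns the grid penetrance whose expected rate is nearest the observed
#' rate; ties are broken toward the lower penetrance (conservative). Observed
#' rates outside the range spanned by the table — possible for confidence
#' bounds computed from noisy frequency estimates — are clamped to the
#' nearest endpoint with a warning.
#'
#' @param table A [build_lookup()] table.
#' @param r_obs Observed rate(s) in `[0, 1]`.
#' @return Unadjusted penetrance estimate(s), one per observed rate.
#' @examples
#' lut <- build_lookup(c("F", "S"), g = 0, N = 2, step = 0.001)
#' invert_rate(lut, 0.5)
#' @export
invert_rate <- function(table, r_obs) {
  stopifnot(inherits(table, "penetrance_lookup"))
  if (anyNA(r_obs) || any(r_obs < 0) || any(r_obs > 1))
    stop("observed rates must lie in [0, 1]")
  rng <- range(table$rate)
  out_of_range <- r_obs < rng[1] | r_obs > rng[2]
  if (any(out_of_range)) {
    warning("observed rate outside the range of expected rates; ",
            "clamping to the nearest endpoint")
    r_obs <- pmin(pmax(r_obs, rng[1]), rng[2])
  }
  vapply(r_obs, function(r) table$f[which.min(abs(table$rate - r))],
         numeric(1))
}

#' Invert an observed rate by bisection on the closed form
#'
#' Continuous alternative to the lookup table: solves
#' `expected_rate(f) = r_obs` on `[0, 1]` by root bisection, exploiting the
#' monotonicity of the rate curve. Agrees with [invert_rate()] to within one
#' grid step; useful as a cross-check and when sub-grid resolution is wanted.
#'
#' @inheritParams build_lookup
#' @param r_obs Observed rate in `[0, 1]` (scalar).
#' @param tol Convergence tolerance on `f`.
#' @return The penetrance solving the rate equation (clamped endpoint with a
#'   warning when `r_obs` lies outside the attainable range).
#' @examples
#' invert_rate_bisection(c("F", "S"), g = 0, N = 2, r_obs = 0.5)
#' @export
invert_rate_bisection <- function(states, g = 0, N, r_obs, rate_state = NULL,
                                  tol = 1e-9) {
  combo <- as_state_combination(states, rate_state)
  if (length(r_obs) != 1L || is.na(r_obs) || r_obs < 0 || r_obs > 1)
    stop("r_obs must be a single rate in [0, 1]")
  fn <- function(f) expected_rate(f, g = g, N = N, states = combo) - r_obs
  r0 <- expected_rate(0, g = g, N = N, states = combo)
  r1 <- expected_rate(1, g = g, N = N, states = combo)
  lo <- min(r0, r1); hi <- max(r0, r1)
  if (r_obs < lo || r_obs > hi) {
    warning("observed rate outside the attainable range; ",
            "returning the nearest endpoint")
    nearer_r0 <- abs(r_obs - r0) <= abs(r_obs - r1)
    return(if (nearer_r0) 0 else 1)
  }
  if (fn(0) == 0) return(0)
  if (fn(1) == 0) return(1)
  stats::uniroot(fn, interval = c(0, 1), tol = tol)$root
}
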