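#' Nuclear-family disease-state probabilities
#'
#' For a nuclear family in which exactly one parent carries an autosomal
#' dominant variant, computes the probabilities that the family presents as
#' unaffected (no affected member), sporadic (exactly one affected member) or
#' familial (two or more affected members), as functions of the carrier
#' penetrance `f`, the residual disease risk `g` of non-carriers, and the
#' sibship size `N`.
#'
#' The model counts the carrier parent, the non-carrier parent and `N`
#' offspring. Each offspring inherits the variant with probability 1/2, so
#' carries lifetime risk `f/2 + g/2`; the carrier parent is affected with
#' probability `f` and the non-carrier parent with probability `g`. Writing
#' `b = 1 - f/2 - g/2`:
#' \deqn{P(unaffected) = (1-f)\, b^N (1-g)}
#' \deqn{P(sporadic) = f b^N (1-g) + (1-f) N (f/2+g/2) b^{N-1} (1-g)
#'   + (1-f) b^N g}
#' and `P(familial)` is the complement of their sum. `P(affected)` is
#' `P(sporadic) + P(familial)`. `N` may be non-integer (for instance a Total
#' Fertility Rate): the expressions are evaluated with real exponents. At
#' `g = 0` the model reduces to the variant-necessary formulation in which
#' non-carriers are never affected.
#'
#' @param f Penetrance, in `[0, 1]`. May be a vector.
#' @param g Residual (non-carrier) disease risk, a scalar in `[0, 1)`.
#' @param N Sibship size, a non-negative scalar; non-integer values allowed.
#'
#' @return A data frame with one row per value of `f` and columns `f`,
#'   `p_unaffected`, `p_sporadic`, `p_familial`, `p_affected`. The first three
#'   sum to 1.
#' @examples
#' state_probabilities(f = 0.75, g = 0, N = 1.823)
#' @export
state_probabilities <- function(f, g = 0, N) {
  check_model_params(f, g, N)
  b <- 1 - f / 2 - g / 2
  pu <- (1 - f) * b^N * (1 - g)
  ps <- f * b^N * (1 - g) +
    (1 - f) * N * (f / 2 + g / 2) * b^(N - 1) * (1 - g) +
    (1 - f) * b^N * g
  pf <- 1 - pu - ps
  # complement can dip a hair below zero in floating point near f = g = 0
  neg <- pf < 0
  if (any(pf[neg] < -1e-12))
    stop("internal error: familial probability below -1e-12")
  pf[neg] <- 0
  data.frame(f = f, p_unaffected = pu, p_sporadic = ps, p_familial = pf,
             p_affected = ps + pf)
}

#' Expected rate of a disease state among variant-harbouring families
#'
#' The expected rate of the designated state `X` among variant-harbouring
#' families restricted to the modelled states: `P(X) / sum of P(Y)` over the
#' modelled states `Y`, using [state_probabilities()]. This is the curve that
#' a lookup table tabulates against `f` and that an observed rate is inverted
#' through.
#'
#' At `f = 0` with `g = 0` and no unaffected state modelled, all modelled
#' probabilities vanish; the rate is then defined by its limit as `f`
#' approaches 0 from above (0 for the familial rate over `{F,S}`, 1 for the
#' sporadic rate), which keeps the lookup curve continuous at its boundary.
#'
#' @inheritParams state_probabilities
#' @param states A [state_combination()] or character vector of states.
#' @param rate_state Designated state `X`; see [state_combination()].
#'
#' @return Numeric vector of rates in `[0, 1]`, one per value of `f`.
#' @examples
#' expected_rate(0.75, g = 0, N = 1.823, states = c("F", "S"))
#' @export
expected_rate <- function(f, g = 0, N, states, rate_state = NULL) {
  combo <- as_state_combination(states, rate_state)
  x <- rate_state_of(combo)
  sp <- state_probabilities(f, g, N)
  cols <- c(F = "p_familial", S = "p_sporadic", U = "p_unaffected",
            A = "p_affected")
  num <- sp[[cols[[x]]]]
  den <- 0
  for (s in unclass(combo)) den <- den + sp[[cols[[s]]]]
  r <- num / den
  deg <- den <= 0
  if (any(deg)) {
    if (!"U" %in% combo && g == 0 && all(f[deg] == 0)) {
      r[deg] <- switch(x, F = 0, S = 1,
                       stop("no limit convention for rate state ", x))
    } else {
      stop("degenerate state combination: all modelled state probabilities ",
           "are zero and no limit convention applies")
    }
  }
  r
}

check_model_params <- function(f, g, N) {
  if (!is.numeric(f) || anyNA(f) || any(f < 0) || any(f > 1))
    stop("penetrance f must lie in [0, 1]")
  if (!is.numeric(g) || length(g) != 1L || is.na(g) || g < 0 || g >= 1)
    stop("residual risk g must lie in [0, 1)")
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 0)
    stop("sibship size N must be non-negative")
  invisible(TRUE)
}
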