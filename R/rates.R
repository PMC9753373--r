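#' State weighting factors
#'
#' Converts per-state variant frequencies into their contributions to the
#' observed state rate. Within the affected population the familial and
#' sporadic states are weighted by the familiality rate `P(F|A)` and its
#' complement; whenever the unaffected (or pooled affected) state is
#' modelled, affected-state weights are additionally scaled by the lifetime
#' risk `P(A)` and the unaffected state receives `1 - P(A)`:
#' \itemize{
#'   \item `{F,S}`: `W_F = P(F|A)`, `W_S = P(S|A)`
#'   \item `{F,U}`: `W_F = P(F|A) P(A)`, `W_U = 1 - P(A)`
#'   \item `{S,U}`: `W_S = P(S|A) P(A)`, `W_U = 1 - P(A)`
#'   \item `{F,S,U}`: `W_F = P(F|A) P(A)`, `W_S = P(S|A) P(A)`,
#'     `W_U = 1 - P(A)`
#'   \item `{A,U}`: `W_A = P(A)`, `W_U = 1 - P(A)`
#' }
#'
#' @param states A [state_combination()] or character vector of states.
#' @param context A [disease_context()]. The lifetime risk is required
#'   whenever `U` or `A` is modelled; the familiality rate whenever `F` or
#'   `S` is.
#' @return Named numeric vector of weights, one per modelled state.
#' @examples
#' weighting_factors(c("F", "S"), disease_context(familiality = 0.05))
#' @export
weighting_factors <- function(states, context) {
  combo <- as_state_combination(states)
  stopifnot(inherits(context, "disease_context"))
  pa <- context$lifetime_risk
  pfa <- context$familiality
  if (any(c("U", "A") %in% combo) && is.null(pa))
    stop("lifetime risk P(A) is required when the unaffected or affected ",
         "state is modelled")
  if (any(c("F", "S") %in% combo) && is.null(pfa))
    stop("familiality rate P(F|A) is required when the familial or sporadic ",
         "state is modelled")
  w <- c(F = if ("F" %in% combo) pfa else NA_real_,
         S = if ("S" %in% combo) 1 - pfa else NA_real_,
         U = if ("U" %in% combo) 1 - pa else NA_real_,
         A = if ("A" %in% combo) pa else NA_real_)
  if ("U" %in% combo) w[c("F", "S")] <- w[c("F", "S")] * pa
  w[unclass(combo)]
}

#' Observed rate of a disease state among variant-harbouring families
#'
#' Computes the observed rate of the designated state `X` among families
#' harbouring the variant across the modelled states, as the weighted
#' proportion `R = W_X M_X / sum(W_Y M_Y)` of the per-state variant
#' frequencies. When every modelled state carries a standard error, the
#' standard error of `R` is propagated by the first-order delta method
#' treating the per-state estimates as independent (they come from disjoint
#' samples), and a normal confidence interval is attached, clipped to
#' `[0, 1]`.
#'
#' @param freqs A [variant_frequencies()] set covering every modelled state
#'   (extra states are ignored here but may serve [residual_risk()]).
#' @param states States to model; defaults to all states present in `freqs`.
#' @param context A [disease_context()] supplying the weights.
#' @param conf_level Confidence level for the interval (default 0.95).
#'
#' @return An object of class `"observed_rate"`: a list with `rate`, `se`,
#'   `ci_lower`, `ci_upper` (latter three `NA` when standard errors are
#'   incomplete), `weights`, `combo` and `conf_level`.
#' @examples
#' fr <- variant_frequencies(F = variant_frequency(0.300, se = 0.025),
#'                           S = variant_frequency(0.015, se = 0.00255))
#' observed_rate(fr, context = disease_context(familiality = 0.05))
#' @export
observed_rate <- function(freqs, states = NULL, context, conf_level = 0.95) {
  stopifnot(inherits(freqs, "variant_frequency_set"))
  if (is.null(states)) states <- names(freqs)
  combo <- as_state_combination(states)
  missing <- setdiff(unclass(combo), names(freqs))
  if (length(missing))
    stop("no frequency supplied for modelled state(s): ",
         paste(missing, collapse = ", "))
  w <- weighting_factors(combo, context)
  m <- vapply(unclass(combo), function(s) freqs[[s]]$estimate, numeric(1))
  wm <- w * m
  total <- sum(wm)
  if (total <= 0)
    stop("all weighted frequencies are zero; the observed rate is undefined")
  x <- rate_state_of(combo)
  rate <- wm[[x]] / total
  se <- ci_lo <- ci_hi <- NA_real_
  ses <- vapply(unclass(combo),
                function(s) if (is.null(freqs[[s]]$se)) NA_real_ else freqs[[s]]$se,
                numeric(1))
  if (!anyNA(ses)) {
    # dR/dM_X = W_X (T - A) / T^2 ; dR/dM_Y = -A W_Y / T^2 for Y != X
    grad <- -wm[[x]] * w / total^2
    grad[[x]] <- w[[x]] * (total - wm[[x]]) / total^2
    se <- sqrt(sum((grad * ses)^2))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci_lo <- max(0, rate - z * se)
    ci_hi <- min(1, rate + z * se)
  }
  structure(list(rate = rate, se = se, ci_lower = ci_lo, ci_upper = ci_hi,
                 weights = w, combo = combo, conf_level = conf_level),
            class = "observed_rate")
}

#' @export
print.observed_rate <- function(x, ...) {
  cat(sprintf("Observed rate of state %s over {%s}: %.4f",
              rate_state_of(x$combo), paste(unclass(x$combo), collapse = ","),
              x$rate))
  if (!is.na(x$se))
    cat(sprintf("  (se %.4f; %g%% CI %.4f-%.4f)",
                x$se, 100 * x$conf_level, x$ci_lower, x$ci_upper))
  cat("\n")
  invisible(x)
}

#' Residual disease risk of non-carriers
#'
#' Derives, by Bayes' theorem, the residual risk `g` that a person not
#' harbouring the variant develops the disease:
#' \deqn{g = P(A) (1 - M_A) / (1 - P(M))}
#' where `M_A` is the variant frequency among all affected people (the
#' familiality-weighted sum of the familial and sporadic frequencies, or a
#' directly supplied affected-state frequency) and
#' `P(M) = M_A P(A) + M_U (1 - P(A))` is the population frequency of the
#' variant. When no unaffected-state frequency is supplied `M_U` is assumed
#' 0, with a message. For a rare disease `g` is close to 0.
#'
#' @inheritParams observed_rate
#' @return An object of class `"residual_risk"`: list with `g`, `m_affected`
#'   and `p_variant_pop`.
#' @examples
#' fr <- variant_frequencies(F = 0.300, S = 0.015, U = 0)
#' residual_risk(fr, disease_context(lifetime_risk = 1 / 400,
#'                                   familiality = 0.05))
#' @export
residual_risk <- function(freqs, context) {
  stopifnot(inherits(freqs, "variant_frequency_set"),
            inherits(context, "disease_context"))
  pa <- context$lifetime_risk
  if (is.null(pa))
    stop("lifetime risk P(A) is required to derive the residual risk g")
  if (!is.null(freqs$A)) {
    m_a <- freqs$A$estimate
  } else {
    if (is.null(freqs$F) || is.null(freqs$S))
      stop("residual risk needs either an affected-state frequency or both ",
           "familial and sporadic frequencies")
    pfa <- context$familiality
    if (is.null(pfa))
      stop("familiality rate P(F|A) is required to pool the familial and ",
           "sporadic frequencies")
    m_a <- freqs$F$estimate * pfa + freqs$S$estimate * (1 - pfa)
  }
  if (is.null(freqs$U)) {
    message("no unaffected-state frequency supplied; assuming M_U = 0")
    m_u <- 0
  } else m_u <- freqs$U$estimate
  p_m_pop <- m_a * pa + m_u * (1 - pa)
  if (p_m_pop >= 1)
    stop("population variant frequency is 1; residual risk undefined")
  g <- pa * (1 - m_a) / (1 - p_m_pop)
  structure(list(g = g, m_affected = m_a, p_variant_pop = p_m_pop),
            class = "residual_risk")
}

#' @export
print.residual_risk <- function(x, ...) {
  cat(sprintf("Residual non-carrier risk g = %.6g (M_A = %.6g, P(M) = %.6g)\n",
              x$g, x$m_affected, x$p_variant_pop))
  invisible(x)
}

#' Standard error from a confidence-interval bound
#'
#' Back-converts a reported confidence interval to a standard error via the
#' normal z-score: `se = (estimate - lower) / z`, with `z` the two-sided
#' quantile for the given level (1.96 at 95%).
#'
#' @param estimate Point estimate.
#' @param ci_lower Lower confidence bound (must not exceed the estimate).
#' @param conf_level Confidence level of the reported interval.
#' @return The implied standard error.
#' @examples
#' se_from_ci(0.300, 0.251) # 0.025
#' @export
se_from_ci <- function(estimate, ci_lower, conf_level = 0.95) {
  if (ci_lower > estimate)
    stop("lower confidence bound exceeds the estimate")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  (estimate - ci_lower) / z
}
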