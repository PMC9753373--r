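#' Per-state variant frequency estimate
#'
#' Records the heterozygous variant frequency in one disease state, either as
#' a decimal estimate with an optional standard error, or as raw counts
#' `k` carriers out of `n` sampled. When counts are given the frequency is
#' kept at full precision (`k/n`), which matters for reproducing rates to
#' three decimals, and a binomial standard error is filled in unless one is
#' supplied. A string of the form `"k/n"` (e.g. `"126/3770"`) is accepted as
#' shorthand for counts.
#'
#' @param estimate Frequency in `[0, 1]`, or a `"k/n"` string.
#' @param se Standard error of the estimate (optional, non-negative).
#' @param k,n Carrier count and sample size (optional; used instead of
#'   `estimate`).
#'
#' @return An object of class `"variant_frequency"` with fields `estimate`,
#'   `se`, `k`, `n`.
#' @examples
#' variant_frequency(0.300, se = 0.025)
#' variant_frequency(k = 126, n = 3770)
#' variant_frequency("130/10898")
#' @export
variant_frequency <- function(estimate = NULL, se = NULL, k = NULL, n = NULL) {
  if (is.character(estimate)) {
    parts <- strsplit(estimate, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("frequency strings must have the form \"k/n\"")
    k <- as.numeric(parts[1]); n <- as.numeric(parts[2])
    estimate <- NULL
  }
  if (!is.null(k) || !is.null(n)) {
    if (is.null(k) || is.null(n) || is.na(k) || is.na(n) || n <= 0 ||
        k < 0 || k > n)
      stop("counts require 0 <= k <= n with n > 0")
    if (!is.null(estimate) && abs(estimate - k / n) >= 1e-12)
      stop("estimate disagrees with k/n")
    estimate <- k / n
    if (is.null(se)) se <- sqrt(estimate * (1 - estimate) / n)
  }
  if (is.null(estimate) || is.na(estimate) || estimate < 0 || estimate > 1)
    stop("frequency estimate must lie in [0, 1]")
  if (!is.null(se) && (is.na(se) || se < 0))
    stop("standard error must be non-negative")
  structure(list(estimate = estimate, se = se, k = k, n = n),
            class = "variant_frequency")
}

#' Per-state variant frequency set
#'
#' Collects [variant_frequency()] records for the disease states with data,
#' named by state letter (`F`, `S`, `U`, `A`). Plain numbers and `"k/n"`
#' strings are promoted to `variant_frequency` objects.
#'
#' @param ... Named arguments, one per state.
#' @return An object of class `"variant_frequency_set"` (a named list).
#' @examples
#' variant_frequencies(F = variant_frequency(0.300, se = 0.025),
#'                     S = variant_frequency(0.015, se = 0.00255))
#' variant_frequencies(F = "126/3770", S = "130/10898", U = "10/21383")
#' @export
variant_frequencies <- function(...) {
  x <- list(...)
  if (length(x) == 0L || is.null(names(x)) || any(names(x) == ""))
    stop("frequencies must be named by state letter (F, S, U, A)")
  names(x) <- toupper(names(x))
  bad <- setdiff(names(x), c("F", "S", "U", "A"))
  if (length(bad)) stop("unknown state(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(x))) stop("duplicated state")
  x <- lapply(x, function(e) {
    if (inherits(e, "variant_frequency")) e else variant_frequency(e)
  })
  structure(x[intersect(c("F", "S", "U", "A"), names(x))],
            class = "variant_frequency_set")
}

#' @export
print.variant_frequency <- function(x, ...) {
  cat(sprintf("M = %.6g", x$estimate))
  if (!is.null(x$k)) cat(sprintf(" (%g/%g)", x$k, x$n))
  if (!is.null(x$se)) cat(sprintf(", se = %.3g", x$se))
  cat("\n")
  invisible(x)
}

#' @export
print.variant_frequency_set <- function(x, ...) {
  for (s in names(x)) { cat(s, ": ", sep = ""); print(x[[s]]) }
  invisible(x)
}

#' Disease context: lifetime risk and familiality rate
#'
#' Population-level disease characteristics used to weight per-state variant
#' frequencies and to derive the residual non-carrier risk: the lifetime risk
#' of the disease in the general population, `P(A)`, and the first-degree
#' familiality rate `P(F|A)`, the proportion of affected people whose disease
#' is familial. The sporadic rate `P(S|A) = 1 - P(F|A)` is always derived,
#' never stored.
#'
#' @param lifetime_risk `P(A)` in `[0, 1]`, or `NULL` if unknown.
#' @param familiality `P(F|A)` in `[0, 1]`, or `NULL` if unknown.
#' @return An object of class `"disease_context"`.
#' @examples
#' disease_context(lifetime_risk = 1 / 400, familiality = 0.05)
#' @export
disease_context <- function(lifetime_risk = NULL, familiality = NULL) {
  for (v in list(lifetime_risk, familiality))
    if (!is.null(v) && (!is.numeric(v) || is.na(v) || v < 0 || v > 1))
      stop("disease context probabilities must lie in [0, 1]")
  structure(list(lifetime_risk = lifetime_risk, familiality = familiality),
            class = "disease_context")
}

#' @export
print.disease_context <- function(x, ...) {
  cat("Lifetime risk P(A):",
      if (is.null(x$lifetime_risk)) "not set" else format(x$lifetime_risk),
      "\nFamiliality P(F|A):",
      if (is.null(x$familiality)) "not set" else format(x$familiality), "\n")
  invisible(x)
}
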