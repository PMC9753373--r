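#' Simulate variant-harbouring nuclear families
#'
#' Generates a synthetic population of nuclear families in which one parent
#' carries the variant, for calibrating the penetrance estimator and for
#' validation. Each family draws a sibship size, transmits the variant to
#' each offspring with probability 1/2, and samples affection independently
#' per member: carriers are affected with probability `f`, non-carriers with
#' probability `g`. The family state counts affected members across the
#' carrier parent, the other parent and all offspring: none affected =
#' unaffected, exactly one = sporadic, two or more = familial.
#'
#' Sibship sizes are integers, yet population-level sibship is typically
#' supplied as a non-integer Total Fertility Rate; by default sizes are drawn
#' from a Poisson distribution with the requested mean. A fixed (rounded)
#' size and a two-point floor/ceiling mixture matching the mean are available
#' as alternatives. The choice matters: under Poisson sibships families with
#' no offspring can never present as familial when `g = 0`, which is the main
#' source of the bias the simulation-based correction removes.
#'
#' @inheritParams state_probabilities
#' @param mean_sibship Target mean sibship size (e.g. a Total Fertility
#'   Rate).
#' @param n_families Number of families to simulate.
#' @param seed Optional integer seed; when supplied the population is fully
#'   reproducible. When `NULL` the current RNG stream is used.
#' @param sibship_dist One of `"poisson"` (default), `"fixed"` (every family
#'   has `round(mean_sibship)` offspring) or `"mixture"` (floor/ceiling
#'   two-point mixture with the exact requested mean).
#'
#' @return A data frame with one row per family: `sibship_size`,
#'   `sib_carriers`, `sib_affected`, `parent_carrier_affected`,
#'   `parent_noncarrier_affected`, `n_affected` and `family_state` (factor
#'   with levels `unaffected`, `sporadic`, `familial`). The call settings are
#'   kept as attributes.
#' @examples
#' fam <- simulate_families(0.5, g = 0, mean_sibship = 2, n_families = 100,
#'                          seed = 1)
#' table(fam$family_state)
#' @export
simulate_families <- function(f, g = 0, mean_sibship, n_families,
                              seed = NULL,
                              sibship_dist = c("poisson", "fixed", "mixture")) {
  sibship_dist <- match.arg(sibship_dist)
  check_model_params(f, g, mean_sibship)
  if (length(f) != 1L) stop("f must be a scalar here")
  if (!is.numeric(n_families) || n_families < 1)
    stop("n_families must be at least 1")
  n_families <- as.integer(n_families)
  if (!is.null(seed)) set.seed(seed)
  k <- switch(sibship_dist,
    poisson = stats::rpois(n_families, mean_sibship),
    fixed = rep.int(as.integer(round(mean_sibship)), n_families),
    mixture = {
      fl <- floor(mean_sibship)
      as.integer(fl) + stats::rbinom(n_families, 1L, mean_sibship - fl)
    })
  sib_car <- stats::rbinom(n_families, k, 0.5)
  aff_car <- stats::rbinom(n_families, sib_car, f)
  aff_non <- stats::rbinom(n_families, k - sib_car, g)
  par_car <- stats::rbinom(n_families, 1L, f)
  par_non <- stats::rbinom(n_families, 1L, g)
  n_aff <- aff_car + aff_non + par_car + par_non
  state <- factor(ifelse(n_aff == 0L, "unaffected",
                  ifelse(n_aff == 1L, "sporadic", "familial")),
                  levels = c("unaffected", "sporadic", "familial"))
  out <- data.frame(sibship_size = k, sib_carriers = sib_car,
                    sib_affected = aff_car + aff_non,
                    parent_carrier_affected = par_car,
                    parent_noncarrier_affected = par_non,
                    n_affected = n_aff, family_state = state)
  attr(out, "settings") <- list(f = f, g = g, mean_sibship = mean_sibship,
                                n_families = n_families, seed = seed,
                                sibship_dist = sibship_dist)
  out
}

#' Rate of the designated state in a simulated population
#'
#' Restricts a simulated population to the families whose state is among the
#' modelled states and returns the share presenting as the designated state
#' `X` — the simulated analogue of the observed rate. For the `{A,U}`
#' combination the sporadic and familial states are pooled as affected.
#'
#' @param families A population from [simulate_families()].
#' @inheritParams expected_rate
#' @return The simulated rate (a proportion).
#' @examples
#' fam <- simulate_families(0.5, g = 0, mean_sibship = 2, n_families = 1000,
#'                          seed = 1)
#' simulated_state_rate(fam, c("F", "S"))
#' @export
simulated_state_rate <- function(families, states, rate_state = NULL) {
  combo <- as_state_combination(states, rate_state)
  lab <- c(F = "familial", S = "sporadic", U = "unaffected")
  st <- as.character(families$family_state)
  if ("A" %in% combo) st[st %in% c("sporadic", "familial")] <- "affected"
  keep_labels <- ifelse(unclass(combo) == "A", "affected",
                        lab[unclass(combo)])
  keep <- st %in% keep_labels
  if (!any(keep))
    stop("no simulated families fall in the modelled states")
  x <- rate_state_of(combo)
  target <- if (x == "A") "affected" else lab[[x]]
  mean(st[keep] == target)
}
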