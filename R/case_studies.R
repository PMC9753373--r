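#' Bundled case-study inputs
#'
#' The published case-study inputs for four variant-disease pairs, as
#' transcribed from the source reports: the LRRK2 p.Gly2019Ser variant for
#' Parkinson's disease (modelled over four disease-state combinations),
#' BMPR2 variants for heritable pulmonary arterial hypertension (two
#' datasets, with the second also split by variant class), and SOD1 variants
#' and the C9orf72 repeat expansion for amyotrophic lateral sclerosis (Asian
#' and European ancestry strata). Where the source supplies raw carrier
#' counts these are stored as counts so frequencies retain full precision.
#' Published result values (residual risk, observed rate and penetrance with
#' confidence intervals) are attached as a `reference` element for
#' comparison; they are never used in estimation.
#'
#' @return A named list of case configurations, each a list with `id`,
#'   `gene`, `disease`, `subset`, `freqs` ([variant_frequencies()]),
#'   `context` ([disease_context()]), `N`, `states` and `reference`.
#' @examples
#' names(case_studies())
#' @export
case_studies <- function() {
  vf <- variant_frequency
  pd <- disease_context(lifetime_risk = 1 / 37, familiality = 0.105)
  pah <- disease_context(lifetime_risk = 1 / 20, familiality = 0.055)
  als <- disease_context(lifetime_risk = 1 / 400, familiality = 0.050)
  lrrk2 <- variant_frequencies(F = vf(k = 126, n = 3770, se = 2.92e-3),
                               S = vf(k = 130, n = 10898, se = 1.04e-3),
                               U = vf(k = 10, n = 21383, se = 1.47e-4))
  cs <- list(
    lrrk2_fsu = list(
      gene = "LRRK2", disease = "PD", subset = "European; states F,S,U",
      freqs = lrrk2, context = pd, N = 1.572, states = c("F", "S", "U"),
      reference = list(g = 0.0267, rate = 0.113, rate_ci = c(0.071, 0.155),
                       f_g0 = 0.37, f_g0_ci = c(0.285, 0.443),
                       f_g = 0.334, f_g_ci = c(0.249, 0.408))),
    lrrk2_fs = list(
      gene = "LRRK2", disease = "PD", subset = "European; states F,S",
      freqs = lrrk2, context = pd, N = 1.572, states = c("F", "S"),
      reference = list(g = 0.0267, rate = 0.247, rate_ci = c(0.202, 0.292),
                       f_g0 = 0.429, f_g0_ci = c(0.348, 0.509),
                       f_g = 0.379, f_g_ci = c(0.299, 0.461))),
    lrrk2_fu = list(
      gene = "LRRK2", disease = "PD", subset = "European; states F,U",
      freqs = lrrk2, context = pd, N = 1.572, states = c("F", "U"),
      reference = list(g = 0.0267, rate = 0.172, rate_ci = c(0.081, 0.264),
                       f_g0 = 0.35, f_g0_ci = c(0.247, 0.428),
                       f_g = 0.32, f_g_ci = c(0.215, 0.399))),
    lrrk2_su = list(
      gene = "LRRK2", disease = "PD", subset = "European; states S,U",
      freqs = lrrk2, context = pd, N = 1.572, states = c("S", "U"),
      reference = list(g = 0.0267, rate = 0.388, rate_ci = c(0.235, 0.541),
                       f_g0 = 0.293, f_g0_ci = c(0.161, 0.45),
                       f_g = 0.275, f_g_ci = c(0.138, 0.438))),
    bmpr2_d1 = list(
      gene = "BMPR2", disease = "PAH", subset = "dataset 1, all variants",
      freqs = variant_frequencies(F = vf(k = 202, n = 247, se = 0.025),
                                  S = vf(k = 200, n = 1174, se = 0.011),
                                  U = 0),
      context = pah, N = 1.543, states = c("F", "S"),
      reference = list(g = 0.0401, rate = 0.218, rate_ci = c(0.195, 0.242),
                       f_g0 = 0.382, f_g0_ci = c(0.339, 0.426),
                       f_g = 0.308, f_g_ci = c(0.266, 0.351))),
    bmpr2_d2 = list(
      gene = "BMPR2", disease = "PAH", subset = "dataset 2, all variants",
      freqs = variant_frequencies(F = vf(k = 40, n = 58, se = 0.061),
                                  S = vf(k = 26, n = 126, se = 0.036),
                                  U = 0),
      context = pah, N = 1.543, states = c("F", "S"),
      reference = list(g = 0.0388, rate = 0.163, rate_ci = c(0.111, 0.215),
                       f_g0 = 0.281, f_g0_ci = c(0.186, 0.376),
                       f_g = 0.212, f_g_ci = c(0.12, 0.305))),
    bmpr2_d2_snv = list(
      gene = "BMPR2", disease = "PAH", subset = "dataset 2, SNVs and indels",
      freqs = variant_frequencies(F = vf(0.569, se = 0.065),
                                  S = vf(0.159, se = 0.033), U = 0),
      context = pah, N = 1.543, states = c("F", "S"),
      reference = list(g = 0.0413, rate = 0.173, rate_ci = c(0.107, 0.238),
                       f_g0 = 0.299, f_g0_ci = c(0.179, 0.419),
                       f_g = 0.225, f_g_ci = c(0.11, 0.342))),
    bmpr2_d2_sv = list(
      gene = "BMPR2", disease = "PAH", subset = "dataset 2, structural",
      freqs = variant_frequencies(F = vf(0.121, se = 0.043),
                                  S = vf(0.048, se = 0.019), U = 0),
      context = pah, N = 1.543, states = c("F", "S"),
      reference = list(g = 0.0475, rate = 0.129, rate_ci = c(0.011, 0.246),
                       f_g0 = 0.218, f_g0_ci = c(0.014, 0.432),
                       f_g = 0.138, f_g_ci = c(0, 0.345))),
    sod1_asian = list(
      gene = "SOD1", disease = "ALS", subset = "Asian",
      freqs = variant_frequencies(F = vf(0.300, se = 0.025),
                                  S = vf(0.015, se = 2.55e-3), U = 0),
      context = als, N = 1.823, states = c("F", "S"),
      reference = list(g = 0.00243, rate = 0.513, rate_ci = c(0.420, 0.606),
                       f_g0 = 0.829, f_g0_ci = c(0.665, 1),
                       f_g = 0.826, f_g_ci = c(0.661, 1))),
    sod1_european = list(
      gene = "SOD1", disease = "ALS", subset = "European",
      freqs = variant_frequencies(F = vf(0.148, se = 0.017),
                                  S = vf(0.012, se = 2.55e-3), U = 0),
      context = als, N = 1.543, states = c("F", "S"),
      reference = list(g = 0.00245, rate = 0.394, rate_ci = c(0.281, 0.506),
                       f_g0 = 0.705, f_g0_ci = c(0.496, 0.933),
                       f_g = 0.701, f_g_ci = c(0.491, 0.926))),
    c9orf72_asian = list(
      gene = "C9orf72", disease = "ALS", subset = "Asian",
      freqs = variant_frequencies(F = vf(0.04, se = 0.010),
                                  S = vf(0.01, se = 5.10e-3), U = 0),
      context = als, N = 1.823, states = c("F", "S"),
      reference = list(g = 0.00247, rate = 0.174, rate_ci = c(0.013, 0.335),
                       f_g0 = 0.263, f_g0_ci = c(0.0156, 0.522),
                       f_g = 0.258, f_g_ci = c(0.0108, 0.518))),
    c9orf72_european = list(
      gene = "C9orf72", disease = "ALS", subset = "European",
      freqs = variant_frequencies(F = vf(0.32, se = 0.020),
                                  S = vf(0.05, se = 5.10e-3), U = 0),
      context = als, N = 1.543, states = c("F", "S"),
      reference = list(g = 0.00234, rate = 0.252, rate_ci = c(0.208, 0.296),
                       f_g0 = 0.443, f_g0_ci = c(0.363, 0.524),
                       f_g = 0.439, f_g_ci = c(0.358, 0.52)))
  )
  for (id in names(cs)) cs[[id]]$id <- id
  cs
}

#' Run the bundled case studies
#'
#' Executes the full estimation pipeline for each bundled case study, once
#' assuming no residual non-carrier risk (`g = 0`) and once with `g` derived
#' by Bayes' theorem, and returns one row per case in the layout of the
#' published results table.
#'
#' @param cases Case list as returned by [case_studies()] (possibly a
#'   subset).
#' @param seed Base seed; case `i` uses `seed + i` for its calibration
#'   simulations so rows are individually reproducible.
#' @param correct_bias Apply the simulation-based correction (disable for a
#'   fast, deterministic steps 1-3 run).
#' @param ... Further arguments passed to [estimate_penetrance()] (e.g.
#'   `n_families`).
#' @return A data frame with the inputs, observed rate and penetrance
#'   estimates (with confidence bounds) per case.
#' @examples
#' \donttest{
#' run_case_studies(case_studies()["sod1_asian"], seed = 1,
#'                  correct_bias = FALSE)
#' }
#' @export
run_case_studies <- function(cases = case_studies(), seed = 1,
                             correct_bias = TRUE, ...) {
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    run <- function(gmode)
      suppressMessages(estimate_penetrance(
        cs$freqs, cs$context, N = cs$N, g = gmode, states = cs$states,
        correct_bias = correct_bias,
        seed = if (is.null(seed)) NULL else seed + i, ...))
    e0 <- run("zero")
    eg <- run("auto")
    data.frame(id = cs$id, gene = cs$gene, disease = cs$disease,
               subset = cs$subset,
               states = paste(cs$states, collapse = ","),
               rate_state = rate_state_of(e0$combo), N = cs$N, g = eg$g,
               rate = e0$observed_rate$rate,
               rate_lower = e0$observed_rate$ci_lower,
               rate_upper = e0$observed_rate$ci_upper,
               f_g0 = e0$f_adjusted, f_g0_lower = e0$ci_lower,
               f_g0_upper = e0$ci_upper,
               f_g = eg$f_adjusted, f_g_lower = eg$ci_lower,
               f_g_upper = eg$ci_upper)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
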