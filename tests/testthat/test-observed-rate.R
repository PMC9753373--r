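test_that("weighting factors follow the state-combination rules", {
  expect_equal(weighting_factors(c("F", "S"),
                                 disease_context(familiality = 0.05)),
               c(F = 0.05, S = 0.95))
  w <- weighting_factors(c("F", "S", "U"),
                         disease_context(lifetime_risk = 0.027,
                                         familiality = 0.105))
  expect_equal(w, c(F = 0.0028350, S = 0.0241650, U = 0.973),
               tolerance = 1e-12)
  expect_equal(weighting_factors(c("A", "U"),
                                 disease_context(lifetime_risk = 1)),
               c(A = 1, U = 0))
  expect_error(weighting_factors(c("F", "U"),
                                 disease_context(familiality = 0.1)),
               "lifetime risk")
  expect_error(weighting_factors(c("F", "S"),
                                 disease_context(lifetime_risk = 0.1)),
               "familiality")
})

test_that("observed rates reproduce the published case-study values", {
  als <- als_context()
  r <- observed_rate(sod1_asian_freqs(), c("F", "S"), als)
  expect_equal(round(r$rate, 3), 0.513)

  pd <- disease_context(lifetime_risk = 1 / 37, familiality = 0.105)
  lrrk2 <- variant_frequencies(F = "126/3770", S = "130/10898",
                               U = "10/21383")
  expect_equal(round(observed_rate(lrrk2, c("F", "S"), pd)$rate, 3), 0.247)
  expect_equal(round(observed_rate(lrrk2, c("F", "S", "U"), pd)$rate, 3),
               0.113)
  # full-precision counts matter: the rounded frequencies give 0.245, not
  # the published 0.247
  lrrk2_rounded <- variant_frequencies(F = 0.033, S = 0.012)
  expect_false(round(observed_rate(lrrk2_rounded, c("F", "S"),
                                   pd)$rate, 3) == 0.247)
})

test_that("a zero frequency in one modelled state pins the rate at 0 or 1", {
  ctx <- disease_context(familiality = 0.05)
  fr <- variant_frequencies(F = 0.3, S = 0)
  expect_equal(observed_rate(fr, c("F", "S"), ctx)$rate, 1)
  fr2 <- variant_frequencies(F = 0, S = 0.3)
  expect_equal(observed_rate(fr2, c("F", "S"), ctx)$rate, 0)
  expect_error(observed_rate(variant_frequencies(F = 0, S = 0),
                             c("F", "S"), ctx), "all weighted frequencies")
  expect_error(observed_rate(variant_frequencies(F = 0.3), c("F", "S"), ctx),
               "no frequency supplied")
})

test_that("residual risk matches the published Bayes-derived values", {
  g_sod1 <- residual_risk(sod1_asian_freqs(), als_context())
  expect_equal(round(g_sod1$g, 5), 0.00243)

  pd <- disease_context(lifetime_risk = 1 / 37, familiality = 0.105)
  lrrk2 <- variant_frequencies(F = "126/3770", S = "130/10898",
                               U = "10/21383")
  expect_equal(round(residual_risk(lrrk2, pd)$g, 4), 0.0267)

  # rare disease, no unaffected carriers: g tends to the lifetime risk scale
  expect_equal(residual_risk(
    variant_frequencies(F = 0.1, S = 0.01, U = 0),
    disease_context(lifetime_risk = 0, familiality = 0.05))$g, 0)
  # an omitted unaffected state is assumed variant-free, with a message
  expect_message(residual_risk(variant_frequencies(F = 0.1, S = 0.01),
                               disease_context(lifetime_risk = 0.01,
                                               familiality = 0.05)),
                 "M_U = 0")
})

test_that("standard errors recovered from confidence bounds use the z-score
          conversion", {
  expect_equal(se_from_ci(0.300, 0.251), 0.025, tolerance = 1e-4)
  expect_equal(se_from_ci(0.4, 0.4), 0)
  expect_equal(se_from_ci(0.32, 0.2808), 0.020, tolerance = 1e-4)
  expect_error(se_from_ci(0.3, 0.31), "exceeds")
})

test_that("delta-method intervals reproduce the published rate intervals", {
  r <- observed_rate(sod1_asian_freqs(), c("F", "S"), als_context())
  expect_equal(r$ci_lower, 0.420, tolerance = 2e-3)
  expect_equal(r$ci_upper, 0.606, tolerance = 2e-3)

  pah <- disease_context(lifetime_risk = 0.05, familiality = 0.055)
  bmpr2 <- variant_frequencies(
    F = variant_frequency(k = 202, n = 247, se = 0.025),
    S = variant_frequency(k = 200, n = 1174, se = 0.011))
  r2 <- observed_rate(bmpr2, c("F", "S"), pah)
  expect_equal(round(r2$rate, 3), 0.218)
  expect_equal(r2$ci_lower, 0.195, tolerance = 5e-3)
  expect_equal(r2$ci_upper, 0.242, tolerance = 5e-3)
})

test_that("rate intervals shrink with the input errors and stay in [0, 1]", {
  ctx <- disease_context(familiality = 0.05)
  fr0 <- variant_frequencies(F = variant_frequency(0.3, se = 0),
                             S = variant_frequency(0.015, se = 0))
  r0 <- observed_rate(fr0, c("F", "S"), ctx)
  expect_equal(r0$se, 0)
  expect_equal(r0$ci_lower, r0$rate)
  expect_equal(r0$ci_upper, r0$rate)

  fr_big <- variant_frequencies(F = variant_frequency(0.3, se = 0.4),
                                S = variant_frequency(0.015, se = 0.4))
  r_big <- observed_rate(fr_big, c("F", "S"), ctx)
  expect_gte(r_big$ci_lower, 0)
  expect_lte(r_big$ci_upper, 1)

  # missing standard error in any modelled state disables propagation
  fr_na <- variant_frequencies(F = variant_frequency(0.3, se = 0.02),
                               S = 0.015)
  expect_true(is.na(observed_rate(fr_na, c("F", "S"), ctx)$se))
})

test_that("frequency constructors validate and keep counts at full
          precision", {
  v <- variant_frequency(k = 126, n = 3770)
  expect_equal(v$estimate, 126 / 3770, tolerance = 1e-15)
  expect_equal(variant_frequency("130/10898")$estimate, 130 / 10898)
  expect_error(variant_frequency(1.2), "\\[0, 1\\]")
  expect_error(variant_frequency(k = 5, n = 2), "k <= n")
  expect_error(variant_frequency(0.5, se = -1), "non-negative")
  expect_error(variant_frequencies(0.5), "named")
  expect_error(variant_frequencies(Q = 0.5), "unknown state")
})
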