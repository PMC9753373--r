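test_that("degenerate penetrance values give the expected family states", {
  p <- state_probabilities(f = 0, g = 0, N = 2)
  expect_equal(unlist(p[c("p_unaffected", "p_sporadic", "p_familial",
                          "p_affected")]),
               c(p_unaffected = 1, p_sporadic = 0, p_familial = 0,
                 p_affected = 0))
  for (N in c(0, 1, 1.823, 4)) {
    expect_equal(state_probabilities(f = 1, g = 0, N = N)$p_unaffected, 0)
  }
})

test_that("state probabilities match frozen high-precision values at a
          non-integer sibship size", {
  p <- state_probabilities(f = 0.75, g = 0, N = 1.823)
  expect_equal(p$p_unaffected, 0.10613, tolerance = 1e-4)
  expect_equal(p$p_sporadic, 0.43447, tolerance = 1e-4)
  expect_equal(p$p_familial, 0.45941, tolerance = 1e-4)
})

test_that("state probabilities match exhaustive enumeration at integer N", {
  cases <- expand.grid(f = c(0.1, 0.5, 0.9), g = c(0, 0.1, 0.4),
                       N = c(0, 1, 2, 4, 6))
  for (i in seq_len(nrow(cases))) {
    f <- cases$f[i]; g <- cases$g[i]; N <- cases$N[i]
    got <- state_probabilities(f, g, N)
    want <- enum_state_probs(f, g, N)
    expect_equal(got$p_unaffected, want[["p_unaffected"]], tolerance = 1e-12)
    expect_equal(got$p_sporadic, want[["p_sporadic"]], tolerance = 1e-12)
    expect_equal(got$p_familial, want[["p_familial"]], tolerance = 1e-12)
  }
})

test_that("unaffected, sporadic and familial probabilities sum to one on a
          parameter grid", {
  fs <- seq(0, 1, length.out = 50)
  gs <- seq(0, 0.98, length.out = 50)
  Ns <- c(0, 1, 1.823, 3, 6)
  for (g in gs) for (N in Ns) {
    p <- state_probabilities(fs, g, N)
    expect_true(all(abs(p$p_unaffected + p$p_sporadic + p$p_familial - 1)
                    < 1e-12))
    expect_true(all(abs(p$p_affected - p$p_sporadic - p$p_familial) < 1e-12))
    expect_true(all(p$p_unaffected >= 0 & p$p_sporadic >= 0 &
                    p$p_familial >= 0))
  }
})

test_that("with no residual risk the model reduces to the variant-necessary
          form", {
  fs <- seq(0, 1, length.out = 21)
  for (N in c(1, 1.543, 2.5)) {
    got <- state_probabilities(fs, g = 0, N = N)
    want <- vapply(fs, gfree_state_probs, numeric(3), N = N)
    expect_equal(got$p_unaffected, unname(want["p_unaffected", ]),
                 tolerance = 1e-12)
    expect_equal(got$p_sporadic, unname(want["p_sporadic", ]),
                 tolerance = 1e-12)
    expect_equal(got$p_familial, unname(want["p_familial", ]),
                 tolerance = 1e-12)
  }
})

test_that("expected rate reproduces the familial share of affected families", {
  expect_equal(expected_rate(0.75, g = 0, N = 1.823, states = c("F", "S")),
               0.51395, tolerance = 1e-4)
  expect_equal(expected_rate(1, g = 0, N = 2, states = c("A", "U")), 1)
  # f -> 0 limit convention over {F,S}: familial rate 0, sporadic rate 1
  expect_equal(expected_rate(0, g = 0, N = 2, states = c("F", "S")), 0)
  expect_equal(expected_rate(0, g = 0, N = 2, states = c("F", "S"),
                             rate_state = "S"), 1)
  # with residual risk the rate is defined at f = 0 without any convention
  expect_gt(expected_rate(0, g = 0.1, N = 2, states = c("F", "S")), 0)
})

test_that("the familial rate over {F,S} is non-decreasing in penetrance", {
  fs <- seq(0, 1, length.out = 401)
  for (g in c(0, 0.05)) for (N in c(1.543, 1.823, 3)) {
    r <- expected_rate(fs, g = g, N = N, states = c("F", "S"))
    expect_true(all(diff(r) >= -1e-12))
  }
})

test_that("invalid model parameters are rejected", {
  expect_error(state_probabilities(1.5, 0, 2), "penetrance")
  expect_error(state_probabilities(0.5, 1, 2), "residual risk")
  expect_error(state_probabilities(0.5, 0, -1), "sibship")
  expect_error(state_combination(c("A", "F")), "invalid state combination")
  expect_error(state_combination(c("F", "S"), rate_state = "U"),
               "not among the modelled states")
})
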