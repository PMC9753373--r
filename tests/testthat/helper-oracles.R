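# Independent oracles for the nuclear-family disease model.

# Exhaustive enumeration of all carrier-transmission and affection outcomes
# for a family of {carrier parent, non-carrier parent, N sibs}. Each sib is
# enumerated over four joint (carrier, affected) outcomes with probabilities
# f/2, (1-f)/2, g/2, (1-g)/2; parents over affected yes/no. Integer N only.
enum_state_probs <- function(f, g, N) {
  stopifnot(N == round(N), N >= 0)
  sib_aff <- c(1, 0, 1, 0)
  sib_p <- c(f / 2, (1 - f) / 2, g / 2, (1 - g) / 2)
  grids <- c(list(caff = 0:1, naff = 0:1),
             rep(list(seq_len(4)), N))
  gr <- as.matrix(expand.grid(grids))
  p <- ifelse(gr[, 1] == 1, f, 1 - f) * ifelse(gr[, 2] == 1, g, 1 - g)
  n_aff <- gr[, 1] + gr[, 2]
  if (N > 0) {
    for (j in seq_len(N) + 2L) {
      p <- p * sib_p[gr[, j]]
      n_aff <- n_aff + sib_aff[gr[, j]]
    }
  }
  c(p_unaffected = sum(p[n_aff == 0]),
    p_sporadic = sum(p[n_aff == 1]),
    p_familial = sum(p[n_aff >= 2]))
}

# Independently coded variant-necessary (g = 0) model: non-carriers are
# never affected, each sib is affected with probability f/2.
gfree_state_probs <- function(f, N) {
  pu <- (1 - f) * (1 - f / 2)^N
  ps <- f * (1 - f / 2)^N + (1 - f) * N * (f / 2) * (1 - f / 2)^(N - 1)
  c(p_unaffected = pu, p_sporadic = ps, p_familial = 1 - pu - ps)
}

# Shared case-study inputs used across test files.
sod1_asian_freqs <- function() {
  variant_frequencies(F = variant_frequency(0.300, se = 0.025),
                      S = variant_frequency(0.015, se = 2.55e-3),
                      U = 0)
}
als_context <- function() {
  disease_context(lifetime_risk = 1 / 400, familiality = 0.05)
}
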