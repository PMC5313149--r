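# Shared fixtures for the suite: small noise-free and noisy synthetic
# campaigns built from the package's own generator.

yd6 <- default_cultivars("YD6")
w14 <- default_cultivars("W14")

# A compact scenario: one cultivar, two N rates, four ranks, one plant.
small_scenario <- function(cultivars = default_cultivars("YD6"),
                           noise_cv = 0, replicates = 1L,
                           ranks = c(1:3, 5L),
                           n_rates = data.frame(
                             n_rate = c("N1", "N3"),
                             ancsh = c(2.2, 3.8),
                             agb = c(2.0, 2.0))) {
  ssa_scenario(cultivars = cultivars, n_rates = n_rates, ranks = ranks,
               replicates = replicates, noise_cv = noise_cv,
               temp_noise_sd = 0)
}

# Noise-free observations that exercise every rank segment (1..3 and
# 4..9), both cultivars, plus the generating truth.
full_noise_free <- function() {
  generate_dataset(
    ssa_scenario(n_rates = data.frame(n_rate = c("N1", "N2", "N3"),
                                      ancsh = c(2.2, 3.1, 3.8),
                                      agb = c(2.0, 2.0, 2.0)),
                 ranks = 1:8, replicates = 1L, noise_cv = 0,
                 temp_noise_sd = 0),
    seed = 42)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual - expected) <= rel_tol * abs(expected)),
              label = sprintf("%s within %g relative of %s",
                              paste(signif(actual, 6), collapse = ", "),
                              rel_tol,
                              paste(signif(expected, 6), collapse = ", ")))
}
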