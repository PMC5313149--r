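test_that("RRMSE matches hand arithmetic and its contract", {
  expect_equal(rrmse(c(10, 20, 30), c(10, 20, 30)), 0)
  expect_equal(rrmse(c(12, 18, 33), c(10, 20, 30)),
               100 * sqrt(17 / 3) / 20, tolerance = 1e-12)
  expect_equal(rrmse(c(12, 18, 33), c(10, 20, 30)), 11.90, tolerance = 1e-3)
  expect_equal(rrmse(11, 10), 10)
  expect_error(rrmse(1:3, 1:2), "equal length")
  expect_error(rrmse(c(1, 2), c(-1, 1)), "positive")
})

test_that("RRMSE is scale invariant", {
  set.seed(21)
  sim <- runif(40, 10, 60)
  obs <- sim * (1 + rnorm(40, sd = 0.1))
  base <- rrmse(sim, obs)
  for (k in c(0.1, 2, 57)) {
    expect_equal(rrmse(k * sim, k * obs), base, tolerance = 1e-10)
  }
})

test_that("pooled RRMSE is not bracketed by group RRMSEs in general", {
  # equal relative errors but very different group means: the pooled
  # normalizer mixes the means while the large-mean group dominates the
  # RMSE, pushing the pooled value above both group values
  sim_a <- c(1.3, 0.7)
  obs_a <- c(1, 1)      # group A: rrmse 30 %
  sim_b <- c(130, 70)
  obs_b <- c(100, 100)  # group B: rrmse 30 %
  pooled <- rrmse(c(sim_a, sim_b), c(obs_a, obs_b))
  grp <- c(rrmse(sim_a, obs_a), rrmse(sim_b, obs_b))
  expect_false(pooled >= min(grp) && pooled <= max(grp))
})

test_that("validation on the model's own noise-free output is exact", {
  d <- full_noise_free()
  rep <- validate_dataset(d$observations, d$truth$cultivars,
                          scenario = d$truth$scenario)
  expect_equal(rep$overall_rrmse, 0, tolerance = 1e-9)
  expect_true(all(rep$by_group$rrmse < 1e-9))
  expect_equal(rep$n_points, nrow(d$observations))
})

test_that("validation RRMSE under noise is reproducible and noise-scaled", {
  spec <- small_scenario(noise_cv = 0.05, replicates = 2L)
  d <- generate_dataset(spec, seed = 202)
  rep <- validate_dataset(d$observations, d$truth$cultivars,
                          scenario = d$truth$scenario)
  d2 <- generate_dataset(spec, seed = 202)
  rep2 <- validate_dataset(d2$observations, d2$truth$cultivars,
                           scenario = d2$truth$scenario)
  expect_equal(rep$overall_rrmse, rep2$overall_rrmse)
  # 5 % multiplicative noise should land the pooled RRMSE near 5 %
  expect_gt(rep$overall_rrmse, 2)
  expect_lt(rep$overall_rrmse, 10)
})

test_that("a direct MaxSSA3 column bypasses the nitrogen equations", {
  d <- full_noise_free()
  direct <- d$truth$groups[, c("cultivar", "n_rate", "max_ssa3")]
  rep <- validate_dataset(d$observations, d$truth$cultivars,
                          scenario = direct)
  expect_equal(rep$overall_rrmse, 0, tolerance = 1e-9)
})

test_that("groups without resolvable inputs are flagged and excluded", {
  d <- generate_dataset(small_scenario(), seed = 8)
  scen <- d$truth$scenario[d$truth$scenario$n_rate == "N1", , drop = FALSE]
  expect_warning(
    rep <- validate_dataset(d$observations, d$truth$cultivars, scen),
    "excluded")
  expect_equal(nrow(rep$skipped), 1L)
  expect_true(all(rep$pairs$n_rate == "N1"))
  bad <- transform(scen, n_rate = "N9")
  expect_error(
    suppressWarnings(
      validate_dataset(d$observations, d$truth$cultivars, bad)),
    "resolvable")
})
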