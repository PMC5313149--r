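test_that("plateau extraction takes the per-group maximum", {
  obs <- data.frame(
    cultivar = "YD6", n_rate = "N3",
    rank = rep(c(2L, 3L), each = 4),
    tt = rep(c(100, 300, 500, 700), 2),
    ssa_deg = c(0, 20, 50, 50.2, 0, 25, 58, 58))
  mx <- extract_max_ssa(obs)
  expect_equal(mx$max_ssa, c(50.2, 58))
  expect_equal(extract_max_ssa(
    transform(obs, ssa_deg = 0))$max_ssa, c(0, 0))
  expect_error(extract_max_ssa(obs[0, ]), "no observations")
})

test_that("normalization yields dimensionless pooled pairs", {
  d <- full_noise_free()
  norm <- normalize_observations(d$observations, d$truth$cultivars)
  expect_equal(nrow(norm), nrow(d$observations))  # pooling conserves points
  expect_true(all(norm$nssa >= 0 & norm$nssa <= 1))
  # plateau points map to y = 1
  expect_equal(max(norm$nssa), 1)
  # a zero-plateau group is skipped with a warning
  obs <- d$observations
  obs$ssa_deg[obs$rank == 1 & obs$cultivar == "YD6"] <- 0
  expect_warning(norm2 <- normalize_observations(obs, d$truth$cultivars),
                 "zero maximum")
  expect_true(all(norm2$rank != 1 | norm2$cultivar != "YD6"))
})

test_that("logistic fit round-trips noise-free generated curves", {
  x <- seq(0, 1, length.out = 50)
  y <- 1 / (1 + 17.62 * exp(-6.88 * x))
  f <- fit_logistic(x, y)
  expect_rel_equal(coef(f), c(ssa_a = 17.62, ssa_b = 6.88), 1e-3)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # invariant to point order
  idx <- sample(length(x))
  f2 <- fit_logistic(x[idx], y[idx])
  expect_equal(coef(f2), coef(f), tolerance = 1e-10)
  expect_error(fit_logistic(c(0.2, 0.8), c(0.1, 0.9)), "at least 3")
})

test_that("logistic fit recovers coefficients under 5 % noise", {
  set.seed(101)
  x <- runif(200)
  y <- 1 / (1 + 17.62 * exp(-6.88 * x)) * (1 + rnorm(200, sd = 0.05))
  f <- fit_logistic(x, y)
  expect_rel_equal(coef(f), c(ssa_a = 17.62, ssa_b = 6.88), 0.10)
  expect_lt(f$r_squared, 1)
})

test_that("power-law fit recovers both cultivars' coefficients exactly", {
  for (cv in list(yd6, w14)) {
    tt <- initial_tt(1:10, cv)  # exact (TT, leaf count) pairs
    leaves <- (1:10) + 2
    f <- fit_leaf_appearance(tt, leaves)
    expect_rel_equal(coef(f),
                     c(phyl_a = cv$phyl_a, phyl_b = cv$phyl_b), 1e-6)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
  }
  expect_error(fit_leaf_appearance(c(100, 200, 300), c(5, 5, 5)),
               "degenerate")
  expect_error(fit_leaf_appearance(c(-1, 200, 300), c(3, 5, 7)),
               "positive")
})

test_that("rank-profile fit recovers the stored segments", {
  f <- fit_rank_profile(1:9, rank_profile_ratio(1:9))
  expect_rel_equal(
    coef(f),
    c(sln_a = 0.1334, sln_b = 0.6054, sln_c = -0.1345, sln_d = 1.3507),
    1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_rank_profile(1:3, rank_profile_ratio(1:3)),
               "second")
  # OLS shift property: +c moves intercepts only
  f2 <- fit_rank_profile(1:9, rank_profile_ratio(1:9) + 0.2)
  expect_equal(coef(f2)[c("sln_a", "sln_c")],
               coef(f)[c("sln_a", "sln_c")], tolerance = 1e-10)
  expect_equal(coef(f2)[c("sln_b", "sln_d")],
               coef(f)[c("sln_b", "sln_d")] + 0.2, tolerance = 1e-10)
})

test_that("group comparison reports p = 1 for identical curves and
           detects gross offsets", {
  x <- rep(seq(0.05, 0.95, length.out = 30), 2)
  y0 <- 1 / (1 + 17.62 * exp(-6.88 * x))
  g <- rep(c("A", "B"), each = 30)
  same <- group_difference_test(x, y0, g)
  expect_equal(same$p_value[same$comparison == "overall"], 1,
               tolerance = 1e-9)
  set.seed(5)
  noise <- rnorm(60, sd = 0.02)
  shifted <- y0 + noise + ifelse(g == "B", 0.2, 0)  # 10x the noise SD
  diffp <- group_difference_test(x, shifted, g)
  expect_lt(diffp$p_value[diffp$comparison == "overall"], 0.05)
  # unequal group sizes are accepted
  keep <- c(rep(TRUE, 30), rep(c(TRUE, FALSE), 15))
  expect_s3_class(group_difference_test(x[keep], shifted[keep], g[keep]),
                  "data.frame")
  expect_error(group_difference_test(x, y0, rep("A", 60)), "2 groups")
})

test_that("full calibration pipeline recovers every stored coefficient
           from noise-free data", {
  d <- full_noise_free()
  scen <- d$truth$scenario
  cal <- calibrate_ssa_model(d$observations, d$truth$cultivars,
                             scenario = scen)
  expect_rel_equal(coef(cal$logistic), c(ssa_a = 17.62, ssa_b = 6.88),
                   1e-3)
  expect_rel_equal(
    coef(cal$profile),
    c(sln_a = 0.1334, sln_b = 0.6054, sln_c = -0.1345, sln_d = 1.3507),
    1e-3)
  expect_equal(cal$logistic$r_squared, 1, tolerance = 1e-6)
  # pooled groups are statistically indistinguishable by construction
  expect_gt(cal$group_test$p_value[cal$group_test$comparison == "overall"],
            0.05)
})
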