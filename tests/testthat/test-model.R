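# Closed-form oracles: ITT_n = ((n+2)/a)^(1/b) etc. evaluated directly
# here, independently of the package's composition path.

test_that("development-window start matches the inverted power law", {
  expect_equal(initial_tt(3, yd6), ((3 + 2) / 0.0583)^(1 / 0.7936),
               tolerance = 1e-12)
  expect_equal(initial_tt(3, yd6), 272.97, tolerance = 1e-4)
  expect_equal(initial_tt(1, yd6), 143.41, tolerance = 1e-4)
  expect_equal(initial_tt(1, w14), 163.79, tolerance = 1e-4)
  # strictly increasing in rank
  itts <- initial_tt(1:9, yd6)
  expect_true(all(diff(itts) > 0))
  expect_error(initial_tt(0, yd6), "rank")
  expect_error(initial_tt(2.5, yd6), "integer")
})

test_that("window length is three appearance intervals and positive", {
  expect_equal(ssa_window(3, yd6),
               ((3 + 5) / 0.0583)^(1 / 0.7936) -
                 ((3 + 2) / 0.0583)^(1 / 0.7936), tolerance = 1e-12)
  expect_equal(ssa_window(3, yd6), 220.57, tolerance = 1e-4)
  expect_equal(ssa_window(1, yd6), 200.07, tolerance = 1e-4)
  for (n in 1:9) {
    expect_equal(ssa_window(n, yd6),
                 initial_tt(n + 3, yd6) - initial_tt(n, yd6),
                 tolerance = 1e-10)
  }
  expect_true(all(ssa_window(1:9, w14) > 0))
})

test_that("normalized thermal time is 0/0.5/1 at start/mid/end", {
  itt <- initial_tt(4, yd6)
  dtt <- ssa_window(4, yd6)
  expect_equal(normalize_tt(itt, 4, yd6), 0)
  expect_equal(normalize_tt(itt + dtt, 4, yd6), 1)
  expect_equal(normalize_tt(itt + dtt / 2, 4, yd6), 0.5)
})

test_that("normalized SSA follows the printed branches", {
  itt <- initial_tt(3, yd6)
  dtt <- ssa_window(3, yd6)
  expect_equal(normalized_ssa(itt - 1, 3, yd6), 0)
  expect_equal(normalized_ssa(itt, 3, yd6), 1 / (1 + 17.62),
               tolerance = 1e-12)
  expect_equal(normalized_ssa(itt + dtt, 3, yd6),
               1 / (1 + 17.62 * exp(-6.88)), tolerance = 1e-12)
  expect_equal(normalized_ssa(itt + dtt + 1, 3, yd6), 1)
  # edge-jump magnitudes of the literal implementation
  lc <- logistic_coeffs()
  expect_equal(normalized_ssa(itt, 3, yd6) - normalized_ssa(itt - 1e-9, 3, yd6),
               1 / (1 + lc$ssa_a), tolerance = 1e-6)
  expect_equal(1 - normalized_ssa(itt + dtt, 3, yd6),
               1 - 1 / (1 + lc$ssa_a * exp(-lc$ssa_b)), tolerance = 1e-12)
})

test_that("normalized SSA is bounded and nondecreasing on dense grids", {
  for (n in c(1L, 4L, 8L)) {
    tt <- seq(0, 1500, by = 1)
    y <- normalized_ssa(tt, n, yd6)
    expect_true(all(y >= 0 & y <= 1))
    expect_true(all(diff(y) >= 0))
  }
})

test_that("rank profile matches the stored piecewise line, peaks at 3", {
  expect_equal(rank_profile_ratio(3), 0.1334 * 3 + 0.6054)
  expect_equal(rank_profile_ratio(1), 0.7388)
  expect_equal(rank_profile_ratio(9), -0.1345 * 9 + 1.3507)
  vals <- rank_profile_ratio(1:9)
  expect_equal(which.max(vals), 3L)
  expect_true(all(diff(vals[1:3]) > 0))
  expect_true(all(diff(vals[4:9]) < 0))
  expect_error(rank_profile_ratio(10), "rank")
  expect_error(rank_profile_ratio(0), "rank")
})

test_that("critical N concentration follows the dilution curve", {
  expect_equal(critical_n_concentration(1.0), 5.18)
  expect_equal(critical_n_concentration(4.0), 5.18 * 4^(-0.52),
               tolerance = 1e-12)
  agb <- seq(0.5, 12, by = 0.5)
  expect_true(all(diff(critical_n_concentration(agb)) < 0))
  expect_error(critical_n_concentration(0), "positive")
})

test_that("nitrogen factor is the ratio clipped at one", {
  expect_equal(nitrogen_factor(2.59, 5.18), 0.5)
  expect_equal(nitrogen_factor(6.0, 5.18), 1)
  expect_equal(nitrogen_factor(5.18, 5.18), 1)
  set.seed(11)
  fn <- nitrogen_factor(runif(100, 0, 8), runif(100, 0.5, 6))
  expect_true(all(fn >= 0 & fn <= 1))
  expect_error(nitrogen_factor(2, 0), "positive")
  expect_equal(nitrogen_factor_for(nitrogen_status(2.59, 1.0)), 0.5)
})

test_that("MaxSSA3 scales the variety parameter by FN", {
  expect_equal(max_ssa3(yd6, 1), 58.0)
  expect_equal(max_ssa3(w14, 1), 50.0)
  expect_equal(max_ssa3(yd6, 0.9), 52.2)
  expect_error(max_ssa3(yd6, 1.2), "fn")
})

test_that("simulated SSA composes curve, profile and nitrogen scaling", {
  end3 <- initial_tt(3, yd6) + ssa_window(3, yd6)
  expect_equal(simulate_ssa(3, end3 + 50, yd6), 58.0 * 1.0056,
               tolerance = 1e-12)
  expect_equal(simulate_ssa(5, 2000, yd6), 58.0 * rank_profile_ratio(5),
               tolerance = 1e-12)
  expect_equal(simulate_ssa(5, initial_tt(5, yd6) - 1, yd6), 0)
  # plateau bound with equality beyond the window
  for (n in c(2L, 6L)) {
    tt <- seq(0, 2000, by = 10)
    cap <- yd6$mmax_ssa3 * rank_profile_ratio(n)
    expect_true(all(simulate_ssa(n, tt, yd6) <= cap + 1e-12))
  }
  # nondecreasing in FN at fixed (n, tt)
  fns <- seq(0, 1, by = 0.1)
  mid <- initial_tt(4, yd6) + 0.4 * ssa_window(4, yd6)
  ys <- vapply(fns, function(f) simulate_ssa(4, mid, yd6, fn = f),
               numeric(1))
  expect_true(all(diff(ys) >= 0))
})

test_that("leaf count inverts the window-start relation", {
  expect_equal(leaf_count_at(initial_tt(3, yd6), yd6), 5, tolerance = 1e-10)
  expect_equal(leaf_count_at(0, yd6), 0)
  for (n in 1:6) {
    expect_equal(leaf_count_at(initial_tt(n, w14), w14), n + 2,
                 tolerance = 1e-10)
  }
})
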