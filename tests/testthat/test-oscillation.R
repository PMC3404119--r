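test_that("find_peaks recovers sine maxima to sub-grid accuracy", {
  t <- seq(0, 3, by = 0.001)
  pk <- find_peaks(sin(2 * pi * t), t)
  expect_equal(pk$time, c(0.25, 1.25, 2.25), tolerance = 1e-4)
  expect_equal(pk$value, rep(1, 3), tolerance = 1e-6)
})

test_that("constant signals have no peaks and plateaus report midpoints", {
  expect_identical(nrow(find_peaks(rep(2, 100))), 0L)
  x <- c(0, 1, 2, 3, 3, 3, 2, 1, 0)
  pk <- find_peaks(x, seq_along(x))
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$time, 5)  # midpoint of the plateau at indices 4:6
  expect_equal(pk$value, 3)
})

test_that("successive peaks of a damped cosine decay by exp(-period)", {
  t <- seq(0, 5, by = 0.0005)
  pk <- find_peaks(exp(-t) * cos(2 * pi * t), t)
  ratios <- pk$value[-1] / pk$value[-nrow(pk)]
  expect_equal(ratios, rep(exp(-1), length(ratios)), tolerance = 1e-3)
})

test_that("summarize recovers exact period and amplitude of a pure sine", {
  t <- seq(0, 30, by = 0.002)
  tr <- segclock:::new_trajectory(t, cbind(5 + 2 * sin(2 * pi * t)), "x")
  s <- summarize_oscillation(tr, "x")
  expect_identical(s$classification, "sustained")
  expect_equal(s$period, 1, tolerance = 1e-4)
  expect_equal(s$amplitude, 4, tolerance = 1e-4)
})

test_that("period estimates are invariant to the analysis window phase", {
  tr <- wt_sim()
  base <- summarize_oscillation(tr, "total_her1")$period
  # drop a non-integer number of cycles from the start of the grid
  for (shift in c(0.37, 1.61)) {
    keep <- tr$times >= shift
    shifted <- segclock:::new_trajectory(tr$times[keep],
                                         tr$states[keep, , drop = FALSE],
                                         tr$labels,
                                         params = attr(tr, "params"))
    expect_lt(abs(summarize_oscillation(shifted, "total_her1")$period -
                    base) / base, 0.001)
  }
})

test_that("classification matches the mutant physiology", {
  s7 <- summarize_oscillation(cached_sim("her7",
                                         make_mutant(clock_params(),
                                                     "her7")),
                              "total_her1")
  expect_identical(s7$classification, "damped")
  expect_identical(s7$amplitude, 0)  # asymptotic amplitude
  expect_true(is.na(s7$period))
  expect_gt(s7$damped_period, 0)
  sz <- summarize_oscillation(cached_sim("zero",
                                         clock_params(kappa1 = 0,
                                                      kappa7 = 0,
                                                      kappa6 = 0)),
                              "total_her1")
  expect_identical(sz$classification, "fixed_point")
})

test_that("sustained/damped boundary decisions are stable under dt halving", {
  p7 <- make_mutant(clock_params(), "her7")
  s1 <- summarize_oscillation(simulate_clock(p7, dt = 0.01), "total_her1")
  s2 <- summarize_oscillation(simulate_clock(p7, dt = 0.005), "total_her1")
  expect_identical(s1$classification, s2$classification)
  wt1 <- summarize_oscillation(simulate_clock(clock_params(), dt = 0.005),
                               "total_her1")
  expect_identical(wt1$classification, wt_summary()$classification)
})

test_that("short trajectories are rejected with guidance", {
  t <- seq(0, 5, by = 0.01)
  tr <- segclock:::new_trajectory(t, cbind(sin(2 * pi * t)), "x")
  expect_error(summarize_oscillation(tr, "x"), "extend t_end")
})

test_that("percent_period_change is signed and guards non-sustained input", {
  wt <- clock_params()
  expect_equal(percent_period_change(wt, wt), 0)
  het <- percent_period_change(make_mutant(wt, "hes6_het"), wt)
  expect_gt(het, 0)  # heterozygote slower than wildtype
  expect_error(percent_period_change(make_mutant(wt, "her7"), wt),
               "sustain")
})
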