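test_that("repression follows the single-Hill form in d11 + d67", {
  expect_identical(repression(0, 0, 2), 1)
  # the combined dimer level at threshold halves production for any n
  for (n in c(1, 2, 3.5)) expect_equal(repression(0.5, 0.5, n), 0.5)
  expect_equal(repression(10, 0, 2), 1 / 101)
  expect_error(repression(-1, 0, 2), ">= 0")
})

test_that("minimal RHS matches the written equations at corner states", {
  p <- clock_params()
  z <- numeric(3)
  expect_equal(clock_rhs(z, z, z, p), c(p$kappa1, p$kappa6, p$kappa7))
  p0 <- clock_params(kappa1 = 0, kappa7 = 0, kappa6 = 0, delta = 2)
  expect_equal(clock_rhs(rep(1, 3), z, z, p0), rep(-1 - 3 * 2, 3))
  # the Hes6 equation carries no delay and no repression: derivatives are
  # invariant under changes of the delayed states
  d1 <- clock_rhs(c(1, 2, 3), c(1, 1, 1), c(2, 2, 2), p)
  d2 <- clock_rhs(c(1, 2, 3), c(5, 0, 1), c(0, 3, 3), p)
  expect_identical(d1[2], d2[2])
  expect_false(d1[1] == d2[1])
})

test_that("mutants zero (or halve) the production of the mutated genes", {
  wt <- clock_params()
  expect_equal(make_mutant(wt, "her7")$kappa7, 0)
  expect_equal(make_mutant(wt, "her7")$kappa1, wt$kappa1)
  expect_equal(make_mutant(wt, "hes6")$kappa6, 0)
  expect_equal(unclass(make_mutant(wt, "wildtype")), unclass(wt))
  d <- make_mutant(wt, "her1;her7")
  expect_equal(c(d$kappa1, d$kappa7, d$kappa6), c(0, 0, 90))
  expect_equal(make_mutant(wt, "hes6_het")$kappa6, 45)
  expect_error(make_mutant(wt, "her9"))
})

test_that("total protein counts monomers in every equilibrium dimer", {
  for (f in c("her1", "her7", "hes6"))
    expect_identical(total_protein(c(0, 0, 0), f), 0)
  expect_identical(total_protein(c(1, 0, 0), "her1"), 3)
  expect_identical(total_protein(c(1, 1, 1), "hes6"), 5)
  # hand evaluation at an asymmetric state: h = (2, 1, 3)
  expect_identical(total_protein(c(2, 1, 3), "her1"), 2 + 8 + 2 + 6)
  expect_identical(total_protein(c(2, 1, 3), "her7"), 3 + 18 + 6 + 3)
})

test_that("components stay within the production-bounded box", {
  p <- clock_params()
  tr <- wt_sim()
  expect_true(all(tr$states >= 0))
  expect_true(all(tr$states[, "h1"] <= p$kappa1))
  expect_true(all(tr$states[, "h6"] <= p$kappa6))
  expect_true(all(tr$states[, "h7"] <= p$kappa7))
  expect_equal(attr(tr, "n_clamped"), 0, ignore_attr = TRUE)
})

test_that("zero production decays to the empty state", {
  p0 <- clock_params(kappa1 = 0, kappa7 = 0, kappa6 = 0)
  tr <- cached_sim("zero", p0)
  expect_lt(max(tail(tr$states, 1)), 1e-10)
  s <- summarize_oscillation(tr, "total_her1")
  expect_identical(s$classification, "fixed_point")
})

test_that("wildtype oscillates sustainably; total Hes6 oscillates despite constant production", {
  s <- wt_summary()
  expect_identical(s$classification, "sustained")
  expect_gt(s$period, 0)
  s6 <- summarize_oscillation(wt_sim(), "total_hes6")
  expect_identical(s6$classification, "sustained")
  expect_gt(s6$amplitude, 0)
})

test_that("effective degradation averages the per-capita loss rate", {
  tr0 <- constant_trajectory(c(0, 0, 0))
  e0 <- effective_degradation(tr0, clock_params(), "her1")
  expect_equal(e0$rate, 1)
  expect_equal(e0$half_life, log(2))
  tr1 <- constant_trajectory(c(1, 1, 1))
  e1 <- effective_degradation(tr1, clock_params(), "her1")
  expect_equal(e1$rate, 4)
  expect_equal(e1$half_life, log(2) / 4)
  # losing Hes6 stabilizes the oscillating proteins
  ewt <- effective_degradation(wt_sim(), clock_params(), "her1")
  tr6 <- cached_sim("hes6", make_mutant(clock_params(), "hes6"))
  e6 <- effective_degradation(tr6, make_mutant(clock_params(), "hes6"),
                              "her1")
  expect_gt(ewt$rate, e6$rate)
})

test_that("the stoichiometric factor-2 variant changes numbers, not the phenotypes", {
  p2 <- clock_params(homodimer_double_loss = TRUE)
  s <- summarize_oscillation(cached_sim("wt_h2", p2), "total_her1")
  expect_identical(s$classification, "sustained")
  s6 <- summarize_oscillation(cached_sim("hes6_h2", make_mutant(p2, "hes6")),
                              "total_her1")
  expect_identical(s6$classification, "sustained")
  expect_gt(s6$period, s$period)  # hes6 mutant still slower
})

test_that("parameter configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("kappa6: 45", "tau1: 1.04"), path)
  p <- read_clock_config(path)
  expect_equal(p$kappa6, 45)
  expect_equal(p$tau1, 1.04)
  expect_equal(p$kappa1, 10)  # untouched defaults
  writeLines("kappa9: 1", path)
  expect_error(read_clock_config(path), "unknown parameter")
})

test_that("parameter validation rejects nonsense", {
  expect_error(clock_params(kappa1 = -1), ">= 0")
  expect_error(clock_params(n = 0.5), "n must be >= 1")
  expect_error(clock_params(tau1 = NA), "finite")
})
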