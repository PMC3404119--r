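test_that("per-embryo periods are OLS slopes of time on somite index", {
  expect_equal(fit_period(2:5, c(0, 25, 50, 75)), 25)
  # hand OLS on slightly noisy points: slope 125/5 = 25
  expect_equal(fit_period(2:5, c(0, 24, 52, 74)), 25)
  expect_error(fit_period(2:3, c(0, 25)), "at least 3")
  expect_error(fit_period(2:5, c(0, 25, 20, 75)), "increase strictly")
})

test_that("period fits are invariant to time origin and index offsets", {
  t <- c(0, 24, 52, 74)
  base <- fit_period(2:5, t)
  expect_equal(fit_period(2:5, t + 1000), base)
  expect_equal(fit_period(12:15, t), base)
})

test_that("normalization divides by the control mean within each batch", {
  est <- data.frame(embryo_id = paste0("e", 1:3),
                    batch = "b1",
                    genotype = c("wildtype", "wildtype", "hes6"),
                    period_min = c(24, 26, 30),
                    n_somites = 10, normalized_period = NA)
  out <- normalize_periods(est)
  expect_equal(out$normalized_period, c(0.96, 1.04, 1.2))
  expect_equal(mean(out$normalized_period[out$genotype == "wildtype"]), 1)
  # idempotence against the already-normalized values
  est2 <- out
  est2$period_min <- out$normalized_period
  expect_equal(normalize_periods(est2)$normalized_period,
               out$normalized_period)
  # all-equal periods normalize to exactly one
  est$period_min <- rep(25, 3)
  expect_true(all(normalize_periods(est)$normalized_period == 1))
  est$genotype <- "hes6"
  expect_error(normalize_periods(est), "control")
})

test_that("batch structure is respected in normalization", {
  est <- data.frame(embryo_id = paste0("e", 1:4),
                    batch = c("b1", "b1", "b2", "b2"),
                    genotype = c("wildtype", "hes6", "wildtype", "hes6"),
                    period_min = c(20, 22, 30, 33),
                    n_somites = 10, normalized_period = NA)
  out <- normalize_periods(est)
  expect_equal(out$normalized_period[out$genotype == "hes6"],
               c(1.1, 1.1))
})

test_that("group comparison matches exact Mann-Whitney enumeration", {
  # n = 3 vs 3 with complete separation: U = 0, exact two-tailed
  # p = 2 * (1 / choose(6, 3)) = 0.1
  cmp <- compare_periods(c(1, 2, 3), c(10, 11, 12))
  expect_equal(cmp$p_value, 0.1)
  same <- suppressWarnings(compare_periods(c(1, 2, 3), c(1, 2, 3)))
  expect_gt(same$p_value, 0.99)
  x <- c(1.0, 1.1, 0.9, 1.05)
  ci <- compare_periods(x, x + 1)$ci_a
  expect_equal(ci, mean(x) + c(-1, 1) * 1.96 * sd(x) / 2)
  expect_error(compare_periods(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("boundary tables round-trip through TSV and feed the pipeline", {
  b <- gen_boundary_table(c(wildtype = 24, hes6 = 25.44), n_embryos = 4,
                          somite_range = 2:10, timing_sd = 0.5, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_boundaries_tsv(b, path)
  back <- read_boundaries_tsv(path)
  est <- normalize_periods(fit_periods(back))
  expect_identical(nrow(est), 8L)
  expect_equal(mean(est$normalized_period[est$genotype == "wildtype"]), 1)
})

test_that("synthetic cohorts with a 6% period gap are recovered and detected", {
  base <- 24
  b <- gen_boundary_table(c(wildtype = base, hes6 = 1.06 * base),
                          n_embryos = 25, somite_range = 2:17,
                          timing_sd = 0.03 * base, seed = 11)
  est <- normalize_periods(fit_periods(b))
  hes6 <- est$normalized_period[est$genotype == "hes6"]
  wt <- est$normalized_period[est$genotype == "wildtype"]
  cmp <- compare_periods(hes6, wt, labels = c("hes6", "wildtype"))
  # truth 1.06 lies inside the 95% CI of the recovered mean
  expect_gte(1.06, cmp$ci_a[1])
  expect_lte(1.06, cmp$ci_a[2])
  expect_lt(cmp$p_value, 0.01)
})
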