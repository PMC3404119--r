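test_that("exact linear series give exact slopes with zero error", {
  s <- binding_series("x", 1:6, 0.5 * (1:6))
  fit <- fit_relative_affinity(s)
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$stderr, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # background offsets leave the slope unchanged
  s2 <- binding_series("x", 1:6, 3 + 0.5 * (1:6))
  expect_equal(fit_relative_affinity(s2)$slope, 0.5)
})

test_that("noise-free synthetic series recover true slope ratios exactly", {
  set <- gen_binding_series(c(strong = 2, weak = 0.5), noise_cv = 0,
                            seed = 1)
  fs <- fit_relative_affinity(set$strong)
  fw <- fit_relative_affinity(set$weak)
  expect_equal(fs$slope / fw$slope, 4, tolerance = 1e-10)
})

test_that("non-binding probes fit slope 0 and degenerate input errors", {
  s <- binding_series("pparg", 1:5, rep(0, 5))
  expect_equal(fit_relative_affinity(s)$slope, 0)
  expect_error(fit_relative_affinity(binding_series("z", rep(2, 4), 1:4)),
               "zero variance")
  expect_error(binding_series("short", 1:2, 1:2), "at least 3")
})

test_that("normalization pins the strongest interaction at one", {
  df <- data.frame(probe_id = c("a", "b", "c"), slope = c(2, 1, 0.5),
                   stderr = 0.1, r_squared = 1, normalized = NA,
                   group = NA)
  expect_equal(normalize_affinities(df)$normalized, c(1, 0.5, 0.25))
  single <- df[1, ]
  expect_equal(normalize_affinities(single)$normalized, 1)
  df$slope[3] <- -0.2
  expect_warning(out <- normalize_affinities(df), "clamped")
  expect_equal(out$normalized[3], 0)
  df$slope <- 0
  expect_error(suppressWarnings(normalize_affinities(df)), "all slopes")
})

test_that("normalized affinities are invariant to common signal scaling", {
  truth <- c(a = 1.5, b = 0.6, c = 0.2)
  set <- gen_binding_series(truth, noise_cv = 0.05, seed = 7)
  fits1 <- normalize_affinities(lapply(set, fit_relative_affinity))
  scaled <- lapply(set, function(s)
    binding_series(s$probe_id, 37 * s$free, 37 * s$bound))
  fits2 <- normalize_affinities(lapply(scaled, fit_relative_affinity))
  expect_equal(fits1$normalized, fits2$normalized, tolerance = 1e-10)
})

test_that("slope comparison follows the normal z-test", {
  same <- list(slope = 1, stderr = 0.1)
  expect_equal(compare_slopes(same, same), 1)
  strong <- list(slope = 1, stderr = 0.01)
  null_ <- list(slope = 0, stderr = 0.01)
  expect_lt(compare_slopes(strong, null_), 1e-10)
  a <- list(slope = 1, stderr = 0.5); b <- list(slope = 0.9, stderr = 0.5)
  expect_equal(compare_slopes(a, b),
               2 * pnorm(-0.1 / sqrt(0.5)), tolerance = 1e-12)
  expect_gt(compare_slopes(a, b), 0.05)
  expect_error(compare_slopes(list(slope = 1, stderr = 0), b), "positive")
})

test_that("library ranking collapses the degenerate position into CACGNG", {
  cores <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             c("A", "C", "G", "T")), 1, paste,
                 collapse = "")
  cores <- paste0("CAC", cores)
  truth <- setNames(rep(0.05, 64), cores)
  truth["CACGTG"] <- 1
  truth["CACGCG"] <- 0.8
  truth["CACGAG"] <- 0.45
  truth["CACGGG"] <- 0.45
  set <- gen_binding_series(truth, noise_cv = 0.02, seed = 3)
  rl <- rank_library(lapply(set, fit_relative_affinity))
  expect_identical(rl$best_core, "CACGNG")
  expect_identical(rl$top_sequence, "CACGTG")
  expect_true(rl$consensus)
  # uniform affinities: no consensus callable
  uni <- gen_binding_series(setNames(rep(0.5, 64), cores), noise_cv = 0.02,
                            seed = 4)
  expect_warning(rl2 <- rank_library(lapply(uni, fit_relative_affinity)),
                 "no clear consensus")
  expect_false(rl2$consensus)
  # missing permutations flagged
  w <- capture_warnings(rank_library(normalize_affinities(
    lapply(set[1:10], fit_relative_affinity))))
  expect_true(any(grepl("missing", w)))
})

test_that("binding series round-trip through TSV", {
  set <- gen_binding_series(c(p1 = 1, p2 = 0.3), noise_cv = 0.1, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_binding_tsv(set, path)
  back <- read_binding_tsv(path)
  expect_setequal(names(back), names(set))
  expect_equal(back$p1$bound, set$p1$bound, tolerance = 1e-8)
})
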