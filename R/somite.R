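#' Fit the somitogenesis period of one embryo
#'
#' The per-embryo period in minutes per somite is the ordinary
#' least-squares slope of boundary-formation time on somite index. The fit
#' is invariant to uniform time shifts and to relabeling somite indices by
#' a constant offset.
#'
#' @param somite_index Integer somite indices (contiguous range, e.g. 2:17).
#' @param time_min Boundary-formation times in minutes, strictly increasing
#'   with somite index.
#' @param embryo_id Optional id used in error messages.
#' @return Period in minutes per somite (the fitted slope).
#' @examples
#' fit_period(2:5, c(0, 25, 50, 75)) # 25
#' @export
fit_period <- function(somite_index, time_min, embryo_id = "embryo") {
  if (length(somite_index) != length(time_min))
    stop("somite_index and time_min must have equal length")
  if (length(somite_index) < 3L)
    stop("embryo '", embryo_id,
         "': at least 3 boundaries are required to fit a period")
  o <- order(somite_index)
  somite_index <- somite_index[o]; time_min <- time_min[o]
  if (any(diff(time_min) <= 0))
    stop("embryo '", embryo_id,
         "': formation times must increase strictly with somite index")
  unname(stats::coef(stats::lm(time_min ~ somite_index))[2])
}

#' Fit periods for every embryo of a boundary table
#'
#' @param boundaries Data.frame with columns `embryo_id`, `batch`,
#'   `genotype`, `somite_index`, `time_min` (one row per boundary).
#'   `genotype` may be withheld (all `NA`) to support blind analysis and
#'   merged in later.
#' @return A data.frame of `period_estimates` with one row per embryo:
#'   `embryo_id`, `batch`, `genotype`, `period_min`, `n_somites`,
#'   `normalized_period` (`NA` until [normalize_periods()]).
#' @export
fit_periods <- function(boundaries) {
  need <- c("embryo_id", "batch", "somite_index", "time_min")
  if (!all(need %in% names(boundaries)))
    stop("boundary table needs columns: ", paste(need, collapse = ", "))
  if (!"genotype" %in% names(boundaries))
    boundaries$genotype <- NA_character_
  sp <- split(boundaries, boundaries$embryo_id)
  rows <- lapply(sp, function(d)
    data.frame(embryo_id = d$embryo_id[1], batch = d$batch[1],
               genotype = d$genotype[1],
               period_min = fit_period(d$somite_index, d$time_min,
                                       d$embryo_id[1]),
               n_somites = nrow(d), normalized_period = NA_real_))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize periods to the control-group mean within each batch
#'
#' Divides every per-embryo period by the mean period of the control
#' genotype measured in the same experimental batch, yielding the
#' dimensionless normalized somitogenesis period (control mean 1 by
#' construction). Normalizing already-normalized values against their own
#' control is idempotent.
#'
#' @param estimates Data.frame from [fit_periods()].
#' @param control_group Genotype label of the control population.
#' @return The estimates with `normalized_period` filled.
#' @export
normalize_periods <- function(estimates, control_group = "wildtype") {
  stopifnot(all(c("genotype", "batch", "period_min") %in% names(estimates)))
  out <- lapply(split(estimates, estimates$batch), function(d) {
    ctrl <- d$period_min[d$genotype == control_group]
    if (!length(ctrl))
      stop("batch '", d$batch[1], "' has no '", control_group,
           "' control embryos")
    d$normalized_period <- d$period_min / mean(ctrl)
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare normalized periods between two genotype groups
#'
#' Two-tailed Mann-Whitney U test (exact for small untied samples, normal
#' approximation with tie correction otherwise) plus normal-theory 95%
#' confidence intervals of each group mean (`mean +/- 1.96 sd / sqrt(n)`).
#'
#' @param a,b Numeric vectors of per-embryo (normalized) periods, each of
#'   length >= 3.
#' @param labels Length-2 character labels for reporting.
#' @return A `period_comparison`: list with `p_value`, `mean_a`, `mean_b`,
#'   `ci_a`, `ci_b`, `n_a`, `n_b`, `labels`.
#' @examples
#' compare_periods(c(1, 2, 3), c(10, 11, 12))$p_value # exact 0.1
#' @export
compare_periods <- function(a, b, labels = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 embryos")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = NULL, correct = TRUE))
  ci <- function(x)
    mean(x) + c(-1, 1) * 1.96 * stats::sd(x) / sqrt(length(x))
  structure(list(p_value = wt$p.value, mean_a = mean(a), mean_b = mean(b),
                 ci_a = ci(a), ci_b = ci(b), n_a = length(a),
                 n_b = length(b), labels = labels),
            class = "period_comparison")
}

#' @export
print.period_comparison <- function(x, ...) {
  cat(sprintf("%s: mean %.4f [%.4f, %.4f] (n=%d)\n", x$labels[1], x$mean_a,
              x$ci_a[1], x$ci_a[2], x$n_a))
  cat(sprintf("%s: mean %.4f [%.4f, %.4f] (n=%d)\n", x$labels[2], x$mean_b,
              x$ci_b[1], x$ci_b[2], x$n_b))
  cat(sprintf("Mann-Whitney U (two-tailed): p = %.4g\n", x$p_value))
  invisible(x)
}

#' Read / write boundary tables as TSV
#'
#' Columns: `embryo_id`, `batch`, `genotype`, `somite_index`, `time_min`.
#' @param boundaries Data.frame of boundary records.
#' @param path File path.
#' @return `read_boundaries_tsv` returns the data.frame.
#' @export
write_boundaries_tsv <- function(boundaries, path) {
  utils::write.table(boundaries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_boundaries_tsv
#' @export
read_boundaries_tsv <- function(path) {
  utils::read.delim(path)
}
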