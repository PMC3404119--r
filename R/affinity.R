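#' Construct a binding titration series
#'
#' Paired free-signal / bound-signal fluorescence measurements for one
#' probe (a protein pair or a DNA 12-mer), assumed to lie in the linear
#' (sub-Kd) regime where bound signal is proportional to free signal with a
#' slope proportional to 1/Kd.
#'
#' @param probe_id Probe label.
#' @param free,bound Non-negative matched signal vectors, length >= 3.
#' @param group Optional library / promoter tag.
#' @return An object of class `binding_series`.
#' @export
binding_series <- function(probe_id, free, bound, group = NA_character_) {
  free <- as.numeric(free); bound <- as.numeric(bound)
  if (length(free) != length(bound))
    stop("free and bound signals must have equal length")
  if (length(free) < 3L) stop("a binding series needs at least 3 points")
  if (any(free < 0) || any(bound < 0)) stop("signals must be >= 0")
  structure(list(probe_id = as.character(probe_id), free = free,
                 bound = bound, group = group),
            class = "binding_series")
}

#' @export
print.binding_series <- function(x, ...) {
  cat("Binding series '", x$probe_id, "': ", length(x$free),
      " points, free in [", format(min(x$free)), ", ",
      format(max(x$free)), "]\n", sep = "")
  invisible(x)
}

#' Fit a relative affinity as the slope of the free-vs-bound line
#'
#' Ordinary least squares of bound signal on free signal, with intercept
#' (constant background fluorescence does not bias the slope). In the
#' linear regime the slope is proportional to 1/Kd, so slope ratios report
#' relative affinities.
#'
#' @param series A [binding_series()], optionally truncated by `max_free`.
#' @param max_free Optional cutoff dropping points with free signal above
#'   this value (saturation guard).
#' @return A `relative_affinity`: list with `probe_id`, `slope`, `stderr`,
#'   `r_squared`, `normalized` (`NA` until [normalize_affinities()]),
#'   `group`.
#' @examples
#' s <- binding_series("x", 1:5, 0.5 * (1:5))
#' fit_relative_affinity(s)$slope # 0.5
#' @export
fit_relative_affinity <- function(series, max_free = NULL) {
  stopifnot(inherits(series, "binding_series"))
  free <- series$free; bound <- series$bound
  if (!is.null(max_free)) {
    keep <- free <= max_free
    if (sum(keep) < 3L) stop("fewer than 3 points below max_free")
    free <- free[keep]; bound <- bound[keep]
  }
  if (stats::var(free) == 0)
    stop("free signal has zero variance for probe '", series$probe_id, "'")
  fit <- stats::lm(bound ~ free)
  # summary.lm warns on exact fits (stderr 0), a legitimate case here
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  co <- sm$coefficients
  structure(list(probe_id = series$probe_id,
                 slope = unname(co["free", "Estimate"]),
                 stderr = unname(co["free", "Std. Error"]),
                 r_squared = sm$r.squared,
                 normalized = NA_real_, group = series$group),
            class = "relative_affinity")
}

#' @export
print.relative_affinity <- function(x, ...) {
  cat(sprintf("Relative affinity '%s': slope %.4g +/- %.3g (R^2 %.3f)%s\n",
              x$probe_id, x$slope, x$stderr, x$r_squared,
              if (is.na(x$normalized)) ""
              else sprintf(", normalized %.3f", x$normalized)))
  invisible(x)
}

#' @export
#' @method as.data.frame relative_affinity
as.data.frame.relative_affinity <- function(x, ...) {
  data.frame(probe_id = x$probe_id, slope = x$slope, stderr = x$stderr,
             r_squared = x$r_squared, normalized = x$normalized,
             group = x$group)
}

affinity_table <- function(x) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, "relative_affinity")) return(as.data.frame(x))
  do.call(rbind, lapply(x, as.data.frame))
}

#' Normalize a set of relative affinities to its strongest interaction
#'
#' Divides every slope by the maximum slope of the set, so the strongest
#' interaction gets normalized affinity 1 (ties share it). Negative fitted
#' slopes — which arise only from noise around zero binding — are clamped
#' to 0 with a warning.
#'
#' @param x A list of `relative_affinity` objects or the corresponding
#'   data.frame.
#' @return A data.frame with the `normalized` column filled, ordered as the
#'   input.
#' @examples
#' df <- data.frame(probe_id = c("a", "b"), slope = c(2, 1),
#'                  stderr = 0.1, r_squared = 1, normalized = NA,
#'                  group = NA)
#' normalize_affinities(df)$normalized # 1, 0.5
#' @export
normalize_affinities <- function(x) {
  df <- affinity_table(x)
  if (nrow(df) == 0L) stop("empty affinity set")
  if (any(df$slope < 0)) {
    warning(sum(df$slope < 0),
            " negative slope(s) clamped to 0 (noise around zero binding)")
    df$slope[df$slope < 0] <- 0
  }
  mx <- max(df$slope)
  if (mx <= 0) stop("all slopes are zero; cannot normalize")
  df$normalized <- df$slope / mx
  df
}

#' Compare two fitted slopes with a two-sided z-test
#'
#' Tests equality of two independent fitted slopes using the combined
#' standard error: `z = (slope_a - slope_b) / sqrt(se_a^2 + se_b^2)`
#' against the standard normal.
#'
#' @param a,b `relative_affinity` objects (or lists with `slope` and
#'   `stderr`), both with `stderr > 0`.
#' @return Two-sided p-value.
#' @examples
#' a <- list(slope = 1, stderr = 0.5); b <- list(slope = 0.9, stderr = 0.5)
#' compare_slopes(a, b) # ~ 0.89
#' @export
compare_slopes <- function(a, b) {
  if (!is.numeric(a$stderr) || !is.numeric(b$stderr) ||
      a$stderr <= 0 || b$stderr <= 0)
    stop("both slopes need a positive standard error")
  z <- (a$slope - b$slope) / sqrt(a$stderr^2 + b$stderr^2)
  2 * stats::pnorm(-abs(z))
}

#' Rank the 64-permutation CACNNN binding library
#'
#' Sorts the library by normalized affinity and calls the consensus core
#' family by collapsing the degenerate fifth position (CACG\[N\]G etc.):
#' 6-mers are grouped by the pattern obtained from replacing position 5
#' with N, families ranked by mean normalized affinity, and a consensus is
#' called when the top family is at least twice as strong (mean) as the
#' remaining sequences. Per-sequence ranking is kept alongside.
#'
#' @param x Affinities for all 64 `CACNNN` permutations (list of
#'   `relative_affinity` or data.frame with `probe_id` = the 6-mer).
#' @return List with `ranked` (data.frame sorted by decreasing normalized
#'   affinity), `families` (per-family means), `best_core` (e.g.
#'   `"CACGNG"`), `top_sequence`, and `consensus` (`FALSE` when the library
#'   is too uniform to call one, with a warning).
#' @export
rank_library <- function(x) {
  df <- normalize_affinities(x)
  expected <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T"))[, 3:1], 1, paste,
                    collapse = "")
  expected <- paste0("CAC", expected)
  missing <- setdiff(expected, df$probe_id)
  if (length(missing))
    warning("library is missing ", length(missing), " permutation(s): ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
  ranked <- df[order(-df$normalized, df$probe_id), ]
  fam <- ranked
  fam$family <- paste0(substr(fam$probe_id, 1, 4), "N",
                       substr(fam$probe_id, 6, 6))
  fmeans <- stats::aggregate(normalized ~ family, fam, mean)
  fmeans <- fmeans[order(-fmeans$normalized), ]
  best <- fmeans$family[1]
  rest <- fam$normalized[fam$family != best]
  consensus <- length(rest) > 0 &&
    fmeans$normalized[1] >= 2 * mean(rest)
  if (!consensus)
    warning("no clear consensus core: the top family is not well separated")
  list(ranked = ranked, families = fmeans, best_core = best,
       top_sequence = ranked$probe_id[1], consensus = consensus)
}

#' Read / write binding series as TSV
#'
#' Columns: `probe_id`, `free`, `bound`, optional `group`.
#' @param series_list Named list of [binding_series()].
#' @param path File path.
#' @return `read_binding_tsv` returns a named list of `binding_series`.
#' @export
write_binding_tsv <- function(series_list, path) {
  rows <- lapply(series_list, function(s)
    data.frame(probe_id = s$probe_id, free = s$free, bound = s$bound,
               group = s$group))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_binding_tsv
#' @export
read_binding_tsv <- function(path) {
  df <- utils::read.delim(path)
  out <- lapply(split(df, df$probe_id), function(d)
    binding_series(d$probe_id[1], d$free, d$bound,
                   if ("group" %in% names(d)) d$group[1] else NA))
  out[unique(df$probe_id)]
}
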