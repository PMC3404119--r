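#' Locate local maxima of a uniformly sampled signal
#'
#' Three-point local maxima with parabolic sub-grid refinement of both the
#' peak time and height. Plateaus (runs of equal values higher than both
#' neighbours) report their midpoint without refinement.
#'
#' @param x Numeric signal sampled on a uniform grid.
#' @param times Sample times (uniform); defaults to `0:(n-1)`.
#' @return A data.frame with columns `time` and `value`, one row per peak.
#' @examples
#' t <- seq(0, 3, by = 0.001)
#' find_peaks(sin(2 * pi * t), t)$time # ~ 0.25, 1.25, 2.25
#' @export
find_peaks <- function(x, times = seq_along(x) - 1) {
  n <- length(x)
  stopifnot(n == length(times))
  if (n < 3L) return(data.frame(time = numeric(), value = numeric()))
  dt <- times[2] - times[1]
  out_t <- numeric(); out_v <- numeric()
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      # scan a possible plateau
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j <= n - 1L && x[j + 1L] < x[i]) {
        if (j > i) { # plateau: midpoint, no refinement
          out_t <- c(out_t, (times[i] + times[j]) / 2)
          out_v <- c(out_v, x[i])
        } else {
          a <- x[i - 1L]; b <- x[i]; cc <- x[i + 1L]
          den <- a - 2 * b + cc
          d <- if (den != 0) (a - cc) / (2 * den) else 0
          out_t <- c(out_t, times[i] + d * dt)
          out_v <- c(out_v, b - 0.25 * (a - cc) * d)
        }
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(time = out_t, value = out_v)
}

find_troughs <- function(x, times = seq_along(x) - 1) {
  p <- find_peaks(-x, times)
  p$value <- -p$value
  p
}

resolve_observable <- function(traj, observable) {
  if (is.numeric(observable)) {
    stopifnot(length(observable) == length(traj$times))
    return(list(x = observable, name = "custom"))
  }
  if (observable %in% colnames(traj$states))
    return(list(x = traj$states[, observable], name = observable))
  if (grepl("^total_", observable)) {
    fac <- sub("^total_", "", observable)
    return(list(x = total_protein(traj, fac), name = observable))
  }
  stop("unknown observable '", observable, "'")
}

#' Summarize the oscillation of a trajectory
#'
#' Extracts period, amplitude and a qualitative class from a simulated
#' trajectory: `sustained` (the last ten peak-to-peak amplitudes vary by
#' less than 1% and exceed the amplitude floor), `damped` (oscillations were
#' present but decay below the floor, or still shrink by more than 1% per
#' cycle at the end of the run), or `fixed_point` (no genuine oscillation).
#' The first half of the run is treated as transient. Following the
#' convention of reporting only asymptotic amplitudes, `amplitude` is 0 for
#' non-sustained classes and `period` is `NA`; for damped trajectories the
#' mean interval between decaying peaks is available as `damped_period`.
#'
#' @param traj A `dde_trajectory`.
#' @param observable A component label (e.g. `"h1"`), a total-protein
#'   selector (`"total_her1"`, `"total_her7"`, `"total_hes6"`), or a numeric
#'   vector on the trajectory grid.
#' @param eps Amplitude floor below which oscillations count as extinct;
#'   default `1e-3 * kappa1` of the attached parameters, or `1e-3` times the
#'   signal scale when no parameters are attached.
#' @return An `oscillation_summary`: list with `period`, `amplitude`,
#'   `classification`, `decay_rate` (per-cycle amplitude ratio; 1 when
#'   sustained), `n_cycles_used`, `damped_period` and `observable`.
#' @examples
#' tr <- simulate_clock(clock_params(), t_end = 300)
#' summarize_oscillation(tr, "total_her1")
#' @export
summarize_oscillation <- function(traj, observable = "total_her1",
                                  eps = NULL) {
  stopifnot(inherits(traj, "dde_trajectory"))
  obs <- resolve_observable(traj, observable)
  x <- obs$x
  times <- traj$times
  n <- length(times)
  if (n < 10L) stop("trajectory too short to analyze; extend t_end")
  if (is.null(eps)) {
    p <- attr(traj, "params")
    eps <- if (!is.null(p) && !is.null(p$kappa1) && p$kappa1 > 0)
      1e-3 * p$kappa1 else 1e-3 * max(abs(x), 1e-12)
  }

  mk <- function(classification, period = NA_real_, amplitude = 0,
                 decay_rate = NA_real_, n_cycles = 0L,
                 damped_period = NA_real_) {
    structure(list(period = period, amplitude = amplitude,
                   classification = classification, decay_rate = decay_rate,
                   n_cycles_used = n_cycles, damped_period = damped_period,
                   observable = obs$name, eps = eps),
              class = "oscillation_summary")
  }

  # peaks over the whole run (small initial skip), cycle amplitudes as
  # peak minus the following trough
  skip <- times[1] + 0.02 * (times[n] - times[1])
  sel <- times >= skip
  pk <- find_peaks(x[sel], times[sel])
  tr_ <- find_troughs(x[sel], times[sel])
  # genuine peaks: prominence above numeric noise
  tiny <- 1e-9 * max(abs(x), 1)
  if (nrow(pk) >= 1 && nrow(tr_) >= 1) {
    base <- stats::approx(tr_$time, tr_$value, xout = pk$time, rule = 2)$y
    keep <- (pk$value - base) > tiny
    amps_all <- (pk$value - base)[keep]
    pk <- pk[keep, , drop = FALSE]
  } else amps_all <- numeric()

  if (nrow(pk) < 3L) {
    # no oscillation after (or before) the transient
    return(mk("fixed_point"))
  }

  est_period <- stats::median(diff(pk$time))
  if ((times[n] - times[1]) < 20 * est_period)
    stop("trajectory spans fewer than 20 putative cycles; extend t_end")

  half <- times[1] + (times[n] - times[1]) / 2
  in_win <- pk$time >= half
  winpk <- pk[in_win, , drop = FALSE]
  winamps <- amps_all[in_win]
  above <- amps_all > eps
  damped_period <- if (sum(above) >= 3)
    mean(diff(pk$time[above])) else NA_real_

  if (nrow(winpk) >= 3 && all(winamps > eps)) {
    lastk <- utils::tail(winamps, 10)
    rel_range <- (max(lastk) - min(lastk)) / mean(lastk)
    ratio <- lastk[length(lastk)] / lastk[length(lastk) - 1]
    if (rel_range < 0.01 && ratio >= 0.99) {
      ncyc <- min(10L, nrow(winpk) - 1L)
      period <- mean(utils::tail(diff(winpk$time), ncyc))
      wstart <- winpk$time[nrow(winpk)] - ncyc * period
      wsel <- times >= wstart
      amplitude <- max(x[wsel]) - min(x[wsel])
      return(mk("sustained", period = period, amplitude = amplitude,
                decay_rate = 1, n_cycles = ncyc,
                damped_period = damped_period))
    }
    return(mk("damped", decay_rate = ratio, n_cycles = length(winamps),
              damped_period = damped_period))
  }
  # oscillations existed but the steady-state window has none above floor
  ratio <- if (length(amps_all) >= 2) {
    r <- amps_all[-1] / amps_all[-length(amps_all)]
    stats::median(r[is.finite(r)])
  } else NA_real_
  mk("damped", decay_rate = ratio, n_cycles = sum(above),
     damped_period = damped_period)
}

#' @export
print.oscillation_summary <- function(x, ...) {
  cat("Oscillation of", x$observable, "->", x$classification, "\n")
  if (x$classification == "sustained")
    cat(sprintf("  period = %.4f, amplitude = %.4f (over %d cycles)\n",
                x$period, x$amplitude, x$n_cycles_used))
  else if (x$classification == "damped")
    cat(sprintf("  asymptotic amplitude 0 (floor %.3g); decaying-cycle period = %s\n",
                x$eps,
                if (is.na(x$damped_period)) "NA"
                else sprintf("%.4f", x$damped_period)))
  invisible(x)
}

#' @export
#' @method as.data.frame oscillation_summary
as.data.frame.oscillation_summary <- function(x, ...) {
  data.frame(observable = x$observable, classification = x$classification,
             period = x$period, amplitude = x$amplitude,
             decay_rate = x$decay_rate, n_cycles_used = x$n_cycles_used,
             damped_period = x$damped_period)
}

#' Percent change in steady-state period between two parameter sets
#'
#' Simulates both parameter sets with the same solver settings, summarizes
#' the chosen observable and returns `100 * (period_a - period_b) /
#' period_b`. Both conditions must oscillate sustainably; otherwise the
#' comparison is refused as incomparable.
#'
#' @param p_a,p_b [clock_params()] objects.
#' @param t_end,dt Solver settings passed to [simulate_clock()].
#' @param observable Observable for [summarize_oscillation()].
#' @return Signed percent difference (scalar).
#' @examples
#' \donttest{
#' wt <- clock_params()
#' percent_period_change(wt, make_mutant(wt, "hes6")) # ~ -6%
#' }
#' @export
percent_period_change <- function(p_a, p_b, t_end = 300, dt = NULL,
                                  observable = "total_her1") {
  sa <- summarize_oscillation(simulate_clock(p_a, t_end = t_end, dt = dt),
                              observable)
  sb <- summarize_oscillation(simulate_clock(p_b, t_end = t_end, dt = dt),
                              observable)
  if (sa$classification != "sustained" || sb$classification != "sustained")
    stop("both conditions must oscillate sustainably; got '",
         sa$classification, "' and '", sb$classification, "'")
  100 * (sa$period - sb$period) / sb$period
}
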