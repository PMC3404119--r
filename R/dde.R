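#' Define a delay differential equation problem
#'
#' Bundles everything the method-of-steps integrator needs: the right-hand
#' side, the constant lags, the history function, the integration window and
#' the state dimension.
#'
#' @param rhs Function `rhs(t, y, lags)` returning the derivative vector;
#'   `lags` is a list of delayed state vectors, one per entry of `delays`,
#'   in the same order.
#' @param delays Numeric vector of non-negative constant lags (may be empty
#'   for an ODE).
#' @param history Either a function `history(t)` valid for `t <= t_span[1]`,
#'   or a constant numeric vector of length `dim`.
#' @param t_span Length-2 numeric, `c(t0, t_end)` with `t_end > t0`.
#' @param dim State dimension.
#' @param labels Optional component names (defaults to `y1..ydim`).
#'
#' @return An object of class `dde_problem`.
#' @seealso [integrate_dde()]
#' @export
dde_problem <- function(rhs, delays, history, t_span, dim,
                        labels = paste0("y", seq_len(dim))) {
  stopifnot(is.function(rhs), is.numeric(delays), length(t_span) == 2L)
  if (any(delays < 0)) stop("all delays must be >= 0")
  if (!(t_span[2] > t_span[1])) stop("t_end must be greater than t0")
  if (dim < 1) stop("state dimension must be >= 1")
  if (!is.function(history)) {
    history <- as.numeric(history)
    if (length(history) != dim)
      stop("constant history must have length ", dim)
  }
  if (length(labels) != dim) stop("labels must have length ", dim)
  structure(list(rhs = rhs, delays = as.numeric(delays), history = history,
                 t_span = as.numeric(t_span), dim = as.integer(dim),
                 labels = as.character(labels)),
            class = "dde_problem")
}

#' @export
print.dde_problem <- function(x, ...) {
  cat("DDE problem: dim", x$dim, "| delays",
      if (length(x$delays)) paste(signif(x$delays, 4), collapse = ", ")
      else "(none)",
      "| t in [", x$t_span[1], ",", x$t_span[2], "]\n")
  invisible(x)
}

#' Integrate a DDE problem with fixed-step RK4 and the method of steps
#'
#' Classical fourth-order Runge-Kutta with a fixed step. Delayed states are
#' interpolated from the stored solution with cubic Hermite patches; lookups
#' at or before `t0` use the history. When any positive delay is present,
#' `dt` must not exceed a tenth of the smallest positive delay, so all
#' delayed stage arguments lie in the already-computed solution.
#'
#' @param problem A [dde_problem()].
#' @param dt Positive step size.
#' @param out_by Optional output spacing (a multiple of `dt`); defaults to
#'   every step. Thinning keeps large stiff runs at a manageable size.
#' @param clamp_nonneg Clamp negative components to zero after each step
#'   (concentration semantics); the number of clamped components is recorded
#'   in the `n_clamped` attribute. Default `FALSE` for the generic solver.
#'
#' @return A `dde_trajectory`: list with `times` (uniform grid), `states`
#'   (time x dim matrix) and `labels`.
#' @examples
#' pr <- dde_problem(function(t, y, lags) -y, delays = numeric(),
#'                   history = 1, t_span = c(0, 1), dim = 1)
#' tr <- integrate_dde(pr, dt = 0.01)
#' tail(tr$states[, 1], 1) # ~ exp(-1)
#' @export
integrate_dde <- function(problem, dt, out_by = NULL, clamp_nonneg = FALSE) {
  stopifnot(inherits(problem, "dde_problem"), dt > 0)
  pos <- problem$delays[problem$delays > 0]
  if (length(pos) && dt > min(pos) / 10 + 1e-12)
    stop("dt must be <= min(positive delays)/10 = ", min(pos) / 10)
  t0 <- problem$t_span[1]; t_end <- problem$t_span[2]
  stride <- if (is.null(out_by)) 1L else max(1L, as.integer(round(out_by / dt)))
  nsteps <- ceiling((t_end - t0) / dt - 1e-9)
  nsteps <- as.integer(ceiling(nsteps / stride) * stride)
  y0 <- if (is.function(problem$history)) {
    h0 <- problem$history(t0)
    if (length(h0) != problem$dim)
      stop("history(t0) must return a vector of length ", problem$dim)
    as.numeric(h0)
  } else problem$history
  res <- .dde_rk4_cpp(0L, problem$rhs, numeric(), problem$delays,
                      problem$history, y0, t0, t0 + nsteps * dt, dt,
                      stride, clamp_nonneg)
  new_trajectory(res$times, res$states, problem$labels,
                 n_clamped = res$n_clamped)
}

new_trajectory <- function(times, states, labels, n_clamped = 0L,
                           params = NULL, subclass = NULL) {
  colnames(states) <- labels
  structure(list(times = as.numeric(times), states = states,
                 labels = as.character(labels)),
            n_clamped = n_clamped, params = params,
            class = c(subclass, "dde_trajectory"))
}

#' @export
print.dde_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("Trajectory:", n, "points, t in [", format(x$times[1]), ",",
      format(x$times[n]), "], components:",
      paste(x$labels, collapse = ", "), "\n")
  nc <- attr(x, "n_clamped")
  if (!is.null(nc) && nc > 0)
    cat("  (", nc, "negative components clamped to zero )\n")
  invisible(x)
}

#' @export
#' @method as.data.frame dde_trajectory
as.data.frame.dde_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' @export
plot.dde_trajectory <- function(x, which = x$labels, ...) {
  which <- match.arg(which, x$labels, several.ok = TRUE)
  cols <- grDevices::hcl.colors(max(3L, length(which)), "Dark 3")
  graphics::matplot(x$times, x$states[, which, drop = FALSE], type = "l",
                    lty = 1, col = cols[seq_along(which)],
                    xlab = "time (monomer lifetimes)",
                    ylab = "concentration", ...)
  graphics::legend("topright", legend = which, lty = 1,
                   col = cols[seq_along(which)], bty = "n")
  invisible(x)
}

#' Write / read a trajectory as TSV
#'
#' Columns: `time`, then one column per component.
#'
#' @param traj A `dde_trajectory`.
#' @param path File path.
#' @return `read_trajectory_tsv` returns a `dde_trajectory`;
#'   `write_trajectory_tsv` returns `path` invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  stopifnot(inherits(traj, "dde_trajectory"))
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "time") stop("first column must be 'time'")
  new_trajectory(df$time, as.matrix(df[-1]), names(df)[-1])
}
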