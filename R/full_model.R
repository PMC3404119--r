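#' Parameters of the full mass-action dimer model
#'
#' Extends the reduced-model parameters with explicit dimerization kinetics:
#' one shared association rate `a` and dissociation rate `b` across all
#' Hes/Her pairs, degradation rates `c` (monomers) and `c_dim` (dimers),
#' and the half-repression dimer threshold `D0`. In reduced units (`c = 1`)
#' the equilibrium reduction maps onto [clock_params()] with
#' `delta = c_dim * a / (c * b)` and `D0 = a / b`; the defaults are derived
#' from the reduced parameters so that the fast-dimerization limit
#' reproduces the minimal model (with the exact mass-action bookkeeping of
#' two monomers per homodimer, i.e. the factor-2 loss variant).
#'
#' @param p A [clock_params()] object supplying `kappa`, `tau`, `n`.
#' @param a Dimer association rate; default `b / K` with `K = c_dim /
#'   (c * delta)` so the equilibrium reduction reproduces the reduced
#'   model's `delta`.
#' @param b Dimer dissociation rate; default `fastness * (c + c_dim)`, the
#'   fast-dimerization regime (complex relaxation `fastness`-fold faster
#'   than every other rate).
#' @param c Degradation rate of monomers; default 1 (reduced time unit).
#' @param c_dim Degradation rate of dimers. The reduced model's
#'   dimer-mediated loss `delta * h_i * (h1+h6+h7)` is the decay of
#'   equilibrium dimers, `delta = c_dim / (c * K)`; for the reduced
#'   equations to emerge the dimer pool must also be a small mass fraction,
#'   which requires `c_dim >> c` at fixed `delta` (default 200). Setting
#'   `c_dim = c` recovers fully uniform decay, in which case total protein
#'   obeys plain delayed production-degradation and the reduced h-form is
#'   not recovered (see the package vignette).
#' @param D0 Half-repression dimer threshold; default `1 / K`, which makes
#'   the equilibrium dimer level `h_i h_j / K` in units of `D0` equal the
#'   minimal model's `h_i h_j` (threshold scaled to 1).
#' @param fastness Speed multiple used for the default `b`.
#' @return An object of class `full_clock_params`.
#' @export
full_params <- function(p = clock_params(), a = NULL, b = NULL, c = 1,
                        c_dim = 200, D0 = NULL, fastness = 20) {
  stopifnot(inherits(p, "clock_params"))
  if (p$delta <= 0) stop("the full model requires delta > 0")
  K <- c_dim / (c * p$delta)
  if (is.null(b)) b <- if (is.null(a)) fastness * (c + c_dim) else a * K
  if (is.null(a)) a <- b / K
  if (is.null(D0)) D0 <- (a / b) # 1 / K_eff for user-supplied a, b
  if (a <= 0 || b <= 0 || c <= 0 || c_dim <= 0 || D0 <= 0)
    stop("a, b, c, c_dim and D0 must all be > 0")
  structure(c(unclass(p), list(a = a, b = b, c = c, c_dim = c_dim,
                               D0 = D0)),
            class = "full_clock_params")
}

# closed-form asymptotic bounds: h_i <= (sqrt(1 + 4 delta kappa_i) - 1) /
# (2 delta) since dh_i <= kappa_i - h_i - delta h_i^2
monomer_bounds <- function(p) {
  k <- c(p$kappa1, p$kappa6, p$kappa7)
  if (p$delta == 0) return(k)
  (sqrt(1 + 4 * p$delta * k) - 1) / (2 * p$delta)
}

#' @export
print.full_clock_params <- function(x, ...) {
  cat("Full dimer-model parameters:\n")
  cat(sprintf("  kappa1 = %g, kappa7 = %g, kappa6 = %g, tau1 = %g, tau7 = %g, n = %g\n",
              x$kappa1, x$kappa7, x$kappa6, x$tau1, x$tau7, x$n))
  cat(sprintf("  a = %g, b = %g, c = %g, c_dim = %g, D0 = %g (K = b/a = %g)\n",
              x$a, x$b, x$c, x$c_dim, x$D0, x$b / x$a))
  invisible(x)
}

full_state_labels <- c("h1", "h6", "h7", "d11", "d16", "d17", "d66", "d67",
                       "d77")

#' Right-hand side of the full mass-action model
#'
#' Nine variables: monomers `h1, h6, h7` and the six unordered dimers.
#' Each pair forms at rate `a` (with `a h_i^2` for homodimers, consuming
#' two monomers) and dissociates at `b`; monomers decay at `c` and dimers
#' at `c_dim`. Repression of Her1/Her7 production reads the actual delayed
#' dimer variables `d11` and `d67` scaled by `D0`; Hes6 production is
#' constant.
#'
#' @param now,delayed_tau1,delayed_tau7 Numeric length-9 states ordered as
#'   `h1, h6, h7, d11, d16, d17, d66, d67, d77`.
#' @param p A [full_params()] object.
#' @return Numeric length-9 derivative.
#' @export
full_rhs <- function(now, delayed_tau1, delayed_tau7, p) {
  stopifnot(inherits(p, "full_clock_params"), length(now) == 9L,
            length(delayed_tau1) == 9L, length(delayed_tau7) == 9L)
  if (any(c(now, delayed_tau1, delayed_tau7) < 0))
    stop("concentrations must be >= 0")
  h1 <- now[1]; h6 <- now[2]; h7 <- now[3]
  d11 <- now[4]; d16 <- now[5]; d17 <- now[6]
  d66 <- now[7]; d67 <- now[8]; d77 <- now[9]
  a <- p$a; b <- p$b; cc <- p$c; cd <- p$c_dim
  r1 <- repression(delayed_tau1[4] / p$D0, delayed_tau1[8] / p$D0, p$n)
  r7 <- repression(delayed_tau7[4] / p$D0, delayed_tau7[8] / p$D0, p$n)
  c(p$kappa1 * r1 - cc * h1 - 2 * a * h1^2 + 2 * b * d11 -
      a * h1 * h6 + b * d16 - a * h1 * h7 + b * d17,
    p$kappa6 - cc * h6 - 2 * a * h6^2 + 2 * b * d66 -
      a * h1 * h6 + b * d16 - a * h6 * h7 + b * d67,
    p$kappa7 * r7 - cc * h7 - 2 * a * h7^2 + 2 * b * d77 -
      a * h1 * h7 + b * d17 - a * h6 * h7 + b * d67,
    a * h1^2 - (b + cd) * d11,
    a * h1 * h6 - (b + cd) * d16,
    a * h1 * h7 - (b + cd) * d17,
    a * h6^2 - (b + cd) * d66,
    a * h6 * h7 - (b + cd) * d67,
    a * h7^2 - (b + cd) * d77)
}

#' Equilibrium dimer levels from monomer concentrations
#'
#' Mass-action equilibrium: `d_ij = h_i * h_j / K` (and `h_i^2 / K` for
#' homodimers) with `K = b / a` the dissociation equilibrium constant.
#'
#' @param h Numeric length-3 monomer state `(h1, h6, h7)`.
#' @param K Equilibrium constant, > 0.
#' @return Named numeric length-6: `d11, d16, d17, d66, d67, d77`.
#' @examples
#' equilibrium_dimers(c(2, 0, 3), 1) # d11 = 4, d17 = 6, rest with h6 zero
#' @export
equilibrium_dimers <- function(h, K) {
  stopifnot(length(h) == 3L)
  if (any(h < 0)) stop("monomer concentrations must be >= 0")
  if (!is.numeric(K) || length(K) != 1L || K <= 0)
    stop("K must be a single value > 0")
  c(d11 = h[1]^2, d16 = h[1] * h[2], d17 = h[1] * h[3], d66 = h[2]^2,
    d67 = h[2] * h[3], d77 = h[3]^2) / K
}

# conservative explicit-stability step for the stiff dimerization kinetics
full_stable_dt <- function(p) {
  hmax <- max(monomer_bounds(
    structure(unclass(p), class = "clock_params")))
  lambda <- p$b + p$c_dim + p$c + 6 * p$a * hmax
  min(min(p$tau1, p$tau7) / 100, 1.5 / lambda)
}

#' Simulate the full dimer model
#'
#' Integrates the nine-variable mass-action model from zero history. The
#' default step obeys both the delay constraint and an explicit-stability
#' bound for the fast dimerization kinetics, so runs in the
#' fast-dimerization regime use very small internal steps; the returned
#' trajectory is thinned to `out_by` spacing.
#'
#' @param p A [full_params()] object.
#' @param t_end Duration (reduced time units).
#' @param dt Step; defaults to [the stability-limited step].
#' @param out_by Output spacing, default 0.005.
#' @return A `dde_trajectory` with the nine components labeled
#'   `h1, h6, h7, d11, d16, d17, d66, d67, d77`.
#' @export
simulate_full <- function(p, t_end = 150, dt = NULL, out_by = 0.005) {
  stopifnot(inherits(p, "full_clock_params"))
  if (is.null(dt)) dt <- full_stable_dt(p)
  stride <- max(1L, as.integer(round(out_by / dt)))
  nsteps <- ceiling(t_end / dt - 1e-9)
  nsteps <- as.integer(ceiling(nsteps / stride) * stride)
  pv <- c(kappa1 = p$kappa1, kappa6 = p$kappa6, kappa7 = p$kappa7,
          n = p$n, a = p$a, b = p$b, c = p$c, c_dim = p$c_dim, D0 = p$D0)
  res <- .dde_rk4_cpp(2L, NULL, pv, c(p$tau1, p$tau7), numeric(9),
                      numeric(9), 0, nsteps * dt, dt, stride, TRUE)
  tr <- new_trajectory(res$times, res$states, full_state_labels,
                       n_clamped = res$n_clamped, params = p,
                       subclass = "full_clock_trajectory")
  tr
}

# total Her1 protein in the full model: monomer + 2 per homodimer + one per
# heterodimer, using the actual dimer variables
full_total_her1 <- function(traj) {
  m <- traj$states
  m[, "h1"] + 2 * m[, "d11"] + m[, "d16"] + m[, "d17"]
}

#' Check the equilibrium reduction of the full model
#'
#' Integrates the full model with the dimerization rates `(a, b)` scaled by
#' a speed factor (the equilibrium constant `K = b/a` is unchanged) and the
#' minimal model with matched parameters, then compares the steady-state
#' oscillation period of total Her1 and the maximum relative deviation of
#' the monomer trajectories over the steady-state window. As the speed
#' factor grows, the full model approaches the equilibrium-reduced model.
#'
#' @param p_full A [full_params()] object.
#' @param p_min The matched [clock_params()] object.
#' @param scale Speed factor multiplying `a` and `b`.
#' @param t_end,dt Solver settings (full-model `dt` adapts to the scaled
#'   stiffness when `NULL`).
#' @return A `reduction_report`: list with `consistent` (parameter match),
#'   `mismatches`, `period_full`, `period_min`, `period_rel_diff`,
#'   `max_monomer_deviation`, `scale`.
#' @export
reduction_check <- function(p_full, p_min, scale = 1, t_end = 150,
                            dt = NULL) {
  stopifnot(inherits(p_full, "full_clock_params"),
            inherits(p_min, "clock_params"))
  mismatches <- character()
  for (f in c("kappa1", "kappa7", "kappa6", "tau1", "tau7", "n"))
    if (!isTRUE(all.equal(p_full[[f]], p_min[[f]])))
      mismatches <- c(mismatches, f)
  delta_implied <- p_full$c_dim * p_full$a / (p_full$c * p_full$b)
  if (abs(delta_implied - p_min$delta) > 1e-8 * max(1, p_min$delta))
    mismatches <- c(mismatches, "delta != c_dim*a/(c*b)")
  ps <- p_full
  ps$a <- p_full$a * scale
  ps$b <- p_full$b * scale
  trf <- simulate_full(ps, t_end = t_end, dt = dt)
  trm <- simulate_clock(p_min, t_end = t_end)
  sf <- summarize_oscillation(trf, full_total_her1(trf))
  sm <- summarize_oscillation(trm, "total_her1")
  if (sf$classification != "sustained" || sm$classification != "sustained")
    warning("non-sustained oscillation in reduction check (",
            sf$classification, " / ", sm$classification, ")")
  prd <- if (is.na(sf$period) || is.na(sm$period)) NA_real_
         else abs(sf$period - sm$period) / sm$period
  # compare monomers on the common output grid over the steady-state window
  tmin <- max(trf$times[1], trm$times[1])
  tmax <- min(trf$times[length(trf$times)], trm$times[length(trm$times)])
  t_cmp <- seq((tmin + tmax) / 2, tmax, length.out = 2000)
  dev <- 0
  for (comp in c("h1", "h6", "h7")) {
    xf <- stats::approx(trf$times, trf$states[, comp], xout = t_cmp)$y
    xm <- stats::approx(trm$times, trm$states[, comp], xout = t_cmp)$y
    sc <- max(abs(xm), 1e-12)
    dev <- max(dev, max(abs(xf - xm)) / sc)
  }
  structure(list(consistent = length(mismatches) == 0L,
                 mismatches = mismatches, scale = scale,
                 period_full = sf$period, period_min = sm$period,
                 period_rel_diff = prd, max_monomer_deviation = dev),
            class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat("Equilibrium-reduction check (speed factor ", x$scale, "):\n",
      sep = "")
  if (!x$consistent)
    cat("  INCONSISTENT parameter sets:",
        paste(x$mismatches, collapse = ", "), "\n")
  cat(sprintf("  period full = %s, minimal = %s (rel diff %s)\n",
              format(x$period_full), format(x$period_min),
              format(x$period_rel_diff)))
  cat(sprintf("  max relative monomer deviation = %.4g\n",
              x$max_monomer_deviation))
  invisible(x)
}
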