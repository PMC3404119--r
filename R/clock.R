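#' Parameters of the reduced three-variable clock model
#'
#' Dimensionless parameterization of the Her1/Her7/Hes6 circuit after the
#' equilibrium (fast-dimerization) reduction: time is measured in monomer
#' lifetimes, dimer levels are expressed in units of the half-repression
#' threshold, and dimers are the products of monomer concentrations.
#' The defaults are the wildtype reference values.
#'
#' @param kappa1,kappa7,kappa6 Dimensionless production rates of Her1, Her7
#'   and Hes6. Wildtype: 10, 10, 90. Hes6 production is constitutive (no
#'   delay, no repression).
#' @param tau1,tau7 Dimensionless production delays of Her1 and Her7
#'   (transcription + splicing + translation lag). Wildtype: 1.02 and 1.00 —
#'   the 2% asymmetry reflects the longer, intron-richer *her1* gene.
#' @param n Phenomenological Hill coefficient for repression via multiple
#'   promoter binding sites. Wildtype: 2.
#' @param delta Effective dimer-mediated degradation rate: loss of monomers
#'   that are sequestered in dimers at equilibrium. Wildtype: 1.
#' @param homodimer_double_loss If `TRUE`, the dimer-mediated loss term
#'   counts two monomers per homodimer decay (`h_i * (S + h_i)` instead of
#'   `h_i * S` with `S = h1 + h6 + h7`). Exposed as a stoichiometric
#'   variant; the default bookkeeping treats all dimer species equally.
#'
#' @return An object of class `clock_params`.
#' @examples
#' p <- clock_params()            # wildtype
#' make_mutant(p, "hes6")         # kappa6 = 0
#' @export
clock_params <- function(kappa1 = 10, kappa7 = 10, kappa6 = 90,
                         tau1 = 1.02, tau7 = 1.00, n = 2, delta = 1,
                         homodimer_double_loss = FALSE) {
  p <- list(kappa1 = kappa1, kappa7 = kappa7, kappa6 = kappa6,
            tau1 = tau1, tau7 = tau7, n = n, delta = delta,
            homodimer_double_loss = isTRUE(homodimer_double_loss))
  validate_clock_params(p)
  structure(p, class = "clock_params")
}

validate_clock_params <- function(p) {
  num <- c("kappa1", "kappa7", "kappa6", "tau1", "tau7", "n", "delta")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number")
  }
  if (any(unlist(p[c("kappa1", "kappa7", "kappa6", "tau1", "tau7",
                     "delta")]) < 0))
    stop("rates and delays must be >= 0")
  if (p$n < 1) stop("Hill coefficient n must be >= 1")
  invisible(p)
}

#' @export
print.clock_params <- function(x, ...) {
  cat("Clock parameters (dimensionless):\n")
  cat(sprintf("  kappa1 = %g, kappa7 = %g, kappa6 = %g\n",
              x$kappa1, x$kappa7, x$kappa6))
  cat(sprintf("  tau1 = %g, tau7 = %g, n = %g, delta = %g\n",
              x$tau1, x$tau7, x$n, x$delta))
  if (x$homodimer_double_loss)
    cat("  (homodimer losses counted with factor 2)\n")
  invisible(x)
}

#' @export
#' @method as.data.frame clock_params
as.data.frame.clock_params <- function(x, ...) {
  data.frame(kappa1 = x$kappa1, kappa7 = x$kappa7, kappa6 = x$kappa6,
             tau1 = x$tau1, tau7 = x$tau7, n = x$n, delta = x$delta)
}

#' Read clock parameters from a YAML config file
#'
#' The file holds flat `key: value` pairs named as in [clock_params()];
#' missing keys keep their wildtype defaults.
#'
#' @param path Path to a YAML file.
#' @return A `clock_params` object.
#' @export
read_clock_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(clock_params))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown parameter(s) in config: ",
                        paste(bad, collapse = ", "))
  do.call(clock_params, vals)
}

#' Genotypes of the mutant panel
#'
#' Mutants are modeled by zeroing the production rate of each mutated gene;
#' the hes6 heterozygote halves Hes6 production.
#' @export
clock_genotypes <- c("wildtype", "her1", "her7", "hes6", "her7;hes6",
                     "her1;hes6", "her1;her7", "hes6_het")

#' Hill repression by DNA-binding dimers
#'
#' Production fraction under joint repression by the Her1 homodimer and the
#' Her7:Hes6 heterodimer, the only two dimer species with strong DNA
#' binding. Both enter one Hill term additively, with dimer levels in units
#' of the half-repression threshold: `1 / (1 + (d11 + d67)^n)`. A combined
#' dimer level of 1 therefore halves production.
#'
#' @param d11 Her1:Her1 homodimer level (threshold units), >= 0.
#' @param d67 Her7:Hes6 heterodimer level (threshold units), >= 0.
#' @param n Hill coefficient.
#' @return Production fraction in `[0, 1]` (vectorized).
#' @examples
#' repression(0, 0, 2)    # 1: no repressor
#' repression(0.5, 0.5, 3) # 0.5 at the threshold, any n
#' @export
repression <- function(d11, d67, n) {
  if (any(d11 < 0) || any(d67 < 0)) stop("dimer levels must be >= 0")
  1 / (1 + (d11 + d67)^n)
}

#' Right-hand side of the reduced clock model
#'
#' Derivatives of the Her1, Hes6 and Her7 monomer concentrations. Her1 and
#' Her7 production is delayed (by `tau1` and `tau7` respectively) and
#' repressed by the equilibrium dimer levels `d11 = h1^2` and
#' `d67 = h6 * h7` evaluated at the delayed time; Hes6 production is
#' constant. Each monomer decays linearly (turnover) plus via degradation of
#' the dimers that sequester it (`delta` term).
#'
#' @param now Numeric length-3 `(h1, h6, h7)`, current state.
#' @param delayed_tau1 State at `s - tau1`.
#' @param delayed_tau7 State at `s - tau7`.
#' @param p A [clock_params()] object.
#' @return Numeric length-3 derivative `(dh1, dh6, dh7)`.
#' @export
clock_rhs <- function(now, delayed_tau1, delayed_tau7, p) {
  stopifnot(inherits(p, "clock_params"), length(now) == 3L,
            length(delayed_tau1) == 3L, length(delayed_tau7) == 3L)
  if (any(c(now, delayed_tau1, delayed_tau7) < 0))
    stop("concentrations must be >= 0")
  S <- sum(now)
  loss <- if (p$homodimer_double_loss) now * (S + now) else now * S
  r1 <- repression(delayed_tau1[1]^2, delayed_tau1[2] * delayed_tau1[3], p$n)
  r7 <- repression(delayed_tau7[1]^2, delayed_tau7[2] * delayed_tau7[3], p$n)
  c(p$kappa1 * r1 - now[1] - p$delta * loss[1],
    p$kappa6 - now[2] - p$delta * loss[2],
    p$kappa7 * r7 - now[3] - p$delta * loss[3])
}

#' Simulate the reduced clock model
#'
#' Integrates the three-variable model from constant zero history (the
#' production terms bootstrap the dynamics; only the steady-state attractor
#' is analyzed). Uses the compiled fast path of the method-of-steps RK4
#' integrator.
#'
#' @param p A [clock_params()] object.
#' @param t_end Duration in monomer lifetimes; the default 300 holds well
#'   over 20 cycles after the transient.
#' @param dt Step size; default `min(tau1, tau7)/100`.
#' @param t0 Start time (default 0).
#' @return A `clock_trajectory` (a [dde_trajectory][integrate_dde] with
#'   components `h1`, `h6`, `h7` and the parameters attached).
#' @examples
#' tr <- simulate_clock(clock_params(), t_end = 60)
#' @export
simulate_clock <- function(p, t_end = 300, dt = NULL, t0 = 0) {
  stopifnot(inherits(p, "clock_params"))
  if (is.null(dt)) dt <- min(p$tau1, p$tau7) / 100
  delays <- c(p$tau1, p$tau7)
  pos <- delays[delays > 0]
  if (length(pos) && dt > min(pos) / 10 + 1e-12)
    stop("dt must be <= min(positive delay)/10")
  nsteps <- as.integer(ceiling((t_end - t0) / dt - 1e-9))
  pv <- c(kappa1 = p$kappa1, kappa6 = p$kappa6, kappa7 = p$kappa7,
          n = p$n, delta = p$delta,
          homod2 = as.numeric(p$homodimer_double_loss))
  res <- .dde_rk4_cpp(1L, NULL, pv, delays, numeric(3), numeric(3),
                      t0, t0 + nsteps * dt, dt, 1L, TRUE)
  if (res$n_clamped > 0)
    warning(res$n_clamped,
            " negative state components clamped to zero during integration")
  new_trajectory(res$times, res$states, c("h1", "h6", "h7"),
                 n_clamped = res$n_clamped, params = p,
                 subclass = "clock_trajectory")
}

#' Derive mutant parameters from a genotype
#'
#' Mutated genes have their production rate set to zero (`her1` -> kappa1,
#' `her7` -> kappa7, `hes6` -> kappa6; double mutants zero both); the hes6
#' heterozygote (`hes6_het`) halves kappa6.
#'
#' @param p A [clock_params()] object (typically the wildtype reference).
#' @param genotype One of [clock_genotypes].
#' @return A modified `clock_params` object.
#' @examples
#' make_mutant(clock_params(), "her7;hes6")
#' @export
make_mutant <- function(p, genotype) {
  stopifnot(inherits(p, "clock_params"))
  genotype <- match.arg(genotype, clock_genotypes)
  q <- unclass(p)
  if (genotype %in% c("her1", "her1;hes6", "her1;her7")) q$kappa1 <- 0
  if (genotype %in% c("her7", "her7;hes6", "her1;her7")) q$kappa7 <- 0
  if (genotype %in% c("hes6", "her7;hes6", "her1;hes6")) q$kappa6 <- 0
  if (genotype == "hes6_het") q$kappa6 <- p$kappa6 / 2
  structure(q, class = "clock_params")
}

#' Total protein level including dimer-sequestered monomers
#'
#' Total concentration of a factor counting free monomer plus every monomer
#' residing in equilibrium dimers: two per homodimer, one per heterodimer.
#' For Her1, `h1 + 2*h1^2 + h1*h6 + h1*h7` (analogously for the others).
#'
#' @param state Either a numeric length-3 `(h1, h6, h7)` or a
#'   `clock_trajectory`, in which case the total is computed along the whole
#'   trajectory.
#' @param factor One of `"her1"`, `"her7"`, `"hes6"`.
#' @return A scalar, or a numeric vector over the trajectory grid.
#' @examples
#' total_protein(c(1, 0, 0), "her1") # 3
#' total_protein(c(1, 1, 1), "hes6") # 5
#' @export
total_protein <- function(state, factor = c("her1", "her7", "hes6")) {
  factor <- match.arg(factor)
  if (inherits(state, "dde_trajectory")) {
    m <- state$states
    if (!all(c("h1", "h6", "h7") %in% colnames(m)))
      stop("trajectory lacks monomer components h1, h6, h7")
    h1 <- m[, "h1"]; h6 <- m[, "h6"]; h7 <- m[, "h7"]
  } else {
    stopifnot(is.numeric(state), length(state) == 3L)
    if (any(state < 0)) stop("concentrations must be >= 0")
    h1 <- state[1]; h6 <- state[2]; h7 <- state[3]
  }
  switch(factor,
         her1 = h1 + 2 * h1^2 + h1 * h6 + h1 * h7,
         hes6 = h6 + 2 * h6^2 + h1 * h6 + h6 * h7,
         her7 = h7 + 2 * h7^2 + h1 * h7 + h6 * h7)
}

#' Effective degradation rate and half-life of a monomer
#'
#' The instantaneous per-capita loss rate of a monomer in the reduced model
#' is `r(s) = 1 + delta * (h1 + h6 + h7)` (linear turnover plus loss through
#' dimer-sequestered degradation; with the factor-2 variant the monomer's
#' own level is counted twice). Returns the time average of `r` over an
#' integer number of steady-state cycles and the corresponding half-life
#' `ln(2) / <r>`. Damped or fixed-point trajectories use the terminal state.
#'
#' @param traj A `clock_trajectory`.
#' @param p The [clock_params()] used for the simulation (defaults to the
#'   parameters attached to `traj`).
#' @param component One of `"her1"`, `"her7"`, `"hes6"`.
#' @return List with `rate` and `half_life`.
#' @export
effective_degradation <- function(traj, p = attr(traj, "params"),
                                  component = c("her1", "her7", "hes6")) {
  component <- match.arg(component)
  stopifnot(inherits(traj, "dde_trajectory"), inherits(p, "clock_params"))
  m <- traj$states
  idx <- switch(component, her1 = "h1", hes6 = "h6", her7 = "h7")
  S <- rowSums(m[, c("h1", "h6", "h7"), drop = FALSE])
  own <- m[, idx]
  r <- 1 + p$delta * (if (p$homodimer_double_loss) S + own else S)
  s <- summarize_oscillation(traj, observable = idx)
  if (s$classification == "sustained") {
    # average over an integer number of cycles at the end of the run
    ncyc <- max(1L, s$n_cycles_used)
    t1 <- traj$times[length(traj$times)]
    t0 <- t1 - ncyc * s$period
    sel <- traj$times >= t0
    rate <- mean(r[sel])
  } else {
    rate <- r[length(r)]
  }
  list(rate = rate, half_life = log(2) / rate)
}
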