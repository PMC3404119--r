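#' Sweep the Hes6 production rate
#'
#' Simulates and summarizes the clock along a grid of `kappa6` values for
#' one or both canonical scenarios: `kappa7_equal_kappa1` (Her7 production
#' intact) and `kappa7_zero` (her7 mutant). Named genotype markers are
#' annotated wherever the grid contains the matching corner: `kappa6 = 0`
#' with Her7 intact is the hes6 mutant, `kappa6` at its wildtype value with
#' `kappa7 = 0` the her7 mutant, `kappa6 = 0` with `kappa7 = 0` the
#' her7;hes6 double mutant, and the intact corner the wildtype.
#'
#' @param base A [clock_params()] object (the wildtype reference).
#' @param grid Increasing `kappa6` values in `[0, 150]`.
#' @param scenarios Character subset of
#'   `c("kappa7_equal_kappa1", "kappa7_zero")`.
#' @param t_end,dt Solver settings per point.
#' @param observable Observable summarized at each point.
#' @return A `kappa6_sweep`: data.frame with columns `scenario`, `kappa6`,
#'   `classification`, `period`, `amplitude`, `damped_period`, `genotype`
#'   (marker or `NA`), plus attributes `base` and `observable`. Integrator
#'   failures are recorded as `classification = "error"` and the sweep
#'   continues.
#' @export
kappa6_sweep <- function(base = clock_params(),
                         grid = seq(0, 150, by = 5),
                         scenarios = c("kappa7_equal_kappa1", "kappa7_zero"),
                         t_end = 300, dt = NULL,
                         observable = "total_her1") {
  stopifnot(inherits(base, "clock_params"))
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  grid <- sort(as.numeric(grid))
  if (any(grid < 0) || any(grid > 150))
    stop("kappa6 grid must lie within [0, 150]")
  rows <- list()
  for (sc in scenarios) {
    k7 <- if (sc == "kappa7_zero") 0 else base$kappa1
    for (k6 in grid) {
      p <- base
      p$kappa7 <- k7; p$kappa6 <- k6
      s <- tryCatch(
        summarize_oscillation(simulate_clock(p, t_end = t_end, dt = dt),
                              observable),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(s))
        data.frame(scenario = sc, kappa6 = k6, classification = "error",
                   period = NA_real_, amplitude = NA_real_,
                   damped_period = NA_real_)
      else
        data.frame(scenario = sc, kappa6 = k6,
                   classification = s$classification, period = s$period,
                   amplitude = s$amplitude, damped_period = s$damped_period)
    }
  }
  out <- do.call(rbind, rows)
  out$genotype <- NA_character_
  mark <- function(sc, k6, g) {
    i <- out$scenario == sc & out$kappa6 == k6
    out$genotype[i] <<- g
  }
  kwt <- base$kappa6
  mark("kappa7_equal_kappa1", 0, "hes6")
  mark("kappa7_equal_kappa1", kwt, "wildtype")
  mark("kappa7_zero", 0, "her7;hes6")
  mark("kappa7_zero", kwt, "her7")
  structure(out, base = base, observable = observable,
            class = c("kappa6_sweep", "data.frame"))
}

#' @export
plot.kappa6_sweep <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  cols <- c(kappa7_equal_kappa1 = "blue", kappa7_zero = "darkgreen")
  for (what in c("amplitude", "period")) {
    graphics::plot(NA, xlim = range(x$kappa6),
                   ylim = range(x[[what]], na.rm = TRUE),
                   xlab = expression(kappa[6]), ylab = what, ...)
    for (sc in unique(x$scenario)) {
      d <- x[x$scenario == sc, ]
      graphics::lines(d$kappa6, d[[what]], col = cols[[sc]])
      m <- d[!is.na(d$genotype), ]
      if (nrow(m)) graphics::points(m$kappa6, m[[what]], pch = 19,
                                    col = cols[[sc]])
    }
  }
  invisible(x)
}

#' Simulate and classify the mutant panel
#'
#' One simulation per genotype via [make_mutant()], summarized on total
#' Her1 protein (total Her7 for her1-mutant backgrounds, where Her1
#' production is absent).
#'
#' @param base Wildtype [clock_params()].
#' @param genotypes Genotypes to include (default: all eight).
#' @param t_end,dt Solver settings.
#' @return A data.frame with columns `genotype`, `observable`,
#'   `classification`, `period`, `amplitude`, `damped_period`.
#' @export
mutant_panel <- function(base = clock_params(), genotypes = clock_genotypes,
                         t_end = 300, dt = NULL) {
  genotypes <- match.arg(genotypes, clock_genotypes, several.ok = TRUE)
  rows <- lapply(genotypes, function(g) {
    p <- make_mutant(base, g)
    obs <- if (p$kappa1 == 0) "total_her7" else "total_her1"
    s <- summarize_oscillation(simulate_clock(p, t_end = t_end, dt = dt),
                               obs)
    data.frame(genotype = g, observable = obs,
               classification = s$classification, period = s$period,
               amplitude = s$amplitude, damped_period = s$damped_period)
  })
  do.call(rbind, rows)
}

#' Scan the Her1 production delay
#'
#' Repeats [kappa6_sweep()] for several values of `tau1`, tracing how the
#' delay asymmetry between *her1* and *her7* tunes the period gap between
#' the wildtype-like and her7-mutant scenarios.
#'
#' @param base Wildtype [clock_params()].
#' @param tau1_values Delays to scan (default 1.00, 1.02, 1.04).
#' @param grid,t_end,dt Passed to [kappa6_sweep()].
#' @return Named list of `kappa6_sweep` objects, one per `tau1`.
#' @export
delay_scan <- function(base = clock_params(),
                       tau1_values = c(1.00, 1.02, 1.04),
                       grid = seq(0, 150, by = 5), t_end = 300, dt = NULL) {
  out <- lapply(tau1_values, function(tau1) {
    p <- base; p$tau1 <- tau1
    kappa6_sweep(p, grid = grid, t_end = t_end, dt = dt)
  })
  names(out) <- paste0("tau1=", format(tau1_values))
  out
}

#' One-at-a-time parameter sensitivity analysis
#'
#' Multiplies each parameter in turn by each multiplier, re-simulates, and
#' records period and amplitude together with percent changes against the
#' unperturbed reference.
#'
#' @param base Wildtype [clock_params()]; must oscillate sustainably.
#' @param multipliers Factors applied one at a time (symmetric around 1).
#' @param parameters Which parameters to scan.
#' @param t_end,dt Solver settings.
#' @return A `sensitivity_table` data.frame with columns `parameter`,
#'   `multiplier`, `classification`, `period`, `amplitude`,
#'   `period_pct_change`, `amplitude_pct_change`. The `multiplier = 1` rows
#'   equal the reference.
#' @export
sensitivity <- function(base = clock_params(),
                        multipliers = c(0.5, 0.8, 0.9, 1.0, 1.1, 1.25, 2.0),
                        parameters = c("kappa1", "kappa7", "kappa6",
                                       "tau1", "tau7", "delta", "n"),
                        t_end = 300, dt = NULL) {
  stopifnot(inherits(base, "clock_params"))
  ref <- summarize_oscillation(simulate_clock(base, t_end = t_end, dt = dt))
  if (ref$classification != "sustained")
    stop("reference parameters must yield sustained oscillations")
  rows <- list()
  for (par in parameters) {
    for (m in multipliers) {
      if (m == 1) {
        s <- ref
      } else {
        p <- base
        p[[par]] <- base[[par]] * m
        s <- tryCatch(
          summarize_oscillation(simulate_clock(p, t_end = t_end, dt = dt)),
          error = function(e) NULL)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, multiplier = m,
        classification = if (is.null(s)) "error" else s$classification,
        period = if (is.null(s)) NA_real_ else s$period,
        amplitude = if (is.null(s)) NA_real_ else s$amplitude)
    }
  }
  out <- do.call(rbind, rows)
  out$period_pct_change <- 100 * (out$period - ref$period) / ref$period
  out$amplitude_pct_change <-
    100 * (out$amplitude - ref$amplitude) / ref$amplitude
  structure(out, reference = ref,
            class = c("sensitivity_table", "data.frame"))
}

#' Cycle-averaged monomer and dimer levels per genotype
#'
#' Averages the monomer concentrations over the steady-state window of each
#' genotype's simulation and reports the equilibrium dimer levels computed
#' from the cycle-averaged trajectory, alongside the half-repression
#' threshold (1 in threshold units) for comparison with the repressive
#' species d11 and d67.
#'
#' @param base Wildtype [clock_params()].
#' @param genotypes Genotypes to include.
#' @param t_end,dt Solver settings.
#' @return A data.frame with columns `genotype`, `h1`, `h6`, `h7`, `d11`,
#'   `d16`, `d17`, `d66`, `d67`, `d77`, `threshold`.
#' @export
dimer_levels <- function(base = clock_params(),
                         genotypes = clock_genotypes, t_end = 300,
                         dt = NULL) {
  genotypes <- match.arg(genotypes, clock_genotypes, several.ok = TRUE)
  rows <- lapply(genotypes, function(g) {
    p <- make_mutant(base, g)
    tr <- simulate_clock(p, t_end = t_end, dt = dt)
    sel <- tr$times >= (tr$times[1] + tr$times[length(tr$times)]) / 2
    m <- tr$states[sel, , drop = FALSE]
    # time-averaged equilibrium dimers (products averaged along the cycle)
    d <- colMeans(cbind(d11 = m[, "h1"]^2, d16 = m[, "h1"] * m[, "h6"],
                        d17 = m[, "h1"] * m[, "h7"], d66 = m[, "h6"]^2,
                        d67 = m[, "h6"] * m[, "h7"], d77 = m[, "h7"]^2))
    data.frame(genotype = g, h1 = mean(m[, "h1"]), h6 = mean(m[, "h6"]),
               h7 = mean(m[, "h7"]), d11 = d[["d11"]], d16 = d[["d16"]],
               d17 = d[["d17"]], d66 = d[["d66"]], d67 = d[["d67"]],
               d77 = d[["d77"]], threshold = 1)
  })
  do.call(rbind, rows)
}
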