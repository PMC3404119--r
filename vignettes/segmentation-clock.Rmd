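---
title: "Modeling the zebrafish segmentation clock core circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the zebrafish segmentation clock core circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segclock)
```

## The circuit and the model

Somites form rhythmically under the control of the segmentation clock, a
gene-regulatory oscillator running in every presomitic mesoderm cell. In
zebrafish the core of this oscillator is built from three Hes/Her-family
bHLH repressors: Her1 and Her7, whose transcription oscillates, and Hes6,
which is produced at a constant rate. All pairwise dimers among the three
proteins form promiscuously, but only two species bind DNA strongly — the
Her1:Her1 homodimer and the Her7:Hes6 heterodimer — and both repress the
*her1* and *her7* promoters through the same H-box sites. The remaining
dimers are not inert: they sequester monomers away from the DNA-binding
pool and are degraded together with the monomers they contain, so the
"dimer cloud" sets both the availability and the effective stability of
the repressors.

`segclock` implements this circuit as a delay differential equation (DDE)
model in dimensionless units (time in monomer lifetimes, dimer levels in
units of the half-repression threshold). The reduced model follows the
three monomer concentrations $h_1, h_6, h_7$:

$$
\begin{aligned}
\dot h_1 &= \kappa_1\,
  \frac{1}{1 + \big(h_1^2 + h_6 h_7\big)^n\big|_{s-\tau_1}}
  - h_1 - \delta\, h_1 (h_1 + h_6 + h_7),\\
\dot h_6 &= \kappa_6 - h_6 - \delta\, h_6 (h_1 + h_6 + h_7),\\
\dot h_7 &= \kappa_7\,
  \frac{1}{1 + \big(h_1^2 + h_6 h_7\big)^n\big|_{s-\tau_7}}
  - h_7 - \delta\, h_7 (h_1 + h_6 + h_7).
\end{aligned}
$$

Dimers are in fast equilibrium, so the repressive species are the monomer
products $d_{11} = h_1^2$ and $d_{67} = h_6 h_7$, evaluated at the delayed
time ($\tau_1$, $\tau_7$ are the production delays of Her1 and Her7; Hes6
production is constitutive and undelayed). Both repressors enter a single
Hill term additively — the data show one common threshold for the two
DNA-binding dimers, and a single term is the most parsimonious reading.
Each monomer is lost through its own turnover (the linear term) and
through degradation of any dimer that contains it (the $\delta$ term);
this dimer-mediated loss is how constitutively produced Hes6 couples into
the oscillator's period.

### Parameters

| parameter | meaning | wildtype default |
|---|---|---|
| `kappa1`, `kappa7` | Her1/Her7 production rates (dimensionless) | 10 |
| `kappa6` | Hes6 production rate | 90 |
| `tau1`, `tau7` | production delays (monomer lifetimes) | 1.02, 1.00 |
| `n` | phenomenological Hill coefficient (multiple promoter sites) | 2 |
| `delta` | effective dimer-mediated degradation rate | 1 |

The 2% delay asymmetry between `tau1` and `tau7` reflects the longer,
intron-richer *her1* gene; it is the one asymmetry needed to place the
simulated her7 mutant's period on the wildtype value. No mapping from
dimensionless time to minutes is asserted anywhere in the package — all
period statements are relative.

Mutants are parameter operations, not new models: `make_mutant()` zeroes
the production rate(s) of the mutated gene(s), and halves `kappa6` for the
hes6 heterozygote.

### What the model reproduces

Running `mutant_panel()` classifies each genotype's steady-state dynamics
of total Her1 (total Her7 where Her1 production is absent):

* wildtype, her1, hes6 and her7;hes6: sustained oscillations;
* her7: oscillations initiate, then decay to zero amplitude (damped) —
  Her1 monomer is mopped up into Her1:Hes6 heterodimers, starving the
  Her1 homodimer loop;
* her1;hes6 and her1;her7: a fixed point, no oscillation — both feedback
  loops are severed.

`kappa6_sweep()` traces period and amplitude against Hes6 production for
the intact (`kappa7 = kappa1`) and her7-mutant (`kappa7 = 0`) scenarios,
and reproduces the headline effects: period decreases as `kappa6` grows
(the package's simulations put the wildtype about 8% faster than the
`kappa6 = 0` hes6 mutant, against roughly 6% observed in embryos — the
printed functional forms admit some reconstruction latitude, and no
parameter was fitted); lowering `kappa6` in the her7 mutant background
rescues the oscillation amplitude (the epistasis result); and total Hes6
protein oscillates even though its production is constant, purely through
rhythmic changes in its effective degradation (`effective_degradation()`
quantifies this as the cycle-averaged per-capita loss rate
$1 + \delta\,(h_1+h_6+h_7)$ and the corresponding half-life).

### The delay scan and the `kappa6 = 0` corner

`delay_scan()` repeats the sweep at `tau1` = 1.00, 1.02, 1.04. At equal
delays the simulated her7 mutant runs strictly faster than the intact
scenario across intermediate `kappa6`; the 2% asymmetry closes that gap
to under 1.5% at `kappa6` = 30–90 (at 90 the mutant is damped, and the
comparison uses the mean interval of its decaying cycles, reported as
`damped_period`). The `kappa6 = 0` corner is deliberately excluded from
the "match" statement: there the two scenarios are the hes6 single and
her7;hes6 double mutant, for which the model *predicts* a period gap
(the double mutant is slower because Her7 no longer destabilizes Her1) —
asserting a match there would contradict the model's own prediction, so
the package's checks assert the gap instead.

## The full dimer-cloud model and the equilibrium reduction

`full_params()`/`simulate_full()` implement the unreduced mass-action
network: three monomers and all six dimers, with shared association rate
`a` and dissociation rate `b` across pairs, monomer decay `c`, dimer
decay `c_dim`, and repression read from the actual delayed `d11` and
`d67` scaled by the threshold `D0`.

A point worth spelling out, because it constrains any such model: if
dimers decay at exactly the monomer rate (`c_dim = c`), then total
protein $T_i = h_i + 2d_{ii} + \sum_{j\ne i} d_{ij}$ obeys
$\dot T_i = \kappa_i R_i - c\,T_i$ *exactly*, for any dimerization speed.
The fast-dimerization limit is then a plain delayed
production–degradation system whose effective loss rate is just $c$ — the
dimer-mediated acceleration of turnover disappears, and at the wildtype
parameters that system does not oscillate. The reduced model above can
therefore only arise as an equilibrium limit when dimer degradation
outpaces monomer turnover: with $K = b/a$ and
$\delta = c_\mathrm{dim}/(cK)$, taking $c \ll c_\mathrm{dim} \ll b$ makes
the dimer pool a small, fast-equilibrating mass fraction whose decay
produces exactly the $\delta$-term. The package's defaults
(`c_dim = 200`, `b = 20 (c + c_dim)`) realize this hierarchy;
`c_dim = c` remains available for exploring the uniform-decay variant.

The exact mass-action bookkeeping counts two monomers per homodimer
decay, so the limit carries the loss term
$h_i(2h_i + h_j + h_k)$ rather than $h_i(h_1+h_6+h_7)$. Both variants are
available in the reduced model (`homodimer_double_loss`); they change
steady-state periods by about 1%, and none of the qualitative mutant
phenotypes. `reduction_check()` integrates the full model with `(a, b)`
scaled by a speed factor and reports the period gap and trajectory
deviation against the matched reduced model; the gap shrinks
monotonically with speed and is within 1% from 10x onward when compared
against the factor-2 variant (the exact limit).

## Numerical scheme

Integration uses classical fixed-step RK4 under the method of steps,
implemented in C++. Delayed states are read from the stored solution by
cubic Hermite interpolation (continuous C1 patches from stored states and
derivatives); lookups at or before the start time use the history
function. The step is required to satisfy `dt <= min(delay)/10`, which
guarantees every delayed stage argument lies in the already-computed part
of the solution — no extrapolation is ever taken. Design choices:

* **History.** Constant zero history: production bootstraps the dynamics,
  and only the steady-state attractor is analyzed. Initial conditions are
  not part of any reported quantity.
* **Step size.** Default `min(tau1, tau7)/100` (0.01 for the wildtype).
  The suite verifies fourth-order convergence on an exponential-decay
  oracle, a neutral linear DDE oscillating at its analytic period
  $4\tau$, and that halving `dt` moves the reported clock period by less
  than 0.1%.
* **Stiffness.** The full model in the fast-dimerization regime is stiff
  for an explicit method; `simulate_full()` bounds the step by
  $1.5/(b + c_\mathrm{dim} + c + 6 a\, h_\mathrm{max})$ with
  $h_\mathrm{max}$ from the closed-form bound
  $h_i \le (\sqrt{1+4\delta\kappa_i}-1)/(2\delta)$, stores the recent
  solution in a ring buffer, and thins the output grid.
* **Positivity.** States are clamped at zero after each step and the
  event is counted; at the study parameters clamping never triggers
  (asserted in the tests).

Oscillation analysis (`summarize_oscillation()`) discards the first half
of the run as transient, finds peaks by three-point comparison with
parabolic sub-grid refinement (plateau midpoints for flat tops), and
classifies: *sustained* if the last ten cycle amplitudes vary by less
than 1% and exceed the amplitude floor (`eps`, default
$10^{-3}\kappa_1$); *damped* if oscillations existed but decay below the
floor or still shrink by over 1% per cycle at the end; *fixed point*
otherwise. Reported amplitudes for non-sustained trajectories are their
asymptotic value, zero; the mean interval of decaying cycles is kept
separately as `damped_period`, which is what sweep figures plot for
damped conditions. Problem sizes used throughout the packaged analyses:
`t_end = 300` (about 130 cycles) for reduced-model runs, `t_end = 120`
and speed factors 10–100 for the reduction checks — enough that every
reported period is converged well below the tolerances attached to it.

## Data-analysis procedures

The binding-affinity module mirrors microfluidic equilibrium titrations
(MITOMI): in the sub-$K_d$ linear regime, bound signal is proportional to
free signal with slope $\propto 1/K_d$, so the OLS slope of bound on free
(with intercept — constant background fluorescence is real and does not
bias the slope) is a relative affinity. Sets are normalized to their
strongest member; slopes are compared with a two-sided z-test on the
combined standard errors; `rank_library()` ranks the 64 `CACNNN`
permutations and calls the consensus family by collapsing the degenerate
fifth position (a consensus requires the top family to be at least twice
the mean of the rest). Saturating points can be dropped with `max_free`;
enforcing the linear regime is otherwise the caller's responsibility.

`scan_hbox()` finds H-box cores (`CACGNG`; `strict = TRUE` narrows to the
in-vivo-relevant `CACG[T/C]G`) on both strands, reports each as a
12-mer in 0-based half-open coordinates with 3-nt flanks (N-padded at
sequence ends), and collapses the palindromic `CACGTG` double hit to one
+ strand record. The scanner is validated against a brute-force 12-mer
enumerator on random 10-kb sequences.

The somite-timing module estimates each embryo's somitogenesis period as
the OLS slope of boundary-formation time on somite index (at least three
boundaries), normalizes per experimental batch by the control-genotype
mean, and compares genotypes with a two-tailed Mann-Whitney U test plus
normal-theory 95% confidence intervals (`mean ± 1.96 sd/√n`; the normal
form is a documented choice — the original spreadsheet convention cannot
be recovered). The genotype column may be withheld during fitting to
support blind analysis.

## Synthetic data: what it does and does not emulate

All pipeline inputs are generated, with ground truth attached, by seeded
generators:

* `gen_binding_series()` — log-spaced free signals, bound =
  background + slope·free·exp(ε) with lognormal ε (CV-scaled,
  positivity-preserving). Emulates linear-regime titrations only: no
  saturation, no chip-position effects, no image quantification noise.
* `gen_boundary_table()` — boundary times linear in somite index with
  Gaussian timing noise and jittered onsets; genotype effect sizes enter
  as true periods (the packaged recovery tests use 2% and 6% slowdowns at
  a 24 min base period with 3% timing noise over somites 2–17, n = 25
  per arm). No inter-embryo period variability beyond timing noise, no
  temperature or staging covariates.
* `gen_promoter()` — i.i.d. background DNA at a chosen GC content with
  planted 12-mers (optionally with spurious background cores re-drawn, for
  single-site scenarios). No dinucleotide structure or promoter
  architecture.

Passing recovery tests on these inputs demonstrates that the estimators
are unbiased and correctly calibrated under their stated noise models —
not that real chips or real embryos satisfy those models.

## Limitations

Single-cell model only: no Delta-Notch cell–cell coupling, no spatial
PSM gradients or wave patterns, no separate mRNA species, and no
anterior slowing. Parameters are deliberately symmetric except where a
qualitative trend requires otherwise, and none were fit numerically, so
simulated periods are relative statements, not quantitative predictions.
Absolute binding constants are out of scope — only relative affinities
are meaningful in the linear titration regime.
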