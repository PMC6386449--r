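---
title: "Modeling toxin excitations in a mazEF-type toxin-antitoxin module"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling toxin excitations in a mazEF-type toxin-antitoxin module}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taexcite)
```

## The system and the model

Type II toxin-antitoxin (TA) modules such as *mazEF* encode an
intracellular toxin (MazF, an endoribonuclease) and an antitoxin (MazE)
that neutralizes it by complex formation. The antitoxin turns over much
faster than the toxin, so under proteolytic stress the free-toxin pool
can transiently escape neutralization. The feature this package centers
on is *toxin-induced cleavage of the module's own transcript*: above a
threshold free-toxin level, the toxin degrades the mRNA it is
translated from, shutting down both its own production and that of its
antidote. That switch converts a quietly buffered module into an
excitable system in which perturbations trigger large transient toxin
spikes.

The dimensional model tracks mRNA `M`, free antitoxin `A`, free toxin
`T` and the neutral complex `AT` (molecules per cell; rates in s^-1):

$$
\begin{aligned}
\dot M &= r_F D - d_m M - d_{large}\,\frac{T^n}{T^n + K_t^n}\,M\\
\dot A &= b_1 M - a_T A T - d_a A\\
\dot T &= b_2 M - a_T A T - d_c T + d_{a2} AT\\
\dot{AT} &= a_T A T - d_c AT - d_{a2} AT
\end{aligned}
$$

with `d_a2 = F d_a` the slower in-complex antitoxin degradation. The
defaults (`ta_params_table1()`) are the *mazEF* reference values:
transcription 0.121 s^-1, translation 0.122 / 0.009 s^-1, mRNA
half-life 5.7 min, hundredfold cleavage-induced mRNA decay, threshold
15 toxins with Hill coefficient 2, dilution from a 40 min cell cycle,
antitoxin degradation eight times faster. Bimolecular rates measured in
molar units are converted to per-molecule rates with a volume factor
of `r format(volume_factor(0.6e-18), big.mark = ",")` molecules per
cell per molar (0.6 um^3 cell; the conversion uses Avogadro's number
rounded to 6.02e23, which is the precision the factor is quoted at).

Two conventions deserve mention because the printed sources are
ambiguous about them:

* **Dilution rate.** A 40 min cell cycle gives
  `d_c = log(2)/2400 = 2.888e-4`, while the rounded value 0.00028 is
  also in circulation. Only the former reproduces the normalized
  dilution rate 1.96, so the `"derived"` preset is the default; the
  `"printed"` preset keeps the rounded numbers for users who want them
  verbatim.
* **Operator binding.** Transcriptional autoregulation is modeled as a
  repression factor `r/(r + y)` with `y` the complex level. The
  reference binding parameter 4.9 is specified in *molecules of AT*,
  not in normalized `y` units: only that reading reproduces the
  documented stochastic excitability of the DNA-binding variant at
  moderate stress (the normalized reading leaves the system silent for
  millions of seconds of simulated time). `dna_r_from_counts()`
  performs the conversion.

## Nondimensionalization and the reduced model

With `eps = b_2/b_1 ≈ 0.074` measuring the translation-rate asymmetry,
the scalings `m = (d_m/(r_F D eps)) M`, `a, x, y = (d_m/eps) (A, T,
AT)` and `tau = d_m t` turn the system into a normalized form whose
parameters are order one except for `beta = d_large/d_m + 1 = 100` and
`eps` itself (`normalize_params()`; the round trip through
`denormalize_params()` is exact to 1e-12). Three timescales separate:
mRNA relaxes on order `1/eps`, antitoxin on order one, toxin and
complex on order `eps`. Setting the two fast derivatives to zero (the
quasi-steady-state approximation) slaves mRNA and antitoxin to the
toxin level,

$$
m(x) = \frac{1/\epsilon}{1 + (\beta - 1)\frac{x^n}{x^n + \kappa^n}},
\qquad
a(x) = \frac{\gamma\, m(x)}{\alpha x + \delta_a},
$$

leaving a two-dimensional system in `(x, y)` that can be read in the
phase plane. The `m(x)` expression is a quotient (division by the
bracket): that is the only reading consistent with setting
`dm/dtau = 0` in the normalized equations.

`nullclines()` returns `NC(x)` and `NC(y)`; with `n >= 2` the
`NC(x)` curve is folded and its middle branch is the excitation
threshold: trajectories kicked across it run through a full toxin
excursion - mRNA is cleaved, translation collapses, complexes keep
releasing toxin for a while, and dilution finally clears the spike -
before returning to the single fixed point.

```{r phase-plane, fig.width = 6, fig.height = 4.5}
np <- normalize_params(ta_params_table1())
np2 <- set_stress(np, delta_a = 1.5, epsilon = 0.074)
fp <- find_fixed_points(np2)[[1]]
traj <- ta_integrate(np2, c(0.9 * np2$kappa, fp$y), 60 / np2$epsilon,
                     representation = "reduced")
plot(nullclines(np2), traj = traj)
```

## Regimes, stress and the Hopf bifurcation

Stress enters through the antitoxin degradation rate (protease
activity; `delta_a`) and the toxin translation rate (`eps`). A
`delta_a` change rescales `delta_a` and `delta_AT` together, with the
in-complex fraction `F = delta_AT * eps / delta_a` held fixed. An
`eps` change stands for a change of the dimensional translation rate
`b_2`, so every `eps`-dependent normalized parameter co-varies
(`delta_c`, `kappa`, `delta_AT` inversely; `alpha` proportionally).
The package deliberately uses this dimensional convention for both
`apply_stress()` and the continuation in `continue_branch()`: sweeping
`eps` alone, with the other normalized parameters pinned, leaves the
fixed point stable over the whole plausible range and abolishes the
translation-rate route to oscillations that the model family is known
to have.

`classify_regime()` distinguishes three regimes:

* **oscillatory** - the fixed point is unstable; the system settles on
  a limit cycle of repeated excitations (`delta_a = 3`).
* **excitable** - the fixed point is a *stable focus* (complex
  eigenvalues, the signature of the nearby Hopf bifurcation) and a
  probe displacement just beyond the threshold branch triggers an
  excursion at least tenfold above the fixed-point toxin level
  (`delta_a = 2`).
* **monostable** - anything else; in particular a stable node, where
  the threshold sits far from the fixed point relative to the noise
  scale (`delta_a = 1`).

The focus condition is load-bearing: a pure excursion probe would also
label the weakly stressed system excitable, because a *deterministic*
super-threshold kick always triggers a spike when a threshold exists
at all. What distinguishes the regimes observed in stochastic
simulations is whether intrinsic fluctuations can reach the threshold,
and the focus/node transition tracks that boundary over the reference
stress range.

`continue_branch()` tracks the fixed point over either stress
parameter, and `detect_hopf()` refines the stability change: at
`eps = 0.074` a supercritical Hopf sits at `delta_a ≈ 2.07` with
onset period `2 pi / Im(lambda) ≈ 2.1` (finite - type II
excitability). Criticality is decided by probing the *stable* side for
a coexisting large cycle (the subcritical signature); the emerging
cycle itself is useless for this purpose here because the Canard
explosion inflates it to full amplitude within a parameter window far
narrower than the numerical precision of the crossing. Past the
bifurcation, `limit_cycle_metrics()` shows the period falling
monotonically with stress - more frequent excitations - while the
excitation time shrinks slowly.

## Stochastic counterpart

`build_reactions()` derives the Gillespie channels term-by-term from
the deterministic equations, so the stoichiometry-weighted propensities
reproduce the ODE right-hand side *exactly* at every state
(`mean_field_rhs()`; this holds for every variant and is asserted in
the tests). The sampler (`gillespie_run()`) is the direct method in
compiled code, draws from R's RNG (seed-reproducible), and implements
piecewise-constant stress by advancing the clock to each window
boundary and redrawing - exact for exponential waiting times. Species
counts are recorded on a regular sampling grid.

Two detection choices matter when comparing stochastic and
deterministic excitations:

* **Hysteresis grouping.** With a cleavage threshold of only 15
  molecules, shot noise chops a single excursion into many brief
  super-threshold intervals. `excitation_stats()` therefore ends an
  event only when the count falls below `K_t/2`, while durations still
  measure time above `K_t`. Without this, the stochastic mean
  excitation time is biased low by construction rather than by
  dynamics.
* **Edge events.** Excursions already in progress at the start or end
  of a trace have undefined duration and are discarded (counted
  separately).

With these conventions the oscillatory regime (`delta_a = 3`) gives a
stochastic mean excitation time within one standard deviation of the
deterministic value, and a stochastic period *longer* than the
deterministic one - crossing the threshold takes waiting time. In the
large-volume limit (volume factor and initial counts scaled 100-fold,
bimolecular rate scaled down accordingly) the mean stochastic
excursion converges onto the deterministic orbit; the package compares
the paths in sup norm *relative to the excursion amplitude*, because
pointwise relative error is ill-conditioned on the steep collapse
flank where run-to-run timing jitter of a fraction of a time unit
moves the crossing by more than the local value.

## The closed-form excitation estimate

In the limit `x >> kappa` with production and binding dropped, toxin
obeys a two-exponential solution (`analytic_excitation()`): release
from the complex pool at rate `eps * delta_AT` on top of dilution at
`eps * delta_c`. The package implements the formula exactly as stated
and reports its deviation honestly: with the reference parameters the
cleaved-state translation floor is `gamma/(eps beta) ≈ 1`, so the
neglected binding flux is *not* small, and the estimate overshoots the
actual decaying flank substantially (tens of percent at the peak and
growing toward the downward crossing). It captures the shape - rise,
peak, exponential tail - and the limiting rates, not the quantitative
profile; `compare_excursion()` reports the discrepancy. Where the
formula's assumptions do hold exactly (binding and production switched
off), the integrator reproduces it to solver precision, which is the
regression test the package relies on.

## Model extensions

* **Secondary complex (TAT).** One antitoxin can neutralize a second
  toxin; `z` forms at rate `alpha x y` and releases *two* toxins when
  its antitoxin is degraded. The total complexed toxin `c = y + 2z`
  obeys the same structural equation as `y` in the minimal model, so
  the excitation mechanism is unchanged, but the extra binding term
  `-alpha y x` buffers free toxin: the threshold moves up and the
  stochastic excitation frequency drops (at `delta_a = 3` the TAT
  variant fires an order of magnitude less often than the minimal
  one).
* **Operator binding (DNA).** Repressing transcription by
  `r/(r + y)` lowers the complex pool at equilibrium without raising
  the threshold, so noise reaches it more easily: at `delta_a = 1.5`
  the minimal and TAT models are stochastically silent while the
  DNA-binding variant fires.
* **Growth-rate and translational inhibition.** High free toxin slows
  growth (`f_t = S_t/(1 + B_t x)` scaling every dilution term: `T`,
  `AT`, `TAT`) and global translation (`f_m = S_m/(1 + B_m x)` scaling
  both translation terms). Degradation rates (`d_m`, `d_a`) are
  biochemical and are not scaled; whether the mRNA should also feel
  dilution is left as in the base model (no `d_c` on `M`). Slowing
  dilution keeps the cell in the toxic state longer - the excitation
  time at `delta_a = 2` grows severalfold with `B_t = 1`. With a
  hyperbolic cleavage response (`n = 1`) the nullcline `NC(x)` has no
  fold and hence no excitation threshold; translational inhibition
  restores the degree-two nonlinearity and with it the bend, which is
  the structural requirement for excitability. The package checks this
  claim at the nullcline level and as a stochastic event-frequency
  contrast; with these parameters the n = 1 stochastic events remain
  small near-threshold excursions rather than full spikes.

## Numerical choices

* Integration uses `deSolve::lsoda` with relative tolerance 1e-8
  (three separated timescales make the system stiff during cleavage
  switching). States are clipped to zero within solver tolerance;
  undershoot beyond `10 * tol` raises an error instead of being
  masked.
* Fixed points are found by seeding a damped Newton iteration from
  sign changes of `dx/dtau` along `NC(y)` on a log-spaced grid
  (1e-3 to 1e3), merging roots closer than 1e-6 relative. The Jacobian
  of the minimal reduced model is analytic (chain rule through `m(x)`
  and `a(x)`) and is verified against central differences in the
  tests; variants use finite differences.
* The excitability probe displaces `x` to 1.05 times the
  threshold-branch location at the fixed point's `y` and integrates
  for `50/eps` time units; the tenfold-excursion cut mirrors the
  order-of-magnitude spikes the system produces.
* Continuation is natural-parameter (the branch has no folds in the
  scanned ranges); Hopf crossings are refined by bisection to 1e-3 -
  1e-4 in the parameter.
* Long-run cycle metrics use `tau_end = 500/eps` with the first half
  discarded as transient; both are configurable arguments.
* Problem sizes in the bundled checks (twenty stochastic runs of 2e5 s
  for the oscillatory comparison, eight 100-fold-volume runs for the
  large-volume limit, two seeds per variant for the frequency
  contrasts) were chosen so each comparison's sampling error is well
  below the effect it measures.

## What the synthetic scenarios do and do not show

The bundled scenarios (`list_scenarios()`) generate all inputs from
the parameter table - there is no external data. They emulate a single
cell with fixed volume, constant gene copy number, instantaneous
stress switches, and intrinsic (copy-number) noise only. Real cells
add extrinsic noise, growth-rate feedback on all rates, cell division
with partitioning noise, and population selection, none of which are
modeled; passing checks therefore validate the dynamical mechanism -
cleavage-driven excitability near a supercritical Hopf - not a
quantitative prediction of in vivo spike statistics.

## Known limitations

* The closed-form excitation estimate is qualitative at the reference
  `beta` (see above).
* Criticality classification cannot distinguish a supercritical Hopf
  from a very weakly subcritical one (fold of cycles closer to onset
  than the probe offset).
* The stochastic DNA-binding model treats operator occupancy as a
  Hill-modulated transcription propensity rather than an explicit
  bound/unbound operator species; at one binding site and fast
  operator kinetics these coincide in the mean, not in higher
  moments.
* No tau-leaping: runs at 100-fold volume take minutes, and larger
  volume factors are impractical with the exact sampler.
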