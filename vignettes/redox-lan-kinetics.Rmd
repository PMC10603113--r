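---
title: "Kinetics of iron redox communication in a two-species co-culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of iron redox communication in a two-species co-culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxlan)
```

## The system

Two bacterial species exchange a redox signal through a shared, closed
iron pool. *Shewanella putrefaciens* (the "router") respires on Fe³⁺ and
reduces it to Fe²⁺; *Rhodopseudomonas palustris* (the "actuator") takes up
electrons from Fe²⁺, reoxidizing it to Fe³⁺ while growing
photoferrotrophically. A Zn₂GeO₄:Mn persistent-luminescence nanoprobe reads
the redox state of the pool out non-destructively: its log₁₀ intensity is
linear in the Fe²⁺/Fe_total ratio. The pool is fixed at Fe_total = 2 mM,
all of it initially Fe³⁺, over a 96-h incubation started from a 1 %
inoculum of each species (0.008 OD₆₀₀).

This package implements the quantitative layers of that system: probe and
absorbance calibration, monoculture transduction kinetics, the coupled
co-culture model, parameter estimation, and a synthetic-data generator
that stands in for the wet-lab measurements so everything is testable
offline.

## Calibration

The probe calibration is the line

$$\log_{10}(I) = a \, C_{\mathrm{Fe^{2+}}/\mathrm{Fe_{total}}} + b,
\qquad a = 0.01764,\; b = 2.126,$$

with the ratio expressed in **percent** (0–100). The percent convention is
a package decision: the printed slope spans a plausible log-intensity
range (2.126 at 0 % to 3.890 at 100 %) only if the ratio is a percentage;
a fraction convention (0–1) is selectable for users whose instruments
report fractions. Inverse prediction divides out the slope and clips
readouts that fall slightly outside the calibrated range (flagging them)
rather than rejecting them, since measurement noise routinely pushes a
readout past the end of a standard curve. Raw intensities are
log-transformed before any fitting; non-positive intensities are rejected
outright instead of being offset-shifted, because an additive offset would
silently change the slope.

The same least-squares machinery serves the o-phenanthroline absorbance
curve (absorbance at 510 nm against Fe²⁺ concentration, `"absolute"`
convention).

```{r}
cal <- probe_calibration()
predict_log_intensity(cal, c(0, 50, 100))
fe2_from_intensity(cal, 10^3.008, fe_total = 2)
```

## Monoculture transduction: the 4PL primitive

Fe²⁺ in a bare monoculture follows a four-parameter logistic in time,

$$f(t) = B + \frac{A - B}{1 + (t/C)^D},$$

with early asymptote $A$, late asymptote $B$, half-transition time $C$
(hours; $f(C) = (A+B)/2$ exactly) and shape $D$. A bare router culture
accumulates Fe²⁺ (the curve itself); a bare actuator culture is written
for the transformed pool, so its Fe²⁺ observable is $\mathrm{Fe_{total}} - f(t)$.

Fitting uses Levenberg–Marquardt least squares. When no initialization is
given, $A$ and $B$ start at the first and last observed values, $C$ at the
time closest to their midpoint, and $D = 2$ — standard 4PL practice.
Default bounds ($C \le 10\,t_{\max}$, $D \le 20$, asymptotes within the
observed range widened by one range) prevent divergence on nearly flat
data. Exactly constant data leave the likelihood flat in $(C, D)$; the fit
then returns the canonical tie-break $C = \mathrm{median}(t)$, $D = 1$,
flagged degenerate, so output is deterministic. The loss is unweighted
least squares.

## The co-culture model

The state is (router OD, actuator OD, Fe²⁺); Fe³⁺ is **never integrated**
but derived as $\mathrm{Fe_{total}} - \mathrm{Fe^{2+}}$, which makes iron
conservation exact by construction. With $[S]$, $[R]$ the densities and
$f$ the Fe²⁺ concentration:

$$\frac{d[S]}{dt} = f \,[S]\, g_S(t), \qquad
\frac{d[R]}{dt} = (\mathrm{Fe_{total}} - f) \,[R]\, g_R(t), \qquad
\frac{df}{dt} = [S]\, q_S(t) - [R]\, q_R(t).$$

Each per-cell coefficient is a "rate block": a constant amplitude over a
4PL-shaped denominator, moving sigmoidally from amplitude/early_denom at
$t = 0$ to amplitude/late_denom. Growth blocks carry the symbols
$E, F, G, H, I$ per species and Fe-rate blocks $J, K, L, M, N$, and the
flat parameter files use exactly those names so a reader can cross-check a
configuration against the equations.

Two modelling notes. First, the actuator's growth is driven by the Fe³⁺
pool $(\mathrm{Fe_{total}} - f)$ even though the organism oxidizes Fe²⁺;
this follows the source equations as printed. An `actuator_driver = "fe2"`
switch exposes the inverted variant for sensitivity analysis only.
Second, the single Fe²⁺ state is shared: the per-species Fe²⁺ symbols in
the growth equations all refer to the same pool.

### Packaged default parameters

No numeric kinetic constants are published for the co-culture; the
packaged defaults were derived once, by inverse design, from the
documented features of the dynamics: Fe²⁺ rises from 0 to a **0.76 mM**
peak near mid-incubation and declines thereafter, while both OD channels
grow monotonically from 0.008 OD to about 1 OD. Target trajectories with
those features were converted to the rate coefficients they imply, rate
blocks were fitted to the coefficients, and a few amplitudes were polished
so the simulated peak lands on 0.76 mM (the shipped set gives 0.7597 mM at
51.25 h, declining to 0.33 mM at 96 h). The full derivation ships as
`scripts/derive_default_params.R` in the source repository.

```{r}
traj <- simulate_lan(default_truth(), times = seq(0, 96, by = 2))
find_peak(traj$time_h, traj$fe2_mM)
conservation_report(traj)
```

### Numerical choices

Integration uses an adaptive explicit Runge–Kutta scheme (Dormand–Prince
4(5), deSolve's `ode45`) at relative/absolute tolerances 1e-8/1e-10.
Solver round-off can leave Fe²⁺ marginally outside $[0, \mathrm{Fe_{total}}]$;
excursions are clamped in post-processing, the clamp magnitude is recorded
on the trajectory, and clamps above 1e-6 mM raise a warning.

Two properties of this model deserve attention:

* **Error amplification.** Growth is signal-driven and exponential over
  roughly five ln-units, with a positive feedback loop (more Fe²⁺ → more
  router biomass → more Fe²⁺ production). Early numerical error is
  amplified about a thousand-fold by 96 h. At the production tolerances
  the trajectory is converged to ~1e-6 (halving or tightening the
  tolerances changes nothing beyond that), but runs at much looser
  tolerances (say rtol 1e-6) carry ~1e-4-scale global error with *any*
  integrator. The refinement check in the test suite therefore compares
  the production tolerances against halved and ten-fold-tightened runs.
  Shape exponents in the rate blocks are kept at or above 1.5 during
  derivation: $t^p$ with $p < 1$ has unbounded slope at $t = 0$, which
  destroys the accuracy of explicit Runge–Kutta steps across the origin.

* **Finite-time blow-up.** The printed equations have no saturation. If
  Fe²⁺ overshoots the pool size, the actuator driver turns negative, the
  consumption side collapses, and router growth runs away in finite time;
  growth amplitudes only ~5 % above the defaults already diverge. The
  integrator therefore runs inside a guarded core: once the state leaves a
  generous trust region the solution is frozen and the escape time
  recorded. `simulate_lan()` turns that into an informative error;
  the fitting objective instead converts escape time into a finite,
  continuous penalty so the optimizer can find its way back into the
  integrable region from a bad initialization.

## Fitting and the recovery harness

`fit_lan_model()` fits any subset of the 24 parameters to any combination
of the observable channels (Fe²⁺, router OD, actuator OD) by
Levenberg–Marquardt. Channels carry different units, so each channel's
residuals are standardized by its observed range — a scale estimate that is
robust on short (9-point) series, unlike a variance. Because jointly
estimating all constants from a single-condition time course is ill-posed,
the default frees the growth blocks and keeps the Fe-rate blocks fixed at
their initialization (typically monoculture pre-fits), mirroring how the
co-culture model is constructed on top of the bare-culture ones. The
accepted-step rule of Levenberg–Marquardt guarantees the returned residual
sum of squares never exceeds the initialization's.

`recovery_experiment()` quantifies the workflow end-to-end: per seed it
generates a noisy synthetic series, perturbs the free parameters of the
initialization by up to ±15 %, refits, and scores the per-channel Pearson
correlation between the fitted trajectory and the noisy observations. The
default mask frees only the two growth amplitudes (`E_S`, `E_R`) — they
are the dominant, well-identified directions, and the hair-trigger
sensitivity described above means the data pin them very tightly. At the
default noise, 25 seeds give median correlations of about 0.97 on the
Fe²⁺ channel and >0.999 on the OD channels, with sub-percent relative
RMSE on the free parameters.

## The synthetic generator

`generate_coculture_series()` emulates the measured channel set: additive
Gaussian noise on Fe²⁺ (sd 0.08 mM) and OD (sd 0.02), a raw luminescence
channel obtained by passing the noise-free Fe²⁺/Fe_total ratio through the
probe calibration with mean-centred multiplicative log-normal noise (CV
5 %), and an absorbance channel as a linear map of Fe²⁺ (0.5 AU/mM + 0.02
blank, an effective phenanthroline response) with additive noise (sd
0.01). The default grid samples 0–96 h every 12 h. The noise magnitudes
are calibrated, not measured: replicate-level noise is not published, so
the defaults were chosen to reproduce the reported model–data fidelity
(Pearson R ≈ 0.9 on Fe²⁺, ≈ 0.99 on OD) and the ≥ 0.99 correlation between
the paired luminescence and absorbance readouts.

Noisy concentrations are truncated into their physical ranges and the
truncation count recorded. Note that at $t = 0$ the clean values sit *on*
the boundary (no Fe²⁺ yet; OD at the inoculum), so roughly half of the
draws there truncate by construction; away from the boundaries truncation
is rare (≪ 1 %).

What the generator does **not** emulate: replicate correlation structure,
instrument drift, heteroscedasticity along the curve, or any biological
deviation from the ODE model itself. Passing recovery tests therefore
demonstrates the estimator is correct *under the model*, not that the
model is correct for any particular culture.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data: 9-point grids (0–96 h every
12 h) for generation and fitting, 25-seed recovery and correlation
experiments, 100-seed calibration recovery, 50 random truths for the 4PL
refit oracle, and a ~1300-point brute-force grid as the independent check
on the 4PL optimizer. These sizes give stable medians and means while
keeping the whole suite fast.

## Known limitations

* The model is the printed two-species system: no third species, no
  electron-shuttle or inhibitor terms, no oxygen/light dependence, no
  spatial structure, and no product (lycopene) state variable.
* The equations blow up for parameter regions that overshoot the iron
  pool; the package diagnoses this rather than re-parameterizing the
  model, since the equations are implemented as printed.
* Default kinetic constants are a reconstruction consistent with the
  documented dynamics, not published values; treat them as a realistic
  operating point, not as measurements.
* The 1 OD ≙ 10⁹ cells conversion (`od_to_cells()`) is a reporting
  convention, applied only at boundaries, never inside the dynamics.
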