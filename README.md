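# redoxlan

Kinetic modelling of Fe³⁺/Fe²⁺ redox communication in a two-species
microbial co-culture — a "biological LAN" in which an iron-reducing router
(*Shewanella putrefaciens*) and an iron-oxidizing actuator
(*Rhodopseudomonas palustris*) exchange electrons through a shared 2 mM
iron pool, read out optically by a persistent-luminescence nanoprobe.

The package is for quantitative microbiologists and systems biologists who
want to simulate, fit, and stress-test this class of redox-coupled
co-culture model without wet-lab data: every stage runs on synthetic
observations with the measurement structure of the real experiment.

## The model

Probe calibration (ratio in percent):

```
log10(I) = 0.01764 * C_Fe2+/Fe_total + 2.126
```

Monoculture transduction is four-parameter logistic,
`f(t) = B + (A − B) / (1 + (t/C)^D)`; a bare router culture accumulates
Fe²⁺ along the curve, a bare actuator culture along `Fe_total − f(t)`.

The co-culture couples the two species through the shared pool
(state: router OD `[S]`, actuator OD `[R]`, Fe²⁺ `f`; Fe³⁺ is derived as
`Fe_total − f`, so conservation is exact):

```
d[S]/dt = f * [S] * g_S(t)
d[R]/dt = (Fe_total − f) * [R] * g_R(t)
df/dt   = [S] * q_S(t) − [R] * q_R(t)
```

with each per-cell coefficient a constant amplitude over a 4PL-shaped
denominator (symbols E..I for growth, J..N for the Fe rates). Integration
is adaptive explicit Runge–Kutta (Dormand–Prince 4(5)) at tolerances
1e-8/1e-10. Estimation is Levenberg–Marquardt over a configurable free
subset of the 24 parameters, with per-channel range standardization.

## Worked example

```r
library(redoxlan)

# simulate the packaged co-culture conditions: 2 mM Fe3+, 96 h
traj <- simulate_lan(default_truth(), times = seq(0, 96, by = 2))
find_peak(traj$time_h, traj$fe2_mM)
#> $t_peak
#> [1] 52
#> $peak
#> [1] 0.7595825
#> $interior
#> [1] TRUE

# generate a noisy observation table and refit the growth amplitudes
obs <- generate_coculture_series(noise = noise_spec(seed = 7))
fit <- fit_lan_model(obs, default_truth(), free = c("E_S", "E_R"))
fit
#> Co-culture model fit: 2 free parameter(s) [E_S, E_R]
#>   standardized RSS = 0.1294, converged = TRUE, iterations = 3

pearson_r(obs$cells_S_od, fit$fitted$cells_S_od)
#> [1] 0.9992892
```

The peak is the shared Fe²⁺ pool cresting at ~0.76 mM mid-incubation
before actuator consumption overtakes router production; the Pearson
correlations quantify model–data agreement per channel (≈0.97 for Fe²⁺ and
>0.99 for OD at the default noise).

A thin command-line wrapper ships in `inst/cli/redoxlan.R`
(`generate`, `calibrate`, `fit-4pl`, `simulate`, `fit-lan`, `recover`,
`run`), and `run_pipeline()` executes the full
generate → calibrate → fit → simulate → refit chain into one directory.

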