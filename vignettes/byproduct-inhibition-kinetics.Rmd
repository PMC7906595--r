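---
title: "Modeling byproduct inhibition in batch alcoholic fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling byproduct inhibition in batch alcoholic fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermkin)
```

## The model

During glucose fermentation by *Saccharomyces cerevisiae* the major
secondary metabolites — glycerol, acetic acid and succinic acid — accumulate
in the broth in near-constant proportion to the glucose consumed. Although a
batch run never accumulates enough of them to stop fermentation outright,
they measurably depress the growth rate, and the effect compounds over the
run. `fermkin` models this with a multiplicative correction to the Monod
law. Writing $X$, $S$, $P$, $Z$ for the biomass, glucose, ethanol and lumped
byproduct concentrations (g/L):

$$\mu(S, Z) = \mu_{max,0}\,\frac{S}{K_s + S}\, f(Z),$$

$$\frac{dX}{dt} = \mu X,\qquad
  \frac{dS}{dt} = -\frac{\mu X}{Y_{x/s}},\qquad
  \frac{dP}{dt} = -Y_{p/s}\frac{dS}{dt},\qquad
  \frac{dZ}{dt} = -Y_{z/s}\frac{dS}{dt}.$$

The inhibition factor $f$ acts only on the maximum specific growth
coefficient: in byproduct-spiking experiments the half-saturation constant
stays within a narrow 11.4–11.7 g/L band while the observed $\mu_{max}$
falls from 0.244 h⁻¹ to zero as $Z$ approaches a critical concentration
$Z_m$. Because $K_s$ is untouched, multiplying $\mu_{max,0}$ or the whole
Monod term is numerically identical; the package applies $f$ to the full
term.

Assumptions worth stating explicitly:

* **Lumped byproduct.** Glycerol, acetate and succinate act through one
  combined concentration $Z$ (the spiking experiments used the mixture in
  its naturally occurring 56/36/8 mass ratio). Per-component inhibition
  constants are out of scope; `split_byproducts()` only partitions $Z$
  for reporting.
* **Constant yields.** $Y_{x/s}$, $Y_{p/s}$, $Y_{z/s}$ are constants of the
  run (measured values vary little over $S_0$ = 25–250 g/L). This makes
  $X$, $P$ and $Z$ affine functions of consumed substrate — the
  mass-balance identities the test suite checks at every grid point.
* **No maintenance or decay term**, no ethanol or substrate inhibition, no
  pH/temperature dependence: the model targets the byproduct effect in
  isolation, under the conditions where it was calibrated.

## Inhibition families

Any candidate $f$ must satisfy $f(0) = 1$ and $f(Z_m) = 0$ and decrease
monotonically in between. Three families are built in, all defined on the
scaled concentration $z = \min(Z/Z_m, 1)$:

| family | $f(z)$ | free parameters |
|---|---|---|
| `linear` | $1 - z$ | $\mu_{max,0}$, $Z_m$ |
| `parabolic` | $1 - z^2$ | $\mu_{max,0}$, $Z_m$ |
| `exponential` | $(1 - z)^{K_z}$ | $\mu_{max,0}$, $Z_m$, $K_z$ |

The `exponential` tag denotes the Luong-type power law. A literal
exponential $e^{-K_z Z}$ cannot reach zero at finite $Z_m$, so it fails the
stated limit conditions; the power law satisfies both and admits the
calibrated exponent $K_z = 0.83$ directly. This reading was fixed once as a
design decision; the family registry
(`register_inhibition_family()`) is deliberately open so an alternative
functional form can be added without touching the solver or the fitting
code. With $K_z = 1$ the power law reduces to the linear family — which is
why family selection breaks R² ties toward fewer parameters.

Beyond $Z_m$, $f$ is clamped at zero: growth stops, it does not reverse.

## Calibrated defaults

All defaults are the calibrated values of the source study and are bundled
in `reference_fixtures()`:

* $\mu_{max,0} = 0.244$ h⁻¹, $K_s = 11.5$ g/L (midpoint of the observed
  11.4–11.7 band), $Z_m = 60$ g/L, $K_z = 0.83$;
* yields $Y_{x/s} = 0.28$, $Y_{p/s} = 0.42$, $Y_{z/s} = 0.0442$ g/g
  (averages of six runs at $S_0$ = 25–250 g/L);
* inoculum $X_0 = 1$ g/L, $P_0 = Z_0 = 0$ ($Z_0 > 0$ is supported for
  spiked-byproduct experiments);
* simulation horizon 72 h, the duration of the monitored runs.

Units are fixed package-wide (h, g/L, h⁻¹); there is no conversion layer.

## Numerical choices

**Integrator.** The reference integrator is the classical fixed-step RK4
with `dt = 0.01` h. A fixed step keeps runs bit-reproducible and makes the
convergence order directly testable (halving `dt` shrinks the Richardson
difference ≈16×). Stage values that overshoot a concentration below zero
are clamped to zero before the rate evaluation; because every rate is
proportional to the same $\mu X$ term, clamping preserves the
stoichiometric coupling exactly, and the mass-balance residual stays below
$10^{-6} S_0$ along complete trajectories. Substrate exhaustion freezes the
system ($S \le 0 \Rightarrow$ all derivatives 0).

**Fermentation time.** Monod dynamics only reach $S = 0$ asymptotically,
so "fermentation complete" needs a convention: the package uses the time at
which 99% of the initial substrate is consumed
(`threshold_fraction = 0.01`, configurable), linearly interpolated between
the bracketing grid samples. `model_delay()` reports how much later the
inhibited model reaches that point than classical Monod with the same
constants; the delay is positive and grows with $S_0$, since more substrate
means more accumulated byproduct.

**Inhibition fitting.** `fit_inhibition()` minimizes squared residuals of
$\mu_{max,0} f(Z)$ with Levenberg–Marquardt under box constraints
(`minpack.lm::nls.lm`). Starting values are multi-start: $Z_m$ at 1.2× the
largest $Z$ with observed growth, $K_z \in \{0.5, 1, 2\}$, $\mu_{max,0}$ at
the $Z = 0$ observation; the lower bound keeps $Z_m$ above every
concentration with nonzero growth. $\mu_{max,0}$ is free by default and can
be fixed by flag. Non-convergence is reported honestly in the result, never
raised as an error. R² uses deviations about the observation mean. On
noise-free data every family round-trips to its generating parameters
within $10^{-4}$ relative error.

**Monod fitting from a time course.** `fit_monod_params()` fits
$(\mu_{max}, K_s)$ by simulating the classical model inside the objective
and comparing biomass and glucose jointly, each residual divided by that
variable's observed range so neither dominates. The objective integrates at
`dt = 0.1` h (discretization bias ~$10^{-8}$, far below measurement noise)
and is minimized by Nelder–Mead on log-parameters from two half-saturation
starts. One caveat belongs here rather than in small print: with a sparse
13-sample schedule, $K_s$ is informed only by the brief transition around
substrate exhaustion, so under realistic noise its point estimate can move
far while the fitted trajectory barely changes. Noise-free courses are
recovered essentially exactly; noisy-data users should read the objective
value and the fitted curve, not the bare $K_s$.

## What the synthetic data emulate — and what they do not

`generate_timecourse()` reproduces the monitored-batch design: the 13-point
sampling schedule (0, 2, ..., 72 h) and measurement error modeled as
multiplicative Gaussian noise (default 5% relative, an approximation of
HPLC repeatability) with an optional additive floor, truncated at zero.
`generate_mu_vs_z()` emulates the spiking experiment behind the inhibition
curve: growth coefficients at $Z$ = 0–55 g/L, with the observed $K_s$ drawn
uniformly from its empirically stable band. Both are deterministic given
the seed; the lactic-acid channel is absent throughout (uncontaminated
fermentations produce none).

The generators inherit the model's own idealizations: no autocorrelated
sensor drift, no inter-run biological variability, no model misspecification
— the data-generating process *is* the fitted model plus white noise. A
passing recovery test therefore demonstrates internal consistency and
statistical power under the stated noise, not that the model is correct for
any particular broth.

## Validation protocol and problem sizes

The shipped test suite checks, among others:

* mass balance within $10^{-6} S_0$ at `dt = 0.01` h for $S_0$ = 100, 150,
  200 g/L, and fourth-order grid convergence;
* agreement with the closed-form exponential solution ($K_s \to 0$, no
  inhibition) to $10^{-8}$ relative at `dt = 0.001` h, and with an
  independent fixed-step RK4 implementation (deSolve) on identical rate
  equations;
* pointwise $S_{modified}(t) \ge S_{Monod}(t)$ and a fermentation-time
  delay non-decreasing over $S_0 \in \{100, 150, 200\}$ g/L;
* model comparison on synthetic inhibited data: MSE/RMSE pooled over the
  three validation concentrations favor the modified model for substrate
  and product. Pooling mirrors how such validation statistics are reported
  for multi-run designs; a single 13-sample course at one concentration
  does not reliably separate two models whose trajectories differ by less
  than the noise. Biomass cannot discriminate at all here: both models
  share the identical stoichiometric plateau.
* bootstrap calibration: percentile intervals (199 resamples) for
  $(Z_m, K_z)$ cover the generating values in ≥ 90% of 200 replicates at
  5% noise.

## Limitations

* Batch operation only — no fed-batch or chemostat terms, although the
  inhibition effect is expected to matter *more* under long continuous
  operation where byproducts accumulate further.
* The lumped-$Z$ treatment cannot attribute inhibition to individual
  byproducts, and the calibration is strain- and condition-specific
  ($K_z$ in particular).
* The fixed-step integrator is adequate for these mildly nonlinear
  dynamics but is not a stiff solver.
* Printed reference values (the yield table, endpoint concentrations,
  calibrated constants) enter as literal fixtures; the underlying raw
  time courses are not public, so error statistics against the original
  experiments are reproducible only in their qualitative ordering, which
  is what the pooled comparison checks.
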