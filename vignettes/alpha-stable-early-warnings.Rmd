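---
title: "Early warning signals under alpha-stable noise: models, estimators, and protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early warning signals under alpha-stable noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphaews)
library(dplyr)
```

## The problem

Statistical early warning signals (EWS) anticipate tipping points in noisy
dynamical systems: as a bifurcation parameter $k$ approaches the bifurcation
at $k = 0$, the restoring force weakens ("critical slowing down") and the
response to noise inflates. The classical indicators — rising variance and
lag-1 autocorrelation — rest on Gaussian small-noise theory. Many
environmental time series, however, are heavy-tailed. This package studies
the one-dimensional model

$$dX(t) = -U'(X(t), k)\,dt + dN^{(\alpha)}(t),$$

where $N^{(\alpha)}$ is a symmetric $\alpha$-stable (Lévy) process with
characteristic exponent $\alpha \in (0, 2]$ and scale $\gamma_N$, and $U$ is
either the linear Ornstein–Uhlenbeck (OU) potential $k x^2/2$ or the fold
(saddle-node) potential $x^3/3 - kx$. For $\alpha < 2$ the driving noise has
infinite variance, so the *sample* variance of the response never converges:
it keeps drifting upward with sample size, which can masquerade as an early
warning signal even when the system is perfectly stationary (a false
positive). The package implements the remedy: the stable **scale parameter**
$\gamma_X$ of the response, which is always defined, and for the stationary
linear response obeys

$$\gamma_X = \gamma_N \left(\frac{1}{\alpha k}\right)^{1/\alpha},$$

strictly increasing as $k \downarrow 0$. At $\alpha = 2$ this reduces to the
classical Gaussian variance scaling, since a Gaussian stable law with scale
$\gamma$ has variance $2\gamma^2$, so $\operatorname{Var}X = 2\gamma_X^2 =
\gamma_N^2/k$.

A note on that last constant: with the scale convention
$\varphi(u) = \exp(-\gamma^\alpha|u|^\alpha)$ used throughout, the increments
of the Gaussian driving process over $dt$ have variance $2\gamma_N^2\,dt$.
The stationary OU variance is therefore $\gamma_N^2/k$, and `ou_variance()`
implements exactly that — it is the unique prefactor under which the
variance route and the scale route agree to machine precision
(`sqrt(ou_variance(Inf, k, g)/2) == gamma_x_limit(k, 2, g)`), which the test
suite asserts to 12 significant digits. One sometimes sees the prefactor
quoted as $\gamma_N^2/(2k)$; that corresponds to a driving process whose
unit-time variance is $\gamma_N^2$ rather than $2\gamma_N^2$ and is
inconsistent with this package's (and the stable literature's) scale
convention.

## The stable family and its sampler

`stable_params(alpha, gamma)` pins the symmetric centered family
$S\alpha S(\gamma)$: skewness and location are fixed at zero and rejected
otherwise. Closed-form densities exist only at $\alpha = 2$ (Gaussian) and
$\alpha = 1$ (Cauchy) and are exposed via `sas_pdf()`; all other densities
are deliberately *not* part of the API (the tests reproduce them by numeric
Fourier inversion of `sas_cf()` where needed).

Sampling uses the Chambers–Mallows–Stuck (CMS) transform of a uniform angle
$\Theta$ on $(-\pi/2, \pi/2)$ and a unit exponential $W$. Two design points
matter:

* **Base-draw sharing.** The pair $(\Theta, W)$ is generated from the seed
  *before* the $\alpha$-dependent transform, so the same seed consumes the
  same base randomness for every $\alpha$. Extreme angle events (the driver
  of heavy-tail extremes) then hit the same sample indices across all
  heavy-tailed $\alpha$, which is what makes cross-$\alpha$ comparisons of
  simulated trajectories meaningful. The Gaussian endpoint is the one
  exception: at $\alpha = 2$ the angle factor $\sin(2\Theta)$ stays bounded
  and extremes come from large $W$ instead, so Gaussian extremes do not
  co-locate with heavy-tail extremes — a structural fact of the family, not
  of the sampler.
* **Scale convention.** $\alpha = 2$ means variance $2\gamma^2$, not
  $\gamma^2$. All estimator factors (e.g. the Gaussian IQR-to-scale factor
  1.908 rather than $2 \times 0.6745 = 1.349$ or $2.698$) follow from this;
  mixing conventions is the classic $\sqrt2$ bug, and the test suite pins
  the factor numerically.

```{r}
z <- sas_sample(1e4, stable_params(2, 1), seed = 1)
var(z)  # close to 2 = 2 * gamma^2
```

## Integration: tamed Euler–Maruyama

Heavy-tailed increments occasionally throw the state far from equilibrium;
under the superlinear fold drift the plain Euler–Maruyama update then
explodes in a few steps. The package's default scheme tames the drift,
$-U' \mapsto -U'/(1 + \epsilon|U'|)$, bounding the per-step drift
displacement by $\Delta t/\epsilon$ while perturbing it only at order
$\epsilon|U'|$ near equilibrium. The plain scheme is kept
(`plain_euler_maruyama()`) as a reference and to demonstrate the documented
blow-up; divergence is flagged on the returned trajectory rather than
thrown.

Numerical choices, with defaults:

| parameter | default | why |
|---|---|---|
| $\Delta t$ | 0.004 | reference study conditions; resolves the fastest rate on the $k$ grids ($k\Delta t \le 0.4$) |
| $\epsilon$ | $\Delta t/100 = 4\times10^{-5}$ | only a bound "$\epsilon \ll \Delta t$" is principled; this perturbs the drift by 0.004% at $|U'| = 1$ yet caps post-jump displacement at 100 per step. Conclusions are insensitive across $\epsilon \in [\Delta t/1000, \Delta t/10]$ |
| $X_0$ | 0.5 | near, not at, the stable state of both reference models |
| $\gamma_N$ | 0.1 | reference noise scale |

The closed-form theory assumes $X_0 = 0$; simulations start at $X_0 = 0.5$,
so every protocol discards a burn-in before comparing to theory. The
$k$-schedule is held piecewise constant within a step and evaluated at the
step's start (the standard explicit-scheme convention). For the fold model
a trajectory is stopped once the post-update state falls below
$-\sqrt k - k/10$, just past the basin boundary at the unstable fixed point
$-\sqrt k$; beyond it the deterministic flow runs to $-\infty$, so
continuing would only record the blow-up. The stopping rule is evaluated at
the current step's $k$.

## Estimating the indicator

`fit_sas_quantile()` is the default estimator: the tail-width ratio
$\nu_\alpha = (q_{.95}-q_{.05})/(q_{.75}-q_{.25})$ is inverted to
$\hat\alpha$ through a table of the standard stable law's quantiles
(computed once by numeric inversion of the stable distribution function and
frozen as plain constants; anchors 2.439/1.908 at the Gaussian end and
6.314/2 at the Cauchy point agree with the published quantile-estimator
literature), then $\hat\gamma = \mathrm{IQR}/c(\hat\alpha)$. Quantiles use
linear interpolation between order statistics, so the estimate varies
continuously with $n$; $\hat\alpha$ is clipped to $[0.6, 2]$, the table's
validity range. `fit_sas_ecf()` — regression of
$\log(-\log\hat\varphi(u))$ on $\log u$ — is the independent cross-check;
the two agree on common draws within the tolerances asserted in the tests.

By default both parameters are estimated jointly, because in applications
$\alpha$ is unknown; `fixed_alpha` fixes the exponent where the driving tail
index is treated as known (the sensitivity tests use it). The windowed
series operate on **raw states** with **trailing (causal) windows** anchored
at their last point — an early-warning statistic must not look into the
future — and within the slow reference ramp the fixed-point drift across
one 300-point window (a change of at most 0.03 in $k$) is treated as
negligible. `smooth_series()` is a centered moving average with symmetric
edge shrinkage, a presentation aid only; decision rules should use the raw
series.

Small-window caution: a window of 300 *consecutive* states spans few
correlation times when $k$ is large (at $k = 5$, $\tau = 1/k$ is 50 steps,
so about 6 effective samples). The sample IQR of so short a correlated
segment systematically underestimates the marginal IQR, biasing
single-window $\hat\gamma_X$ low by on the order of 10–15% at the start of
the reference ramp, with large window-to-window scatter. Medians or means
across many windows/trajectories, as used in the protocols, are the
reliable readout.

## The three protocols (and what the generator does and does not emulate)

`ews_experiment()` freezes the study conditions; its defaults *are* the
reference conditions, not tuning knobs.

1. **Equilibrium** (`run_equilibrium()`): constant $k \in \{100, 10, 1,
   0.1, 0.01\}$, 100 estimations, each pooling 70 thinned points from each
   of 5 trajectories of 10 000 steps. Burn-in is the first 30% of steps and
   the 70 points are evenly spaced over the remainder — the printed count is
   fixed by the protocol, the selection scheme is this package's documented
   choice (spacing $\gg$ the correlation time over most of the $k$ grid).
   Within an estimation the identical noise sequence is reused across the
   whole $k$ grid, and base seeds are shared across $\alpha$, so the $k$-
   and $\alpha$-dependence is pure drift response. Fold replicates whose
   trajectories escape are flagged `stopped`, kept in the output, and
   excluded from theory comparisons by `summarise_equilibrium()` (their
   data are basin-truncated); they still enter the qualitative trend
   summaries. At $k = 0.01$ equilibrium is genuinely not reached within
   10 000 steps (the relaxation time exceeds the trajectory), matching the
   known deviation very close to the bifurcation.
2. **Non-equilibrium ramp** (`run_nonequilibrium()`): 10 000 equilibration
   steps at $k = 5$, then $k$ stepped down by $10^{-4}$ per integration
   step. The ramp stops one step short of $k = 0$: "5 to 0 by $10^{-4}$"
   admits 50 000 or 50 001 grid points, and the protocol's step count fixes
   50 000, so the bifurcation value itself is never simulated (last value
   $10^{-4}$). Indicators every 150 steps on trailing 300-point windows →
   332 anchors; 100-point smoothing applies to the *estimate* series (not
   the states — the smoothing is presentational, and smoothing states
   before estimation would distort the fitted scale).
3. **Divergence demonstration** (`run_divergence()`): 100 OU trajectories
   at constant $k = 1$, 10 000 equilibration + 10 000 measurement steps,
   expanding-window running statistics every 300 steps. The running
   variance keeps jumping for $\alpha < 2$ (each fresh extreme resets it)
   while the running $\hat\gamma_X$ settles — the false-positive contrast.
   Note the quantitative honesty required here: at $k = 1$ the measurement
   segment spans only ~40 correlation times, so even the *Gaussian* running
   variance still fluctuates by tens of percent between mid-run and the
   end; the contrast between the two indicators, and between $\alpha = 2$
   and $\alpha < 2$, is the robust readout, not any individual
   stabilization count.

Per-trajectory seeds derive from the master seed by a fixed counter scheme
(independent of $\alpha$ and $k$ by design); a protocol rerun with the same
master seed is bit-identical.

What the generator emulates: stationary heavy-tailed forcing of a slowly
ramped one-dimensional system. What it does not: skewed or shifted stable
laws, temporally correlated ("red") noise, measurement error,
multi-dimensional dynamics, and post-tipping behavior ($k < 0$). Passing
tests therefore demonstrate the indicator's behavior under ideal
$S\alpha S$ forcing, not robustness to the further non-idealities of field
data.

## Problem sizes used by the test suite

The suite exercises reduced but statistically meaningful sizes, chosen as
the package's own test design: stationary-law recovery on $2\times10^6$-step
OU paths; equilibrium protocols at 20 of 100 estimations; the ramp protocol
at 5 of 15 trajectories; the divergence demonstration at its full 100
trajectories; estimator sweeps at $n = 5000$ and $5\times10^4$ across 100
seeds. The acceptance script (`scripts/acceptance.R`) recomputes the same
quantities from scratch at these sizes.

## Known limitations

* The quantile tables cover $\alpha \in [0.6, 2]$; more extreme exponents
  are clipped.
* No theoretical lag-1 autocorrelation is provided for $\alpha < 2$ (none
  is available); `lag1_autocorr()` is the empirical statistic only.
* $\gamma_X$ theory is exact for the linear model and first-order
  (linearization, $\kappa = 2\sqrt k$) for the fold; agreement degrades
  very close to and very far from the bifurcation, where higher-order terms
  and basin escapes dominate.
* Estimation from short windows of correlated states is biased low (see
  above); window length trades bias against responsiveness and is left to
  the user in applications.

## A worked call

```{r}
theory_table(k = c(10, 1, 0.1), alpha = c(2, 1.3), gamma_n = 0.1) |>
  select(k, alpha, gamma_x)

spec <- ews_experiment("equilibrium", model = "ou", alphas = c(2, 1.3),
                       k_values = c(10, 1), n_replicates = 3,
                       n_steps = 5000, master_seed = 1)
summarise_equilibrium(run_equilibrium(spec))
```
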