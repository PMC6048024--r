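---
title: "Modelling and measuring chitin particle degradation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring chitin particle degradation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chitindeg)
library(dplyr)
```

## The system and the model

Marine particulate organic matter is consumed by bacteria that attach to
particle surfaces, secrete hydrolytic enzymes, and grow on the released
monomers. `chitindeg` models this for a single strain colonizing a model
chitin particle with two coupled processes: attachment of planktonic cells
and growth-coupled depolymerization by attached cells. With bacterial load
rescaled by the biomass conversion factor, the dynamics are

$$\frac{db}{dt} = \alpha + \beta\, b^{\,n}, \qquad
  \frac{dR}{dt} = -\beta\, b,$$

with $b(0) = 0$ and $R(0) = R_0$. The parameters, their units and their
interpretation:

- $\alpha$ — rescaled attachment rate ($a_0 [B]_0 / r$; with the package's
  default convention $r = 1$, simply $a_0 [B]_0$). It sets how fast the
  founding population accumulates and is the only parameter through which
  the planktonic concentration $[B]_0$ (cells/ml) enters.
- $\beta$ — combined degradation–growth rate $r\,p$ (1/h). It is both the
  exponential growth rate of the attached population and the per-capita
  depolymerization scale.
- $n$ — cooperativity exponent. $n = 1$ is mass action (no density
  dependence); $n > 1$ makes per-capita growth increase with density, as
  expected if secreted enzymes act as shared public goods.
- $R_0$ — initial particle resource, in abstract resource units. Neither
  a monomer count nor a volume is implied; only ratios such as
  $\beta R_0 / \alpha$ matter to the dynamics.

For $n = 1$ the system has the closed form
$b(t) = (\alpha/\beta)(e^{\beta t} - 1)$ and
$R(t) = R_0 - b(t) + \alpha t$, implemented in
`closed_form_trajectory()`; `integrate_trajectory()` solves the general
case with deSolve (rtol $10^{-8}$, atol $10^{-10}$). The two agree to
better than $10^{-6}$ relative error over the full degradation window,
which the test suite verifies over random parameter draws, along with the
exact mass-accounting identity $R_0 - R(t) = b(t) - \alpha t$.

The particle half-life $\tau_{1/2}$ is the time at which $R = R_0/2$;
because consumed resource is strictly increasing (for $\alpha > 0$),
`model_half_life()` finds it by bracketed root finding (time tolerance
$10^{-6}$ h). When attachment is slow compared to growth
($\alpha \ll \beta R_0$), the total degradation time is approximately

$$T = \frac{1}{\beta}\left(\ln R_0 + \ln \beta + \ln \frac{1}{\alpha}\right),$$

linear in $-\ln [B]_0$: every tenfold dilution of the inoculum delays
degradation by $(1/\beta)\ln 10$ hours. `degradation_time_approx()`
implements this and errors out when $\beta R_0 / \alpha \le 1$, where the
assumption collapses.

### Finite-time blow-up for $n > 1$

For $n > 1$ the attached load $b$ reaches infinity in finite time (for
$n = 2$ the growth phase is a Riccati equation with a tangent-shaped
solution). Physically the resource is finite, so the package caps $b$ at
the $R_0$-equivalent load: integration stops at a terminal root $b = R_0$
and continues with the exact linear consumption $dR/dt = -\beta R_0$. This
avoids pushing a stiff solver through the blow-up while preserving the
half-life semantics; a unit test checks the $n = 2$ half-life against the
closed-form tangent/cap oracle.

### Choice of sweep window

`half_life_curve()` defaults to $a_0 = 0.01$, $\beta = 0.005$,
$R_0 = 10^6$. The log-linear law is a slow-attachment result, so the
package's standard sweep covers four decades of $[B]_0$ at
$\alpha/\beta R_0 \le 2\times10^{-3}$ (`b0 = 10^seq(-1, 3, 0.5)` with the
defaults), where the line has $R^2 > 0.9999$ and the recovered $\beta$ is
within a fraction of a percent. Outside that regime — large inocula where
attachment alone consumes a sizable share — the model itself predicts
curvature even at $n = 1$, which is worth remembering when interpreting
curvature as evidence of cooperativity: the cooperativity test below should
be applied to data from comparable inoculum regimes. A second printed
parameter set ($R_0 = 10^5$, $\beta = 0.005$) is in circulation for
cooperative sweeps; both are plain arguments, nothing is hard-wired.

## From images to half-lives

The measurement pipeline starts from tabulated cross-section areas of
single particles (segmentation itself is out of scope). Areas in pixel²
are converted at 0.4545 µm/pixel and mapped to volumes under a sphere
assumption, $V = \tfrac{4}{3}\pi (A/\pi)^{3/2}$ (`area_to_volume()`), then
normalized to the $t = 0$ volume so particles of different sizes are
comparable (`normalize_trajectory()`). Swelling above the initial volume —
a real feature of hydrogel particles just before collapse — is retained,
not clipped.

`fit_sigmoid()` estimates $(k, \tau_{1/2})$ by least squares of
$v(t) = 1/(1 + e^{k(t - \tau_{1/2})})$ with both parameters constrained
positive (Levenberg–Marquardt with box bounds, starting from $k = 0.5$ and
a data-driven $\tau$ start — the last time the trajectory is above 0.5 —
with five deterministic jittered restarts). Numerical choices worth
stating:

- **Censoring rule.** A trajectory that never drops below 0.5 within the
  observation window has no half-volume crossing, so no interior estimate
  exists: the fit is declared censored and the final observation time is a
  lower bound. The rule is deliberately the same event that defines
  $\tau_{1/2}$.
- **Upper asymptote fixed at 1.** Swelling contributes residuals rather
  than extra parameters; this matches the two-parameter form's robustness
  on 121-point trajectories.
- **Restarts are a fixed grid,** not random draws, so fits are exactly
  reproducible and never touch the global RNG.
- **Pooling.** `pooled_half_life()` averages non-censored replicates and
  reports the censored count separately; mixed censoring is surfaced with
  a warning, never imputed, and an all-censored condition is classified
  blocked. Both fitting orders (per particle, then average; or fit the
  mean curve) are available in `fit_halflife()`, with per-particle the
  default since it propagates replicate dispersion.

## Inference on dose series, cocultures and phase planes

`fit_inoculum_scaling()` fits $\tau_{1/2} = t_0 - (1/\beta)\ln[B_p]_0$ by
OLS (level means by default; pooled replicates optionally) and reports
$t_0$, the slope per ln-unit and per decade, $\hat\beta = -1/\text{slope}$
and $R^2$. Censored points are excluded rather than substituted at the
horizon — substitution would flatten the slope. Internal fits use natural
log; the per-decade slope is provided for reading against log10 axes.

`test_cooperativity()` compares linear vs quadratic polynomials in
$\ln[B_p]_0$ with an extra-sum-of-squares F-test (threshold 0.05). Exactly
collinear input is reported as p = 1 rather than a 0/0 F statistic. The
type-I rate at the nominal level is checked by simulation in the suite.

`coculture_effect()` compares replicate half-lives in monoculture vs
coculture by one-way ANOVA (two groups) with the three-tier edge
classification (complete inhibition when all coculture replicates are
censored, then p < 0.05, then p < 0.1). Degenerate zero-variance inputs
with equal means return p = 1. `parasitism_summary()` reduces CFU series
to consumer doublings ($\log_2$ final/initial), the degrader's
coculture/monoculture yield ratio, and a conservation flag (total
coculture yield at or below total monoculture yield).

On the phase plane, `classify_blocked()` calls a cell blocked only when
*every* replicate is censored; partial censoring is "delayed". The
critical consumer:degrader ratio $\gamma^\ast$ is bracketed by the largest
$\gamma$ with an unblocked cell and the smallest $\gamma$ at which all
cells are blocked, with the geometric midpoint as point estimate — the
natural choice on multiplicative inoculum grids, where thresholds are only
resolvable to a grid step. Cells are pooled across degrader rows by
default (the ratio hypothesis); `by_row = TRUE` estimates per row so the
hypothesis itself can be examined. All-blocked or none-blocked grids yield
one-sided bounds, not point estimates.

## What the synthetic generator emulates — and what it does not

`generator_config()` fixes the study conditions: imaging every 2 h for at
most 240 h, three replicate particles per condition, 5% multiplicative
Gaussian noise on normalized volume, optional pre-collapse swell bump
(Gaussian-shaped, off by default), collapse steepness $k = 0.5$ h⁻¹. The
generators emit:

- volume trajectories from the sigmoid observation model at a prescribed
  or model-derived half-life (`generate_volume_trajectory()`,
  `generate_mechanistic_trajectory()`);
- dose series in which each level's replicates run through the full
  trajectory-then-fit pipeline (`generate_dose_series()`);
- coculture grids with a hard ratio threshold $\gamma^\ast$ and a linear
  delay $\tau = \tau_{\text{mono}}(1 + c\gamma)$ below it
  (`generate_coculture_grid()`);
- CFU series with exact consumer doublings and yield conservation by
  construction (`generate_cfu_series()`).

Every generator records its ground truth (attributes and manifests) and
derives all randomness from the config seed, so identical seeds give
bit-identical output without touching the caller's RNG stream.

These are deliberately phenomenological observation models. Passing
recovery tests on them shows the estimators are consistent with the shapes
and noise the assay produces — plateau–collapse volume curves, censoring
at the horizon, ratio-threshold blocking — not that real particles obey a
two-parameter sigmoid, that measurement noise is exactly multiplicative
Gaussian, or that blocking is mechanistically a hard threshold in
$\gamma$. In particular the coculture delay model exists to validate the
phase-plane estimators, not to claim a mechanism for inhibition (surface
occlusion and gradient alteration both remain plausible). The problem
sizes used throughout the suite — 20-draw oracle comparisons, 100-replicate
estimator studies, 100 seeded 5×5 grids — were chosen as the smallest sets
that make the stochastic checks stable.

## Known limitations

- No carrying capacity on the particle surface: $b$ grows without bound
  for $n = 1$ and is only capped at $R_0$ for $n > 1$. A capacity term
  would alter late-time dynamics but not the attachment-dominated part of
  the degradation time.
- No spatial structure, monomer diffusion field, or explicit two-species
  coculture ODE: coculture handling is intentionally phenomenological
  (ratios, thresholds, ANOVA).
- $R_0$'s units are abstract; absolute half-lives are only meaningful once
  $\alpha$ and $\beta$ are calibrated for a strain.
- The horizon default is 240 h everywhere; analyses of assays stopped
  earlier should set `horizon_h` accordingly, since censoring and
  blocking classifications depend on it.

## A compact worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 1, noise_sd = 0.05)
dose <- generate_dose_series(10^seq(2, 4, 0.5), cfg,
                             a0 = 0.01, beta = 0.05, r0 = 1e6)
fit <- fit_inoculum_scaling(dose)
glance(fit)
autoplot(fit)

grid <- generate_coculture_grid(1.25e5 * 4^(0:4), 1.25e5 * 4^(0:4),
                                generator_config(seed = 1, gamma_star = 16,
                                                 effect_slope = 0.3),
                                tau_mono = 40)
estimate_critical_gamma(grid)
plot_phase_plane(grid)
```
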