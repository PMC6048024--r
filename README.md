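# chitindeg

Kinetics of chitin particle degradation by marine bacteria: a modelling
and analysis toolkit for particle-volume time-lapse assays.

## The problem

Biopolymer particles in the ocean are consumed by surface-attached
bacterial communities, and how fast a particle turns over depends on who
colonizes it. In the model system this package targets, ~50 µm chitin
hydrogel beads are incubated with defined strains — *primary degraders*
that secrete chitinases, and *secondary consumers* that cannot degrade
chitin but cross-feed on released byproducts — and imaged every 2 h for up
to 240 h. The observable is a plateau–collapse volume trajectory per
particle; the quantity of interest is the particle half-life τ½, the time
to half the initial volume. `chitindeg` is for researchers who run such
assays (or model them) and need the full chain from raw cross-section
areas to kinetic parameters, interaction classifications, and validated
estimators.

## The model and the estimators

Attachment–growth–degradation dynamics, in rescaled form:

$$\frac{db}{dt} = \alpha + \beta b^{\,n}, \qquad \frac{dR}{dt} = -\beta b,
\qquad b(0) = 0,\; R(0) = R_0,$$

where α = a₀[B]₀/r is the (inoculum-proportional) attachment rate,
β = r·p the combined degradation–growth rate, and n the cooperativity
exponent (n = 1: mass action). For n = 1 there is a closed form, and the
total degradation time obeys T ≈ (1/β)(ln R₀ + ln β − ln α) when
attachment is slow — so τ½ is linear in −ln [B]₀ and each tenfold dilution
of the inoculum costs (1/β)·ln 10 hours. The package provides:

- **model core** — closed-form and numerical trajectories, model
  half-lives, the analytic degradation-time approximation, inoculum sweeps
  (`closed_form_trajectory()`, `integrate_trajectory()`,
  `model_half_life()`, `degradation_time_approx()`, `half_life_curve()`);
- **half-life extraction** — area→volume conversion (sphere assumption,
  0.4545 µm/pixel), normalization, constrained sigmoid fits
  `1/(1 + e^{k(t − τ½)})` with censoring for never-collapsing particles
  (`area_to_volume()`, `normalize_trajectory()`, `fit_sigmoid()`,
  `fit_halflife()`, `pooled_half_life()`);
- **kinetics inference** — the scaling fit τ½ = t₀ − (1/β)ln[Bp]₀, a
  quadratic-term F-test for cooperativity, one-way-ANOVA coculture edge
  classification, and parasitism accounting from CFU series
  (`fit_inoculum_scaling()`, `test_cooperativity()`, `coculture_effect()`,
  `parasitism_summary()`);
- **phase planes** — blocked/delayed classification over degrader ×
  consumer inoculum grids and bracketing of the critical ratio
  γ\* = [Bs]₀/[Bp]₀ above which degradation is blocked
  (`classify_blocked()`, `estimate_critical_gamma()`,
  `export_heatmap_table()`, `plot_phase_plane()`);
- **synthetic data** — seeded generators for every input the pipeline
  consumes, with ground truth attached (`generator_config()`,
  `generate_volume_trajectory()`, `generate_dose_series()`,
  `generate_coculture_grid()`, `generate_cfu_series()`);
- **pipeline entry points** — `cli_simulate()`, `cli_synth()`, `cli_fit()`
  (file-based, manifest + checksums), plus a thin shell wrapper in
  `inst/scripts/chitindeg`.

Everything is data-frame-first: functions take tibbles and return tibbles,
fitted objects have `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(chitindeg)

# model half-life at a typical coastal inoculum
p <- degradation_params(a0 = 0.01, b0 = 5e5, p = 0.005, r0 = 1e6)
model_half_life(p)
#> # A tibble: 1 × 3
#>   tau_half censored horizon
#>      <dbl> <lgl>      <dbl>
#> 1     172. FALSE     100000

# synthetic dose series through the full trajectory-then-fit pipeline
cfg <- generator_config(seed = 1, noise_sd = 0.05)
dose <- generate_dose_series(10^seq(2, 4, by = 0.5), cfg,
                             a0 = 0.01, beta = 0.05, r0 = 1e6)
fit_inoculum_scaling(dose)
#> <scaling_fit>  tau_half ~ t0 - (1/beta) ln(b0)
#>   t0 = 293.8 h, slope = -19.85 h/ln-unit (-45.72 h/decade)
#>   beta_hat = 0.05037 1/h, R^2 = 0.999995, n = 5 (0 censored excluded)

# coculture phase plane with a known blocking threshold
grid <- generate_coculture_grid(1.25e5 * 4^(0:4), 1.25e5 * 4^(0:4),
                                generator_config(seed = 1, gamma_star = 16,
                                                 effect_slope = 0.3),
                                tau_mono = 40)
estimate_critical_gamma(grid)
#> # A tibble: 1 × 5
#>   gamma_star gamma_lower gamma_upper bound monotone_violations
#>        <dbl>       <dbl>       <dbl> <chr>               <int>
#> 1          8           4          16 point                   0
```

The model half-life of 172 h says a particle at this inoculum outlives a
week; the scaling fit recovers the generating β = 0.05 1/h to within 1%
with the expected ~46 h delay per tenfold dilution; and the γ\* bracket
(4, 16] contains the generator's true threshold of 16, to within the
resolution of a 4-fold grid.

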