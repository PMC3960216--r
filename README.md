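# pemrelease

Diffusion modelling of drug release from polyelectrolyte-multilayer
(PEM) coated particles.

Layer-by-layer (LbL) assembly wraps drug-loaded polymer particles (e.g.
PLGA nanoparticles carrying a model protein such as BSA) in alternating
polycation/polyanion layers. The film acts as an extra diffusion barrier,
retarding release — but how much, for which particle sizes, and how much
of an apparent retardation is really drug *lost* during the coating
steps? This package is for formulation scientists and modellers who want
those questions answered quantitatively, with every number reproducible
from code.

## What's inside

**The steady-state composite-sphere model.** For a core of radius
*r₂* (diffusivity *D₁*) under a shell of thickness *t* (outer radius
*r₃ = r₂ + t*, diffusivity *D₂*, partition coefficient *K*), the
mass-transfer rate from an interior radius *r₁* to the surface is
*M = (Cᵢ − C₀) / R_T* with series resistances

```
R_a = (r2 − r1) / (4π D1 r1 r2)      (core side)
R_b = t / (4π (K·D2) r2 r3)          (PEM shell)
R_T = R_a + R_b
```

and the coated/uncoated rate ratio (the **retardation ratio**, 1 = no
retardation) is `R_a / (R_a + R_b)`, exactly 1 at *t = 0* (no coating)
and at *D₁ = 0* (capsule limit), and rising monotonically to 1 as the
particle grows at fixed shell thickness.

**A conservative transient solver** (`solve_release()`): finite-volume
radial diffusion through core and shell with a partition jump at the
interface and a sink at the surface, mass-conservative to rounding
level, validated against the analytic homogeneous-sphere series.

**Assay bookkeeping** (`cumulative_mass_released()`, `drug_loading()`,
`encapsulation_efficiency()`, `loss_summary()`,
`loss_adjusted_release()`): aliquot-and-replenish cumulative release,
loading/efficiency percentages, and per-layer coating drug-loss
accounting, including the classic artifact where losing drug during
coating shrinks the percentage basis and masquerades as retardation.

**A seeded synthetic-data generator** (`synthetic_config()`,
`generate_release_curves()`, `generate_coating_run()`,
`generate_zeta_sequence()`) producing triplicate release curves with a
burst fraction, decaying per-layer loss sequences anchored to the
reported condition totals, and alternating-sign ζ-potential sequences.

**Parameter estimation** (`fit_release()`, `empirical_retardation()`):
bounded multi-start least squares of the solver-based forward model, and
direct retardation measurement from coated/uncoated curve pairs with
replicate-bootstrap intervals.

## Worked example

A 330 nm (diameter) nanoparticle with a 20 nm PEM shell whose
permeability is dominated by partitioning (*K* = 0.02):

```r
library(pemrelease)

sp <- composite_sphere(r2 = 0.165, t = 0.02,      # um
                       D1 = 2e-4, D2 = 2e-4,      # um^2/h
                       K = 0.02)
total_resistance(sp)
#> Series resistances: R_a = 2411.44, R_b = 13034.8, R_T = 15446.2
retardation_ratio(sp)
#> [1] 0.1561181
```

The shell carries ~84% of the total resistance, so the coated particle
releases at ~16% of the bare particle's early rate. The same shell on
bigger particles:

```r
size_sweep(sp, r2_values = c(0.33, 2, 60, 160))
#>       r2     ratio
#> 1   0.33 0.2592593
#> 2   2.00 0.6688742
#> 3  60.00 0.9836119
#> 4 160.00 0.9937896
```

At 60–160 µm the ratio is ≥ 0.98 — the coating no longer matters, which
is why retardation is only observed on small particles. Synthetic
triplicates and an empirical retardation estimate:

```r
cfg <- synthetic_config(seed = 1)    # 40% burst, 3% noise, triplicates
uncoated <- generate_release_curves(cfg, coated = FALSE)
coated   <- generate_release_curves(cfg, coated = TRUE)
empirical_retardation(coated, uncoated)[c("ratio", "interval")]
#> $ratio
#> [1] 0.5875987
#> $interval
#> [1] 0.5782818 0.5957961
```

(The fraction-mode ratio over the whole sampling window sits above the
early-rate ratio of 0.156 because both curves share the 40% burst.) And
the loss-accounting artifact: release 5 µg from a batch that contained
100 µg but lost 15% during coating, and the books say

```r
render_percent(loss_adjusted_release(percent_release(5, 100), 15))
#> [1] 5.9
```

— 5.9% "release", down from the 20% the uncoated batch showed, even
though the barrier did only part of the work. The six condition totals
in `bsa_loss_totals()` average to `5.4`%.

## Documentation

The methods vignette (`vignettes/pem-release-model.Rmd`) documents the
model assumptions, the solver design, the window choice for dynamic
ratio estimates, what the synthetic generator does and does not emulate,
and known limitations.
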