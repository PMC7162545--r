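# dlrobust

Tools for analysing how the **Dorsal (Dl) morphogen gradient** of the early
*Drosophila* embryo keeps its target-gene expression boundaries in place when
the maternal *dl* gene dosage is halved (1x), wildtype (2x), or doubled (4x).

Dl, the fly NF-κB homolog, forms a ventral-to-dorsal nuclear concentration
gradient that switches on *snail* (*sna*) at high levels and *short
gastrulation* (*sog*) at intermediate levels. Gene-expression borders are
concentration thresholds on this gradient, so the naive expectation is that
changing the morphogen dose shifts every border drastically. Measured borders
barely move. This package implements, end to end, the analysis chain used to
dissect that robustness:

* **Empirical dosage-scaling model.** The nuclear gradient is described as

  `c(x) = α [ exp(−x² / 2σ²) + m·|x| + b ]`

  with dosage-proportional amplitude `α`, width `σ`, tail slope `m` and basal
  level `b` (x is the ventral-to-dorsal coordinate on [0, 1]). Borders are
  threshold crossings `c(x_g) = θ`, and their dosage sensitivity is the
  analytic coefficient `φ = (∂ ln x_g / ∂ ln α)_θ = −c(x_g)/(x_g c′(x_g))`.

* **Mechanistic compartment model.** 51 nuclei/cytoplasm compartments across
  the DV half-circumference with free Dl (`u`) and Dl/Cact complex (`w`):

  `du_h/dT = a₁λ_d Δu_h + a₂ β(x_h) w_h/(κ + w_h) − a₃ γ u_h`
  `dw_h/dT = a₄λ_dc Δw_h − a₅ β(x_h) w_h/(κ + w_h) + a₆ γ u_h`

  where `β(x) = β₀ exp(−(x/φ_T)²)` is the ventrally restricted Toll-mediated
  dissociation rate (Michaelis–Menten constant `κ`) and `γ` re-associates Dl
  with Cactus. The model is integrated over the ~60 minutes of nuclear cycle
  14 from all-Dl-in-complex initial conditions, with dosage entering as the
  initial complex concentration.

* **Robustness screen.** The five free rates (λ_d, λ_dc, β₀, γ, κ) are drawn
  log-uniformly over \[1e−3, 1e3\]; each draw is simulated at dosages
  0.5/1/2, gene borders are fitted as free-Dl thresholds minimizing the
  least-squares error against the measured 1x/2x/4x border positions, and
  sets with every border error below 1.5 are classified robust. Ensemble
  analytics report the shuttling enrichment (length-scale ratio ρ > 1), the
  Toll-saturation bound on κ, and amplitude-ratio distributions.

* **Quantification and statistics.** Gaussian-with-tail fits of per-embryo
  intensity profiles, normalization `X = (I − B − 0.7M)/A`, 301-point grid
  averaging, canonical-template gene-border extraction with goodness-of-fit
  filtering, log-log dosage-sensitivity slopes, weighted qPCR ΔCT summaries,
  canonical nc14 amplitude curves, bootstrap amplitude ratios, and the
  (α_1x, α_4x) amplitude-pair optimization.

* **Synthetic data.** Every input the real study measured (nuclear-intensity
  profiles, gene-expression profiles, amplitude time courses, qPCR tables)
  is emulated with known ground truth, so the whole pipeline is testable
  without imaging data.

## Worked example

```r
library(dlrobust)

wt  <- empirical_params(b = 0.4)    # raw fluorescence basal level
dec <- empirical_params(b = 0.11)   # deconvolved free-Dl gradient

predict_domains(wt, c(sna = 0.20))
#>   border alpha     theta       x_g expressed saturated
#> 1    sna   0.5 0.7911123        NA     FALSE     FALSE
#> 2    sna   1.0 0.7911123 0.2000000      TRUE     FALSE
#> 3    sna   2.0 0.7911123 0.3892663      TRUE     FALSE
```

With the raw basal level, halving the dose (`alpha = 0.5`) loses *sna*
expression outright, and doubling it pushes the border from 20% to 39% of
the axis — a lethal rearrangement. Deconvolving the Dl/Cact contribution
(`b = 0.11`) softens but does not rescue the prediction: the 1x *sna* domain
collapses to under 7% of the axis,

```r
predict_domains(dec, c(sna = 0.20))
#>   border alpha     theta        x_g expressed saturated
#> 1    sna   0.5 0.5011123 0.06916774      TRUE     FALSE
#> 2    sna   1.0 0.5011123 0.20000000      TRUE     FALSE
#> 3    sna   2.0 0.5011123 0.28292046      TRUE     FALSE

min_sensitivity(dec)
#>         x_g      phi
#> 1 0.3397226 0.356873
```

and even the best-placed border keeps a sensitivity coefficient of ~0.36,
above the ~0.3 engineering rule of thumb. Dosage scaling alone cannot
explain the observed robustness, which motivates the mechanistic screen:

```r
cfg <- screen_config(n_sets = 2000, seed = 42)
records <- run_screen(cfg)
summarize_ensemble(records)
#> Screen summary: 4/2000 robust (0.20%)
#>   fraction rho > 1 among robust: 0.250
#>   robust kappa in [0.00217, 0.194]
#>   amplitude ratios: 1x/2x in [0.85, 0.998], 4x/2x in [1, 1.09]
```

Robust parameter sets are rare (a fraction of a percent), all have small
Toll saturation constants κ, and their 4x:2x amplitude ratios stay well
below the factor-of-two dosage change — Toll saturation decouples nuclear
Dl levels from dose. See the methods vignette
(`vignettes/dlrobust-methods.Rmd`) for the model assumptions, parameter
defaults, and the composition of the robust ensemble.

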