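# layerlight

Dual-slope frequency-domain near-infrared spectroscopy (DS FD-NIRS) in
layered head models.

fNIRS signals collected on the scalp mix cerebral hemodynamics with
contamination from the scalp, skull and CSF the light crosses on the way.
`layerlight` implements the computational chain used to quantify that
mixing and to undo it: a **white Monte Carlo** transport kernel that records
per-layer photon path lengths `l_jk` so the complex reflectance

```
R = 1/(N A) Σ_k exp(−Σ_j μa_j l_jk) · exp(i ω Σ_j l_jk n_j / c)
```

can be assembled for *any* absorption set by exact re-weighting; the
semi-infinite homogeneous diffusion model with extrapolated boundary
conditions; the six DS FD-NIRS data types (SDI₂₅, SDI₃₇, SDφ₂₅, SDφ₃₇,
DSI, DSφ) with the **self-calibrated dual-slope fit** of effective
homogeneous (μa, μs′); retrieval of effective absorption changes
Δμa,M = ΔM / J_M and hemoglobin changes via Beer's law; the **three-layer
sensitivity-matrix inversion** that separates superficial from cerebral
absorption changes by Moore–Penrose least squares on

```
S_M,i = (∂M/∂μa,i) / Σ_j ∂M/∂μa,j      Δμa_M = S · (Δμa_superficial, Δμa_deep)
```

and a block-protocol **functional pipeline** (folding average over 45 s
stimulus–rest cycles, 3 s moving average, 3σ peak detection) together with
a seeded synthetic run generator to test it against planted truth.

It is written for researchers in diffuse optics / fNIRS methods who want a
desk-scale, fully scripted replica of this analysis chain: tibbles in and
out, `tidy()`/`glance()` on fitted objects, `autoplot()` on results.

## Worked example

Fit the effective homogeneous properties of a three-layer head model
(scalp+skull 10 mm, 2 mm CSF, brain), then separate a planted deep
absorption change from the superficial layer:

```r
library(layerlight)

medium <- make_three_layer(L1 = 10, mua1 = 0.017, mua3 = 0.021,
                           musp1 = 0.75, musp3 = 1.1)
ledger <- run_white_mc(medium, make_ds_array(), n_photons = 1e7, seed = 1)

fit <- fit_absolute_properties(compute_datatypes(
  assemble_reflectance(ledger, medium$layers$mua)))
tidy(fit)
#> # A tibble: 2 × 3
#>   term  estimate unit
#>   <chr>    <dbl> <chr>
#> 1 mua     0.0139 mm^-1
#> 2 musp    0.457  mm^-1

S <- build_sensitivity_matrix(layer_derivatives(ledger, medium$layers$mua))
pr <- perturbed_reflectance(ledger, medium$layers$mua, c(0, 0, 0.001))
dM <- unlist(compute_datatypes(pr$perturbed)[1, DATA_TYPES]) -
      unlist(compute_datatypes(pr$base)[1, DATA_TYPES])
sol <- solve_layers(retrieve_dmua(dM, S$J_sum), S)
tidy(sol)
#> # A tibble: 2 × 3
#>   layer             dmua   sem
#>   <chr>            <dbl> <dbl>
#> 1 superficial 0.00000256    NA
#> 2 deep        0.000963      NA
```

The fitted (0.0139, 0.46) mm⁻¹ are *effective* homogeneous properties —
note μs′ far below either layer's true scattering, the signature of the
low-scattering CSF gap. The inversion attributes essentially all of the
planted 1e-3 mm⁻¹ deep perturbation to the deep layer and ~0 to the
superficial layer.

A synthetic functional run through the same machinery:

```r
fw <- forward_model(ledger = ledger)
ts <- generate_functional_run(fw, ds_protocol(), deep_peak_dmua = 1e-3,
                              noise_sd = 1e-4, seed = 7)
functional_pipeline(ts)    # folded, smoothed, 3-sigma peak per data type
```

## Package layout

| area | functions |
|---|---|
| media & optodes | `make_two_layer()`, `make_three_layer()`, `make_ds_array()`, `media_to_yaml()` |
| Monte Carlo | `run_white_mc()`, `fresnel_reflectance()` |
| forward models | `assemble_reflectance()`, `perturbed_reflectance()`, `layer_derivatives()`, `diffusion_reflectance()`, `homogeneous_jacobian()` |
| dual-slope engine | `compute_datatypes()`, `fit_absolute_properties()`, `retrieve_dmua()`, `beer_lambert()` |
| layer inversion | `build_sensitivity_matrix()`, `solve_layers()`, `propagate_sem()` |
| functional | `ds_protocol()`, `hemodynamic_kernel()`, `generate_functional_run()`, `folding_average()`, `moving_average()`, `detect_peak()`, `summarize_module()`, `functional_pipeline()` |
| campaigns | `sweep_spec()`, `run_campaign()`, `export_results()` |

See `vignettes/layered-models.Rmd` for the model assumptions, parameter
defaults, numerical choices and known limitations, and
`inst/scripts/layerlight.R` for a thin command-line wrapper.
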