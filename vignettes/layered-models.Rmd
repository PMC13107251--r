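---
title: "Dual-slope FD-NIRS in layered head models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-slope FD-NIRS in layered head models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Functional near-infrared spectroscopy measures cerebral hemodynamics through
the scalp, skull and cerebrospinal fluid (CSF), so every photon that carries
information about the brain also carries contamination from the superficial
layers it crossed twice. Dual-slope (DS) frequency-domain (FD) measurements —
two sources and two detectors arranged so that each source sees one short
(25 mm) and one long (37 mm) distance — suppress both optode coupling factors
and superficial sensitivity by averaging the two single-distance (SD) slopes
of `ln(rho^2 I)` and of the phase `phi` versus distance. `layerlight`
implements the full computational chain needed to study how layered head
anatomy shapes what each of the six DS FD-NIRS data types
(SDI25, SDI37, SDphi25, SDphi37, DSI, DSphi) actually measures:

1. a white Monte Carlo transport kernel for layered slabs,
2. assembly of complex reflectance and its per-layer absorption derivatives,
3. the analytic homogeneous diffusion model and the self-calibrated fit of
   effective optical properties from dual slopes,
4. retrieval of effective absorption changes per data type,
5. a three-layer sensitivity-matrix inversion separating superficial from
   cerebral absorption changes,
6. a block-protocol functional pipeline with a synthetic run generator.

## White Monte Carlo with a path ledger

The kernel (`run_white_mc()`) tracks photons through a stack of layers inside
a 200 x 100 x 100 mm box, with a pencil-beam source normal to the surface,
Fresnel reflection at the refractive-index step to the outside (n = 1.4 to
1.0; effective reflection coefficient 0.493), absorbing lateral and bottom
faces, and isotropic scattering (g = 0; Henyey–Greenstein available when
g != 0, with `mus = musp / (1 - g)`). Free paths are sampled in optical-depth
units and converted with the local scattering coefficient, so the leftover
depth is carried correctly across interfaces between layers of different
`musp` — this matters for the CSF layer, whose `musp = 0.01 mm^-1` gives a
100 mm mean free path.

Crucially, no absorption is applied during transport. For every detected
photon the kernel records the path length traveled in each layer
(`l_jk`), and the reflectance for any absorption set is assembled afterwards
as

    R = 1/(N A) * sum_k exp(-sum_j mua_j l_jk) * exp(i omega sum_j l_jk n_j / c)

(`assemble_reflectance()`). The re-weighting is exact, so one simulation
serves an entire absorption sweep, baseline and perturbed states share the
same photons (which makes small differences nearly noise-free), and the
per-layer derivatives `dR/dmua_j = -<l_jk-weighted sum>` are analytic
(`layer_derivatives()`, verified against central finite differences to
1e-6 relative).

Two tally modes exist. A disc mode scores photons on the physical 1 mm detectors,
which needs ~1e9+ photons for usable statistics. The default annular mode
exploits the lateral homogeneity of the medium and scores on 2 mm wide rings
centered on each source at the nominal 25 and 37 mm distances; it reaches
~1-3% slope precision at 1e7 photons (about a minute of CPU). Distances
are labeled by their nominal ring centers. Photons are terminated at a total
path of 2000 mm (configurable); for `mua >= 0.002 mm^-1` the discarded
weight is below `e^-4` of the detected signal, and for the head-like media
here (`mua ~ 0.014-0.021`) it is entirely negligible.

Each source gets an independent, seed-derived random stream, so runs are
bit-reproducible and the two mirror sources are statistically independent.

## The analytic model and the self-calibrated fit

`diffusion_reflectance()` evaluates the semi-infinite homogeneous diffusion
model with extrapolated boundary conditions via the two-source image
construction: isotropic source at `z0 = 1/musp`, image at `-(z0 + 2 zb)`,
`zb = 2 D (1 + Reff)/(1 - Reff)`, `D = 1/(3 musp)` (the absorption-free
convention; `1/(3(mua+musp))` is available by flag), and complex attenuation
`k = sqrt((mua - i omega n/c)/D)` taken with positive real part, so the
phase grows with distance. The observable is the fluence at the boundary:
the DS slopes cancel any multiplicative factor, so the fluence form is
sufficient and keeps the Jacobians consistent with the fit.

`fit_absolute_properties()` inverts measured dual slopes into effective
homogeneous `(mua, musp)`. The initial guess uses the infinite-medium
closed forms on the slope pair (`kr^2 - ki^2 = 3 mua musp`,
`2 kr ki = 3 musp omega n/c`); a damped Newton iteration then matches the
semi-infinite model's dual slopes to the measured ones, to a residual below
1e-9 mm^-1 (typically 4 iterations). The binding correctness contract is
the round trip: analytic slopes generated anywhere in
`mua in [0.005, 0.025], musp in [0.4, 1.8]` are recovered to much better
than 0.1%. Non-convergence is flagged on the returned object, never silent.

Jacobians of the six data types with respect to homogeneous `mua`
(`homogeneous_jacobian()`) are central finite differences with step
1e-5 mm^-1, verified by step-halving; analytic exactness is unnecessary
since the retrieval `dmua_M = dM / J_M` is itself first order.

## What the effective properties and changes mean

Fitting a homogeneous model to data from a layered medium produces
*effective* properties that can sit outside the range spanned by the layers
(a 0.4/1.1 scattering sandwich fits to `musp ~ 0.37`), and effective
absorption changes `dmua_M` that understate a deep perturbation to a degree
that depends on the data type. Reproducing that hierarchy — phase deeper
than intensity, DS deeper than SD, `dmua_SD25 < dmua_SD37 < dmua_DS` within
each family — is the package's central validated behavior.

Two numerical caveats are quantified by the test suite:

- Linearization: retrieving a homogeneous change of 1e-3 mm^-1 through
  baseline Jacobians carries ~1% curvature error on intensity types and
  ~4% on phase types (at 1e-4 all six are within 1%).
- Diffusion-approximation bias: analyzing *transport* (MC) data with
  *diffusion* phase Jacobians leaves a systematic ~10% deficit on DSphi
  even in the homogeneous limit and at 1e7 photons. This is a property of
  the method, shared by any pipeline of this structure; slope-level
  baseline fits are much less affected (a few percent on `mua, musp`).
- A corner of the ordering property: the within-family hierarchy
  `dmua_SD25 < dmua_SD37 < dmua_DS` holds across all caption-constant
  configurations we test, but in the three-layer geometry with a
  high-scattering top (`musp1 = 1.45` over the CSF layer) the retrieved
  *phase* hierarchy compresses as the superficial absorption drops and
  inverts systematically below `mua1 ~ 0.010 mm^-1` (reproduced across
  independent seeds at 1e7 photons). Effective superficial absorption that
  low is at the edge of the physiological range; treat phase-family
  comparisons there with caution.

## Layer separation

For a three-layer medium, `build_sensitivity_matrix()` converts the
per-layer reflectance derivatives into derivatives of each data type by the
chain rule (intensity through `ln|.|`, phase through `arg(.)`, slopes
through the two-point difference), normalizes each row by the sum over all
three layers — the CSF layer stays in the denominator even though it is not
solved for — and keeps the superficial and deep columns. `solve_layers()`
then solves the 6-equation, 2-unknown system with the Moore–Penrose
pseudoinverse and propagates measurement SEMs element-wise through the
pseudoinverse rows under an uncorrelated-noise assumption (the six data
types share photons, so this is an approximation; it is the standard one).
The measurement vector for this step divides data-type changes by the
summed-layer Jacobian (the row sums of the unnormalized derivative matrix);
`retrieve_dmua()` accepts either that or the homogeneous Jacobian, and both
routes are exercised in tests since the intermediate convention is a
genuine ambiguity.

## The synthetic functional generator

`generate_functional_run()` emulates the in vivo block protocol: 60 s
baseline, seven cycles of 15 s stimulus + 30 s rest, 60 s final baseline,
sampled at 10 Hz (a typical FD-NIRS acquisition rate; the default is a
declared synthetic choice, not an inferred one). A difference-of-gammas
response kernel (onset 2 s, rise tau 4 s, fall tau 6 s, small undershoot),
normalized so its maximum equals the planted peak, is tiled over the
cycles in the deepest layer (and optionally the top layer). Data-type
changes come either from first-order layered derivatives (default; valid
at the 1e-3 mm^-1 scale, and compared against the exact path in tests) or
by re-exponentiating the ledger per sample. White Gaussian noise is added
per data type in its own units, and optional sinusoidal cardiac (~1 Hz)
and vasomotion (~0.1 Hz) components enter as global absorption
oscillations. Everything is seeded and bit-reproducible.

What the generator does *not* emulate: motion artifacts, drifts by
default, 1/f physiological noise, subject anatomy, or lateral
inhomogeneity of the response. Passing pipeline tests therefore
demonstrate correctness of the analysis chain under known truth, not
robustness to every feature of real data.

## The functional pipeline

`functional_pipeline()` runs the fixed order fold → smooth → noise
estimate → threshold → window-average:

- `folding_average()` averages the complete 45 s cycles aligned to
  stimulus onset, excluding both baselines.
- `moving_average()` smooths with a centered 3 s window; edge windows
  shrink symmetrically rather than padding.
- `detect_peak()` estimates sigma as the SD of the *unsmoothed* folded
  trace over a 2 s segment placed at 20-22 s into the cycle (early rest;
  the location is configurable). The 3-sigma threshold is applied to the
  smoothed maximum (earliest sample on ties) and the reported value is the
  mean over a +/-1 s window, truncated and flagged at cycle edges. Sigma
  must be estimated before smoothing: a 3 s moving average leaves the
  trace nearly constant across any 2 s segment, so the smoothed-segment SD
  underestimates the noise so badly that the threshold fires on pure noise
  ~90% of the time, defeating the detector's purpose. With the
  pre-smoothing estimate the false-positive rate on white noise is below
  5% (verified over 100 seeded replicates), and the +/-1 s window biases
  the default kernel's peak by well under 5%.
- `summarize_module()` averages peaks across a module's DS sets
  (conventionally four) and reports the SEM, flagged as undefined for a
  single set.

## Problem sizes and reproducibility

The package's own validation runs at desk scale by design: 1e7 photons with
annular tallies for effective-property comparisons (the published
simulations used 9e9 photons with disc detectors — the annular mode exists
precisely to make the physics reachable on one CPU), 2e5-2e6 photons for
unit-level property checks, 100 seeded replicates for false-positive rates,
and 200 for inversion unbiasedness. At 1e7 photons the fitted effective
properties carry ~1-3% Monte Carlo scatter, which is the tolerance used
when comparing against the published values. All randomness — photon
transport, synthetic noise, replicate loops — is controlled by explicit
integer seeds.

## Worked example

```{r example}
library(layerlight)

medium <- make_three_layer(L1 = 10, mua1 = 0.017, mua3 = 0.021,
                           musp1 = 0.75, musp3 = 1.1)
ledger <- run_white_mc(medium, make_ds_array(), n_photons = 1e7, seed = 1)

baseline <- assemble_reflectance(ledger, medium$layers$mua)
fit <- fit_absolute_properties(compute_datatypes(baseline))
tidy(fit)

S <- build_sensitivity_matrix(layer_derivatives(ledger, medium$layers$mua))
pr <- perturbed_reflectance(ledger, medium$layers$mua, c(0, 0, 0.001))
dM <- unlist(compute_datatypes(pr$perturbed)[1, DATA_TYPES]) -
      unlist(compute_datatypes(pr$base)[1, DATA_TYPES])
sol <- solve_layers(retrieve_dmua(dM, S$J_sum), S)
tidy(sol)
```

## Known limitations

- Layered slabs only: no curved geometry, voxelized anatomy, or lateral
  absorption inhomogeneity.
- The homogeneous analysis model is the diffusion approximation; its phase
  Jacobians differ from transport by ~10% (quantified above).
- Noise across the six data types is treated as uncorrelated in the SEM
  propagation although they share photons.
- Only absorption changes are modeled functionally; scattering is held
  fixed over time.
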