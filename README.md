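# coce — quantitative compression OCE with a crack-closure stress–strain law

Quasistatic **compression optical coherence elastography (C-OCE)**
images a tissue while compressing it through a pre-calibrated,
elastically linear reference silicone. Interframe phase differences of
the complex OCT scans give axial displacement and strain; the silicone
acts as an optical stress sensor (its cumulative strain × its known
modulus = applied stress), so each region of the scan yields a
*quantitative* stress–strain curve. Soft tissues are strongly
nonlinear in this regime: their tangent modulus can grow several-fold
within a few percent of compressive strain.

`coce` is an R package for scientists analysing (or simulating) such
experiments. Its core is a three-parameter constitutive law in which
tissue nonlinearity arises from progressive closure of compliant
crack-like interstitial pores:

```
s(σ)     = σ/Em + υt · [1 − exp(−σ/B)]
Eeff(σ)  = Em / [1 + (υt·Em/B) · exp(−σ/B)]
β(σ)     = dEeff/dσ,  peaking at Em/(4B) when υt·Em/B > 1
```

* `Em` (kPa) — Young's modulus of the host matrix, reached once all
  pores are closed;
* `B` (kPa) — characteristic closing stress, the mode of the
  bell-shaped pore density `υ(σ) = (υt/B²)·σ·exp(−σ/B)`;
* `υt` — total volumetric content of compliant pores (also the strain
  excess contributed by their closure).

The package covers the whole chain:

| stage | functions |
|---|---|
| constitutive math | `strain_from_stress`, `tangent_modulus`, `nonlinearity_beta`, `bell_distribution`, `effective_modulus_from_distribution`, `reconstruct_distribution`, `closing_stress`, `average_compliance` |
| phase-resolved strain | `phase_difference`, `displacement_from_phase`, `strain_leastsquares`, `strain_vector`, `accumulate_strain` |
| curves and fitting | `silicone_calibration`, `build_curve`, `fit_constitutive`, `derived_curves`, `standardized_modulus_map`, `gate_classify` |
| synthetic phantoms | `phantom_spec`, `make_frames`, `make_crack_phantom`, `make_curve_samples` |
| IO / pipeline | `run_config`, `run_pipeline`, `write_curve_csv`, `write_fit_json`, `write_map_tiff`, … |

A thin command-line front end ships in `inst/cli/oce.R`
(`Rscript oce.R simulate|run|fit|curve|map|classify …`).

## Worked example

Fit the law to a noisy synthesized curve (the cornea-like triple
`Em = 736, B = 4.1, υt = 0.026` with 1% multiplicative strain noise):

```r
library(coce)

p <- constitutive_params(Em = 736, B = 4.1, vt = 0.026)
curve <- make_curve_samples(p, sigma_max = 25, n_points = 200,
                            noise_sd = 0.01, seed = 1)
fit <- fit_constitutive(curve)
print(fit)
#> Crack-closure constitutive fit
#>   Em = 735 kPa (se 6.8), B = 4.07 kPa (se 0.064), vt = 0.02594 (se 0.00026)
#>   residual RMS = 0.000396 strain, converged: TRUE

tangent_modulus(fit$params, c(1, 5, 10))
#> [1] 157.5811 309.9337 524.4295
```

The recovered triple matches the generating one to well under 1%
despite the noise. The tangent moduli show the hallmark of
crack-closure nonlinearity: the tissue stiffens from ~158 kPa at 1 kPa
of compression to ~524 kPa at 10 kPa, heading toward the 736 kPa
matrix modulus; the nonlinearity parameter `β` peaks at
`Em/(4B) ≈ 45` near `σ = B·ln(υt·Em/B) ≈ 6.3 kPa`.

The same works end-to-end from raw speckle: simulate a two-layer
phantom (silicone over crack-closure tissue) and run the full pipeline:

```r
res <- run_pipeline(run_config(list(
  simulate  = list(n_steps = 20, total_stress_kpa = 20,
                   snr_db = 30, n_x = 32, seed = 7),
  output_dir = "run1", seed = 7)), quiet = TRUE)
res$fit$params
#> Em ≈ 296 kPa, B ≈ 3.9 kPa, vt ≈ 0.049   (generated with 300 / 4 / 0.05)
```

which writes the curve (CSV), fit (JSON), derived curves, frames and a
reproducibility manifest under `run1/`.

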