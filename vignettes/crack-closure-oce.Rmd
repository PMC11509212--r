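---
title: "Methods: a crack-closure stress-strain law for compression OCE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a crack-closure stress-strain law for compression OCE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coce)
```

## The problem

Quasistatic compression optical coherence elastography (C-OCE) presses a
sample through a pre-calibrated, elastically linear silicone layer while
acquiring complex-valued OCT B-scans. Interframe phase differences give
axial displacement, their depth gradient gives incremental strain, and
summation over the compression series gives cumulative strain. Because
the silicone is linear, its cumulative strain times its known Young's
modulus is the applied stress, so plotting silicone-derived stress
against tissue cumulative strain yields a *quantitative* stress-strain
curve for every region of the scan — without a force sensor.

Soft tissues probed this way are strongly nonlinear even at strains of
a few percent: their tangent modulus can grow several-fold between 0
and 10-20 kPa of compression. This package implements a constitutive
law that explains that behaviour mechanistically, the full processing
chain from complex frames to fitted parameters and parameter maps, and
a speckle-level synthetic data generator so that every stage can be
validated offline against exact ground truth.

## The constitutive model

The model attributes tissue nonlinearity to compliant crack-like
interstitial gaps/pores, by analogy with the behaviour of cracked rock.
A thin crack of diameter $D$ and opening $h$ has aspect ratio
$\alpha = h/D \ll 1$. Although its own volume is only $\sim D^2 h$, it
relaxes elastic energy in a volume $\sim D^3$, so even a small total
pore content markedly softens the material. Under uniaxial compression
such a pore closes completely at

$$\sigma_\mathrm{clos} = \alpha E_m, \qquad s_\mathrm{clos} = \alpha,$$

where $E_m$ is the Young's modulus of the host matrix. (Geometric
prefactors of order unity are fixed to exactly 1 throughout the
package; the `prefactor` argument of `closing_stress()` exists only for
sensitivity studies.) Narrower pores close first, so as stress rises
the population of open pores shrinks and the tangent modulus climbs
toward $E_m$.

For a population of pores described by a density $\upsilon(\sigma)$
over closing stress (normalized to total content $\upsilon_t$), the
effective-medium relation is

$$\frac{E_m}{E_\mathrm{eff}(\sigma)} = 1 + E_m
  \int_\sigma^\infty \frac{\upsilon(\sigma')}{\sigma'}\, d\sigma' .$$

Assuming the bell-shaped density
$\upsilon(\sigma) = (\upsilon_t/B^2)\,\sigma\, e^{-\sigma/B}$ — zero at
zero stress, peaked at the characteristic closing stress $B$ — the
integral closes, and integrating the tangent modulus gives the
three-parameter stress-strain law at the heart of the package:

$$s(\sigma) = \frac{\sigma}{E_m}
  + \upsilon_t \left[ 1 - e^{-\sigma/B} \right],$$

$$E_\mathrm{eff}(\sigma) = \frac{E_m}{1 + (\upsilon_t E_m/B)\,
  e^{-\sigma/B}}, \qquad
\beta(\sigma) = \frac{dE_\mathrm{eff}}{d\sigma} .$$

Every parameter is physical: $E_m$ (kPa) is the matrix modulus reached
once the pores are closed, $B$ (kPa) is the mode of the pore
closing-stress distribution, and $\upsilon_t$ (dimensionless) is the
total volumetric pore content — also the strain excess accumulated by
pore closure at large stress. The dimensionless nonlinearity parameter
$\beta$ peaks at $E_m/(4B)$, at $\sigma = B\ln(\upsilon_t E_m/B)$,
precisely when $\upsilon_t E_m/B > 1$, i.e. when pores more than halve
the zero-stress modulus (`has_beta_peak()`).

The model targets the compressive regime of tissues with compliant
pores. It does not describe tensile fiber-unbending nonlinearity,
orientation-dependent crack compliance tensors, or poroviscoelastic
dynamics; those are out of scope.

## Conventions and units

* Stress and moduli in kPa, strain dimensionless; no unit inference.
* Compressive stress and compressive strain are both **positive**.
* The interframe phase is $\Phi = \arg(a_2\,\bar a_1)$, which grows
  when optical path grows. Under contact compression scatterers move
  toward the probe, so the strain estimators negate the phase slope:
  $s = -\frac{\lambda_0}{4\pi n}\,\frac{\partial \Phi}{\partial z}$.
  This keeps all three conventions (phase definition, displacement
  relation, compression-positive strain) mutually consistent.
* Cumulative strain follows the summation convention
  $S = \sum_i s_i$. Summing fixed-pixel (Eulerian) strain increments
  accumulates the *logarithmic* strain, so the phantom realizes a
  stated cumulative strain $S$ as a thickness scale factor $e^{-S}$;
  with that choice the pipeline's summed estimates converge exactly to
  the stated $S$. At the strains relevant here ($S \lesssim 0.2$) the
  distinction from engineering strain reaches only a few percent, but
  ignoring it would bias the stress axis by exactly that much.

## Strain estimation

Two estimators are provided.

`strain_leastsquares()` unwraps the interframe phase along each A-scan
(cumulative $2\pi$ correction), then fits the local phase slope by
least squares over a running window (default $8 \times 8$ pixels;
masked pixels are excluded and windows with fewer than 3 valid pixels,
or mostly masked, return masked estimates). It is exact on noiseless
phase ramps and preferable when phases are clean.

`strain_vector()` never unwraps. It averages the interframe complex
product $b = a_2 \bar a_1$ laterally (independent speckles), forms the
axial lag-1 product $g(z) = B(z{+}1)\bar B(z)$ whose argument is the
interpixel phase increment, *normalizes $g$ to unit magnitude*, and
averages the resulting phasors over the window before taking the
argument. The normalization matters: neighbouring pixels share
envelope-correlated speckle, and an amplitude-weighted mean
systematically underestimates the phase gradient (by almost a factor
of two at the default envelope/pitch ratio); the unweighted phasor
mean is unbiased to below 1% at 1% interframe strain. Total phase
wrapping is irrelevant because only local increments enter, which is
the estimator's advantage on strongly compressed frames. A coherence
mask (mean resultant length of the phasors, default threshold 0.1)
flags decorrelated estimates.

Interframe strains above ~2% decorrelate pixel-to-pixel comparisons;
estimates beyond a validity cap (default 0.02) trigger a warning
rather than an error. Suprapixel displacement tracking for large
cumulative motion is deliberately not implemented; instead the
compression protocol should keep per-step strains at the percent
level, as in practice.

## From strain to parameters

`build_curve()` averages cumulative strains over rectangular ROIs
(~80-100 µm is typical; `roi_pixels(90, pitch)` converts), converts
the silicone ROI mean to stress, sorts by stress, merges near-ties
(non-monotonicities under 2% of the stress range; larger ones are an
error), and prepends the (0, 0) origin.

`fit_constitutive()` fits $s(\sigma)$ — the law is explicit in that
direction, so no per-iteration root finding — by bounded
Levenberg-Marquardt ($E_m > 0$, $B > 0$, $0 \le \upsilon_t < 1$).
Initialization is data-driven: a straight line through the last stress
quartile gives $1/E_m$ (slope) and $\upsilon_t$ (strain intercept,
clipped to $[10^{-4}, 0.5]$), and $B$ is the stress at which the
nonlinear strain residual reaches $\upsilon_t/2$. Three
multiplicatively perturbed restarts guard against local minima; the
best objective wins. Standard errors come from the Jacobian-based
curvature at the optimum and are asymptotic approximations. An
optional soft-L1 residual transform (`loss = "soft_l1"`) is available
for outlier-bearing curves. $\upsilon_t$ hitting its upper bound
signals model misfit and warns.

`derived_curves()` regenerates $E_\mathrm{eff}(\sigma)$,
$E_\mathrm{eff}(s)$, $\beta(\sigma)$, $\upsilon(\sigma)$ and the
$(E_\mathrm{eff}, \beta)$ parametric trace directly from the fitted
triple (default grid: 200 points on $[0, \max(5B, \sigma_{\max})]$),
so they are bit-identical to direct constitutive-module evaluation.

`standardized_modulus_map()` tiles the tissue, fits each window's
curve, and evaluates the tangent modulus at a common "standardized"
stress (e.g. 1/5/10 kPa): loading inhomogeneity makes tangent moduli
of a nonlinear tissue incomparable across pixels at uneven local
stress, and the standardized evaluation removes that bias. Windows
that never reach the standardized stress are masked.
`gate_classify()` labels $(E_\mathrm{eff}, \beta)$ points by
priority-ordered rectangular gates — a generic utility; clinically
tuned thresholds are out of scope.

## Inverse problem options

`reconstruct_distribution()` inverts
$d(1/E_\mathrm{eff})/d\sigma = -\upsilon(\sigma)/\sigma$ by
Savitzky-Golay differentiation (default window 9 samples, order 2;
non-uniform grids are resampled). Differentiating measured curves is
noise-prone, which is exactly why the parametric fit is the primary
path; the reconstruction is the assumption-free cross-check. Negative
density excursions below $10^{-3}$ of the maximum (differentiation
noise) are clipped silently; larger ones warn, since they imply a
non-monotone compliance. The effective-medium quadrature
(`effective_modulus_from_distribution()`) integrates the tabulated
density by trapezoid rule with the exact lower limit inserted,
truncating where the integrand falls below $10^{-12}$ of its peak; a
distribution with finite density at zero closing stress is rejected
as non-integrable when evaluated at zero stress.

## The synthetic phantom

`make_frames()` renders complex B-scans of a layer stack (by default
200 µm of linear 100 kPa reference silicone over 400 µm of
crack-closure tissue with $E_m = 300$ kPa, $B = 4$ kPa,
$\upsilon_t = 0.05$) under stepwise compression to 20 kPa in 20
steps. Discrete point scatterers (default 10 per 100 µm², roughly ten
per coherence cell, so the coherent sum is circular Gaussian and the
speckle amplitude Rayleigh) are summed with a Gaussian axial envelope
(10 µm FWHM) at λ₀ = 1300 nm, n = 1.4, 5 µm axial and 10 µm lateral
pitch, with additive complex circular Gaussian noise at 30 dB SNR.
Displacement is encoded exactly (subpixel) through the scatterer
phases, which is what makes the phantom a valid oracle for
phase-based strain estimation. A fixed seed makes the output
byte-identical.

Design notes, chosen once:

* **Geometry.** The thin silicone and shallow tissue keep interframe
  displacements well inside the coherence envelope over the whole
  protocol. A thicker stack is physically legitimate but pushes deep
  pixels into decorrelation (displacement comparable to the envelope),
  which the package deliberately does not compensate (no tracking).
* **ROI placement.** Analysis ROIs must stay clear of the
  silicone-tissue interface, which migrates upward by ~35 µm over a
  20% silicone compression; estimation windows straddling it mix the
  two layers' strains and visibly distort the curve shape.
* **Crack phantom.** `make_crack_phantom()` embeds a lens-shaped void
  whose opening shrinks linearly to zero as local stress approaches
  $\sigma_\mathrm{clos} = \alpha E_m$ — the model gives only the
  closure endpoint, and a linear trajectory is the simplest
  interpolant. Strain concentration around the crack tip is not
  modelled; the phantom reproduces layer-mean behaviour only.
* **What the phantom does not emulate:** multiple scattering,
  refraction at interfaces, depth-dependent SNR roll-off, lateral
  PSF (each scatterer contributes to one A-scan), sample tilt and
  friction, or viscoelastic creep between steps. Passing the
  end-to-end tests therefore validates the *processing chain and
  estimator statistics* under realistic speckle, not robustness to
  every experimental artifact.

## Problem sizes and validation

The shipped tests run the full chain on phantoms of 32-48 lateral ×
~130 axial pixels with 20-30 compression steps, which keeps the whole
suite under about a minute while leaving thousands of independent
speckles per ROI. At those sizes: analytic round trips close
(quadrature vs closed-form modulus within 0.5%; Savitzky-Golay
reconstruction of the bell density within 2% RMS; the $\beta$ peak law
to 0.1% over random parameter triples), the speckle pipeline recovers
generating triples within ~2-5% (noiseless) and the same at 25-30 dB
SNR (estimator bias, not additive noise, is the limiting factor), and
a Monte-Carlo study at 1% multiplicative strain noise with 200 samples
keeps the median relative error on $E_m$ under 2%.

## Known limitations

* The bell-shaped density is an ansatz carried over from rock physics;
  the package fits it well to smooth monotone curves but
  `fit_constitutive()` will push $\upsilon_t$ to its bound (and warn)
  on data the law cannot represent.
* $B$ is the least identifiable parameter: percent-level distortions
  of curve shape map into several-percent errors on $B$, so curve
  quality (ROI size, step count) matters most for it.
* Cumulative strains beyond ~20-30% would need displacement tracking
  and a finite-strain treatment beyond the summation convention.
* The dilute-limit interpretation ($\upsilon_t \ll 1$) of the pore
  density is assumed throughout.
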