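## Crack-closure effective-medium constitutive model.
##
## Units are fixed throughout the package: stress and moduli in kPa,
## strain and pore contents dimensionless. Compressive stress and
## compressive strain are both positive. Order-of-magnitude prefactors
## in the pore geometry rules of thumb are fixed to exactly 1 by
## convention; `prefactor` arguments exist only for sensitivity studies.

#' Constitutive parameters of the crack-closure stress-strain law
#'
#' Bundles the parameter triple of the nonlinear law
#' \deqn{s(\sigma) = \sigma/E_m + \upsilon_t\,[1 - \exp(-\sigma/B)]}
#' describing a tissue whose compliant crack-like pores close gradually
#' under compression: `Em` is the Young's modulus of the host (matrix)
#' material once all pores are closed, `B` the characteristic closing
#' stress (the mode of the bell-shaped pore distribution over closing
#' stresses), and `vt` the total volumetric content of compliant pores.
#'
#' @param Em Matrix Young's modulus (kPa), positive scalar.
#' @param B Characteristic closing stress (kPa), positive scalar.
#' @param vt Total volumetric content of compliant pores, in `[0, 1)`.
#' @return An object of class `constitutive_params`.
#' @examples
#' p <- constitutive_params(Em = 300, B = 4, vt = 0.05)
#' strain_from_stress(p, c(0, 2, 10))
#' @export
constitutive_params <- function(Em, B, vt) {
  stopifnot(length(Em) == 1L, length(B) == 1L, length(vt) == 1L)
  if (!is.finite(Em) || Em <= 0) stop("Em must be a positive finite modulus (kPa)")
  if (!is.finite(B) || B <= 0) stop("B must be a positive finite stress (kPa)")
  if (!is.finite(vt) || vt < 0 || vt >= 1) stop("vt must lie in [0, 1)")
  structure(list(Em = Em, B = B, vt = vt), class = "constitutive_params")
}

#' @export
print.constitutive_params <- function(x, ...) {
  cat(sprintf("Crack-closure constitutive parameters:\n  Em = %g kPa, B = %g kPa, vt = %g\n",
              x$Em, x$B, x$vt))
  cat(sprintf("  vt*Em/B = %.4g -> nonlinearity peak at sigma > 0: %s\n",
              x$vt * x$Em / x$B, if (has_beta_peak(x)) "yes" else "no"))
  invisible(x)
}

#' Does the nonlinearity parameter peak at a non-zero stress?
#'
#' The nonlinearity parameter `beta(sigma)` attains an interior maximum
#' `Em/(4B)` at `sigma = B*log(vt*Em/B)` if and only if `vt*Em/B > 1`,
#' i.e. the pores reduce the zero-stress modulus below `Em/2`.
#'
#' @param params A [constitutive_params()] object.
#' @return Logical scalar.
#' @export
has_beta_peak <- function(params) {
  stopifnot(inherits(params, "constitutive_params"))
  params$vt * params$Em / params$B > 1
}

.check_stress <- function(sigma) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)))
    stop("stress must be finite and numeric (kPa)")
  if (any(sigma < 0))
    stop("compressive stress must be non-negative (compression-positive convention)")
  sigma
}

#' Strain at a given compressive stress
#'
#' Evaluates the closed-form stress-strain law
#' `s = sigma/Em + vt*(1 - exp(-sigma/B))`. The first term is the linear
#' response of the host matrix; the second is the extra strain released
#' by progressive closure of compliant pores, saturating at `vt` once
#' essentially all pores are closed.
#'
#' @param params A [constitutive_params()] object.
#' @param sigma Compressive stress (kPa), scalar or vector, `>= 0`.
#' @return Dimensionless axial strain, same length as `sigma`.
#' @export
strain_from_stress <- function(params, sigma) {
  stopifnot(inherits(params, "constitutive_params"))
  .check_stress(sigma)
  sigma / params$Em + params$vt * (1 - exp(-sigma / params$B))
}

#' Tangent Young's modulus at a given stress
#'
#' The local slope `d sigma / d s` of the stress-strain law:
#' `Eeff(sigma) = Em / (1 + (vt*Em/B) * exp(-sigma/B))`. It grows
#' monotonically from `Em/(1 + vt*Em/B)` at zero stress toward the
#' matrix modulus `Em` as the pores close.
#'
#' @inheritParams strain_from_stress
#' @return Tangent modulus (kPa), same length as `sigma`.
#' @export
tangent_modulus <- function(params, sigma) {
  stopifnot(inherits(params, "constitutive_params"))
  .check_stress(sigma)
  params$Em / (1 + (params$vt * params$Em / params$B) * exp(-sigma / params$B))
}

#' Dimensionless nonlinearity parameter
#'
#' `beta(sigma) = d Eeff / d sigma`, the local quadratic-nonlinearity
#' measure of the stress-strain curve. Writing
#' `y = (vt*Em/B) * exp(-sigma/B)`, it equals `(Em/B) * y / (1+y)^2`,
#' which peaks at `Em/(4B)` (where `y = 1`, i.e. at
#' `sigma = B*log(vt*Em/B)`) provided `vt*Em/B > 1`, and otherwise
#' decreases monotonically from `sigma = 0`.
#'
#' @inheritParams strain_from_stress
#' @return Dimensionless nonlinearity parameter, same length as `sigma`.
#' @export
nonlinearity_beta <- function(params, sigma) {
  stopifnot(inherits(params, "constitutive_params"))
  .check_stress(sigma)
  y <- (params$vt * params$Em / params$B) * exp(-sigma / params$B)
  (params$Em / params$B) * y / (1 + y)^2
}

## ---- pore geometry rules of thumb -------------------------------------

#' Geometry of a single crack-like pore
#'
#' A thin crack of diameter `D` and opening `h` has aspect ratio
#' `alpha = h/D << 1`. At the rule-of-thumb level (order-unity factors
#' fixed to 1) its compliance parameter, closing strain and closing
#' stress are `varsigma = alpha`, `s_clos = alpha` and
#' `sigma_clos = alpha * Em`.
#'
#' @param D Crack diameter (micrometres), positive.
#' @param h Crack opening (micrometres), positive and less than `D`.
#' @param Em Matrix Young's modulus (kPa) used for the closing stress.
#' @return An object of class `pore_geometry` with fields `D`, `h`,
#'   `alpha`, `compliance`, `closing_stress_kpa`, `closing_strain`.
#' @export
pore_geometry <- function(D, h, Em) {
  stopifnot(length(D) == 1L, length(h) == 1L, length(Em) == 1L)
  if (!is.finite(D) || D <= 0) stop("D must be positive (um)")
  if (!is.finite(h) || h <= 0) stop("h must be positive (um)")
  alpha <- h / D
  if (alpha >= 1) stop("h/D >= 1: not a thin crack-like pore")
  if (alpha > 0.3)
    warning(sprintf("aspect ratio %.3g exceeds 0.3; thin-crack rules of thumb degrade", alpha))
  structure(list(D = D, h = h, alpha = alpha,
                 compliance = alpha,
                 closing_stress_kpa = closing_stress(alpha, Em),
                 closing_strain = closing_strain(alpha)),
            class = "pore_geometry")
}

#' Closing stress and closing strain of a thin crack
#'
#' Rule-of-thumb closure conditions for a crack-like pore of aspect
#' ratio `alpha` in a matrix of modulus `Em`: the pore is completely
#' closed at compressive stress `sigma_clos = alpha * Em`, i.e. at
#' matrix strain `s_clos = alpha`. The order-unity geometric prefactor
#' is fixed to 1 by package convention; `prefactor` may be varied for
#' sensitivity studies only.
#'
#' @param alpha Aspect ratio `h/D`, in `(0, 1)`.
#' @param Em Matrix Young's modulus (kPa).
#' @param prefactor Order-unity multiplier, default 1.
#' @return Closing stress (kPa) or closing strain (dimensionless).
#' @examples
#' closing_stress(0.1, 200)  # 20 kPa
#' closing_strain(0.1)       # 0.1
#' @export
closing_stress <- function(alpha, Em, prefactor = 1) {
  .check_alpha(alpha)
  if (any(!is.finite(Em)) || any(Em <= 0)) stop("Em must be positive (kPa)")
  prefactor * alpha * Em
}

#' @rdname closing_stress
#' @export
closing_strain <- function(alpha, prefactor = 1) {
  .check_alpha(alpha)
  prefactor * alpha
}

.check_alpha <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("aspect ratio must be positive")
  if (any(alpha >= 1)) stop("aspect ratio >= 1: not a thin crack")
  invisible(alpha)
}

## ---- pore distributions -----------------------------------------------

#' Tabulated distribution of compliant pores
#'
#' Represents the volumetric density of compliant pores over one of
#' three equivalent axes: closing stress `sigma` (density in 1/kPa),
#' aspect ratio `alpha`, or compliance parameter `varsigma` (both
#' dimensionless). The density integrates (trapezoid rule over `grid`)
#' to the total volumetric content `vt`.
#'
#' @param grid Strictly increasing axis sample points (kPa for the
#'   closing-stress axis, dimensionless otherwise).
#' @param density Non-negative density values at `grid`.
#' @param axis One of `"closing_stress"`, `"aspect_ratio"`,
#'   `"compliance"`.
#' @param total_content Optional total content `vt`; when supplied the
#'   trapezoid integral of `density` must match it within 0.5%.
#' @return An object of class `pore_distribution`.
#' @export
pore_distribution <- function(grid, density,
                              axis = c("closing_stress", "aspect_ratio", "compliance"),
                              total_content = NULL) {
  axis <- match.arg(axis)
  if (length(grid) < 2L || length(grid) != length(density))
    stop("grid and density must have equal length >= 2")
  if (any(!is.finite(grid)) || any(diff(grid) <= 0))
    stop("grid must be finite and strictly increasing")
  if (any(!is.finite(density)) || any(density < 0))
    stop("density values must be finite and >= 0")
  integral <- pracma::trapz(grid, density)
  if (is.null(total_content)) {
    total_content <- integral
  } else if (total_content > 0 &&
             abs(integral - total_content) > 5e-3 * total_content) {
    stop(sprintf("density integrates to %.6g but total_content = %.6g (>0.5%% off)",
                 integral, total_content))
  }
  structure(list(grid = grid, density = density, axis = axis,
                 total_content = total_content),
            class = "pore_distribution")
}

#' @export
print.pore_distribution <- function(x, ...) {
  cat(sprintf("Pore distribution over %s: %d samples on [%g, %g], vt = %.4g\n",
              x$axis, length(x$grid), min(x$grid), max(x$grid), x$total_content))
  invisible(x)
}

#' Bell-shaped pore distribution over closing stress
#'
#' The closing-stress density `v(sigma) = (vt/B^2) * sigma * exp(-sigma/B)`
#' that generates the closed-form stress-strain law. It vanishes at
#' `sigma = 0`, peaks at the characteristic stress `sigma = B`, and
#' integrates to `vt` over `[0, Inf)`.
#'
#' @param params A [constitutive_params()] object.
#' @param sigma_grid Increasing non-negative stress grid (kPa).
#' @return A [pore_distribution()] on the closing-stress axis. The
#'   stored `total_content` is the exact `vt` of `params`; the grid
#'   should extend to several tens of `B` if the tabulated density is
#'   meant to capture essentially all of it.
#' @export
bell_distribution <- function(params, sigma_grid) {
  stopifnot(inherits(params, "constitutive_params"))
  .check_stress(sigma_grid)
  if (any(diff(sigma_grid) <= 0)) stop("sigma_grid must be strictly increasing")
  dens <- (params$vt / params$B^2) * sigma_grid * exp(-sigma_grid / params$B)
  structure(list(grid = sigma_grid, density = dens, axis = "closing_stress",
                 total_content = params$vt),
            class = "pore_distribution")
}

#' Effective modulus of a matrix containing a pore distribution
#'
#' Effective-medium reduction of the tangent modulus by the pores not
#' yet closed at the current stress. On the closing-stress axis,
#' \deqn{E_m/E_{\mathrm{eff}}(\sigma) = 1 + E_m \int_\sigma^\infty
#'   \upsilon(\sigma')/\sigma'\, d\sigma';}
#' on the compliance/aspect-ratio axes the lower integration limit is
#' the smallest still-open pore, `alpha_min = sigma/Em`, and the `Em`
#' prefactor is absent. The integral is evaluated by trapezoid
#' quadrature on the tabulated grid (refined with the exact lower
#' limit); tail points where the integrand falls below 1e-12 of its
#' peak are dropped.
#'
#' @param dist A [pore_distribution()].
#' @param Em Matrix modulus (kPa).
#' @param sigma Current compressive stress (kPa), scalar or vector.
#' @return Effective tangent modulus (kPa), same length as `sigma`.
#' @export
effective_modulus_from_distribution <- function(dist, Em, sigma) {
  stopifnot(inherits(dist, "pore_distribution"))
  if (!is.finite(Em) || Em <= 0) stop("Em must be positive (kPa)")
  .check_stress(sigma)
  grid <- dist$grid
  dens <- dist$density
  ## integrand density/axis_value; at an exact zero axis point the
  ## density must vanish too (otherwise the compliance integral diverges)
  integrand <- function(g, d) {
    out <- numeric(length(g))
    z <- g == 0
    if (any(z & d > 0))
      stop("non-integrable pore distribution: finite density at zero axis value")
    out[!z] <- d[!z] / g[!z]
    out
  }
  base_int <- integrand(grid, dens)
  peak <- max(base_int)
  vapply(sigma, function(s) {
    lower <- switch(dist$axis,
                    closing_stress = s,
                    s / Em)  # aspect_ratio / compliance axes
    keep <- grid > lower
    g <- c(lower, grid[keep])
    d <- c(stats::approx(grid, dens, xout = lower, yleft = 0, yright = 0)$y,
           dens[keep])
    f <- integrand(g, d)
    live <- f >= 1e-12 * peak
    if (any(live)) {
      last <- max(which(live))
      g <- g[seq_len(last)]; f <- f[seq_len(last)]
    }
    I <- if (length(g) >= 2) pracma::trapz(g, f) else 0
    ratio <- 1 + if (dist$axis == "closing_stress") Em * I else I
    Em / ratio
  }, numeric(1))
}

#' Modulus reduction by identical compliant inclusions
#'
#' For a matrix containing identical soft inclusions of compliance
#' `varsigma` and total volumetric content `vt`, the modulus ratio is
#' `Em/Eeff = 1 + vt/varsigma`.
#'
#' @param vt Total volumetric content of inclusions.
#' @param compliance Compliance parameter `varsigma` (about the aspect
#'   ratio, for thin cracks).
#' @return The ratio `Em/Eeff` (dimensionless, `>= 1`).
#' @export
identical_pore_modulus_ratio <- function(vt, compliance) {
  if (any(vt < 0)) stop("vt must be >= 0")
  if (any(compliance <= 0)) stop("compliance must be positive")
  1 + vt / compliance
}

#' Average compliance of a nonidentical pore population
#'
#' Inverts the identical-inclusion relation for a measured modulus
#' ratio: `varsigma_av = vt / (Em/Eeff - 1)`. Combining an independently
#' measured modulus reduction with the pore content estimates the
#' characteristic aspect ratio of the pores.
#'
#' @param Em_over_Eeff Measured modulus ratio, `> 1`.
#' @param vt Total volumetric pore content, `> 0`.
#' @return Average compliance parameter (dimensionless).
#' @export
average_compliance <- function(Em_over_Eeff, vt) {
  if (any(vt <= 0)) stop("vt must be positive")
  if (any(Em_over_Eeff <= 1))
    stop("modulus ratio <= 1: no compliant-pore solution")
  vt / (Em_over_Eeff - 1)
}

#' Modulus ratio from crack number density
#'
#' For thin cracks of diameter `D` at number density `ncr` per unit
#' volume, `Em/Eeff = 1 + ncr * D^3`: each crack releases strain energy
#' in a volume of order `D^3`, far larger than its own volume `h*D^2`.
#'
#' @param ncr Crack number density (per unit volume), `>= 0`.
#' @param D Crack diameter (same length unit as `ncr^(-1/3)`), `> 0`.
#' @return The ratio `Em/Eeff`.
#' @export
crack_density_modulus_ratio <- function(ncr, D) {
  if (any(ncr < 0)) stop("ncr must be >= 0")
  if (any(D <= 0)) stop("D must be positive")
  1 + ncr * D^3
}

#' Reconstruct the pore distribution from a measured modulus curve
#'
#' Inverts the effective-medium relation by numerical differentiation:
#' `v(sigma) = -sigma * d(1/Eeff)/d sigma`. The reciprocal modulus is
#' differentiated with a Savitzky-Golay filter (local polynomial least
#' squares), which keeps the inversion usable on noisy measured
#' `Eeff(sigma)` curves. Small negative excursions of the recovered
#' density (below `1e-3` of its maximum, from differentiation noise)
#' are clipped to zero; larger ones trigger a warning because they
#' imply a non-monotone compliance, then are clipped as well.
#'
#' @param sigma Strictly increasing stress samples (kPa), length >= 5.
#'   A non-uniform grid is resampled internally to a uniform one.
#' @param Eeff Positive tangent-modulus samples (kPa) at `sigma`.
#' @param window Savitzky-Golay window length in samples (odd, default 9).
#' @param order Local polynomial order (default 2).
#' @return A [pore_distribution()] on the closing-stress axis whose
#'   `total_content` is the trapezoid integral of the recovered density.
#' @export
reconstruct_distribution <- function(sigma, Eeff, window = 9L, order = 2L) {
  if (length(sigma) < 5L) stop("need at least 5 samples")
  if (length(Eeff) != length(sigma)) stop("sigma and Eeff lengths differ")
  if (any(diff(sigma) <= 0)) stop("sigma must be strictly increasing")
  if (any(Eeff <= 0)) stop("Eeff must be positive")
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  window <- min(window, length(sigma) - (1 - length(sigma) %% 2L))
  if (window <= order) stop("window must exceed polynomial order")
  ## resample to a uniform grid if needed (SG filters assume uniform spacing)
  h <- diff(sigma)
  if (diff(range(h)) > 1e-8 * mean(h)) {
    grid <- seq(min(sigma), max(sigma), length.out = length(sigma))
    Eeff <- stats::approx(sigma, Eeff, xout = grid)$y
    sigma <- grid
    h <- diff(sigma)
  }
  compliance <- 1 / Eeff
  dcds <- signal::sgolayfilt(compliance, p = order, n = window, m = 1, ts = h[1])
  dens <- -sigma * dcds
  ## numerical floor: derivative noise on an essentially constant
  ## compliance must not masquerade as a non-monotone modulus curve
  floor_abs <- 1e-9 * max(sigma) * max(compliance) / diff(range(sigma))
  if (any(dens < -pmax(1e-3 * max(dens, 0), floor_abs)))
    warning("reconstructed density has substantial negative excursions (non-monotone 1/Eeff); clipping to 0")
  dens <- pmax(dens, 0)
  dens[dens < floor_abs] <- 0
  structure(list(grid = sigma, density = dens, axis = "closing_stress",
                 total_content = pracma::trapz(sigma, dens)),
            class = "pore_distribution")
}
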