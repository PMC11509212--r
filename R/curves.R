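## Stress-strain curve assembly, constitutive fitting, and
## standardized-stress tangent-modulus elastograms.

#' Reference-silicone stress calibration
#'
#' The pre-calibrated silicone layer on top of the sample acts as an
#' optical stress sensor: it is elastically linear, so the applied
#' stress equals its Young's modulus times its cumulative strain,
#' `sigma = Esil * S_sil`, at any compression level.
#'
#' @param Esil_kpa Young's modulus of the reference silicone (kPa).
#' @param roi Pixel window inside the silicone layer, as
#'   `list(rows = <int vector>, cols = <int vector>)`.
#' @return Object of class `silicone_calibration`.
#' @export
silicone_calibration <- function(Esil_kpa, roi = NULL) {
  stopifnot(length(Esil_kpa) == 1L, is.finite(Esil_kpa), Esil_kpa > 0)
  structure(list(Esil_kpa = Esil_kpa, roi = roi),
            class = "silicone_calibration")
}

#' Applied stress from silicone cumulative strain
#'
#' @param S_sil Cumulative strain in the reference silicone (`>= 0`).
#' @param cal A [silicone_calibration()].
#' @return Stress in kPa, `Esil * S_sil`.
#' @export
stress_from_silicone <- function(S_sil, cal) {
  stopifnot(inherits(cal, "silicone_calibration"))
  if (any(S_sil < -1e-12, na.rm = TRUE))
    stop("silicone cumulative strain must be >= 0")
  cal$Esil_kpa * S_sil
}

#' Stress-strain curve for one tissue region
#'
#' @param strain Tissue cumulative strain samples (dimensionless).
#' @param stress_kpa Applied stress samples (kPa), non-decreasing.
#' @param roi Optional ROI descriptor (carried as provenance).
#' @param frame_range Optional integer range of source frames.
#' @return Object of class `stress_strain_curve` wrapping a data frame
#'   with columns `strain`, `stress_kpa`.
#' @export
stress_strain_curve <- function(strain, stress_kpa, roi = NULL,
                                frame_range = NULL) {
  if (length(strain) != length(stress_kpa)) stop("length mismatch")
  if (any(!is.finite(strain)) || any(!is.finite(stress_kpa)))
    stop("curve samples must be finite")
  if (any(diff(stress_kpa) < 0)) stop("stress samples must be non-decreasing")
  structure(list(data = data.frame(strain = strain, stress_kpa = stress_kpa),
                 roi = roi, frame_range = frame_range),
            class = "stress_strain_curve")
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("Stress-strain curve: %d samples, stress 0-%.3g kPa, max strain %.4g\n",
              nrow(x$data), max(x$data$stress_kpa), max(x$data$strain)))
  invisible(x)
}

## ROI mean of a cumulative strain map; error when mostly masked
.roi_mean <- function(map, roi, what) {
  sub <- map$S[roi$rows, roi$cols, drop = FALSE]
  msk <- map$mask[roi$rows, roi$cols, drop = FALSE]
  if (mean(msk) < 0.5)
    stop(sprintf("%s ROI is mostly masked (%.0f%% valid)", what, 100 * mean(msk)))
  mean(sub[msk])
}

#' ROI size in pixels from a physical averaging window
#'
#' Strains entering a stress-strain curve are averaged over rectangular
#' regions of roughly 80-100 micrometres to suppress speckle noise;
#' this converts the physical window to a pixel count.
#'
#' @param size_um Window size (micrometres), default 90.
#' @param pitch_um Pixel pitch (micrometres).
#' @return Integer number of pixels (at least 1).
#' @export
roi_pixels <- function(size_um = 90, pitch_um) {
  stopifnot(size_um > 0, pitch_um > 0)
  max(1L, as.integer(round(size_um / pitch_um)))
}

#' Build a stress-strain curve from a compression series
#'
#' For each cumulative-strain map in the series, averages tissue strain
#' over the tissue ROI and silicone strain over the silicone ROI,
#' converts the latter to stress via the calibration, sorts by stress,
#' applies a monotone cleanup (samples violating stress monotonicity by
#' less than 2% of the stress range are merged by averaging; larger
#' violations raise an error), and prepends the `(0, 0)` origin.
#'
#' @param series List of [accumulate_strain()] results, one per
#'   compression step, in acquisition order.
#' @param tissue_roi,silicone_roi `list(rows=, cols=)` pixel windows;
#'   the silicone ROI must lie entirely inside the silicone layer.
#' @param cal A [silicone_calibration()].
#' @return A [stress_strain_curve()].
#' @export
build_curve <- function(series, tissue_roi, silicone_roi, cal) {
  stopifnot(length(series) >= 1L,
            all(vapply(series, inherits, logical(1), "cumulative_strain_map")))
  s <- vapply(series, .roi_mean, numeric(1), roi = tissue_roi, what = "tissue")
  ssil <- vapply(series, .roi_mean, numeric(1), roi = silicone_roi,
                 what = "silicone")
  sigma <- stress_from_silicone(pmax(ssil, 0), cal)
  ord <- order(sigma)
  sigma <- sigma[ord]; s <- s[ord]
  ## monotone cleanup: merge near-ties, fail on gross non-monotonicity
  rng <- max(sigma) - min(sigma)
  viol <- which(diff(sigma) < 0)
  if (length(viol)) {
    if (any(-diff(sigma)[viol] > 0.02 * rng))
      stop("stress sequence non-monotone beyond 2% of range")
    warning("near-ties in stress sequence merged (monotone cleanup)")
    keep <- c(TRUE, diff(sigma) > 0)
    sigma <- sigma[keep]; s <- s[keep]
  }
  stress_strain_curve(c(0, s), c(0, sigma), roi = tissue_roi,
                      frame_range = c(1L, length(series)))
}

## ---- constitutive fit --------------------------------------------------

.default_init <- function(sigma, s) {
  ## last quartile of the curve is near-linear with slope 1/Em and
  ## strain-axis intercept vt (all pores closed there)
  n <- length(sigma)
  i4 <- which(sigma >= stats::quantile(sigma, 0.75))
  if (length(i4) < 3L) i4 <- seq(max(1L, n - 3L), n)
  co <- stats::coef(stats::lm(s[i4] ~ sigma[i4]))
  slope <- co[[2]]
  Em0 <- if (is.finite(slope) && slope > 0) 1 / slope else max(sigma) / max(max(s), 1e-6)
  vt0 <- min(max(co[[1]], 1e-4), 0.5)
  ## B: stress at which the nonlinear residual reaches half of vt
  resid_nl <- s - sigma / Em0
  idx <- which(resid_nl >= vt0 / 2)
  B0 <- if (length(idx)) max(sigma[idx[1]], 1e-3) else max(stats::median(sigma) / 2, 1e-3)
  c(Em = Em0, B = B0, vt = vt0)
}

#' Fit the crack-closure law to a stress-strain curve
#'
#' Bounded Levenberg-Marquardt least squares of strain as an explicit
#' function of stress, `s(sigma) = sigma/Em + vt*(1 - exp(-sigma/B))`
#' (fitting in this direction avoids per-iteration root finding). The
#' default initialization estimates `Em` and `vt` from a straight line
#' through the last stress quartile (where the pores are essentially
#' closed) and `B` from the stress at which the nonlinear strain
#' residual reaches `vt/2`; three multiplicatively perturbed restarts
#' guard against local minima and the best objective wins. Parameter
#' standard errors come from the Jacobian-based curvature at the
#' optimum and are asymptotic approximations.
#'
#' @param curve A [stress_strain_curve()] with at least 10 samples
#'   spanning at least 2 kPa of stress.
#' @param init Optional [constitutive_params()] starting point.
#' @param loss `"linear"` (default) or `"soft_l1"` for a robust
#'   soft-L1 transform of the residuals (outlier-bearing curves).
#' @return Object of class `fit_result`: `params`
#'   ([constitutive_params()]), `se` (named standard errors),
#'   `residual_rms` (strain units), `converged`, `info` (optimizer
#'   diagnostics), and the fitted curve samples.
#' @export
fit_constitutive <- function(curve, init = NULL,
                             loss = c("linear", "soft_l1")) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  loss <- match.arg(loss)
  sigma <- curve$data$stress_kpa
  s <- curve$data$strain
  if (length(sigma) < 10L) stop("need at least 10 curve samples to fit")
  if (diff(range(sigma)) < 2) stop("stress range must span at least 2 kPa")

  model <- function(p, x) x / p[1] + p[3] * (1 - exp(-x / p[2]))
  resid_fn <- function(p) {
    r <- s - model(p, sigma)
    if (loss == "soft_l1") r <- sign(r) * sqrt(2 * (sqrt(1 + r^2) - 1))
    r
  }
  lower <- c(Em = 1e-3, B = 1e-4, vt = 0)
  upper <- c(Em = 1e7, B = 1e4, vt = 0.999)
  p0 <- if (!is.null(init)) {
    stopifnot(inherits(init, "constitutive_params"))
    c(Em = init$Em, B = init$B, vt = init$vt)
  } else .default_init(sigma, s)
  p0 <- pmin(pmax(p0, lower), upper)
  ## deterministic multi-start: the data-driven init plus two
  ## multiplicative perturbations bracketing it
  starts <- list(p0,
                 pmin(pmax(p0 * c(0.5, 0.4, 1.5), lower), upper),
                 pmin(pmax(p0 * c(2.0, 2.5, 0.5), lower), upper))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("constitutive fit failed to converge after multi-start")
  fit <- best$fit
  p <- fit$par
  if (p[["vt"]] > 0.995 * upper[["vt"]])
    warning("vt hit its upper bound: the crack-closure law likely misfits this curve")
  ## asymptotic standard errors from local curvature
  se <- rep(NA_real_, 3)
  jt <- tryCatch({
    J <- .fit_jacobian(p, sigma)
    dof <- max(length(s) - 3L, 1L)
    covm <- best$sse / dof * solve(crossprod(J))
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, 3))
  se <- stats::setNames(jt, c("Em", "B", "vt"))
  params <- constitutive_params(p[["Em"]], p[["B"]], min(p[["vt"]], 0.999))
  structure(list(params = params, se = se,
                 residual_rms = sqrt(mean((s - model(p, sigma))^2)),
                 converged = fit$info %in% 1:4,
                 info = list(status = fit$info, message = fit$message,
                             niter = fit$niter, sse = best$sse),
                 curve = curve,
                 fitted = model(p, sigma)),
            class = "fit_result")
}

## analytic Jacobian of the strain model wrt (Em, B, vt)
.fit_jacobian <- function(p, sigma) {
  Em <- p[[1]]; B <- p[[2]]; vt <- p[[3]]
  cbind(Em = -sigma / Em^2,
        B = -vt * sigma / B^2 * exp(-sigma / B),
        vt = 1 - exp(-sigma / B))
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Crack-closure constitutive fit\n")
  cat(sprintf("  Em = %.4g kPa (se %.2g), B = %.4g kPa (se %.2g), vt = %.4g (se %.2g)\n",
              x$params$Em, x$se[["Em"]], x$params$B, x$se[["B"]],
              x$params$vt, x$se[["vt"]]))
  cat(sprintf("  residual RMS = %.3g strain, converged: %s\n",
              x$residual_rms, x$converged))
  invisible(x)
}

#' Derived curves from a fitted constitutive law
#'
#' Regenerates, purely from the fitted parameter triple, the curves
#' used for tissue characterization: tangent modulus versus stress and
#' versus strain, nonlinearity parameter versus stress, the bell-shaped
#' pore distribution over closing stress, and the parametric
#' `(Eeff, beta)` trace used for gate-based tissue classification.
#'
#' @param fit A [fit_constitutive()] result (or bare
#'   [constitutive_params()]).
#' @param sigma_grid Stress grid (kPa); default 200 points on
#'   `[0, max(5B, max fitted stress)]`.
#' @return List of data frames `Eeff_sigma`, `Eeff_strain`,
#'   `beta_sigma`, `density_sigma`, `plane` (columns `Eeff`, `beta`).
#' @export
derived_curves <- function(fit, sigma_grid = NULL) {
  params <- if (inherits(fit, "fit_result")) fit$params else fit
  stopifnot(inherits(params, "constitutive_params"))
  if (is.null(sigma_grid)) {
    smax <- if (inherits(fit, "fit_result")) max(fit$curve$data$stress_kpa) else 0
    sigma_grid <- seq(0, max(5 * params$B, smax), length.out = 200L)
  }
  Eeff <- tangent_modulus(params, sigma_grid)
  beta <- nonlinearity_beta(params, sigma_grid)
  strain <- strain_from_stress(params, sigma_grid)
  dens <- (params$vt / params$B^2) * sigma_grid * exp(-sigma_grid / params$B)
  list(Eeff_sigma = data.frame(stress_kpa = sigma_grid, Eeff_kpa = Eeff),
       Eeff_strain = data.frame(strain = strain, Eeff_kpa = Eeff),
       beta_sigma = data.frame(stress_kpa = sigma_grid, beta = beta),
       density_sigma = data.frame(stress_kpa = sigma_grid, density = dens),
       plane = data.frame(Eeff_kpa = Eeff, beta = beta))
}

## ---- standardized-stress elastograms ----------------------------------

#' Tangent-modulus map at a standardized stress
#'
#' Loading inhomogeneity makes tangent moduli of a nonlinear tissue
#' incomparable across pixels unless they are evaluated at a common
#' ("standardized") stress. This tiles the tissue area into windows,
#' builds a stress-strain curve per window (window-mean tissue strain
#' against the silicone-derived stress), fits the crack-closure law,
#' and evaluates the tangent modulus at `sigma_std`. Windows whose
#' maximum reached stress falls short of `sigma_std`, or whose fit
#' fails, are masked.
#'
#' @param series List of [accumulate_strain()] results (one per step).
#' @param cal A [silicone_calibration()] whose `roi` locates the
#'   reference silicone.
#' @param sigma_std Standardized stress (kPa), e.g. 1, 5 or 10.
#' @param tissue_rows,tissue_cols Pixel ranges delimiting the tissue
#'   area to map.
#' @param window_px Square window size in pixels (default from a 90 um
#'   window via [roi_pixels()] if `pitch_um` given, else 8).
#' @param pitch_um Optional pixel pitch to derive `window_px`.
#' @return Object of class `tangent_modulus_map`: `Eeff` (matrix, one
#'   value per window), `mask`, `sigma_std`, `window_px`, and the
#'   window centre coordinates `rows`, `cols`.
#' @export
standardized_modulus_map <- function(series, cal, sigma_std,
                                     tissue_rows, tissue_cols,
                                     window_px = NULL, pitch_um = NULL) {
  stopifnot(inherits(cal, "silicone_calibration"), !is.null(cal$roi))
  if (is.null(window_px))
    window_px <- if (!is.null(pitch_um)) roi_pixels(90, pitch_um) else 8L
  window_px <- max(2L, as.integer(window_px))
  sig <- stress_from_silicone(
    pmax(vapply(series, .roi_mean, numeric(1), roi = cal$roi,
                what = "silicone"), 0), cal)
  if (sigma_std > max(sig))
    stop(sprintf("standardized stress %g kPa exceeds the maximum applied stress %.3g kPa",
                 sigma_std, max(sig)))
  r_starts <- seq(tissue_rows[1], tissue_rows[2] - window_px + 1L, by = window_px)
  c_starts <- seq(tissue_cols[1], tissue_cols[2] - window_px + 1L, by = window_px)
  Eeff <- matrix(NA_real_, length(r_starts), length(c_starts))
  ok <- matrix(FALSE, length(r_starts), length(c_starts))
  for (i in seq_along(r_starts)) {
    for (j in seq_along(c_starts)) {
      roi <- list(rows = r_starts[i]:(r_starts[i] + window_px - 1L),
                  cols = c_starts[j]:(c_starts[j] + window_px - 1L))
      res <- tryCatch({
        sw <- vapply(series, .roi_mean, numeric(1), roi = roi, what = "tissue")
        crv <- stress_strain_curve(c(0, sw), c(0, sig))
        ft <- suppressWarnings(fit_constitutive(crv))
        tangent_modulus(ft$params, sigma_std)
      }, error = function(e) NA_real_)
      Eeff[i, j] <- res
      ok[i, j] <- is.finite(res)
    }
  }
  if (mean(ok) < 0.5)
    warning("standardized stress reached / fit succeeded in fewer than half of the windows")
  structure(list(Eeff = Eeff, mask = ok, sigma_std = sigma_std,
                 window_px = window_px,
                 rows = r_starts + (window_px - 1) / 2,
                 cols = c_starts + (window_px - 1) / 2),
            class = "tangent_modulus_map")
}

#' Classify points in the (Eeff, beta) plane by labelled gates
#'
#' Generic rectangular-gate classifier for the stiffness-nonlinearity
#' plane: each `(Eeff, beta)` point receives the label of the first
#' gate (in priority order) containing it, or `"unclassified"`.
#'
#' @param points Data frame with columns `Eeff_kpa` and `beta`.
#' @param gates Data frame with columns `label`, `Eeff_min`,
#'   `Eeff_max`, `beta_min`, `beta_max`, ordered by priority
#'   (bounds inclusive).
#' @return Character vector of labels, one per point.
#' @export
gate_classify <- function(points, gates) {
  need_p <- c("Eeff_kpa", "beta")
  need_g <- c("label", "Eeff_min", "Eeff_max", "beta_min", "beta_max")
  if (!all(need_p %in% names(points))) stop("points need columns Eeff_kpa, beta")
  if (!all(need_g %in% names(gates)))
    stop("malformed gates: need columns ", paste(need_g, collapse = ", "))
  if (any(gates$Eeff_min > gates$Eeff_max) || any(gates$beta_min > gates$beta_max))
    stop("malformed gate: min exceeds max")
  labels <- rep("unclassified", nrow(points))
  for (k in rev(seq_len(nrow(gates)))) {  # earlier rows override later ones
    inside <- points$Eeff_kpa >= gates$Eeff_min[k] &
      points$Eeff_kpa <= gates$Eeff_max[k] &
      points$beta >= gates$beta_min[k] &
      points$beta <= gates$beta_max[k]
    labels[inside] <- as.character(gates$label[k])
  }
  labels
}
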