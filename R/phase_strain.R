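## Phase-resolved axial strain estimation from complex OCT B-scans.
##
## Conventions: frames are complex matrices with rows = axial pixels
## (z, increasing with depth, row 1 at the top surface) and columns =
## lateral pixels. The interframe phase Phi = arg(a2 * Conj(a1)) grows
## when optical path grows, i.e. when scatterers move AWAY from the
## probe; under compression scatterers move toward the probe, so the
## strain estimators negate the phase slope to keep compressive strain
## positive (the package-wide compression-positive convention).

#' Complex OCT B-scan frame
#'
#' Wraps one complex-valued B-scan together with the imaging metadata
#' needed to convert interframe phase differences into displacement and
#' strain: central source wavelength (vacuum), refractive index, and
#' the in-tissue axial / lateral pixel pitches.
#'
#' @param data Complex matrix, rows = axial pixels (depth), columns =
#'   lateral pixels.
#' @param pitch_axial_um In-tissue axial pixel pitch (micrometres).
#' @param pitch_lateral_um Lateral pixel pitch (micrometres).
#' @param lambda0_nm Central wavelength in vacuum (nm), default 1300.
#' @param n Refractive index (scalar, or one value per axial row).
#' @return An object of class `oct_frame`.
#' @export
oct_frame <- function(data, pitch_axial_um, pitch_lateral_um = 10,
                      lambda0_nm = 1300, n = 1.4) {
  if (!is.matrix(data) || !is.complex(data)) data <- matrix(as.complex(data),
                                                            nrow = NROW(data))
  stopifnot(pitch_axial_um > 0, pitch_lateral_um > 0, lambda0_nm > 0)
  if (any(n < 1)) stop("refractive index must be >= 1")
  if (!length(n) %in% c(1L, nrow(data)))
    stop("n must be scalar or one value per axial row")
  structure(list(data = data,
                 pitch_axial_um = pitch_axial_um,
                 pitch_lateral_um = pitch_lateral_um,
                 lambda0_nm = lambda0_nm, n = n),
            class = "oct_frame")
}

.same_grid <- function(f1, f2) {
  identical(dim(f1$data), dim(f2$data)) &&
    isTRUE(all.equal(f1$pitch_axial_um, f2$pitch_axial_um)) &&
    isTRUE(all.equal(f1$lambda0_nm, f2$lambda0_nm)) &&
    isTRUE(all.equal(f1$n, f2$n))
}

#' Interframe phase-difference map
#'
#' Per-pixel phase of `a2 * Conj(a1)`, wrapped to `(-pi, pi]`, with a
#' validity mask from an amplitude threshold (pixels whose amplitude in
#' either frame falls below the threshold carry no reliable phase).
#'
#' @param frame1,frame2 [oct_frame()] objects on identical grids.
#' @param amp_threshold Amplitude noise floor; default 0 keeps all pixels.
#' @return Object of class `phase_diff_map`: fields `phi` (radians),
#'   `mask` (logical), and the frame metadata.
#' @export
phase_difference <- function(frame1, frame2, amp_threshold = 0) {
  stopifnot(inherits(frame1, "oct_frame"), inherits(frame2, "oct_frame"))
  if (!.same_grid(frame1, frame2)) stop("frame grids/metadata do not match")
  prod <- frame2$data * Conj(frame1$data)
  phi <- Arg(prod)
  mask <- Mod(frame1$data) > amp_threshold & Mod(frame2$data) > amp_threshold
  structure(list(phi = phi, mask = mask,
                 pitch_axial_um = frame1$pitch_axial_um,
                 pitch_lateral_um = frame1$pitch_lateral_um,
                 lambda0_nm = frame1$lambda0_nm, n = frame1$n),
            class = "phase_diff_map")
}

#' Axial displacement from interframe phase
#'
#' `U = lambda0 * Phi / (4 pi n)`: a full 2*pi interframe phase shift
#' corresponds to half a wavelength of optical path, i.e.
#' `lambda0/(2n)` of axial displacement.
#'
#' @param phi Phase difference in radians (numeric, or a
#'   [phase_difference()] map, in which case metadata defaults are taken
#'   from it).
#' @param lambda0_nm Central vacuum wavelength (nm).
#' @param n Refractive index.
#' @return Axial displacement in nanometres, same shape as the phase.
#' @export
displacement_from_phase <- function(phi, lambda0_nm = 1300, n = 1.4) {
  if (inherits(phi, "phase_diff_map")) {
    lambda0_nm <- phi$lambda0_nm
    n <- phi$n
    phi <- phi$phi
  }
  lambda0_nm * phi / (4 * pi * n)
}

## running windowed sums along columns via stats::filter (sides = 2)
.runsum <- function(x, w) {
  out <- stats::filter(x, rep(1, w), sides = 2)
  out[is.na(out)] <- NA_real_
  out
}

## least-squares slope of y vs axial index over a running window of w
## samples, per column, with NA-aware accumulation. Returns slope per
## axial step (divide by pitch for physical units) and the valid count.
.window_slope <- function(y, w) {
  nz <- nrow(y); nx <- ncol(y)
  z <- matrix(seq_len(nz), nz, nx)
  v <- !is.na(y)
  y0 <- ifelse(v, y, 0)
  z0 <- ifelse(v, z, 0)
  Sv  <- apply(v * 1, 2, .runsum, w = w)
  Sy  <- apply(y0, 2, .runsum, w = w)
  Sz  <- apply(z0, 2, .runsum, w = w)
  Szz <- apply(z0^2, 2, .runsum, w = w)
  Szy <- apply(z0 * y0, 2, .runsum, w = w)
  denom <- Sv * Szz - Sz^2
  slope <- (Sv * Szy - Sz * Sy) / denom
  slope[!is.finite(slope)] <- NA_real_
  list(slope = slope, count = Sv)
}

## lateral NA-aware running mean over w columns (applied to rows)
.lateral_mean <- function(x, w) {
  if (w <= 1L) return(x)
  v <- !is.na(x)
  x0 <- ifelse(v, x, 0)
  num <- t(apply(x0, 1, .runsum, w = w))
  den <- t(apply(v * 1, 1, .runsum, w = w))
  out <- num / den
  out[!is.finite(out)] <- NA_real_
  out
}

.strain_map <- function(s, mask, window, method, pitch_axial_um,
                        pitch_lateral_um, cap = 0.02) {
  s[!mask] <- NA_real_
  frac <- mean(abs(s) > cap, na.rm = TRUE)
  if (is.finite(frac) && frac > 0.05)
    warning(sprintf("%.1f%% of strain estimates exceed the interframe validity bound %g (decorrelation regime)",
                    100 * frac, cap))
  structure(list(s = s, mask = mask, window = window, method = method,
                 pitch_axial_um = pitch_axial_um,
                 pitch_lateral_um = pitch_lateral_um),
            class = "strain_map")
}

#' Incremental strain by least-squares phase-slope estimation
#'
#' Unwraps the interframe phase along depth (cumulative 2*pi
#' correction per A-scan), then estimates the local axial phase slope
#' by least squares over a running window and scales it to strain via
#' `s = -lambda0/(4 pi n) * dPhi/dz` (negated so that compression,
#' which moves scatterers toward the probe, is positive). Masked
#' pixels are excluded from
#' the regressions; windows with fewer than 3 valid pixels, or more
#' than half masked, yield masked estimates.
#'
#' @param pd A [phase_difference()] map.
#' @param window Integer pair `c(axial, lateral)` window in pixels
#'   (default `c(8, 8)`); the lateral part averages slope estimates.
#' @param cap Interframe strain validity bound (default 0.02); a
#'   decorrelation warning is issued when a noticeable fraction of
#'   estimates exceed it.
#' @return Object of class `strain_map` with fields `s` (dimensionless
#'   strain, NA where masked), `mask`, `window`, `method`.
#' @export
strain_leastsquares <- function(pd, window = c(8L, 8L), cap = 0.02) {
  stopifnot(inherits(pd, "phase_diff_map"))
  wz <- max(3L, as.integer(window[1]))
  wx <- as.integer(window[min(2L, length(window))])
  phi <- pd$phi
  phi[!pd$mask] <- NA_real_
  ## 1-D unwrapping along depth per A-scan (NA-tolerant)
  phi_u <- apply(phi, 2, function(col) {
    ok <- !is.na(col)
    if (sum(ok) >= 2) col[ok] <- signal::unwrap(col[ok])
    col
  })
  if (is.null(dim(phi_u))) phi_u <- matrix(phi_u, nrow = nrow(phi))
  ws <- .window_slope(phi_u, wz)
  nbar <- if (length(pd$n) == 1L) pd$n else matrix(pd$n, nrow(phi), ncol(phi))
  lambda_um <- pd$lambda0_nm / 1000
  s <- -lambda_um / (4 * pi * nbar) * ws$slope / pd$pitch_axial_um
  s <- .lateral_mean(s, wx)
  mask <- is.finite(s) & ws$count >= pmax(3, wz / 2)
  .strain_map(s, mask, c(wz, wx), "leastsquares",
              pd$pitch_axial_um, pd$pitch_lateral_um, cap)
}

## complex running mean along columns / rows built from .runsum
.ax_cavg <- function(z, w) {
  re <- apply(Re(z), 2, .runsum, w = w)
  im <- apply(Im(z), 2, .runsum, w = w)
  out <- complex(real = re, imaginary = im)
  dim(out) <- dim(z)
  out
}
.lat_cavg <- function(z, w) {
  if (w <= 1L) return(z)
  re <- t(apply(Re(z), 1, .runsum, w = w))
  im <- t(apply(Im(z), 1, .runsum, w = w))
  out <- complex(real = re, imaginary = im)
  dim(out) <- dim(z)
  out
}

#' Incremental strain by the vector (complex-plane) method
#'
#' Estimates the axial phase-variation gradient without any phase
#' unwrapping, operating on complex quantities as vectors in the
#' complex plane until the very last step: (i) forms the interframe
#' product `b = a2 * Conj(a1)` and averages it laterally over the
#' window (independent speckles, suppressing speckle phase noise);
#' (ii) forms the axial lag-1 product `g(z) = B(z+1) * Conj(B(z))`,
#' whose argument is the local interpixel phase increment, and
#' normalizes it to unit magnitude so the subsequent averaging is an
#' unweighted phasor mean (amplitude weighting would bias the phase
#' gradient where neighbouring pixels share envelope-correlated
#' speckle); (iii) averages the normalized lag products over the
#' window and converts the argument of the mean to strain. Because
#' only local phase increments enter, wrapping of the total phase
#' variation across depth is irrelevant.
#'
#' @param frame1,frame2 [oct_frame()] objects on identical grids.
#' @param window Integer pair `c(axial, lateral)` averaging window in
#'   pixels (default `c(8, 8)`).
#' @param coherence_threshold Minimum mean resultant length of the
#'   normalized lag products in the window (0..1); estimates below it
#'   are masked (default 0.1).
#' @param amp_threshold Amplitude noise floor passed to the pixel mask.
#' @param cap Interframe strain validity bound (default 0.02).
#' @return Object of class `strain_map`.
#' @export
strain_vector <- function(frame1, frame2, window = c(8L, 8L),
                          coherence_threshold = 0.1, amp_threshold = 0,
                          cap = 0.02) {
  stopifnot(inherits(frame1, "oct_frame"), inherits(frame2, "oct_frame"))
  if (!.same_grid(frame1, frame2)) stop("frame grids/metadata do not match")
  wz <- max(2L, as.integer(window[1]))
  wx <- as.integer(window[min(2L, length(window))])
  b <- frame2$data * Conj(frame1$data)
  pix_ok <- Mod(frame1$data) > amp_threshold & Mod(frame2$data) > amp_threshold
  b[!pix_ok] <- 0 + 0i
  B <- .lat_cavg(b, wx)
  nz <- nrow(B)
  g <- B[2:nz, , drop = FALSE] * Conj(B[1:(nz - 1), , drop = FALSE])
  gm <- Mod(g)
  gn <- g
  nzero <- gm > 0 & is.finite(gm)
  gn[nzero] <- g[nzero] / gm[nzero]
  gn[!nzero] <- 0 + 0i
  gbar <- .lat_cavg(.ax_cavg(gn, wz), wx)
  count <- t(apply(apply(nzero * 1, 2, .runsum, w = wz), 1, .runsum, w = wx))
  coher <- Mod(gbar) / count
  nbar <- if (length(frame1$n) == 1L) frame1$n
          else matrix(frame1$n[2:nz], nz - 1L, ncol(b))
  lambda_um <- frame1$lambda0_nm / 1000
  s_core <- -lambda_um / (4 * pi * nbar) * Arg(gbar) / frame1$pitch_axial_um
  ## re-centre onto the frame grid (lag product lives between pixels)
  s <- matrix(NA_real_, nz, ncol(b))
  s[seq_len(nz - 1L), ] <- s_core
  mask <- matrix(FALSE, nz, ncol(b))
  mask[seq_len(nz - 1L), ] <- is.finite(s_core) & is.finite(coher) &
    coher >= coherence_threshold & count > 0
  .strain_map(s, mask, c(wz, wx), "vector",
              frame1$pitch_axial_um, frame1$pitch_lateral_um, cap)
}

#' Cumulative strain from a sequence of incremental strain maps
#'
#' Elementwise sum `S = sum_i s_i` over the compression series. A pixel
#' masked in more than half of the increments is masked in the result;
#' otherwise the sum runs over its valid increments.
#'
#' @param increments Non-empty list of `strain_map` objects on one grid.
#' @return Object of class `cumulative_strain_map`: fields `S`, `mask`,
#'   `n_increments`.
#' @export
accumulate_strain <- function(increments) {
  if (length(increments) == 0L) stop("empty increment sequence")
  stopifnot(all(vapply(increments, inherits, logical(1), "strain_map")))
  dims <- lapply(increments, function(m) dim(m$s))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("increments are not on a common grid")
  n <- length(increments)
  total <- Reduce(`+`, lapply(increments, function(m) ifelse(m$mask, m$s, 0)))
  masked_count <- Reduce(`+`, lapply(increments, function(m) (!m$mask) * 1))
  mask <- masked_count <= n / 2
  total[!mask] <- NA_real_
  structure(list(S = total, mask = mask, n_increments = n,
                 pitch_axial_um = increments[[1]]$pitch_axial_um,
                 pitch_lateral_um = increments[[1]]$pitch_lateral_um),
            class = "cumulative_strain_map")
}
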