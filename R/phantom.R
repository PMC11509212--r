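## Speckle-level synthetic OCT compression phantom.
##
## Forward model: discrete point scatterers summed coherently with a
## Gaussian axial coherence envelope; stepwise uniaxial compression
## displaces scatterers axially according to each layer's constitutive
## behaviour (exact subpixel encoding through the phase of the coherent
## sum); additive complex circular Gaussian noise at a stated SNR.
## The probe contacts the silicone top, which is the fixed reference
## plane: scatterers move toward the probe as the stack compresses.

#' Layer description for the compression phantom
#'
#' @param name Layer label.
#' @param thickness_um Layer thickness (micrometres).
#' @param model Either `list(type = "linear", E_kpa = <modulus>)` or
#'   `list(type = "crack_closure", params = constitutive_params(...))`.
#' @param n Refractive index.
#' @param scatterer_density Scatterers per 100 square micrometres of
#'   B-scan area (default 10, roughly ten per coherence cell, which
#'   makes the coherent sum circular Gaussian and the speckle fully
#'   developed).
#' @param reflectivity Mean scatterer amplitude (arbitrary units).
#' @return A `phantom_layer` list.
#' @export
phantom_layer <- function(name, thickness_um, model, n = 1.4,
                          scatterer_density = 10, reflectivity = 1) {
  stopifnot(thickness_um > 0, scatterer_density > 0, reflectivity >= 0, n >= 1)
  type <- model$type
  if (identical(type, "linear")) {
    stopifnot(is.numeric(model$E_kpa), model$E_kpa > 0)
  } else if (identical(type, "crack_closure")) {
    stopifnot(inherits(model$params, "constitutive_params"))
  } else stop("model$type must be 'linear' or 'crack_closure'")
  structure(list(name = name, thickness_um = thickness_um, model = model,
                 n = n, scatterer_density = scatterer_density,
                 reflectivity = reflectivity),
            class = "phantom_layer")
}

#' Phantom specification
#'
#' Bundles the layer stack (top to bottom), the imaging model and the
#' stepwise compression protocol. With a fixed `seed` the generated
#' frame sequence is byte-identical across runs.
#'
#' @param layers List of [phantom_layer()] objects, top first (the
#'   first layer is normally the reference silicone).
#' @param n_steps Number of compression steps (`>= 2`).
#' @param total_stress_kpa Total applied stress after the last step.
#' @param lambda0_nm Central wavelength (nm), default 1300.
#' @param pitch_axial_um,pitch_lateral_um Pixel pitches (micrometres),
#'   defaults 5 and 10.
#' @param envelope_fwhm_um FWHM of the Gaussian axial coherence
#'   envelope (micrometres), default 10.
#' @param snr_db Signal-to-noise ratio (dB); `Inf` for noiseless.
#' @param n_x Number of lateral pixels, default 64.
#' @param n_z Number of axial pixels; default covers the stack plus a
#'   small margin.
#' @param seed Integer RNG seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(layers, n_steps = 20L, total_stress_kpa = 20,
                         lambda0_nm = 1300, pitch_axial_um = 5,
                         pitch_lateral_um = 10, envelope_fwhm_um = 10,
                         snr_db = 30, n_x = 64L, n_z = NULL,
                         seed = 1L) {
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, logical(1), "phantom_layer")))
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop("need at least 2 compression steps")
  stopifnot(total_stress_kpa > 0, lambda0_nm > 0, pitch_axial_um > 0,
            pitch_lateral_um > 0, envelope_fwhm_um > 0, n_x >= 1)
  total_um <- sum(vapply(layers, `[[`, numeric(1), "thickness_um"))
  if (is.null(n_z)) n_z <- as.integer(ceiling(total_um / pitch_axial_um)) + 6L
  structure(list(layers = layers, n_steps = n_steps,
                 total_stress_kpa = total_stress_kpa,
                 lambda0_nm = lambda0_nm,
                 pitch_axial_um = pitch_axial_um,
                 pitch_lateral_um = pitch_lateral_um,
                 envelope_fwhm_um = envelope_fwhm_um,
                 snr_db = snr_db, n_x = as.integer(n_x),
                 n_z = as.integer(n_z), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default two-layer compression phantom
#'
#' A 200 um reference silicone (linear, 100 kPa) over 400 um of tissue
#' following the crack-closure law with `Em = 300` kPa, `B = 4` kPa,
#' `vt = 0.05`; 20 steps to 20 kPa at 30 dB SNR. The thin silicone and
#' shallow tissue keep interframe displacements well inside the
#' coherence envelope over the whole protocol, as in practical C-OCE
#' where the reference layer is thin and analysis stays near the
#' surface.
#'
#' @param ... Overrides passed to [phantom_spec()].
#' @param tissue_params Tissue [constitutive_params()].
#' @param Esil_kpa Silicone modulus (kPa).
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(...,
                                 tissue_params = constitutive_params(300, 4, 0.05),
                                 Esil_kpa = 100) {
  layers <- list(
    phantom_layer("silicone", 200, list(type = "linear", E_kpa = Esil_kpa)),
    phantom_layer("tissue", 400, list(type = "crack_closure",
                                      params = tissue_params)))
  phantom_spec(layers, ...)
}

## cumulative strain of one layer at stress sigma
.layer_strain <- function(layer, sigma) {
  if (identical(layer$model$type, "linear")) sigma / layer$model$E_kpa
  else strain_from_stress(layer$model$params, sigma)
}

## scatterer field: positions (depth um, lateral pixel), amplitudes,
## layer index. Deterministic given the RNG state.
.make_scatterers <- function(spec) {
  width_um <- spec$n_x * spec$pitch_lateral_um
  tops <- cumsum(c(0, vapply(spec$layers, `[[`, numeric(1), "thickness_um")))
  depth <- numeric(0); col <- integer(0); amp <- numeric(0); lay <- integer(0)
  for (l in seq_along(spec$layers)) {
    layer <- spec$layers[[l]]
    count <- max(1L, round(layer$scatterer_density *
                             layer$thickness_um * width_um / 100))
    d <- stats::runif(count, tops[l], tops[l + 1])
    x <- sample.int(spec$n_x, count, replace = TRUE)
    a <- rep(layer$reflectivity, count)
    depth <- c(depth, d); col <- c(col, x); amp <- c(amp, a)
    lay <- c(lay, rep(l, count))
  }
  list(depth = depth, col = col, amp = amp, layer = lay, layer_tops = tops)
}

## coherent sum of scatterers at displaced depths into a complex frame
.render_frame <- function(spec, depth_um, col, amp, n_of_scatterer) {
  sigma_env <- spec$envelope_fwhm_um / (2 * sqrt(2 * log(2)))
  K <- as.integer(ceiling(4 * sigma_env / spec$pitch_axial_um))
  nz <- spec$n_z; nx <- spec$n_x
  phase <- 4 * pi * n_of_scatterer * depth_um * 1000 / spec$lambda0_nm
  field <- amp * exp(1i * phase)
  p0 <- floor(depth_um / spec$pitch_axial_um) + 1L
  acc_re <- numeric(nz * nx)
  acc_im <- numeric(nz * nx)
  for (k in -K:K) {
    idx <- p0 + k
    keep <- idx >= 1L & idx <= nz
    if (!any(keep)) next
    centre <- (idx[keep] - 0.5) * spec$pitch_axial_um
    w <- exp(-(centre - depth_um[keep])^2 / (2 * sigma_env^2))
    v <- field[keep] * w
    lin <- idx[keep] + (col[keep] - 1L) * nz
    sums <- rowsum(cbind(Re(v), Im(v)), group = lin)
    where <- as.integer(rownames(sums))
    acc_re[where] <- acc_re[where] + sums[, 1]
    acc_im[where] <- acc_im[where] + sums[, 2]
  }
  matrix(complex(real = acc_re, imaginary = acc_im), nz, nx)
}

#' Generate a compression phantom frame sequence with ground truth
#'
#' Renders `n_steps + 1` complex B-scans (step 0 = uncompressed) of the
#' layer stack under stepwise uniaxial compression. Per step, the
#' applied stress rises by `total_stress_kpa / n_steps`; each layer's
#' cumulative strain follows its constitutive model exactly, and every
#' scatterer is displaced toward the probe by the accumulated
#' compression of the material above it. Cumulative strain `S` is
#' realized kinematically as a thickness scale factor `exp(-S)`: the
#' C-OCE summation convention accumulates fixed-pixel (Eulerian)
#' strain increments, whose sum is the logarithmic strain, so with
#' this scaling the summed estimates converge to the stated `S`
#' exactly rather than to `-log(1-S)`. Displacement is encoded
#' exactly (subpixel) through the coherent phase. Complex white noise
#' is added per frame at the specified SNR.
#'
#' @param spec A [phantom_spec()].
#' @return List with `frames` (list of [oct_frame()]) and `truth`, a
#'   ground-truth list holding per-step stress, per-layer incremental
#'   and cumulative strain, layer interface depths per step, the
#'   generating parameters, and decorrelation warnings for steps whose
#'   interframe strain exceeds 0.02 in any layer.
#' @export
make_frames <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  sc <- .make_scatterers(spec)
  n_of <- vapply(spec$layers, `[[`, numeric(1), "n")[sc$layer]
  thick <- vapply(spec$layers, `[[`, numeric(1), "thickness_um")
  nL <- length(spec$layers)
  sigma_steps <- seq(0, spec$total_stress_kpa, length.out = spec$n_steps + 1L)
  cum <- t(vapply(sigma_steps, function(sg)
    vapply(seq_len(nL), function(l) .layer_strain(spec$layers[[l]], sg),
           numeric(1)), numeric(nL)))
  cum <- matrix(cum, ncol = nL)
  inc <- apply(cum, 2, diff)
  inc <- matrix(inc, ncol = nL)
  warn_steps <- which(apply(abs(inc) > 0.02, 1, any))
  frames <- vector("list", spec$n_steps + 1L)
  interfaces <- matrix(0, spec$n_steps + 1L, nL + 1L)
  noise_sd <- NULL
  for (k in seq_len(spec$n_steps + 1L)) {
    S <- cum[k, ]
    tops_def <- cumsum(c(0, thick * exp(-S)))
    interfaces[k, ] <- tops_def
    rel <- sc$depth - sc$layer_tops[sc$layer]       # depth within own layer
    d_def <- tops_def[sc$layer] + rel * exp(-S[sc$layer])
    A <- .render_frame(spec, d_def, sc$col, sc$amp, n_of)
    if (is.finite(spec$snr_db)) {
      if (is.null(noise_sd)) {
        P <- mean(Mod(A)^2)
        noise_sd <- sqrt(P / 10^(spec$snr_db / 10) / 2)
      }
      A <- A + complex(real = stats::rnorm(length(A), sd = noise_sd),
                       imaginary = stats::rnorm(length(A), sd = noise_sd))
      dim(A) <- c(spec$n_z, spec$n_x)
    }
    frames[[k]] <- oct_frame(A, spec$pitch_axial_um, spec$pitch_lateral_um,
                             spec$lambda0_nm, spec$layers[[1]]$n)
  }
  truth <- list(stress_kpa = sigma_steps,
                cumulative_strain = cum,       # (n_steps+1) x layers
                incremental_strain = inc,      # n_steps x layers
                layer_names = vapply(spec$layers, `[[`, character(1), "name"),
                interfaces_um = interfaces,
                decorrelation_steps = warn_steps,
                spec = spec)
  list(frames = frames, truth = truth)
}

#' Phantom with an embedded crack-like defect
#'
#' Embeds a lens-shaped low-reflectivity void (a crack of diameter `D`
#' and opening `h`, aspect ratio `alpha = h/D`) in a linearly elastic
#' tissue layer of modulus `Em`. Under stress `sigma` the local opening
#' shrinks linearly, `h(sigma) = h0 * max(0, 1 - sigma/sigma_clos)`
#' with `sigma_clos = alpha * Em`, so the defect closes completely at
#' the rule-of-thumb closing stress while the surrounding matrix
#' strains linearly. Material below the crack additionally moves toward
#' the probe by the closed part of the local opening.
#'
#' @param spec A [phantom_spec()] whose last layer is the (linear)
#'   tissue hosting the crack.
#' @param crack A [pore_geometry()].
#' @param centre_um `c(depth, lateral)` crack centre in micrometres
#'   (depth from the sample top surface).
#' @return As [make_frames()], with `truth$crack` holding per-step
#'   opening (um) and the closing stress/strain.
#' @export
make_crack_phantom <- function(spec, crack, centre_um) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(crack, "pore_geometry"))
  tissue_idx <- length(spec$layers)
  tissue <- spec$layers[[tissue_idx]]
  if (!identical(tissue$model$type, "linear"))
    stop("the crack-hosting tissue layer must be linear (matrix modulus Em)")
  tops <- cumsum(c(0, vapply(spec$layers, `[[`, numeric(1), "thickness_um")))
  if (centre_um[1] - crack$h / 2 < tops[tissue_idx] ||
      centre_um[1] + crack$h / 2 > tops[tissue_idx + 1L])
    stop("crack does not fit inside the tissue layer")
  Em <- tissue$model$E_kpa
  sigma_clos <- closing_stress(crack$alpha, Em)

  set.seed(spec$seed)
  sc <- .make_scatterers(spec)
  x_um <- (sc$col - 0.5) * spec$pitch_lateral_um
  dx <- x_um - centre_um[2]
  in_lat <- abs(dx) < crack$D / 2
  h_local <- ifelse(in_lat, crack$h * sqrt(pmax(1 - (2 * dx / crack$D)^2, 0)), 0)
  in_void <- in_lat & abs(sc$depth - centre_um[1]) < h_local / 2
  keep <- !in_void
  sc <- list(depth = sc$depth[keep], col = sc$col[keep], amp = sc$amp[keep],
             layer = sc$layer[keep], layer_tops = sc$layer_tops)
  h_local <- h_local[keep]
  below <- sc$depth > centre_um[1]

  n_of <- vapply(spec$layers, `[[`, numeric(1), "n")[sc$layer]
  thick <- vapply(spec$layers, `[[`, numeric(1), "thickness_um")
  nL <- length(spec$layers)
  sigma_steps <- seq(0, spec$total_stress_kpa, length.out = spec$n_steps + 1L)
  cum <- t(vapply(sigma_steps, function(sg)
    vapply(seq_len(nL), function(l) .layer_strain(spec$layers[[l]], sg),
           numeric(1)), numeric(nL)))
  cum <- matrix(cum, ncol = nL)
  frames <- vector("list", spec$n_steps + 1L)
  opening <- numeric(spec$n_steps + 1L)
  noise_sd <- NULL
  for (k in seq_len(spec$n_steps + 1L)) {
    S <- cum[k, ]
    sg <- sigma_steps[k]
    closure_frac <- min(sg / sigma_clos, 1)
    opening[k] <- crack$h * (1 - closure_frac)
    tops_def <- cumsum(c(0, thick * exp(-S)))
    rel <- sc$depth - sc$layer_tops[sc$layer]
    d_def <- tops_def[sc$layer] + rel * exp(-S[sc$layer])
    d_def <- d_def - ifelse(below, h_local * closure_frac, 0)
    A <- .render_frame(spec, d_def, sc$col, sc$amp, n_of)
    if (is.finite(spec$snr_db)) {
      if (is.null(noise_sd)) {
        P <- mean(Mod(A)^2)
        noise_sd <- sqrt(P / 10^(spec$snr_db / 10) / 2)
      }
      A <- A + complex(real = stats::rnorm(length(A), sd = noise_sd),
                       imaginary = stats::rnorm(length(A), sd = noise_sd))
      dim(A) <- c(spec$n_z, spec$n_x)
    }
    frames[[k]] <- oct_frame(A, spec$pitch_axial_um, spec$pitch_lateral_um,
                             spec$lambda0_nm, spec$layers[[1]]$n)
  }
  truth <- list(stress_kpa = sigma_steps,
                cumulative_strain = cum,
                crack = list(geometry = crack,
                             closing_stress_kpa = sigma_clos,
                             closing_strain = closing_strain(crack$alpha),
                             opening_um = opening),
                spec = spec)
  list(frames = frames, truth = truth)
}

#' Fast stress-strain curve fixture (no speckle)
#'
#' Samples the crack-closure law directly on an even stress grid, with
#' optional multiplicative Gaussian strain noise; bypasses the speckle
#' forward model for Monte-Carlo fitting studies.
#'
#' @param params Generating [constitutive_params()].
#' @param sigma_max Maximum stress (kPa).
#' @param n_points Number of samples (`>= 10`), default 200.
#' @param noise_sd Multiplicative strain noise standard deviation
#'   (e.g. 0.01 for 1%), default 0.
#' @param seed Optional integer seed.
#' @return A [stress_strain_curve()].
#' @export
make_curve_samples <- function(params, sigma_max, n_points = 200L,
                               noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "constitutive_params"), sigma_max > 0)
  n_points <- as.integer(n_points)
  if (n_points < 10L) stop("need at least 10 points")
  if (!is.null(seed)) set.seed(seed)
  sigma <- seq(0, sigma_max, length.out = n_points)
  s <- strain_from_stress(params, sigma)
  if (noise_sd > 0) s <- s * (1 + stats::rnorm(n_points, sd = noise_sd))
  stress_strain_curve(s, sigma)
}
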