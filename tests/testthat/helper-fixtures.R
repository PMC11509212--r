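## Shared fixtures: generated in code, cached across tests in one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- maker()
  .fixture_cache[[key]]
}

## constant-amplitude frame pair with an exact linear phase ramp
## (phase step per pixel = -4 pi n s pitch / lambda, i.e. compressive
## strain s), plus optional additive complex noise at snr_db
ramp_frame_pair <- function(s, nz = 100, nx = 16, snr_db = Inf, seed = 1,
                            lambda0_nm = 1300, n = 1.4, pitch = 5) {
  set.seed(seed)
  phi1 <- matrix(stats::runif(nz * nx, -pi, pi), nz, nx)
  a1 <- exp(1i * phi1)
  step <- -4 * pi * n * s * pitch * 1000 / lambda0_nm
  ramp <- matrix(rep(step * (seq_len(nz) - 1), nx), nz, nx)
  a2 <- a1 * exp(1i * ramp)
  if (is.finite(snr_db)) {
    sd <- sqrt(1 / 10^(snr_db / 10) / 2)
    a1 <- a1 + complex(real = stats::rnorm(nz * nx, sd = sd),
                       imaginary = stats::rnorm(nz * nx, sd = sd))
    a2 <- a2 + complex(real = stats::rnorm(nz * nx, sd = sd),
                       imaginary = stats::rnorm(nz * nx, sd = sd))
    dim(a1) <- dim(a2) <- c(nz, nx)
  }
  list(f1 = oct_frame(a1, pitch, 10, lambda0_nm, n),
       f2 = oct_frame(a2, pitch, 10, lambda0_nm, n))
}

## default two-layer speckle phantom ROIs (200 um silicone / 400 um
## tissue at 5 um pitch). Rows stay clear of the silicone-tissue
## interface, which migrates from 200 um to ~164 um over a 20% silicone
## compression: estimation windows must not straddle it.
sil_roi <- function(cols = 9:24) list(rows = 8:24, cols = cols)
tis_roi <- function(cols = 9:24) list(rows = 46:80, cols = cols)

## frames -> cumulative strain series via the vector method
strain_series <- function(frames, window = c(8L, 8L)) {
  n <- length(frames) - 1L
  incs <- lapply(seq_len(n), function(i)
    suppressWarnings(strain_vector(frames[[i]], frames[[i + 1L]],
                                   window = window)))
  lapply(seq_len(n), function(k) accumulate_strain(incs[seq_len(k)]))
}

## full speckle pipeline: phantom spec -> fitted parameters
recover_params <- function(spec, cols = 9:24) {
  gen <- make_frames(spec)
  series <- strain_series(gen$frames, window = c(8L, 12L))
  cal <- silicone_calibration(100, roi = sil_roi(cols))
  crv <- build_curve(series, tis_roi(cols), sil_roi(cols), cal)
  suppressWarnings(fit_constitutive(crv))
}

## synthetic cumulative-strain map (no speckle), silicone rows on top
synthetic_series <- function(tissue_S_fun, sigmas, nz = 60, nx = 32,
                             sil_rows = 1:20, Esil = 100) {
  lapply(sigmas, function(sg) {
    S <- matrix(0, nz, nx)
    for (j in seq_len(nx)) S[, j] <- tissue_S_fun(sg, j)
    S[sil_rows, ] <- sg / Esil
    structure(list(S = S, mask = matrix(TRUE, nz, nx), n_increments = 1L,
                   pitch_axial_um = 5, pitch_lateral_um = 10),
              class = "cumulative_strain_map")
  })
}

rel_err <- function(est, true) abs(est / true - 1)
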