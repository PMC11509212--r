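test_that("silicone stress conversion is exactly linear", {
  cal <- silicone_calibration(100)
  expect_equal(stress_from_silicone(0.05, cal), 5)
  expect_equal(stress_from_silicone(0, cal), 0)
  S <- c(0.01, 0.2, 0.33)
  expect_equal(stress_from_silicone(S[1] + S[2], cal),
               stress_from_silicone(S[1], cal) + stress_from_silicone(S[2], cal))
  expect_equal(stress_from_silicone(3 * S, cal), 3 * stress_from_silicone(S, cal))
  expect_error(silicone_calibration(-5))
})

test_that("sandwich of contrasting linear layers keeps strains proportional", {
  # moduli ratio 10; the softer layer reaches ~40% cumulative strain
  gen <- cached("sandwich", function() {
    layers <- list(
      phantom_layer("stiff", 200, list(type = "linear", E_kpa = 1000)),
      phantom_layer("soft", 300, list(type = "linear", E_kpa = 100)))
    make_frames(phantom_spec(layers, n_steps = 60, total_stress_kpa = 40,
                             snr_db = Inf, n_x = 16, seed = 21))
  })
  series <- strain_series(gen$frames)
  stiff_roi <- list(rows = 10:28, cols = 5:12)
  soft_roi <- list(rows = 50:70, cols = 5:12)
  S_stiff <- vapply(series, function(m)
    mean(m$S[stiff_roi$rows, stiff_roi$cols], na.rm = TRUE), numeric(1))
  S_soft <- vapply(series, function(m)
    mean(m$S[soft_roi$rows, soft_roi$cols], na.rm = TRUE), numeric(1))
  expect_gt(max(S_soft), 0.35)
  slope <- stats::coef(stats::lm(S_soft ~ S_stiff))[[2]]
  expect_equal(slope, 10, tolerance = 0.03)
})

test_that("build_curve reproduces the generating law on a noiseless phantom", {
  gen <- cached("default_noiseless", function()
    make_frames(default_phantom_spec(n_steps = 20, total_stress_kpa = 20,
                                     snr_db = Inf, n_x = 32, seed = 7)))
  series <- strain_series(gen$frames)
  cal <- silicone_calibration(100, roi = sil_roi())
  crv <- build_curve(series, tis_roi(), sil_roi(), cal)
  expect_identical(crv$data$strain[1], 0)
  expect_identical(crv$data$stress_kpa[1], 0)
  expect_gte(nrow(crv$data), 21)
  p <- constitutive_params(300, 4, 0.05)
  pred <- strain_from_stress(p, crv$data$stress_kpa)
  rms <- sqrt(mean((crv$data$strain - pred)^2)) / max(pred)
  expect_lt(rms, 0.02)
  # ROI pixel arithmetic
  expect_equal(roi_pixels(90, 10), 9L)
  expect_equal(roi_pixels(90, 5), 18L)
})

test_that("fit recovers printed cornea parameters and degenerate limits", {
  # noiseless synthesis and refit of the nonheated-cornea triple
  z1 <- constitutive_params(736, 4.1, 0.026)
  fit <- fit_constitutive(make_curve_samples(z1, 25, 200))
  expect_lt(rel_err(fit$params$Em, 736), 1e-3)
  expect_lt(rel_err(fit$params$B, 4.1), 1e-3)
  expect_lt(rel_err(fit$params$vt, 0.026), 1e-3)
  expect_true(fit$converged)
  expect_lt(fit$residual_rms, 1e-8)
  # purely linear curve: vt -> 0, Em exact
  lin <- stress_strain_curve(seq(0, 20, length.out = 50) / 400,
                             seq(0, 20, length.out = 50))
  lfit <- suppressWarnings(fit_constitutive(lin))
  expect_lt(rel_err(lfit$params$Em, 400), 1e-3)
  expect_lt(lfit$params$vt, 1e-3)
  # contract checks
  expect_error(fit_constitutive(stress_strain_curve(c(0, 1e-3), c(0, 5))),
               "10")
  expect_error(fit_constitutive(
    make_curve_samples(z1, 1, 20)), "2 kPa")
})

test_that("fit tolerates 1% strain noise with small median Em error", {
  z1 <- constitutive_params(736, 4.1, 0.026)
  errs <- vapply(1:10, function(seed) {
    crv <- make_curve_samples(z1, 25, 200, noise_sd = 0.01, seed = seed)
    rel_err(suppressWarnings(fit_constitutive(crv))$params$Em, 736)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.02)
})

test_that("derived curves regenerate bit-identically from the parameters", {
  p <- constitutive_params(300, 4, 0.05)
  fit <- fit_constitutive(make_curve_samples(p, 20, 60))
  dc <- derived_curves(fit)
  grid <- dc$Eeff_sigma$stress_kpa
  expect_identical(dc$Eeff_sigma$Eeff_kpa, tangent_modulus(fit$params, grid))
  expect_identical(dc$beta_sigma$beta, nonlinearity_beta(fit$params, grid))
  expect_identical(dc$Eeff_strain$strain, strain_from_stress(fit$params, grid))
  # density mode at sigma = B
  expect_equal(grid[which.max(dc$density_sigma$density)], fit$params$B,
               tolerance = 0.05 * fit$params$B)
  # beta peak closed form
  expect_equal(max(dc$beta_sigma$beta), fit$params$Em / (4 * fit$params$B),
               tolerance = 1e-3)
  # vt = 0: everything flat
  d0 <- derived_curves(constitutive_params(250, 3, 0), seq(0, 10, 0.1))
  expect_true(all(d0$beta_sigma$beta == 0))
  expect_true(all(d0$density_sigma$density == 0))
  expect_true(all(d0$Eeff_sigma$Eeff_kpa == 250))
})

test_that("standardized modulus maps are uniform for homogeneous phantoms", {
  p <- constitutive_params(300, 4, 0.05)
  sigmas <- seq(1, 20, 1)
  series <- synthetic_series(function(sg, j) strain_from_stress(p, sg), sigmas)
  cal <- silicone_calibration(100, roi = list(rows = 1:20, cols = 1:32))
  map <- standardized_modulus_map(series, cal, sigma_std = 4,
                                  tissue_rows = c(21, 60),
                                  tissue_cols = c(1, 32), window_px = 8)
  expect_true(all(map$mask))
  expect_lt(max(abs(map$Eeff / tangent_modulus(p, 4) - 1)), 0.03)
  expect_error(standardized_modulus_map(series, cal, sigma_std = 100,
                                        tissue_rows = c(21, 60),
                                        tissue_cols = c(1, 32)),
               "exceeds")
  # strongly nonlinear phantom with small B: sigma_std = 10B reaches the
  # Em map, and the low/high-stress maps differ by the closure factor
  p2 <- constitutive_params(300, 1, 0.05)
  series2 <- synthetic_series(function(sg, j) strain_from_stress(p2, sg),
                              seq(0.5, 20, 0.5))
  map_hi <- standardized_modulus_map(series2, cal, sigma_std = 10 * p2$B,
                                     tissue_rows = c(21, 60),
                                     tissue_cols = c(1, 32), window_px = 8)
  expect_lt(max(abs(map_hi$Eeff / p2$Em - 1)), 0.03)
  map_lo <- standardized_modulus_map(series2, cal, sigma_std = 0,
                                     tissue_rows = c(21, 60),
                                     tissue_cols = c(1, 32), window_px = 8)
  expect_equal(mean(map_hi$Eeff) / mean(map_lo$Eeff),
               1 + p2$vt * p2$Em / p2$B, tolerance = 0.05)
})

test_that("two-region phantoms map to the correct modulus contrast", {
  # Em 300 vs 900, same B and vt, evaluated at sigma_std >> B
  pL <- constitutive_params(300, 0.4, 0.05)
  pR <- constitutive_params(900, 0.4, 0.05)
  sigmas <- seq(1, 20, 1)
  series <- synthetic_series(function(sg, j)
    if (j <= 16) strain_from_stress(pL, sg) else strain_from_stress(pR, sg),
    sigmas)
  cal <- silicone_calibration(100, roi = list(rows = 1:20, cols = 1:32))
  map <- standardized_modulus_map(series, cal, sigma_std = 4,
                                  tissue_rows = c(21, 60),
                                  tissue_cols = c(1, 32), window_px = 8)
  left <- mean(map$Eeff[, 1:2]); right <- mean(map$Eeff[, 3:4])
  expect_equal(right / left, 3, tolerance = 0.05)
})

test_that("gate classification resolves priorities and rejects bad gates", {
  gates <- data.frame(label = c("tumor", "stroma"),
                      Eeff_min = c(200, 0), Eeff_max = c(1000, 500),
                      beta_min = c(0, 0), beta_max = c(50, 50))
  pts <- data.frame(Eeff_kpa = c(300, 100, 2000), beta = c(5, 5, 5))
  expect_equal(gate_classify(pts, gates),
               c("tumor", "stroma", "unclassified"))
  # overlap resolved by order: point (300, 5) is inside both
  expect_equal(gate_classify(pts, gates[2:1, ])[1], "stroma")
  expect_error(gate_classify(pts, gates[, -1]), "malformed")
  bad <- gates; bad$Eeff_min[1] <- 2000
  expect_error(gate_classify(pts, bad), "malformed")
})

test_that("end-to-end phantom recovery holds for random parameter triples", {
  set.seed(42)
  for (i in 1:10) {
    Em <- stats::runif(1, 200, 600)
    B <- stats::runif(1, 2, 6)
    vt <- stats::runif(1, 0.02, 0.06)
    p <- constitutive_params(Em, B, vt)
    snr <- if (i %% 2 == 0) 25 else Inf
    tol <- if (is.finite(snr)) 0.10 else 0.05
    spec <- default_phantom_spec(n_steps = 30, total_stress_kpa = 20,
                                 snr_db = snr, n_x = 48, seed = 100 + i,
                                 tissue_params = p)
    fit <- recover_params(spec, cols = 7:42)
    expect_lt(rel_err(fit$params$Em, Em), tol)
    expect_lt(rel_err(fit$params$B, B), tol)
    expect_lt(rel_err(fit$params$vt, vt), tol)
  }
})
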