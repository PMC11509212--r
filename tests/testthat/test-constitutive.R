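test_that("stress-strain law matches hand-evaluated values and limits", {
  # linear limit: no pores
  p0 <- constitutive_params(200, 1, 0)
  expect_equal(strain_from_stress(p0, 20), 0.1)
  # zero stress gives zero strain for any parameters
  p <- constitutive_params(100, 2, 0.05)
  expect_identical(strain_from_stress(p, 0), 0)
  # direct evaluation of the closed form
  expect_equal(strain_from_stress(p, 2), 0.02 + 0.05 * (1 - exp(-1)))
  # asymptote: s -> sigma/Em + vt
  expect_equal(strain_from_stress(p, 1e5), 1e5 / 100 + 0.05, tolerance = 1e-9)
  expect_error(strain_from_stress(p, -1), "non-negative")
  expect_error(constitutive_params(-1, 1, 0.1))
  expect_error(constitutive_params(100, 1, 1))
})

test_that("tangent modulus is the derivative of the law and has correct limits", {
  expect_equal(tangent_modulus(constitutive_params(123, 5, 0), c(0, 3, 100)),
               rep(123, 3))
  p <- constitutive_params(100, 5, 0.5)
  expect_equal(tangent_modulus(p, 1e6), 100)
  expect_equal(tangent_modulus(p, 0), 100 / (1 + 0.5 * 100 / 5))
  # finite-difference oracle at sigma = 3
  h <- 1e-4
  fd <- h * 2 / (strain_from_stress(p, 3 + h) - strain_from_stress(p, 3 - h))
  expect_equal(tangent_modulus(p, 3), fd, tolerance = 1e-6)
  expect_error(tangent_modulus(p, -0.1), "non-negative")
})

test_that("nonlinearity parameter peaks at Em/(4B) when vt*Em/B > 1", {
  expect_equal(nonlinearity_beta(constitutive_params(100, 5, 0), c(0, 2)),
               c(0, 0))
  p <- constitutive_params(100, 5, 0.5)
  expect_true(has_beta_peak(p))
  grid <- seq(0, 60, length.out = 20001)
  b <- nonlinearity_beta(p, grid)
  expect_equal(max(b), 100 / (4 * 5), tolerance = 1e-6)
  expect_equal(grid[which.max(b)], 5 * log(10), tolerance = 1e-3)
  # finite-difference of the tangent modulus
  h <- 1e-4
  fd <- (tangent_modulus(p, 3 + h) - tangent_modulus(p, 3 - h)) / (2 * h)
  expect_equal(nonlinearity_beta(p, 3), fd, tolerance = 1e-5)
  # without a peak, beta decreases monotonically from sigma = 0
  q <- constitutive_params(100, 20, 0.1)   # vt*Em/B = 0.5
  expect_false(has_beta_peak(q))
  expect_true(all(diff(nonlinearity_beta(q, seq(0, 50, 0.5))) < 0))
})

test_that("bell distribution has mode at B and integrates to vt", {
  p <- constitutive_params(300, 4, 0.05)
  grid <- seq(0, 40 * p$B, length.out = 4000)
  d <- bell_distribution(p, grid)
  expect_identical(d$density[1], 0)
  expect_equal(grid[which.max(d$density)], p$B, tolerance = 2e-2)
  expect_equal(pracma::trapz(grid, d$density), p$vt, tolerance = 1e-3)
  expect_s3_class(d, "pore_distribution")
})

test_that("pore distribution constructor enforces normalization and shape", {
  g <- seq(0, 10, 0.1)
  dens <- g * exp(-g)
  expect_silent(pore_distribution(g, dens))
  expect_error(pore_distribution(g, dens, total_content = 2 * pracma::trapz(g, dens)),
               "0.5%")
  expect_error(pore_distribution(g, -dens), ">= 0")
  expect_error(pore_distribution(rev(g), dens), "increasing")
})

test_that("effective modulus from a distribution reproduces the closed form", {
  p <- constitutive_params(300, 4, 0.05)
  grid <- seq(0, 40 * p$B, length.out = 4000)
  d <- bell_distribution(p, grid)
  # no pores: Eeff = Em
  d0 <- bell_distribution(constitutive_params(300, 4, 0), grid)
  expect_equal(effective_modulus_from_distribution(d0, 300, c(0, 4)), c(300, 300))
  # quadrature vs closed-form tangent modulus at sigma = B
  expect_equal(effective_modulus_from_distribution(d, 300, 4),
               tangent_modulus(p, 4), tolerance = 5e-3)
  # identical pores: Em/Eeff = 1 + vt/compliance
  expect_equal(identical_pore_modulus_ratio(0.05, 0.04), 2.25)
  # narrow distribution around compliance 0.04 approximates identical pores
  cg <- seq(0.03, 0.05, length.out = 400)
  nd <- exp(-(cg - 0.04)^2 / (2 * 0.001^2))
  nd <- nd / pracma::trapz(cg, nd) * 0.05
  dn <- pore_distribution(cg, nd, axis = "compliance")
  expect_equal(300 / effective_modulus_from_distribution(dn, 300, 0),
               2.25, tolerance = 2e-3)
  # non-integrable density at zero axis value
  bad <- pore_distribution(seq(0, 1, 0.01), rep(1, 101), axis = "compliance")
  expect_error(effective_modulus_from_distribution(bad, 300, 0),
               "non-integrable")
})

test_that("average compliance inverts the identical-inclusion relation", {
  expect_equal(average_compliance(2, 0.05), 0.05)
  # characteristic aspect ratios land in the 1/30..1/20 band for
  # percent-level pore contents halving-plus the modulus
  expect_equal(average_compliance(2.5, 0.06), 0.04)
  expect_true(average_compliance(2.5, 0.06) >= 1 / 30 &&
                average_compliance(2.5, 0.06) <= 1 / 20)
  expect_error(average_compliance(0.9, 0.05), "no compliant-pore")
  # algebraic round trip
  set.seed(1)
  for (i in 1:20) {
    sc <- stats::runif(1, 0.01, 0.2); vt <- stats::runif(1, 0.005, 0.2)
    expect_equal(average_compliance(1 + vt / sc, vt), sc, tolerance = 1e-10)
  }
})

test_that("crack density rule and closure rules of thumb", {
  expect_equal(crack_density_modulus_ratio(0, 5), 1)
  expect_equal(crack_density_modulus_ratio(1 / 8, 2), 2)
  expect_error(crack_density_modulus_ratio(-1, 2))
  # worked pericardium example: alpha = 0.1, Em = 200 kPa
  expect_equal(closing_stress(0.1, 200), 20)
  expect_equal(closing_strain(0.1), 0.1)
  expect_equal(closing_stress(1e-9, 200), 2e-7)
  expect_error(closing_stress(1.2, 100), "thin crack")
  # pore_geometry ties the rules together
  g <- pore_geometry(D = 200, h = 20, Em = 200)
  expect_equal(g$alpha, 0.1)
  expect_equal(g$closing_stress_kpa, 20)
  expect_equal(g$closing_strain, 0.1)
  expect_equal(g$compliance, g$alpha)
  expect_warning(pore_geometry(D = 10, h = 4, Em = 100), "0.3")
  expect_error(pore_geometry(D = 10, h = 20, Em = 100), "thin")
})

test_that("distribution reconstruction inverts the modulus curve", {
  # constant modulus -> zero density
  sg <- seq(0.5, 20, length.out = 100)
  rec0 <- reconstruct_distribution(sg, rep(250, 100))
  expect_lt(max(abs(rec0$density)), 1e-12)
  # samples of the closed-form modulus recover the bell density
  p <- constitutive_params(300, 4, 0.05)
  sg <- seq(0.01, 30, length.out = 400)
  rec <- reconstruct_distribution(sg, tangent_modulus(p, sg))
  truth <- (p$vt / p$B^2) * sg * exp(-sg / p$B)
  win <- sg >= 0.5 * p$B & sg <= 5 * p$B
  rms <- sqrt(mean((rec$density[win] - truth[win])^2)) / max(truth)
  expect_lt(rms, 0.02)
  expect_equal(rec$total_content, p$vt, tolerance = 0.03)
  expect_error(reconstruct_distribution(1:4, rep(1, 4)), "5 samples")
})

test_that("round trip: distribution -> quadrature -> modulus, and back", {
  set.seed(7)
  for (i in 1:50) {
    Em <- stats::runif(1, 100, 1000)
    B <- stats::runif(1, 0.5, 10)
    vt <- stats::runif(1, 0.005, 0.15)
    p <- constitutive_params(Em, B, vt)
    grid <- seq(0, 40 * B, length.out = 3000)
    d <- bell_distribution(p, grid)
    sig <- c(0.5 * B, B, 3 * B)
    expect_equal(effective_modulus_from_distribution(d, Em, sig),
                 tangent_modulus(p, sig), tolerance = 5e-3)
  }
  # inverse direction on a few triples
  for (i in 1:5) {
    Em <- stats::runif(1, 100, 800); B <- stats::runif(1, 1, 8)
    vt <- stats::runif(1, 0.01, 0.1)
    p <- constitutive_params(Em, B, vt)
    sg <- seq(0.01, 8 * B, length.out = 400)
    rec <- reconstruct_distribution(sg, tangent_modulus(p, sg))
    truth <- (vt / B^2) * sg * exp(-sg / B)
    win <- sg >= 0.5 * B & sg <= 5 * B
    expect_lt(sqrt(mean((rec$density[win] - truth[win])^2)) / max(truth), 0.02)
  }
})

test_that("monotonicity and peak law hold on random parameter triples", {
  set.seed(11)
  sig <- seq(0, 50, length.out = 400)
  for (i in 1:50) {
    p <- constitutive_params(stats::runif(1, 50, 1000),
                             stats::runif(1, 0.5, 10),
                             stats::runif(1, 0.001, 0.3))
    expect_true(all(diff(strain_from_stress(p, sig)) > 0))
    expect_true(all(diff(tangent_modulus(p, sig)) >= 0))
    expect_true(all(nonlinearity_beta(p, sig) >= 0))
  }
  # peak law on triples constrained to vt*Em/B > 1
  n_checked <- 0
  while (n_checked < 50) {
    Em <- stats::runif(1, 100, 1000); B <- stats::runif(1, 0.5, 8)
    vt <- stats::runif(1, 0.01, 0.3)
    if (vt * Em / B <= 1.05) next
    n_checked <- n_checked + 1
    p <- constitutive_params(Em, B, vt)
    grid <- seq(0, B * log(vt * Em / B) * 3 + 5 * B, length.out = 40001)
    b <- nonlinearity_beta(p, grid)
    expect_equal(max(b), Em / (4 * B), tolerance = 1e-3)
    expect_equal(grid[which.max(b)], B * log(vt * Em / B), tolerance = 1e-3)
  }
})
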