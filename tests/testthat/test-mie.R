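# Single-sphere Mie optics: amplitudes, scattering elements, phase function.

test_that("forward amplitudes are equal and inputs are validated", {
  for (r in c(10, 100, 350)) {
    amp <- mie_amplitudes(sphere_spec(r), c(0, pi / 4, pi))
    expect_equal(amp$S1[1], amp$S2[1])
  }
  expect_error(sphere_spec(-5), "positive")
  expect_error(mie_amplitudes(sphere_spec(100), c(-0.1, 0.5)), "\\[0, pi\\]")
  expect_error(mie_amplitudes(spec_for_x(3e4, 1.2), c(0, 1)), "max_terms")
})

test_that("amplitudes match an independent Bessel-function oracle", {
  # frozen spot values for the 100 nm soybean-oil sphere (x = 1.3206,
  # m = 1.46/1.33), independently verified against a second external
  # implementation of the series
  amp <- mie_amplitudes(sphere_spec(100, 632.8, 1.46, 1.33), c(0, pi / 2, pi))
  expect_equal(amp$S1[1], 0.008286695733182659 - 0.15387548637768564i,
               tolerance = 1e-10)
  expect_equal(amp$S1[2], 0.00778490004679034 - 0.1055320796503119i,
               tolerance = 1e-10)
  expect_equal(amp$S2[2], 0.00016920833581863823 - 0.0021108001312872718i,
               tolerance = 1e-10)
  expect_equal(amp$S2[3], -0.007290347355994352 + 0.06832865635861649i,
               tolerance = 1e-10)
  # oracle equivalence across the size-parameter range
  th <- seq(0, pi, length.out = 37)
  for (x in c(0.1, 1, 5, 20)) {
    sp <- spec_for_x(x, 1.2)
    amp <- mie_amplitudes(sp, th)
    orc <- oracle_mie_amplitudes(sp$x, 1.2, th)
    expect_lt(max(abs(Mod(amp$S1) - Mod(orc$S1)) / Mod(orc$S1)), 1e-8)
    expect_lt(max(abs(Mod(amp$S2) - Mod(orc$S2)) / Mod(orc$S2)), 1e-8)
  }
})

test_that("scattering elements satisfy the pure-Mueller identity and limits", {
  th <- seq(0, pi, length.out = 721)
  for (r in c(10, 60, 150, 350)) {
    el <- scattering_elements(mie_amplitudes(sphere_spec(r), th))
    expect_true(all(el$s11 >= 0))
    expect_true(all(abs(el$s12) <= el$s11 * (1 + 1e-12)))
    rel <- abs(el$s11^2 - (el$s12^2 + el$s33^2 + el$s34^2)) / el$s11^2
    expect_lt(max(rel), 1e-9)
    # forward row: equal amplitudes leave no linear or circular coupling
    expect_equal(el$s12[1], 0, tolerance = 1e-12 * el$s11[1])
    expect_equal(el$s34[1], 0, tolerance = 1e-12 * el$s11[1])
  }
})

test_that("Rayleigh limit reproduces the dipole polarization pattern", {
  sp <- spec_for_x(0.01, 1.1 / 1.33)
  el <- scattering_elements(mie_amplitudes(sp, seq(0, pi, length.out = 181)))
  dlp <- -el$s12 / el$s11
  expect_lt(max(abs(dlp - sin(el$theta)^2 / (1 + cos(el$theta)^2))), 1e-3)
  expect_lt(abs(el$g), 1e-3)
  expect_equal(dlp[91], 1, tolerance = 1e-3)  # 90 degrees
})

test_that("anisotropy from quadrature is grid-converged", {
  for (r in c(50, 350)) {
    g1 <- scattering_elements(
      mie_amplitudes(sphere_spec(r), seq(0, pi, length.out = 1000)))$g
    g2 <- scattering_elements(
      mie_amplitudes(sphere_spec(r), seq(0, pi, length.out = 2000)))$g
    expect_lt(abs(g1 - g2), 1e-6)
  }
})

test_that("phase function follows the bivariate form", {
  el <- scattering_elements(mie_amplitudes(sphere_spec(120)))
  th <- c(0.3, 1.2, 2.7)
  # unpolarized: no psi dependence, value = s11
  for (psi in c(0, 1, 4)) {
    expect_equal(phase_function_value(el, th, psi, c(1, 0, 0, 0)),
                 stats::approx(el$theta, el$s11, xout = th)$y)
  }
  # azimuthal integral collapses to 2 pi s11 I for any polarization
  psi_grid <- seq(0, 2 * pi, length.out = 2001)[-2001]
  s <- stokes_vector(1, 0.4, -0.5, 0.3)
  for (t1 in th) {
    num <- mean(phase_function_value(el, t1, psi_grid, s)) * 2 * pi
    expect_equal(num, 2 * pi * stats::approx(el$theta, el$s11, xout = t1)$y,
                 tolerance = 1e-10)
  }
  # horizontal polarization: psi = 0 vs psi = pi/2 picks s11 +/- s12
  s11 <- stats::approx(el$theta, el$s11, xout = th)$y
  s12 <- stats::approx(el$theta, el$s12, xout = th)$y
  expect_equal(phase_function_value(el, th, 0, c(1, 1, 0, 0)), s11 + s12)
  expect_equal(phase_function_value(el, th, pi / 2, c(1, 1, 0, 0)), s11 - s12)
  # never negative for physical Stokes inputs
  set.seed(4)
  for (i in 1:50) {
    u <- stats::runif(3, -1, 1); u <- u / max(1, sqrt(sum(u^2)))
    p <- phase_function_value(el, stats::runif(1, 0, pi),
                              stats::runif(1, 0, 2 * pi - 1e-9),
                              c(1, u))
    expect_gte(p, 0)
  }
  expect_error(phase_function_value(el, 3.5, 0, c(1, 0, 0, 0)), "theta")
  expect_error(phase_function_value(el, 1, 7, c(1, 0, 0, 0)), "psi")
})

test_that("element tables round-trip through tabular text", {
  el <- scattering_elements(mie_amplitudes(sphere_spec(80),
                                           seq(0, pi, length.out = 91)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scattering_elements(el, path)
  df <- read.table(path, header = TRUE)
  expect_equal(df$s11, el$s11)
  expect_equal(df$s34, el$s34)
})
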