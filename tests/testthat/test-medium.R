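# Size distributions, per-event size sampling, bulk optical coefficients.

test_that("size distributions validate and normalise", {
  d <- size_distribution(c(10, 50, 100), c(2, 1, 1))
  expect_equal(sum(d$weights), 1)
  expect_error(size_distribution(c(50, 10), c(1, 1)), "increasing")
  expect_error(size_distribution(c(10, 50), c(-1, 2)), ">= 0")
  expect_error(size_distribution(c(10, 50), c(1, 1), mode = "monodisperse"),
               "exactly one")
  il <- il_size_distribution()
  expect_identical(il$mode, "polydisperse")
  # diameter support 20-700 nm resolved to radii
  expect_equal(range(il$radii_nm), c(10, 350))
})

test_that("monodisperse sampling always returns the single 200 nm size", {
  mono <- monodisperse_distribution(200)
  r <- sample_radius(mono, 1000)
  expect_true(all(2 * r == 200))  # diameter convention
  expect_true(all(r == mono$radii_nm))
})

test_that("polydisperse sampling stays in support and matches its weights", {
  il <- il_size_distribution()
  set.seed(101)
  r <- sample_radius(il, 1e6)
  expect_true(all(r >= 10 & r <= 350))
  counts <- table(factor(r, levels = il$radii_nm))
  expected <- 1e6 * il$weights
  sdev <- sqrt(1e6 * il$weights * (1 - il$weights))
  expect_true(all(abs(as.numeric(counts) - expected) <= 3 * sdev + 3))
})

test_that("reduced scattering follows (1 - g) mu_s with domain checks", {
  expect_equal(reduced_scattering(5, 0), 5)
  expect_equal(reduced_scattering(4, 0.75), 1)
  expect_error(reduced_scattering(4, 1), "g")
  expect_error(reduced_scattering(0, 0.5), "mu_s")
})

test_that("study media hit the five target reduced-scattering values", {
  media <- study_media()
  expect_named(media, paste0("mus_prime=", c(0.5, 1, 1.5, 2, 3)))
  for (m in media) {
    expect_equal(reduced_scattering(m$mu_s, m$g), m$mu_s_prime, tolerance = 1e-12)
  }
  expect_equal(vapply(media, function(m) m$mu_s_prime, 0, USE.NAMES = FALSE),
               c(0.5, 1, 1.5, 2, 3))
})

test_that("Intralipid mapping scales linearly and matches the closed forms", {
  z <- il_optical_properties(0)
  expect_equal(z$mu_s, 0)
  m1 <- il_optical_properties(0.01)
  m2 <- il_optical_properties(0.02)
  expect_equal(m2$mu_s / m1$mu_s, 2, tolerance = 1e-12)
  # frozen hand evaluations of the adopted empirical forms at 632.8 nm
  expect_equal(m1$g, 0.732976, tolerance = 1e-12)
  expect_equal(m1$mu_s, 0.4798223279631372, tolerance = 1e-9)
  expect_equal(m1$mu_s_prime, reduced_scattering(m1$mu_s, m1$g))
  expect_error(il_optical_properties(-0.1), ">= 0")
})

test_that("distribution override files round-trip", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("radius_nm weight", "50 0.25", "150 0.75"), path)
  d <- read_size_distribution(path)
  expect_equal(d$radii_nm, c(50, 150))
  expect_equal(d$weights, c(0.25, 0.75))
})

test_that("cross-section weighting shifts the sampling toward large spheres", {
  num <- make_medium(mus_prime = 1, size_weighting = "number")
  xs <- make_medium(mus_prime = 1, size_weighting = "cross_section")
  mean_r_num <- sum(num$distribution$radii_nm * num$distribution$weights)
  mean_r_xs <- sum(xs$distribution$radii_nm * xs$distribution$weights)
  expect_gt(mean_r_xs, mean_r_num)
  expect_gt(xs$g, num$g)  # larger droplets scatter more forward
})

test_that("distribution-averaged anisotropy is stable under grid refinement", {
  m1 <- make_medium(mus_prime = 1.5, n_theta = 500L)
  m2 <- make_medium(mus_prime = 1.5, n_theta = 1000L)
  expect_equal(m1$g_eff, m2$g_eff, tolerance = 1e-5)
})
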