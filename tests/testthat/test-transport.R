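# Monte Carlo transport: launch, stepping, scattering updates, termination,
# detection, and whole-run invariants.

test_that("launch produces the horizontal pencil beam at the incidence angle", {
  g <- slab_geometry(5)
  p <- launch_photon(g)
  expect_equal(p$stokes, c(1, 1, 0, 0))
  expect_equal(p$pos, c(0, 0, 0))
  expect_equal(acos(p$dir[3]) * 180 / pi, 45, tolerance = 1e-12)
  expect_equal(sqrt(sum(p$dir^2)), 1, tolerance = 1e-12)
  # frame is right-handed with v in the incidence meridian
  expect_equal(qsense:::cross3(p$frame_v, p$frame_w), p$dir, tolerance = 1e-12)
  expect_equal(p$frame_v[2], 0)
  expect_identical(launch_photon(g), launch_photon(g))  # deterministic
})

test_that("free-path steps are exponential with mean 1/mu_t", {
  expect_error(sample_step(0, 0), "positive")
  set.seed(7)
  s <- sample_step(0.5, 1.5, n = 1e6)
  expect_true(all(s >= 0))
  expect_lt(abs(mean(s) - 0.5), 3 * 0.5 / sqrt(1e6))
  ks <- suppressWarnings(stats::ks.test(s, "pexp", 2))
  expect_gt(ks$p.value, 0.001)
})

test_that("propagation moves the photon by exactly s along its direction", {
  g <- slab_geometry(5)
  p <- launch_photon(g)
  expect_equal(propagate(p, 0)$pos, p$pos)
  p$dir <- c(0, 0, 1)
  expect_equal(propagate(p, 2)$pos[3], 2)
  set.seed(3)
  for (i in 1:10) {
    k <- stats::rnorm(3); k <- k / sqrt(sum(k^2))
    p$dir <- k
    s <- stats::runif(1, 0, 5)
    q <- propagate(p, s)
    expect_equal(sqrt(sum((q$pos - p$pos)^2)), s, tolerance = 1e-12)
  }
})

test_that("angle sampling is uniform in the isotropic unpolarized limit", {
  iso <- isotropic_elements()
  set.seed(11)
  draws <- t(replicate(4000, sample_scattering_angles(iso, c(1, 0, 0, 0))))
  expect_true(all(draws[, 1] >= 0 & draws[, 1] <= pi))
  expect_true(all(draws[, 2] >= 0 & draws[, 2] < 2 * pi))
  expect_gt(stats::ks.test(cos(draws[, 1]), "punif", -1, 1)$p.value, 0.001)
  expect_gt(stats::ks.test(draws[, 2], "punif", 0, 2 * pi)$p.value, 0.001)
})

test_that("angle sampling matches the quadrature density for polarized light", {
  el <- scattering_elements(mie_amplitudes(sphere_spec(150)))
  s0 <- c(1, 1, 0, 0)
  set.seed(21)
  n <- 2e4
  draws <- t(replicate(n, sample_scattering_angles(el, s0)))
  # 2-D histogram over cos(theta) x psi against cell probabilities from
  # direct quadrature of P(theta, psi) sin(theta)
  nb_mu <- 8L; nb_psi <- 6L
  mu_br <- seq(-1, 1, length.out = nb_mu + 1)
  psi_br <- seq(0, 2 * pi, length.out = nb_psi + 1)
  obs <- table(cut(cos(draws[, 1]), mu_br, include.lowest = TRUE),
               cut(draws[, 2], psi_br, include.lowest = TRUE))
  mu_f <- seq(-1 + 1e-9, 1 - 1e-9, length.out = 2000)
  psi_f <- seq(0, 2 * pi, length.out = 720)[-720]
  P <- outer(mu_f, psi_f, function(m, p)
    phase_function_value(el, acos(m), p, s0))
  cellp <- matrix(0, nb_mu, nb_psi)
  im <- findInterval(mu_f, mu_br, rightmost.closed = TRUE)
  ip <- findInterval(psi_f, psi_br, rightmost.closed = TRUE)
  for (a in seq_len(nb_mu)) for (b in seq_len(nb_psi))
    cellp[a, b] <- sum(P[im == a, ip == b])
  cellp <- cellp / sum(cellp)
  chi <- suppressWarnings(stats::chisq.test(as.vector(obs), p = as.vector(cellp)))
  expect_gt(chi$p.value, 0.001)
})

test_that("scatter updates preserve purity, norms and meridian invariants", {
  el <- scattering_elements(mie_amplitudes(sphere_spec(150)))
  g <- slab_geometry(5)
  # theta = 0, psi = 0: direction unchanged, Stokes renormalised only
  p <- launch_photon(g)
  q <- scatter_update(p, 0, 0, el)
  expect_equal(q$dir, p$dir, tolerance = 1e-12)
  expect_equal(q$n_events, 1L)
  expect_equal(q$stokes[1], p$weight)
  # random chains: unit direction, orthonormal frame, full polarization kept
  set.seed(31)
  p <- launch_photon(g)
  for (i in 1:200) {
    th <- stats::runif(1, 0, pi); ps <- stats::runif(1, 0, 2 * pi - 1e-9)
    p <- scatter_update(p, th, ps, el)
    expect_equal(sqrt(sum(p$dir^2)), 1, tolerance = 1e-9)
    dop <- sqrt(sum(p$stokes[2:4]^2)) / p$stokes[1]
    expect_equal(dop, 1, tolerance = 1e-9)
  }
  expect_equal(p$n_events, 200L)
  # a pure meridian rotation (frame change) preserves I, V and Q^2 + U^2
  s <- c(1, 0.3, -0.5, 0.2)
  for (gam in c(0.3, 1.1, 4)) {
    r <- qsense:::rotate_stokes_frame(s, gam)
    expect_equal(r[1], s[1])
    expect_equal(r[4], s[4])
    expect_equal(r[2]^2 + r[3]^2, s[2]^2 + s[3]^2, tolerance = 1e-12)
  }
  expect_error(scatter_update(p, 4, 0, el), "range")
})

test_that("termination rules classify depth, event cap and absorption", {
  g <- slab_geometry(2)
  med <- test_medium()
  p <- launch_photon(g)
  p$pos[3] <- 2 + 1e-9
  expect_identical(check_termination(p, g, med)$status, "transmitted")
  p <- launch_photon(g); p$pos[3] <- -1e-9
  expect_match(check_termination(p, g, med)$status, "^reflected")
  p <- launch_photon(g); p$pos[3] <- 1; p$n_events <- 1001L
  expect_identical(check_termination(p, g, med, event_cap = 1000L)$status,
                   "event_cap_killed")
  p$n_events <- 1000L
  expect_identical(check_termination(p, g, med, event_cap = 1000L)$status,
                   "alive")
  # mu_a = 0: the absorption draw can never kill
  set.seed(5)
  p <- launch_photon(g); p$pos[3] <- 1
  for (i in 1:50)
    expect_identical(check_termination(p, g, med, at_interaction = TRUE)$status,
                     "alive")
  # dead photons stay dead
  p$status <- "transmitted"; p$pos[3] <- -1
  expect_identical(check_termination(p, g, med)$status, "transmitted")
})

test_that("detection applies the radius and cone cuts and rotates the frame", {
  g <- slab_geometry(2)
  det <- detector_config(collect_radius_mm = 2, acceptance_deg = 30)
  p <- launch_photon(g)
  p$pos <- c(0, 0, -1e-12); p$dir <- c(0, 0, -1)
  p$frame_v <- c(-1, 0, 0); p$frame_w <- c(0, -1, 0)
  rec <- detect(p, det)
  expect_s3_class(rec, "detection_record")
  expect_lte(rec$exit_pos[3], 0)
  # exit beyond the collection radius -> rejected
  p2 <- p; p2$pos <- c(3, 0, -1e-12)
  expect_null(detect(p2, det))
  # exit outside the acceptance cone -> rejected
  p3 <- p; p3$dir <- c(sin(35 * pi / 180), 0, -cos(35 * pi / 180))
  expect_null(detect(p3, det))
  expect_error(detect(launch_photon(g), det), "top surface")
})

test_that("transport conserves photons and is seed-deterministic", {
  med <- test_medium()
  g <- slab_geometry(2)
  tr <- run_transport(med, g, 5000, seed = 77)
  expect_equal(sum(tr$tallies), 5000)
  tr2 <- run_transport(med, g, 5000, seed = 77)
  expect_identical(tr$detector_stokes, tr2$detector_stokes)
  expect_identical(tr$tallies, tr2$tallies)
  tr3 <- run_transport(med, g, 5000, seed = 78)
  expect_false(identical(tr$detector_stokes, tr3$detector_stokes))
})

test_that("detected photons stay fully polarized while the ensemble does not", {
  med <- test_medium()
  tr <- run_transport(med, slab_geometry(4), 2e4, seed = 13,
                      record_detections = TRUE)
  d <- tr$detections
  expect_gt(nrow(d), 100)
  dop <- sqrt(d$Q^2 + d$U^2 + d$V^2) / d$I
  expect_lt(max(abs(dop - 1)), 1e-9)
  ens <- degree_of_polarization(tr$detector_stokes)
  expect_lte(ens, 1)
  expect_lt(ens, 0.99)  # multiple scattering must depolarize the sum
  # bookkeeping identity: detected I equals the summed accepted weights
  expect_equal(tr$detector_stokes[1], tr$detected_weight_sum, tolerance = 1e-12)
  expect_equal(sum(d$I), tr$detector_stokes[1], tolerance = 1e-9)
})

test_that("ensemble depolarization grows with the number of events", {
  med <- test_medium()
  tr <- run_transport(med, slab_geometry(10), 1e5, seed = 9,
                      record_detections = TRUE)
  d <- tr$detections
  bins <- cut(d$n_events, c(0, 1, 2, 3, 5, 10, 20, 1000))
  agg <- aggregate(cbind(I, Q, U, V) ~ bins, data = d, FUN = sum)
  n_per <- as.numeric(table(bins)[as.character(agg$bins)])
  keep <- n_per >= 100
  dop <- sqrt(agg$Q^2 + agg$U^2 + agg$V^2)[keep] / agg$I[keep]
  ct <- suppressWarnings(
    stats::cor.test(seq_along(dop), dop, method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  expect_gt(dop[1], dop[length(dop)])
})

test_that("a near-transparent thin slab transmits essentially everything", {
  med <- test_medium()
  med$mu_s <- 1e-6
  med$mu_s_prime <- 1e-6 * (1 - med$g)
  tr <- run_transport(med, slab_geometry(1), 5000, seed = 3)
  expect_gt(tr$tallies[["transmitted"]] / 5000, 0.999)
  expect_lt(tr$detector_stokes[1], 5)
})

test_that("semi-infinite convergence: thick slabs agree within MC error", {
  med <- test_medium(1.5)
  tr10 <- run_transport(med, slab_geometry(10), 4e4, seed = 19)
  tr20 <- run_transport(med, slab_geometry(20), 4e4, seed = 23)
  q10 <- q_sense_result(tr10)
  q20 <- q_sense_result(tr20)
  se <- sqrt(q10$se_Q_prime^2 + q20$se_Q_prime^2)
  expect_lt(abs(q10$Q_prime - q20$Q_prime), 3 * se)
})

test_that("weighted-absorption mode agrees with binary death on average", {
  med <- test_medium(1.5)
  med$mu_a <- 0.05
  trb <- run_transport(med, slab_geometry(5), 4e4, seed = 41)
  trw <- run_transport(med, slab_geometry(5), 4e4, seed = 43,
                       absorption = "weighted")
  qb <- q_sense_result(trb)
  qw <- q_sense_result(trw)
  expect_gt(trb$tallies[["absorbed"]], 0)
  expect_equal(trw$tallies[["absorbed"]], 0)
  se <- sqrt(qb$se_Q_prime^2 + qw$se_Q_prime^2)
  expect_lt(abs(qb$Q_prime - qw$Q_prime), 4 * se)
})

test_that("fresnel boundary mode refracts, reflects and still conserves", {
  med <- test_medium(1.5)
  tr <- run_transport(med, slab_geometry(2), 5000, seed = 51,
                      boundary = "fresnel")
  expect_equal(sum(tr$tallies), 5000)
  expect_gt(tr$tallies[["specular_reflected"]], 0)
  expect_gt(tr$detector_stokes[1], 0)
})
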