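# R-level surface of the Monte Carlo transport: geometry and photon-state
# constructors, the individual transport operations as testable units, and
# run_transport() driving the compiled core.
#
# Coordinate convention: right-handed lab frame, depth axis z positive into
# the slab, top surface at z = 0; the incidence meridian is the lab x-z
# plane; "horizontal" launch polarization is the in-meridian axis, which
# projects onto the lab x-axis at the detector.

#' Slab geometry
#'
#' @param thickness_mm Slab thickness `d` (> 0); top surface at depth 0,
#'   bottom at `d`, laterally unbounded.
#' @param incidence_deg Beam polar angle from the surface normal, in the
#'   fixed x-z meridian. Default 45.
#' @return Object of class `slab_geometry`.
#' @export
slab_geometry <- function(thickness_mm, incidence_deg = 45) {
  if (thickness_mm <= 0) stop("'thickness_mm' must be positive")
  if (incidence_deg < 0 || incidence_deg >= 90)
    stop("'incidence_deg' must lie in [0, 90)")
  structure(list(thickness_mm = thickness_mm, incidence_deg = incidence_deg),
            class = "slab_geometry")
}

#' Detector geometry
#'
#' @param collect_radius_mm Collection radius around the beam entry point on
#'   the top surface (mm). Default 2 (reads at the centre of the
#'   illumination spot).
#' @param acceptance_deg Half-angle of the acceptance cone about the upward
#'   surface normal, degrees. Default 30, modelling a lens-coupled
#'   photodiode a few centimetres above the spot; 90 accepts every upward
#'   exit (hemispheric detection, which mixes in oblique single-scattered
#'   exits no physical bench collects).
#' @return Object of class `detector_config`.
#' @export
detector_config <- function(collect_radius_mm = 2, acceptance_deg = 30) {
  if (collect_radius_mm <= 0) stop("'collect_radius_mm' must be positive")
  if (acceptance_deg <= 0 || acceptance_deg > 90)
    stop("'acceptance_deg' must lie in (0, 90]")
  structure(list(collect_radius_mm = collect_radius_mm,
                 acceptance_deg = acceptance_deg),
            class = "detector_config")
}

#' Launch a photon
#'
#' Pencil-beam launch at the origin of the top surface: direction at the
#' geometry's incidence angle in the x-z meridian, Stokes vector (1, 1, 0, 0)
#' (horizontal polarization), unit weight, zero scattering events. Boundaries
#' are index-matched by default, so the in-medium polar angle equals the
#' incidence angle.
#'
#' @param geometry A [slab_geometry()].
#' @return Object of class `photon_state` with fields `pos` (mm), `dir`
#'   (unit 3-vector), `frame_v`/`frame_w` (meridian reference frame; `v` is
#'   the parallel axis, `v x w = dir`), `stokes`, `weight`, `n_events`,
#'   `status`.
#' @export
launch_photon <- function(geometry) {
  stopifnot(inherits(geometry, "slab_geometry"))
  a <- geometry$incidence_deg * pi / 180
  k <- c(sin(a), 0, cos(a))
  fr <- meridian_frame(k)
  structure(list(pos = c(0, 0, 0), dir = k,
                 frame_v = fr$v, frame_w = fr$w,
                 stokes = c(1, 1, 0, 0), weight = 1,
                 n_events = 0L, status = "alive"),
            class = "photon_state")
}

# Meridian reference frame of a direction: w along k x zhat, v = w x k
# (v in the plane of k and the depth axis, v x w = k).  At the poles the
# frame is degenerate; the caller carries the previous frame instead.
meridian_frame <- function(k) {
  st2 <- k[1]^2 + k[2]^2
  if (st2 < 1e-24) return(list(v = c(-1, 0, 0), w = c(0, -1, 0), pole = TRUE))
  w <- c(k[2], -k[1], 0) / sqrt(st2)
  list(v = cross3(w, k), w = w, pole = FALSE)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Stokes transform for a reference-frame rotation by gamma about the
# propagation direction (new parallel axis = cos(g) v + sin(g) w).
rotate_stokes_frame <- function(s, gamma) {
  c2 <- cos(2 * gamma); s2 <- sin(2 * gamma)
  c(s[1], s[2] * c2 + s[3] * s2, -s[2] * s2 + s[3] * c2, s[4])
}

#' Sample a free-path step length
#'
#' Draws `s = -log(z) / (mu_a + mu_s)` with `z` uniform on (0, 1]: the
#' exponential free path of the bulk medium.  The step always uses the
#' medium-average `mu_s`, never a per-particle-size value.
#'
#' @param mu_a,mu_s Absorption and scattering coefficients (mm^-1);
#'   `mu_a + mu_s > 0`.
#' @param n Number of draws.
#' @return Step length(s) in mm.
#' @export
sample_step <- function(mu_a, mu_s, n = 1) {
  mu_t <- mu_a + mu_s
  if (mu_t <= 0) stop("mu_a + mu_s must be positive (infinite step otherwise)")
  stats::rexp(n, rate = mu_t)
}

#' Propagate a photon along its direction
#'
#' @param photon A `photon_state`.
#' @param s Step length (mm, >= 0).
#' @return The photon with `pos` advanced by `s * dir`; nothing else changes.
#' @export
propagate <- function(photon, s) {
  stopifnot(inherits(photon, "photon_state"), s >= 0)
  photon$pos <- photon$pos + s * photon$dir
  photon
}

#' Draw scattering angles by rejection
#'
#' Samples `(theta, psi)` proportional to `P(theta, psi) * sin(theta)` with
#' `P` the bivariate polarised phase function of the element table and the
#' photon's Stokes vector.  The proposal is uniform in `cos(theta)` and
#' `psi`; the envelope constant is the table maximum of `s11` plus the
#' maximum of `|s12|` weighted by the linear-polarised magnitude, times a
#' 1.01 safety factor (provably dominating for piecewise-linear elements).
#'
#' @param elements A [scattering_elements()] table.
#' @param stokes Stokes vector of the incoming photon.
#' @param max_tries Proposal cap; exceeding it signals a broken envelope and
#'   is an error.
#' @return Numeric `c(theta, psi)` in `[0, pi] x [0, 2*pi)`.
#' @export
sample_scattering_angles <- function(elements, stokes, max_tries = 100000L) {
  stopifnot(inherits(elements, "scattering_elements"))
  check_stokes(stokes)
  dth <- diff(elements$theta)
  if (max(dth) - min(dth) > 1e-9 * max(dth))
    stop("element grid must be uniformly spaced for the table sampler")
  .cpp_sample_angles(as.numeric(stokes), elements$theta, elements$s11,
                     elements$s12, as.integer(max_tries))
}

#' Apply one scattering event to a photon
#'
#' Meridian-plane update: the Stokes vector is rotated by `psi` into the
#' scattering plane, multiplied by the single-sphere Mueller matrix at
#' `theta` (elements linearly interpolated on the table grid), and rotated
#' back into the meridian plane of the new direction; the direction is
#' rotated by `(theta, psi)` and the event count incremented.  The Stokes
#' vector is renormalised so `I` equals the photon weight (the intensity
#' factor is carried by the angle sampling).  At pole-degenerate directions
#' the rotated scattering frame is carried in place of the meridian frame.
#'
#' @param photon An alive `photon_state`.
#' @param theta,psi Scattering angles (radians).
#' @param elements A [scattering_elements()] table.
#' @return The updated `photon_state` (unit direction, `n_events + 1`).
#' @export
scatter_update <- function(photon, theta, psi, elements) {
  stopifnot(inherits(photon, "photon_state"),
            inherits(elements, "scattering_elements"))
  if (photon$status != "alive") stop("cannot scatter a dead photon")
  if (theta < 0 || theta > pi || psi < 0 || psi >= 2 * pi)
    stop("scattering angles out of range")
  if (!is.null(elements$S1)) {
    # interpolate the complex amplitudes, not the four elements, so the
    # per-event Mueller matrix stays exactly pure between grid knots
    S1 <- complex(real = stats::approx(elements$theta, Re(elements$S1), xout = theta)$y,
                  imaginary = stats::approx(elements$theta, Im(elements$S1), xout = theta)$y)
    S2 <- complex(real = stats::approx(elements$theta, Re(elements$S2), xout = theta)$y,
                  imaginary = stats::approx(elements$theta, Im(elements$S2), xout = theta)$y)
    s11 <- 0.5 * (Mod(S2)^2 + Mod(S1)^2)
    s12 <- 0.5 * (Mod(S2)^2 - Mod(S1)^2)
    s33 <- Re(Conj(S2) * S1)
    s34 <- Im(Conj(S2) * S1)
  } else {
    s11 <- stats::approx(elements$theta, elements$s11, xout = theta)$y
    s12 <- stats::approx(elements$theta, elements$s12, xout = theta)$y
    s33 <- stats::approx(elements$theta, elements$s33, xout = theta)$y
    s34 <- stats::approx(elements$theta, elements$s34, xout = theta)$y
  }

  S <- rotate_stokes_frame(photon$stokes, psi)
  v <- photon$frame_v; w <- photon$frame_w; k <- photon$dir
  vs <- cos(psi) * v + sin(psi) * w
  ws <- -sin(psi) * v + cos(psi) * w
  k_new <- cos(theta) * k + sin(theta) * vs
  k_new <- k_new / sqrt(sum(k_new^2))
  e_par <- cos(theta) * vs - sin(theta) * k

  Sn <- c(s11 * S[1] + s12 * S[2],
          s12 * S[1] + s11 * S[2],
          s33 * S[3] + s34 * S[4],
          -s34 * S[3] + s33 * S[4])
  Sn <- Sn * (photon$weight / Sn[1])

  fr <- meridian_frame(k_new)
  if (fr$pole) {
    v_new <- e_par; w_new <- ws
  } else {
    v_new <- fr$v; w_new <- fr$w
    gam <- atan2(sum(v_new * ws), sum(v_new * e_par))
    Sn <- rotate_stokes_frame(Sn, gam)
  }
  photon$dir <- k_new
  photon$frame_v <- v_new
  photon$frame_w <- w_new
  photon$stokes <- Sn
  photon$n_events <- photon$n_events + 1L
  photon
}

#' Terminal-status check for a photon
#'
#' Applies the death rules after a move or scattering event: transmitted if
#' the depth exceeds the slab thickness, reflected if above the top surface,
#' absorbed with probability `mu_a / (mu_a + mu_s)` at an interaction
#' (binary absorption rule), and killed when the event count exceeds the
#' cap.  Status transitions are one-way from `"alive"`.
#'
#' @param photon A `photon_state`.
#' @param geometry A [slab_geometry()].
#' @param medium A [make_medium()] object (for `mu_a`, `mu_s`).
#' @param event_cap Maximum number of scattering events (default 1000).
#' @param at_interaction Logical; apply the absorption draw (only meaningful
#'   when called at an interaction site inside the slab).
#' @return The photon, possibly with a terminal `status`.
#' @export
check_termination <- function(photon, geometry, medium, event_cap = 1000L,
                              at_interaction = FALSE) {
  stopifnot(inherits(photon, "photon_state"), inherits(geometry, "slab_geometry"))
  if (photon$status != "alive") return(photon)
  depth <- photon$pos[3]
  if (depth > geometry$thickness_mm) {
    photon$status <- "transmitted"
  } else if (depth < 0) {
    photon$status <- "reflected_undetected"  # refined by detect()
  } else if (photon$n_events > event_cap) {
    photon$status <- "event_cap_killed"
  } else if (at_interaction && medium$mu_a > 0 &&
             stats::runif(1) < medium$mu_a / (medium$mu_a + medium$mu_s)) {
    photon$status <- "absorbed"
  }
  photon
}

#' Detection test for a photon that exited the top surface
#'
#' Accepts the photon iff its surface exit point lies within the collection
#' radius of the beam entry point and its exit direction within the
#' acceptance cone; on acceptance the Stokes vector is rotated into the
#' fixed detector frame (parallel axis = lab x-axis projected transverse to
#' the exit direction) for superposition.
#'
#' @param photon A `photon_state` that crossed the top surface (moving
#'   upward, `pos` at or above depth 0 along its path).
#' @param detector A [detector_config()].
#' @return A list of class `detection_record` (`exit_pos`, `exit_dir`,
#'   `stokes`, `weight`, `n_events`), or `NULL` if rejected.
#' @export
detect <- function(photon, detector = detector_config()) {
  stopifnot(inherits(photon, "photon_state"), inherits(detector, "detector_config"))
  k <- photon$dir
  if (k[3] >= 0) stop("photon is not travelling toward the top surface")
  t <- -photon$pos[3] / k[3]
  exitp <- photon$pos + max(t, 0) * k
  r <- sqrt(exitp[1]^2 + exitp[2]^2)
  upcos <- -k[3]
  if (r > detector$collect_radius_mm ||
      upcos < cos(detector$acceptance_deg * pi / 180)) return(NULL)
  a <- c(1, 0, 0) - k[1] * k
  an <- sqrt(sum(a^2))
  S <- photon$stokes
  if (an > 1e-12) {
    a <- a / an
    gam <- atan2(sum(a * photon$frame_w), sum(a * photon$frame_v))
    S <- rotate_stokes_frame(S, gam)
  }
  structure(list(exit_pos = exitp, exit_dir = k, stokes = S,
                 weight = photon$weight, n_events = photon$n_events),
            class = "detection_record")
}

#' Run the polarized Monte Carlo transport
#'
#' Launches `n_photons` pencil-beam photons with Stokes (1, 1, 0, 0) at the
#' geometry's incidence angle, propagates them through the slab with
#' exponential steps at the medium-average `mu_t`, per-event particle-size
#' resampling from the medium's distribution, meridian-plane polarised
#' scattering, and the binary death rules (absorption, escape, event cap).
#' Photons exiting the top surface inside the detector acceptance are
#' superposed in the detector Stokes frame.  Photons run in `n_batches`
#' consecutive batches for Monte Carlo error estimation.
#'
#' @param medium A [make_medium()] object.
#' @param geometry A [slab_geometry()].
#' @param n_photons Photon budget (>= 1). The study-scale budget is 1e7;
#'   desk-scale runs use 1e4-1e5.
#' @param seed Integer seed for R's RNG (`NULL` leaves the stream alone).
#' @param n_batches Number of batches for error estimation (default 10).
#' @param detector A [detector_config()].
#' @param event_cap Maximum scattering events per photon (default 1000).
#' @param launch_stokes Incident Stokes vector (default horizontal,
#'   `c(1, 1, 0, 0)`).
#' @param absorption `"binary"` (photon dies with probability `mu_a / mu_t`
#'   at each interaction; default) or `"weighted"` (weight is multiplied by
#'   the albedo each event, with Russian roulette below `1e-4`).
#' @param boundary `"matched"` (no refraction or Fresnel reflection;
#'   default) or `"fresnel"` (Snell refraction and polarisation-dependent
#'   Fresnel reflection at both surfaces against an outside index of 1).
#' @param record_detections Keep a per-detection table (event count, Stokes,
#'   exit position/direction); needed for event-resolved diagnostics.
#' @param max_tries Rejection-proposal cap per scattering event.
#' @return Object of class `transport_result`: `detector_stokes` (summed,
#'   detector frame), `batch_stokes` (n_batches x 4), `batch_detected`,
#'   `batch_weight`, `tallies` (named, partitioning `n_photons`),
#'   `detected_weight_sum`, `n_photons`, and optionally `detections`.
#' @export
run_transport <- function(medium, geometry, n_photons, seed = NULL,
                          n_batches = 10L, detector = detector_config(),
                          event_cap = 1000L, launch_stokes = c(1, 1, 0, 0),
                          absorption = c("binary", "weighted"),
                          boundary = c("matched", "fresnel"),
                          record_detections = FALSE, max_tries = 100000L) {
  stopifnot(inherits(medium, "medium"), inherits(geometry, "slab_geometry"))
  absorption <- match.arg(absorption)
  boundary <- match.arg(boundary)
  check_stokes(launch_stokes)
  if (!is.null(seed)) set.seed(seed)
  tb <- medium$tables
  res <- .cpp_run_transport(
    as.integer(n_photons), as.integer(n_batches),
    medium$mu_a, medium$mu_s, geometry$thickness_mm, geometry$incidence_deg,
    as.numeric(launch_stokes), tb$cum_w,
    tb$re1, tb$im1, tb$re2, tb$im2, tb$max_s11, tb$max_as12,
    detector$collect_radius_mm, cos(detector$acceptance_deg * pi / 180),
    as.integer(event_cap), as.integer(max_tries),
    absorption == "weighted", 1e-4, 0.1,
    boundary == "fresnel", medium$n_medium,
    record_detections)
  out <- list(detector_stokes = as.numeric(res$detector_stokes),
              batch_stokes = res$batch_stokes,
              batch_detected = as.integer(res$batch_detected),
              batch_weight = as.numeric(res$batch_weight),
              detected_weight_sum = res$detected_weight_sum,
              tallies = res$tallies,
              n_photons = n_photons,
              medium = medium[c("mu_a", "mu_s", "g", "mu_s_prime")],
              geometry = geometry)
  if (record_detections) {
    m <- t(res$detections)
    colnames(m) <- c("n_events", "weight", "I", "Q", "U", "V",
                     "exit_x", "exit_y", "kx", "ky", "kz")
    out$detections <- as.data.frame(m)
  }
  structure(out, class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf("transport: %g photons, slab %g mm, mu_s' = %.3g mm^-1\n",
              x$n_photons, x$geometry$thickness_mm, x$medium$mu_s_prime))
  cat("  detector Stokes:", format(x$detector_stokes, digits = 5), "\n")
  t <- x$tallies
  cat("  tallies:", paste(names(t), t[], sep = "=", collapse = " "), "\n")
  invisible(x)
}
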