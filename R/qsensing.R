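# Q-sensing observables: analyzer-channel intensities from detector Stokes
# sums, the normalized Q' statistic, and the thickness / reduced-scattering
# sweep experiments.

#' Analyzer-channel intensities from a detector Stokes vector
#'
#' Projects the superposed detector Stokes vector onto the two linear
#' analyzer channels: co-polarized `I_par = (I + Q) / 2` and cross-polarized
#' `I_perp = (I - Q) / 2` (analyzer parallel axis = detector x-axis, matched
#' to the launch polarization).  Their sum recovers `I` and their difference
#' `Q` exactly.
#'
#' @param detector_stokes Stokes vector in the detector frame with
#'   `I >= |Q|` (up to roundoff).
#' @param tol Relative tolerance on the physicality check.
#' @return Named list `I_par`, `I_perp`.
#' @export
stokes_to_intensities <- function(detector_stokes, tol = 1e-9) {
  s <- detector_stokes
  if (length(s) < 2L) stop("need at least the I and Q components")
  if (abs(s[2]) > s[1] * (1 + tol) + tol)
    stop("unphysical superposition: |Q| > I")
  list(I_par = (s[1] + s[2]) / 2, I_perp = (s[1] - s[2]) / 2)
}

#' The normalized Q-sensing statistic
#'
#' `Q' = (I_par - I_perp) / (I_par + I_perp)`: the Q parameter normalized by
#' the total intensity, i.e. the fraction of detected light still carrying
#' the launch polarization (the normalized superficial-scatter intensity).
#'
#' @param I_par,I_perp Co- and cross-polarized intensities; their sum must
#'   be positive.
#' @return Dimensionless value in `[-1, 1]`.
#' @examples
#' compute_q_prime(1, 0)    # 1
#' compute_q_prime(0.5, 0.5)  # 0
#' @export
compute_q_prime <- function(I_par, I_perp) {
  tot <- I_par + I_perp
  if (any(tot <= 0)) stop("total intensity must be positive")
  (I_par - I_perp) / tot
}

#' Q-sensing observables of one transport run
#'
#' Reduces a [run_transport()] result to the Q-sensing cell observables:
#' analyzer-channel intensities, total intensity, Q, the normalized
#' `Q_prime`, and its batch-statistics standard error.
#'
#' @param tr A `transport_result`.
#' @return List with `I_par`, `I_perp`, `I_total`, `Q`, `Q_prime`,
#'   `se_Q_prime`, `n_detected`.
#' @export
q_sense_result <- function(tr) {
  stopifnot(inherits(tr, "transport_result"))
  s <- tr$detector_stokes
  ch <- stokes_to_intensities(s)
  bs <- tr$batch_stokes
  nb <- nrow(bs)
  ok <- bs[, 1] > 0
  qp_b <- (bs[ok, 2]) / (bs[ok, 1])
  se_qp <- if (sum(ok) >= 2) stats::sd(qp_b) / sqrt(sum(ok)) else NA_real_
  list(I_par = ch$I_par, I_perp = ch$I_perp, I_total = s[1], Q = s[2],
       Q_prime = if (s[1] > 0) s[2] / s[1] else NA_real_,
       se_Q_prime = se_qp, n_detected = sum(tr$batch_detected))
}

sweep_row <- function(medium, thickness, res) {
  data.frame(mu_s_prime = medium$mu_s_prime, thickness_mm = thickness,
             I_par = res$I_par, I_perp = res$I_perp, I_total = res$I_total,
             Q = res$Q, Q_prime = res$Q_prime, se_Q_prime = res$se_Q_prime,
             n_detected = res$n_detected)
}

#' Thickness sweep at fixed optical properties
#'
#' One transport run per slab thickness, emitting the Q-sensing observables
#' with Monte Carlo batch errors.  The full study design uses 19 thicknesses
#' (0.6-1.5 mm in 0.1 mm steps, 2-10 mm in 1 mm steps); any increasing grid
#' is accepted.
#'
#' @param medium A [make_medium()] object.
#' @param thicknesses_mm Increasing thickness grid (mm).
#' @param n_photons Photons per run.
#' @param seed RNG seed applied once before the first run (runs consume one
#'   sequential stream, so the whole sweep is reproducible).
#' @param ... Passed to [run_transport()].
#' @return A `sweep_table` data frame with columns `mu_s_prime`,
#'   `thickness_mm`, `I_par`, `I_perp`, `I_total`, `Q`, `Q_prime`,
#'   `se_Q_prime`, `n_detected`.
#' @export
thickness_sweep <- function(medium, thicknesses_mm, n_photons = 1e5,
                            seed = NULL, ...) {
  if (length(thicknesses_mm) == 0 || is.unsorted(thicknesses_mm, strictly = TRUE))
    stop("'thicknesses_mm' must be a non-empty increasing grid")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(thicknesses_mm, function(d) {
    tr <- run_transport(medium, slab_geometry(d), n_photons, seed = NULL, ...)
    sweep_row(medium, d, q_sense_result(tr))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Default study grids
#'
#' The 19-thickness grid of the sweep design: 0.6 to 1.5 mm in 0.1 mm steps
#' and 2 to 10 mm in 1 mm steps.
#'
#' @return Numeric vector of thicknesses (mm).
#' @export
study_thickness_grid <- function() c(seq(0.6, 1.5, by = 0.1), seq(2, 10, by = 1))

#' Reduced-scattering sweep at fixed thickness
#'
#' One transport run per reduced scattering coefficient at a fixed slab
#' thickness (default 10 mm, where Q' has converged): the calibration-ready
#' table mapping `mu_s'` to the plateau Q'.
#'
#' @param mus_primes Reduced scattering grid (mm^-1).
#' @param thickness_mm Slab thickness (mm).
#' @param n_photons Photons per run.
#' @param seed RNG seed (applied once, as in [thickness_sweep()]).
#' @param media Optional pre-built list of media (e.g. [study_media()]);
#'   built from `mus_primes` when `NULL`.
#' @param ... Passed to [study_media()] (and so to [make_medium()]) when
#'   building media.
#' @param transport_args Named list of extra arguments for [run_transport()].
#' @return A `sweep_table` data frame (one row per `mu_s'`).
#' @export
mus_prime_sweep <- function(mus_primes, thickness_mm = 10, n_photons = 1e5,
                            seed = NULL, media = NULL, ...,
                            transport_args = list()) {
  if (length(mus_primes) == 0) stop("'mus_primes' must be non-empty")
  if (is.null(media)) media <- study_media(mus_primes, ...)
  if (!is.null(seed)) set.seed(seed)
  geom <- slab_geometry(thickness_mm)
  rows <- lapply(media, function(m) {
    tr <- do.call(run_transport,
                  c(list(m, geom, n_photons, seed = NULL), transport_args))
    sweep_row(m, thickness_mm, q_sense_result(tr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Write a sweep table as tab-separated text
#'
#' @param table A `sweep_table` (from [thickness_sweep()] or
#'   [mus_prime_sweep()]).
#' @param path Output file path.
#' @export
write_sweep_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sweep table written by [write_sweep_table()]
#'
#' @param path File path.
#' @return A `sweep_table` data frame.
#' @export
read_sweep_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  class(out) <- c("sweep_table", "data.frame")
  out
}
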