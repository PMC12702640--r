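# Calibration-based extraction of the reduced scattering coefficient from a
# converged Q' reading: build a simulated mu_s' -> Q' curve in the converged
# (thick-slab) regime and invert it with a monotone interpolant.

#' Build a Q' calibration curve
#'
#' Runs [mus_prime_sweep()] at a thickness at or beyond the convergence
#' threshold (Q' has plateaued) and packages the resulting monotone curve.
#' The build refuses to emit a curve whose monotonicity is violated beyond
#' three times the combined Monte Carlo error of adjacent points.
#'
#' @param mus_prime_grid Increasing reduced-scattering grid (mm^-1).
#' @param thickness_mm Slab thickness (mm); must be at least
#'   `convergence_threshold_mm`.
#' @param n_photons Photons per grid point.
#' @param seed RNG seed.
#' @param convergence_threshold_mm Minimum thickness accepted as converged
#'   (default 10 mm).
#' @param ... Passed to [mus_prime_sweep()].
#' @return Object of class `calibration_curve`: `mus_prime_grid`,
#'   `q_prime_values` (raw), `q_prime_fit` (strictly decreasing fit used by
#'   the interpolant), `q_prime_errors` (MC batch errors), `model_errors`
#'   (leave-one-out interpolation error per knot), `thickness_mm`,
#'   `metadata` (seed, photon budget, anisotropy assumption note).
#' @export
build_calibration <- function(mus_prime_grid = c(0.5, 1, 1.5, 2, 3),
                              thickness_mm = 10, n_photons = 1e5, seed = 1,
                              convergence_threshold_mm = 10, ...) {
  if (is.unsorted(mus_prime_grid, strictly = TRUE))
    stop("'mus_prime_grid' must be strictly increasing")
  if (thickness_mm < convergence_threshold_mm)
    stop(sprintf("thickness %g mm is below the convergence threshold %g mm",
                 thickness_mm, convergence_threshold_mm))
  sw <- mus_prime_sweep(mus_prime_grid, thickness_mm, n_photons, seed = seed, ...)
  qp <- sw$Q_prime
  se <- sw$se_Q_prime
  dq <- diff(qp)
  tol3 <- 3 * sqrt(se[-1]^2 + se[-length(se)]^2)
  if (any(dq > tol3, na.rm = TRUE)) {
    bad <- which(dq > tol3)
    stop(sprintf(paste0("calibration curve not monotone: Q' rises between ",
                        "mu_s' = %s and %s mm^-1 by more than 3x the MC error ",
                        "(dQ' = %s); increase the photon budget or check the medium"),
                 paste(mus_prime_grid[bad], collapse = ", "),
                 paste(mus_prime_grid[bad + 1], collapse = ", "),
                 paste(signif(dq[bad], 3), collapse = ", ")))
  }
  # strictly decreasing fit for the interpolant: isotonic (decreasing)
  # regression absorbs small MC-noise rises, then ties are separated by an
  # epsilon far below the MC error scale
  fit <- -stats::isoreg(mus_prime_grid, -qp)$yf
  eps <- max(1e-9, 1e-6 * diff(range(qp)))
  for (i in seq_along(fit)[-1]) fit[i] <- min(fit[i], fit[i - 1] - eps)
  # interpolation (model) error of the coarse grid: leave-one-out residuals
  # at interior knots, on the Q' scale
  n <- length(fit)
  loo <- rep(NA_real_, n)
  if (n >= 4) {
    for (i in 2:(n - 1)) {
      pred <- stats::splinefun(mus_prime_grid[-i], fit[-i], method = "hyman")
      loo[i] <- abs(fit[i] - pred(mus_prime_grid[i]))
    }
    loo[1] <- loo[2]
    loo[n] <- loo[n - 1]
  } else {
    loo[] <- 0
  }
  structure(list(
    mus_prime_grid = mus_prime_grid,
    q_prime_values = qp,
    q_prime_fit = fit,
    q_prime_errors = se,
    model_errors = loo,
    thickness_mm = thickness_mm,
    metadata = list(seed = seed, n_photons = n_photons,
                    note = paste("extraction assumes the measurement shares the",
                                 "calibration's anisotropy and absorption"))
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Q' calibration at %g mm (%g photons/point):\n",
              x$thickness_mm, x$metadata$n_photons))
  print(data.frame(mus_prime = x$mus_prime_grid, q_prime = x$q_prime_values,
                   se = x$q_prime_errors), row.names = FALSE)
  invisible(x)
}

#' Extract mu_s' from a measured converged Q'
#'
#' Inverts the calibration curve with a monotone shape-preserving cubic
#' interpolant on the (Q' -> mu_s') inverse map.  The returned interval
#' propagates the measurement error and the curve's Monte Carlo error
#' through the same interpolant.  Queries in the flat high-mu_s' regime
#' (local sensitivity `|dQ'/dmu_s'|` below `sensitivity_floor`) are answered
#' with `low_confidence = TRUE`.  Measured values outside the curve's range
#' are refused (no extrapolation).
#'
#' @param curve A [build_calibration()] object.
#' @param q_prime_measured Measured converged Q' value.
#' @param q_prime_error Standard error of the measurement (default 0).
#' @param sensitivity_floor Flat-regime flag threshold on `|dQ'/dmu_s'|`
#'   (per mm^-1), default 0.02.
#' @param level Nominal confidence level of the interval (default 0.95).
#' @return List with `mus_prime` (point estimate), `interval` (length-2
#'   vector), `sensitivity` (local `|dQ'/dmu_s'|`), `low_confidence`
#'   (logical), and the curve `metadata`.
#' @export
invert_mus_prime <- function(curve, q_prime_measured, q_prime_error = 0,
                             sensitivity_floor = 0.02, level = 0.95) {
  stopifnot(inherits(curve, "calibration_curve"))
  qp <- if (!is.null(curve$q_prime_fit)) curve$q_prime_fit else curve$q_prime_values
  mus <- curve$mus_prime_grid
  if (q_prime_measured > max(qp) || q_prime_measured < min(qp))
    stop(sprintf("measured Q' = %g outside the calibration range [%g, %g]: extrapolation refused",
                 q_prime_measured, min(qp), max(qp)))
  # inverse map: Q' decreasing in mu_s' -> sort ascending in Q'
  ord <- order(qp)
  inv <- stats::splinefun(qp[ord], mus[ord], method = "hyman")
  est <- inv(q_prime_measured)
  # parametric bootstrap: redraw the knots from their MC errors and the
  # measurement from its combined error (including the grid's leave-one-out
  # interpolation error), re-invert, and take percentile quantiles.  A fixed
  # internal RNG stream keeps the function deterministic; the caller's RNG
  # state is untouched.
  me <- if (!is.null(curve$model_errors))
    stats::approx(qp[ord], curve$model_errors[ord],
                  xout = q_prime_measured, rule = 2)$y else 0
  se_k <- ifelse(is.finite(curve$q_prime_errors), curve$q_prime_errors, 0)
  se_q <- sqrt(q_prime_error^2 + me^2)
  boot <- local({
    rs <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (is.null(rs))
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", rs, envir = globalenv()))
    set.seed(285714L)
    B <- 500L
    out <- numeric(B)
    n <- length(qp)
    eps <- max(1e-9, 1e-6 * diff(range(qp)))
    for (b in seq_len(B)) {
      kq <- qp + stats::rnorm(n, 0, se_k)
      for (i in 2:n) kq[i] <- min(kq[i], kq[i - 1] - eps)
      qb <- min(max(q_prime_measured + stats::rnorm(1, 0, se_q), kq[n]), kq[1])
      out[b] <- stats::splinefun(rev(kq), rev(mus), method = "hyman")(qb)
    }
    out
  })
  interval <- unname(stats::quantile(boot, c((1 - level) / 2, (1 + level) / 2)))
  interval <- c(max(min(mus), interval[1]), min(max(mus), interval[2]))
  # local sensitivity of the forward map at the estimate
  dmu <- inv(q_prime_measured, deriv = 1)  # d mu / d Q'
  sens <- if (is.finite(dmu) && dmu != 0) abs(1 / dmu) else 0
  list(mus_prime = est, interval = interval, sensitivity = sens,
       low_confidence = sens < sensitivity_floor,
       metadata = curve$metadata)
}

#' Persist a calibration curve as structured text (JSON)
#'
#' @param curve A [build_calibration()] object.
#' @param path Output file path.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a calibration curve written by [write_calibration()]
#'
#' @param path File path.
#' @return A `calibration_curve` object.
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$mus_prime_grid <- as.numeric(x$mus_prime_grid)
  x$q_prime_values <- as.numeric(x$q_prime_values)
  x$q_prime_errors <- as.numeric(x$q_prime_errors)
  if (!is.null(x$q_prime_fit)) x$q_prime_fit <- as.numeric(x$q_prime_fit)
  if (!is.null(x$model_errors)) x$model_errors <- as.numeric(x$model_errors)
  structure(x, class = "calibration_curve")
}

#' Form Q' from a two-column measured-intensity file
#'
#' Reads whitespace/tab-separated text with header columns `I_par` and
#' `I_perp` (one row per repeat), sums the repeats and forms Q' with a
#' between-repeat standard error.
#'
#' @param path File path.
#' @return List `q_prime`, `se`, `n`.
#' @export
read_measured_q_prime <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  if (!all(c("I_par", "I_perp") %in% names(df)))
    stop("measured-data file needs columns 'I_par' and 'I_perp'")
  qp_i <- compute_q_prime(df$I_par, df$I_perp)
  list(q_prime = compute_q_prime(sum(df$I_par), sum(df$I_perp)),
       se = if (nrow(df) >= 2) stats::sd(qp_i) / sqrt(nrow(df)) else 0,
       n = nrow(df))
}
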