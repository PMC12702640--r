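# Mie amplitude functions and scattering-matrix elements for homogeneous
# spheres.  Bohren & Huffman style series: logarithmic derivative by downward
# recurrence, Riccati-Bessel functions by upward recurrence, angular functions
# pi_n/tau_n by upward recurrence, vectorised over the angular grid.

#' Specify a single spherical scatterer
#'
#' Bundles the geometric and optical parameters of one homogeneous sphere in a
#' host medium and derives its size parameter `x = 2 * pi * r * n_medium /
#' lambda_vacuum` (radius in units of the in-medium wavelength).
#'
#' @param radius_nm Sphere radius in nanometres (> 0).
#' @param wavelength_nm Vacuum wavelength in nanometres (> 0). Default 632.8
#'   (He-Ne line).
#' @param n_particle Refractive index of the sphere, possibly complex.
#'   Default 1.46 (soybean oil, the scattering phase of lipid emulsions).
#' @param n_medium Real refractive index of the host (>= 1). Default 1.33
#'   (water).
#' @return An object of class `sphere_spec` with fields `radius_nm`,
#'   `wavelength_nm`, `n_particle`, `n_medium`, `x` (size parameter) and `m`
#'   (relative index `n_particle / n_medium`).
#' @examples
#' sp <- sphere_spec(100)
#' sp$x
#' @export
sphere_spec <- function(radius_nm, wavelength_nm = 632.8,
                        n_particle = 1.46, n_medium = 1.33) {
  if (!is.numeric(radius_nm) || length(radius_nm) != 1L || radius_nm <= 0)
    stop("'radius_nm' must be a single positive number")
  if (!is.numeric(wavelength_nm) || wavelength_nm <= 0)
    stop("'wavelength_nm' must be positive")
  if (is.complex(n_medium) || n_medium < 1)
    stop("'n_medium' must be real and >= 1")
  x <- 2 * pi * radius_nm * n_medium / wavelength_nm
  structure(list(
    radius_nm = radius_nm,
    wavelength_nm = wavelength_nm,
    n_particle = as.complex(n_particle),
    n_medium = n_medium,
    x = x,
    m = as.complex(n_particle) / n_medium
  ), class = "sphere_spec")
}

#' @export
print.sphere_spec <- function(x, ...) {
  cat(sprintf("sphere: r = %.4g nm, lambda = %.4g nm, m = %s, x = %.6g\n",
              x$radius_nm, x$wavelength_nm, format(x$m), x$x))
  invisible(x)
}

# Wiscombe term count for the Mie series.
mie_nmax <- function(x) ceiling(x + 4 * x^(1/3) + 2)

# Mie expansion coefficients a_n, b_n (n = 1..nmax) for size parameter x and
# relative index m.  Logarithmic derivative D_n(mx) by downward recurrence.
mie_coefficients <- function(x, m, nmax) {
  mx <- m * x
  nstart <- max(nmax, ceiling(Mod(mx))) + 16L
  d <- complex(length.out = nstart)
  d[nstart] <- 0 + 0i
  for (n in (nstart - 1L):1L) {
    rn <- (n + 1) / mx
    d[n] <- rn - 1 / (d[n + 1] + rn)
  }
  n <- seq_len(nmax)
  # Riccati-Bessel psi_n(x), chi_n(x) upward (real argument, stable here)
  psi <- numeric(nmax); chi <- numeric(nmax)
  psi_nm2 <- cos(x); psi_nm1 <- sin(x)     # psi_{-1}, psi_0
  chi_nm2 <- -sin(x); chi_nm1 <- cos(x)    # chi_{-1}, chi_0
  for (k in n) {
    psi[k] <- (2 * k - 1) / x * psi_nm1 - psi_nm2
    chi[k] <- (2 * k - 1) / x * chi_nm1 - chi_nm2
    psi_nm2 <- psi_nm1; psi_nm1 <- psi[k]
    chi_nm2 <- chi_nm1; chi_nm1 <- chi[k]
  }
  xi <- complex(real = psi, imaginary = -chi)
  psi_prev <- c(sin(x), psi[-nmax])
  xi_prev <- complex(real = psi_prev,
                     imaginary = -c(cos(x), chi[-nmax]))
  dn <- d[n]
  ta <- dn / m + n / x
  tb <- dn * m + n / x
  a <- (ta * psi - psi_prev) / (ta * xi - xi_prev)
  b <- (tb * psi - psi_prev) / (tb * xi - xi_prev)
  list(a = a, b = b)
}

#' Complex Mie amplitude functions on an angular grid
#'
#' Sums the Mie series for the complex scattering amplitudes `S1(theta)` and
#' `S2(theta)` of a homogeneous sphere.  `S2` carries the field component
#' parallel to the scattering plane, `S1` the perpendicular one.
#'
#' @param spec A [sphere_spec()].
#' @param theta Angular grid in radians, values in `[0, pi]`. Default 1000
#'   uniform angles.
#' @param max_terms Hard cap on series terms; exceeding it (size parameter far
#'   outside the supported range) is an error, never a silent truncation.
#' @return Object of class `amplitude_table`: list with `theta`, complex
#'   vectors `S1`, `S2`, and the generating `spec`.
#' @examples
#' amp <- mie_amplitudes(sphere_spec(100), seq(0, pi, length.out = 181))
#' amp$S1[1] == amp$S2[1]  # forward-scattering symmetry
#' @export
mie_amplitudes <- function(spec, theta = seq(0, pi, length.out = 1000L),
                           max_terms = 20000L) {
  stopifnot(inherits(spec, "sphere_spec"))
  if (any(theta < 0 | theta > pi)) stop("grid angles must lie in [0, pi]")
  if (is.unsorted(theta, strictly = TRUE)) stop("'theta' must be strictly increasing")
  x <- spec$x
  nmax <- mie_nmax(x)
  if (nmax > max_terms)
    stop(sprintf("Mie series needs %d terms (> max_terms = %d): x = %g too large",
                 nmax, max_terms, x))
  cf <- mie_coefficients(x, spec$m, nmax)
  mu <- cos(theta)
  S1 <- complex(length.out = length(theta))
  S2 <- complex(length.out = length(theta))
  pi_nm1 <- numeric(length(theta))  # pi_0 = 0
  pi_n <- rep(1, length(theta))     # pi_1 = 1
  for (n in seq_len(nmax)) {
    tau_n <- n * mu * pi_n - (n + 1) * pi_nm1
    fac <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + fac * (cf$a[n] * pi_n + cf$b[n] * tau_n)
    S2 <- S2 + fac * (cf$a[n] * tau_n + cf$b[n] * pi_n)
    pi_np1 <- ((2 * n + 1) * mu * pi_n - (n + 1) * pi_nm1) / n
    pi_nm1 <- pi_n
    pi_n <- pi_np1
  }
  if (any(!is.finite(Re(S1))) || any(!is.finite(Re(S2))))
    stop("Mie series did not converge to finite amplitudes")
  structure(list(theta = theta, S1 = S1, S2 = S2, spec = spec),
            class = "amplitude_table")
}

#' Mie scattering and extinction efficiencies
#'
#' @param spec A [sphere_spec()].
#' @return List with `Qsca`, `Qext` (efficiencies) and `Csca_nm2`
#'   (scattering cross section in nm^2).
#' @export
mie_efficiencies <- function(spec) {
  x <- spec$x
  nmax <- mie_nmax(x)
  cf <- mie_coefficients(x, spec$m, nmax)
  n <- seq_len(nmax)
  qsca <- 2 / x^2 * sum((2 * n + 1) * (Mod(cf$a)^2 + Mod(cf$b)^2))
  qext <- 2 / x^2 * sum((2 * n + 1) * Re(cf$a + cf$b))
  list(Qsca = qsca, Qext = qext, Csca_nm2 = qsca * pi * spec$radius_nm^2)
}

#' Scattering-matrix elements from Mie amplitudes
#'
#' Forms the four independent elements of the single-sphere Mueller
#' (scattering) matrix from the complex amplitudes:
#' `s11 = (|S2|^2 + |S1|^2)/2`, `s12 = (|S2|^2 - |S1|^2)/2`,
#' `s33 = Re(S2* S1)`, `s34 = Im(S2* S1)`.  Only three are independent:
#' `s11^2 = s12^2 + s33^2 + s34^2` holds pointwise (pure Mueller-Jones
#' matrix).  Also computes the anisotropy `g` (intensity-weighted mean cosine)
#' and the constant `norm` that makes `s11 / norm` a phase function
#' normalised over the sphere, both by trapezoidal quadrature on the grid.
#'
#' @param amps An [mie_amplitudes()] table.
#' @return Object of class `scattering_elements`: `theta`, `s11`, `s12`,
#'   `s33`, `s34`, `g`, `norm`, plus the generating `spec`.
#' @export
scattering_elements <- function(amps) {
  stopifnot(inherits(amps, "amplitude_table"))
  a1 <- Mod(amps$S1)^2
  a2 <- Mod(amps$S2)^2
  s11 <- 0.5 * (a2 + a1)
  s12 <- 0.5 * (a2 - a1)
  cross <- Conj(amps$S2) * amps$S1
  s33 <- Re(cross)
  s34 <- Im(cross)
  if (all(s11 <= 0)) stop("degenerate scatterer: s11 vanishes everywhere")
  th <- amps$theta
  w_tot <- trapz(th, s11 * sin(th))
  g <- trapz(th, s11 * cos(th) * sin(th)) / w_tot
  norm <- 2 * pi * w_tot
  structure(list(theta = th, s11 = s11, s12 = s12, s33 = s33, s34 = s34,
                 g = g, norm = norm, spec = amps$spec,
                 S1 = amps$S1, S2 = amps$S2),
            class = "scattering_elements")
}

#' @export
print.scattering_elements <- function(x, ...) {
  cat(sprintf("scattering elements: %d angles, x = %.4g, g = %.4f\n",
              length(x$theta), x$spec$x, x$g))
  invisible(x)
}

# trapezoidal rule
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Bivariate single-scattering phase function
#'
#' Evaluates `P(theta, psi) = s11(theta) * I + s12(theta) * (Q cos 2psi +
#' U sin 2psi)` for an incident Stokes vector, with `s11`, `s12` linearly
#' interpolated on the element grid.  This is the (unnormalised) density used
#' to draw scattering angles of polarised photons.
#'
#' @param elements A [scattering_elements()] table.
#' @param theta Scattering angle(s) in `[0, pi]`.
#' @param psi Azimuthal rotation(s) into the scattering plane, in `[0, 2*pi)`.
#' @param stokes Incident Stokes vector `c(I, Q, U, V)` with `I > 0` and
#'   degree of polarization at most 1.
#' @return Non-negative density value(s), recycled over `theta`/`psi`.
#' @export
phase_function_value <- function(elements, theta, psi, stokes) {
  stopifnot(inherits(elements, "scattering_elements"))
  if (any(theta < 0 | theta > pi)) stop("'theta' outside [0, pi]")
  if (any(psi < 0 | psi >= 2 * pi)) stop("'psi' outside [0, 2*pi)")
  check_stokes(stokes)
  s11 <- stats::approx(elements$theta, elements$s11, xout = theta)$y
  s12 <- stats::approx(elements$theta, elements$s12, xout = theta)$y
  s11 * stokes[1] + s12 * (stokes[2] * cos(2 * psi) + stokes[3] * sin(2 * psi))
}

#' Export scattering elements as tabular text
#'
#' Writes a five-column table (`theta`, `s11`, `s12`, `s33`, `s34`) in
#' tab-separated text for inspection or cross-tool comparison.
#'
#' @param elements A [scattering_elements()] table.
#' @param path Output file path.
#' @export
write_scattering_elements <- function(elements, path) {
  stopifnot(inherits(elements, "scattering_elements"))
  df <- data.frame(theta = elements$theta, s11 = elements$s11,
                   s12 = elements$s12, s33 = elements$s33, s34 = elements$s34)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct and validate a Stokes vector
#'
#' @param I,Q,U,V Stokes components; `I >= 0` and `Q^2+U^2+V^2 <= I^2` (up to
#'   roundoff) are enforced.
#' @return Numeric vector `c(I, Q, U, V)` of class `stokes`.
#' @export
stokes_vector <- function(I = 1, Q = 0, U = 0, V = 0) {
  s <- c(I = I, Q = Q, U = U, V = V)
  check_stokes(s)
  class(s) <- "stokes"
  s
}

check_stokes <- function(s, tol = 1e-9) {
  if (length(s) != 4L || !is.numeric(s)) stop("a Stokes vector has 4 numeric components")
  if (s[1] < 0) stop("Stokes I must be >= 0")
  if (sum(s[2:4]^2) > s[1]^2 * (1 + tol) + tol)
    stop("unphysical Stokes vector: Q^2 + U^2 + V^2 > I^2")
  invisible(s)
}

#' Degree of polarization of a Stokes vector
#'
#' @param s Stokes vector `c(I, Q, U, V)`.
#' @return `sqrt(Q^2 + U^2 + V^2) / I` (0 for `I = 0`).
#' @export
degree_of_polarization <- function(s) {
  if (s[1] <= 0) return(0)
  sqrt(sum(s[2:4]^2)) / s[1]
}
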