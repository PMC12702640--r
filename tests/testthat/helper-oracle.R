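# Independent brute-force Mie oracle: expansion coefficients from
# Riccati-Bessel functions built on base R's fractional-order Bessel
# functions (j_n(z) = sqrt(pi/(2 z)) J_{n+1/2}(z)), with the derivative-form
# a_n/b_n expressions.  Real relative index only, which covers every test
# case.  Shares no code with the package's logarithmic-derivative
# implementation.
oracle_mie_amplitudes <- function(x, m, theta) {
  stopifnot(Im(m) == 0)
  m <- Re(m)
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  n <- seq_len(nmax)
  psi_of <- function(z) sqrt(pi * z / 2) * besselJ(z, n + 0.5)
  psi_prev_of <- function(z) sqrt(pi * z / 2) * besselJ(z, n - 0.5)
  chi_of <- function(z) -sqrt(pi * z / 2) * besselY(z, n + 0.5)
  chi_prev_of <- function(z) -sqrt(pi * z / 2) * besselY(z, n - 0.5)

  psi_x <- psi_of(x); psi_x_p <- psi_prev_of(x) - n / x * psi_x
  chi_x <- chi_of(x); chi_x_p <- chi_prev_of(x) - n / x * chi_x
  xi_x <- complex(real = psi_x, imaginary = -chi_x)
  xi_x_p <- complex(real = psi_x_p, imaginary = -chi_x_p)
  mx <- m * x
  psi_mx <- psi_of(mx); psi_mx_p <- psi_prev_of(mx) - n / mx * psi_mx

  a <- (m * psi_mx * psi_x_p - psi_x * psi_mx_p) /
       (m * psi_mx * xi_x_p - xi_x * psi_mx_p)
  b <- (psi_mx * psi_x_p - m * psi_x * psi_mx_p) /
       (psi_mx * xi_x_p - m * xi_x * psi_mx_p)

  S1 <- complex(length.out = length(theta))
  S2 <- complex(length.out = length(theta))
  for (j in seq_along(theta)) {
    mu <- cos(theta[j])
    pi_nm1 <- 0; pi_n <- 1
    s1 <- 0 + 0i; s2 <- 0 + 0i
    for (k in n) {
      tau_n <- k * mu * pi_n - (k + 1) * pi_nm1
      f <- (2 * k + 1) / (k * (k + 1))
      s1 <- s1 + f * (a[k] * pi_n + b[k] * tau_n)
      s2 <- s2 + f * (a[k] * tau_n + b[k] * pi_n)
      pi_np1 <- ((2 * k + 1) * mu * pi_n - (k + 1) * pi_nm1) / k
      pi_nm1 <- pi_n; pi_n <- pi_np1
    }
    S1[j] <- s1; S2[j] <- s2
  }
  list(S1 = S1, S2 = S2)
}

# sphere_spec with a prescribed size parameter (radius back-computed)
spec_for_x <- function(x, m, wavelength_nm = 632.8, n_medium = 1.33) {
  sphere_spec(radius_nm = x * wavelength_nm / (2 * pi * n_medium),
              wavelength_nm = wavelength_nm,
              n_particle = m * n_medium, n_medium = n_medium)
}

# synthetic isotropic pure-Mueller element table (s11 constant)
isotropic_elements <- function(n_theta = 200L) {
  th <- seq(0, pi, length.out = n_theta)
  structure(list(theta = th, s11 = rep(1, n_theta), s12 = rep(0, n_theta),
                 s33 = rep(1, n_theta), s34 = rep(0, n_theta),
                 g = 0, norm = 4 * pi, spec = NULL),
            class = "scattering_elements")
}

# small shared medium (Mie tables are cheap but there is no point rebuilding
# them in every test block)
test_medium <- local({
  cache <- NULL
  function(mus_prime = 1.5) {
    if (is.null(cache)) cache <<- make_medium(mus_prime = 1.5)
    if (mus_prime == 1.5) return(cache)
    m <- cache
    m$mu_s_prime <- mus_prime
    m$mu_s <- mus_prime / (1 - m$g)
    m
  }
})
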