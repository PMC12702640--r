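# Optical medium: particle-size distributions, per-event size sampling, bulk
# coefficients, and the Intralipid concentration -> optical property mapping.

#' Discrete particle-size distribution
#'
#' A discrete set of sphere radii with sampling probabilities. Sizes quoted in
#' the lipid-phantom literature are sphere *diameters*; constructors below
#' take diameters and resolve them to radii, which is what all downstream
#' code uses.
#'
#' @param radii_nm Increasing vector of sphere radii (nm).
#' @param weights Non-negative sampling weights, normalised to sum to 1.
#' @param mode `"polydisperse"` or `"monodisperse"` (the latter requires a
#'   single radius).
#' @return Object of class `size_distribution` with fields `radii_nm`,
#'   `weights`, `mode`.
#' @seealso [il_size_distribution()], [monodisperse_distribution()]
#' @export
size_distribution <- function(radii_nm, weights,
                              mode = c("polydisperse", "monodisperse")) {
  mode <- match.arg(mode)
  if (any(radii_nm <= 0)) stop("radii must be positive")
  if (is.unsorted(radii_nm, strictly = TRUE)) stop("radii must be strictly increasing")
  if (length(weights) != length(radii_nm)) stop("weights and radii differ in length")
  if (any(weights < 0) || sum(weights) <= 0) stop("weights must be >= 0 with positive sum")
  if (mode == "monodisperse" && length(radii_nm) != 1L)
    stop("monodisperse mode has exactly one radius")
  structure(list(radii_nm = as.numeric(radii_nm),
                 weights = as.numeric(weights) / sum(weights),
                 mode = mode),
            class = "size_distribution")
}

#' Intralipid-style polydisperse size distribution
#'
#' Discretised number-weighted size distribution emulating the measured
#' droplet sizes of lipid emulsions: an exponentially decaying number density
#' over diameters 20-700 nm (mean diameter of order 100 nm). The true batch
#' distribution can be substituted via [read_size_distribution()] or
#' [size_distribution()].
#'
#' @param diameter_min_nm,diameter_max_nm Support of the diameter grid (nm).
#' @param by_nm Diameter grid step (nm).
#' @param scale_nm Exponential decay scale of the number density (nm).
#' @return A polydisperse [size_distribution()].
#' @export
il_size_distribution <- function(diameter_min_nm = 20, diameter_max_nm = 700,
                                 by_nm = 20, scale_nm = 100) {
  d <- seq(diameter_min_nm, diameter_max_nm, by = by_nm)
  size_distribution(radii_nm = d / 2, weights = exp(-d / scale_nm),
                    mode = "polydisperse")
}

#' Monodisperse size distribution
#'
#' @param size_nm Sphere diameter (nm); default 200.
#' @return A monodisperse [size_distribution()] (radius `size_nm / 2`).
#' @export
monodisperse_distribution <- function(size_nm = 200) {
  size_distribution(radii_nm = size_nm / 2, weights = 1, mode = "monodisperse")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("%s size distribution: %d radii in [%g, %g] nm\n",
              x$mode, length(x$radii_nm), min(x$radii_nm), max(x$radii_nm)))
  invisible(x)
}

#' Draw particle radii from a size distribution
#'
#' Draws `n` radii with the distribution's weights, consuming exactly one
#' uniform deviate per draw from R's RNG stream (so runs are reproducible
#' under `set.seed()`).
#'
#' @param distribution A [size_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of radii (nm).
#' @export
sample_radius <- function(distribution, n = 1) {
  stopifnot(inherits(distribution, "size_distribution"))
  cw <- cumsum(distribution$weights)
  idx <- findInterval(stats::runif(n), cw) + 1L
  distribution$radii_nm[idx]
}

#' Reduced scattering coefficient
#'
#' `mu_s' = (1 - g) * mu_s`, the similarity-scaled scattering coefficient
#' that accounts for the loss of directional momentum per scattering event.
#'
#' @param mu_s Scattering coefficient (mm^-1, > 0).
#' @param g Anisotropy (mean cosine of the scattering angle), in (-1, 1).
#' @return `mu_s'` in mm^-1.
#' @examples
#' reduced_scattering(4, 0.75)  # 1
#' @export
reduced_scattering <- function(mu_s, g) {
  if (any(mu_s <= 0)) stop("'mu_s' must be positive")
  if (any(g <= -1 | g >= 1)) stop("'g' must lie in (-1, 1)")
  (1 - g) * mu_s
}

#' Intralipid optical properties from concentration
#'
#' Empirical wavelength scaling for the scattering coefficient and anisotropy
#' of diluted Intralipid-10% stock (van Staveren-type forms):
#' `mu_s = C * 0.016 * lambda_um^-2.4` per mL of stock per litre of sample,
#' and `g = 1.1 - 0.58 * lambda_um`. Absorption is taken as negligible.
#'
#' @param concentration Volume fraction of Intralipid-10% stock in the sample
#'   (mL/mL, >= 0). Use twice the fraction for an IL-20% stock.
#' @param wavelength_nm Vacuum wavelength (nm), visible/NIR.
#' @param ... Passed on to [make_medium()] (e.g. `distribution`, `n_theta`).
#' @return A [make_medium()] object with `mu_s`, `g`, `mu_s_prime` from the
#'   empirical forms (for `concentration = 0` a plain list with `mu_s = 0`,
#'   since a scatter-free medium is not a valid transport medium).
#' @export
il_optical_properties <- function(concentration, wavelength_nm = 632.8, ...) {
  if (concentration < 0) stop("'concentration' must be >= 0")
  if (wavelength_nm < 300 || wavelength_nm > 2000)
    stop("'wavelength_nm' outside the supported visible/NIR range")
  lam_um <- wavelength_nm / 1000
  mu_s <- concentration * 1000 * 0.016 * lam_um^(-2.4)  # mm^-1
  g <- 1.1 - 0.58 * lam_um
  if (concentration == 0)
    return(list(mu_a = 0, mu_s = 0, g = g, mu_s_prime = 0))
  make_medium(mu_s = mu_s, g = g, mu_a = 0, wavelength_nm = wavelength_nm, ...)
}

#' Read a size-distribution override file
#'
#' Two-column whitespace/tab-separated text with a header `radius_nm weight`.
#'
#' @param path File path.
#' @return A [size_distribution()].
#' @export
read_size_distribution <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  if (!all(c("radius_nm", "weight") %in% names(df)))
    stop("distribution file needs columns 'radius_nm' and 'weight'")
  mode <- if (nrow(df) == 1L) "monodisperse" else "polydisperse"
  size_distribution(df$radius_nm, df$weight, mode = mode)
}

#' Construct a turbid medium
#'
#' Builds the full optical description of a slab medium: bulk coefficients
#' plus the per-radius Mie amplitude/element tables that drive per-event
#' polarised scattering.  Either give the target `mus_prime` (the anisotropy
#' is then the distribution-averaged single-scattering anisotropy and
#' `mu_s = mus_prime / (1 - g)`), or give `mu_s` and `g` explicitly.
#'
#' Per-event particle sizes are drawn with `size_weighting = "number"`
#' (number-weighted, the default) or `"cross_section"` (weights multiplied by
#' each size's Mie scattering cross section, the physical encounter rate for
#' equal-number densities).  The distribution-averaged anisotropy, and hence
#' `mu_s` for a given `mus_prime`, depends on this choice.
#'
#' @param mus_prime Target reduced scattering coefficient (mm^-1), or `NULL`.
#' @param mu_s,g Explicit scattering coefficient (mm^-1) and anisotropy;
#'   used when `mus_prime` is `NULL`.
#' @param mu_a Absorption coefficient (mm^-1, >= 0). Default 0 (negligible
#'   absorption regime).
#' @param distribution A [size_distribution()]. Default [il_size_distribution()].
#' @param wavelength_nm,n_particle,n_medium Optical constants for the Mie
#'   tables (defaults: He-Ne 632.8 nm, soybean oil 1.46 in water 1.33).
#' @param size_weighting `"number"` or `"cross_section"`.
#' @param n_theta Angular resolution of the precomputed tables.
#' @return Object of class `medium`: bulk fields `mu_a`, `mu_s`, `g`,
#'   `mu_s_prime`, `n_medium`, the `distribution` (with effective sampling
#'   weights), per-radius anisotropies `g_per_radius`, the distribution-
#'   averaged `g_eff`, and the internal scattering tables.
#' @export
make_medium <- function(mus_prime = NULL, mu_s = NULL, g = NULL, mu_a = 0,
                        distribution = il_size_distribution(),
                        wavelength_nm = 632.8, n_particle = 1.46,
                        n_medium = 1.33,
                        size_weighting = c("number", "cross_section"),
                        n_theta = 1000L) {
  size_weighting <- match.arg(size_weighting)
  stopifnot(inherits(distribution, "size_distribution"))
  if (mu_a < 0) stop("'mu_a' must be >= 0")
  tab <- build_scatter_tables(distribution, wavelength_nm, n_particle,
                              n_medium, size_weighting, n_theta)
  if (!is.null(mus_prime)) {
    if (mus_prime <= 0) stop("'mus_prime' must be positive")
    g_bulk <- tab$g_eff
    mu_s <- mus_prime / (1 - g_bulk)
  } else {
    if (is.null(mu_s) || is.null(g))
      stop("give either 'mus_prime' or both 'mu_s' and 'g'")
    if (g <= -1 || g >= 1) stop("'g' must lie in (-1, 1)")
    if (mu_s <= 0) stop("'mu_s' must be positive")
    g_bulk <- g
    mus_prime <- reduced_scattering(mu_s, g)
  }
  structure(list(
    mu_a = mu_a, mu_s = mu_s, g = g_bulk, mu_s_prime = mus_prime,
    n_medium = n_medium, wavelength_nm = wavelength_nm,
    n_particle = n_particle, size_weighting = size_weighting,
    distribution = tab$distribution,
    g_per_radius = tab$g_per_radius, g_eff = tab$g_eff,
    tables = tab$tables
  ), class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf(paste0("turbid medium: mu_a = %g, mu_s = %.4g, g = %.4f, ",
                     "mu_s' = %.4g mm^-1\n  %s sizes (%s-weighted), ",
                     "lambda = %g nm, n = %g/%g\n"),
              x$mu_a, x$mu_s, x$g, x$mu_s_prime,
              x$distribution$mode, x$size_weighting,
              x$wavelength_nm, x$n_particle, x$n_medium))
  invisible(x)
}

# Precompute per-radius complex amplitude tables (exact-purity interpolation
# in the transport core), per-radius rejection envelopes, anisotropies and
# effective sampling weights.
build_scatter_tables <- function(distribution, wavelength_nm, n_particle,
                                 n_medium, size_weighting, n_theta) {
  theta <- seq(0, pi, length.out = n_theta)
  K <- length(distribution$radii_nm)
  re1 <- im1 <- re2 <- im2 <- matrix(0, n_theta, K)
  g_i <- numeric(K)
  csca <- numeric(K)
  max_s11 <- numeric(K)
  max_as12 <- numeric(K)
  for (k in seq_len(K)) {
    sp <- sphere_spec(distribution$radii_nm[k], wavelength_nm, n_particle, n_medium)
    amp <- mie_amplitudes(sp, theta)
    el <- scattering_elements(amp)
    re1[, k] <- Re(amp$S1); im1[, k] <- Im(amp$S1)
    re2[, k] <- Re(amp$S2); im2[, k] <- Im(amp$S2)
    g_i[k] <- el$g
    csca[k] <- mie_efficiencies(sp)$Csca_nm2
    max_s11[k] <- max(el$s11)
    max_as12[k] <- max(abs(el$s12))
  }
  w <- distribution$weights
  if (size_weighting == "cross_section") w <- w * csca
  w <- w / sum(w)
  dist_eff <- size_distribution(distribution$radii_nm, w, mode = distribution$mode)
  list(distribution = dist_eff,
       g_per_radius = g_i,
       g_eff = sum(w * g_i),
       tables = list(theta = theta, re1 = re1, im1 = im1, re2 = re2, im2 = im2,
                     max_s11 = max_s11, max_as12 = max_as12,
                     cum_w = cumsum(w), csca = csca))
}

#' The five study media
#'
#' Convenience constructor for the phantom set used throughout the sweeps:
#' reduced scattering coefficients 0.5, 1, 1.5, 2 and 3 mm^-1 sharing one
#' size distribution (Mie tables are computed once and reused).
#'
#' @param mus_primes Reduced scattering grid (mm^-1).
#' @param ... Passed to [make_medium()].
#' @return Named list of `medium` objects (names like `"mus_prime=1.5"`).
#' @export
study_media <- function(mus_primes = c(0.5, 1, 1.5, 2, 3), ...) {
  base <- make_medium(mus_prime = mus_primes[1], ...)
  out <- lapply(mus_primes, function(mp) {
    m <- base
    m$mu_s_prime <- mp
    m$mu_s <- mp / (1 - m$g)
    m
  })
  names(out) <- paste0("mus_prime=", mus_primes)
  out
}
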