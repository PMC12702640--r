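# qsense

Polarized-light Monte Carlo simulation of turbid slabs and **Q-sensing**:
extracting the reduced scattering coefficient of a scattering medium from
the polarization memory of its backscattered light.

## The problem

Light backscattered from tissue or a tissue-mimicking phantom mixes a
superficial, still-polarized component with a deep, multiply-scattered,
depolarized background. Reading the co-polarized and cross-polarized
intensities I&#8741; and I&#8869; through a linear analyzer and forming

```
Q' = (I∥ − I⊥) / (I∥ + I⊥)
```

isolates the superficial fraction: with the decomposition
I&#8741; = I_s + I_d/2, I&#8869; = I_d/2 (superficial I_s, diffuse I_d),
Q' = I_s / (I_s + I_d). As a slab thickens, Q' decays to a plateau that is
unique to the medium's reduced scattering coefficient
μ_s' = (1 − g)·μ_s — so a converged Q' reading measures μ_s'.

The package implements the full computational chain for users in
biomedical optics and phantom metrology:

- **Mie optics** — complex amplitudes S1, S2 and the scattering-matrix
  elements s11, s12, s33, s34 (with s11² = s12² + s33² + s34²) per
  particle size, anisotropy and phase-function normalization
  (`sphere_spec()`, `mie_amplitudes()`, `scattering_elements()`).
- **Polydisperse media** — lipid-emulsion size distributions with
  per-event size resampling, number- or cross-section-weighted; bulk
  μ_a, μ_s, g, μ_s'; an Intralipid concentration → optical-property
  mapping (`make_medium()`, `il_size_distribution()`,
  `il_optical_properties()`).
- **Meridian-plane Monte Carlo** — Stokes-vector transport in a slab:
  pencil-beam launch at 45° with horizontal polarization (1,1,0,0),
  exponential steps s = −ln(z)/(μ_a+μ_s), rejection-sampled scattering
  angles from the bivariate phase function
  P(θ,ψ) = s11·I + s12·(Q cos2ψ + U sin2ψ), pure-Mueller Stokes updates,
  binary death rules with a 1000-event cap, and lens-like detection at
  the illumination center (`run_transport()`; compiled core).
- **Q-sensing sweeps and inversion** — thickness and μ_s' sweeps with
  Monte Carlo error bars, a monotone 10-mm calibration curve, and the
  bootstrap-propagated extraction of μ_s' from a measured Q'
  (`thickness_sweep()`, `mus_prime_sweep()`, `build_calibration()`,
  `invert_mus_prime()`).

## Worked example

Build the μ_s' = 1.5 mm⁻¹ phantom, watch Q' decay and converge, then
recover an unknown μ_s' from a fresh simulated measurement:

```r
library(qsense)
med <- make_medium(mus_prime = 1.5)
med
#> turbid medium: mu_a = 0, mu_s = 1.735, g = 0.1352, mu_s' = 1.5 mm^-1
#>   polydisperse sizes (number-weighted), lambda = 632.8 nm, n = 1.46/1.33

sw <- thickness_sweep(med, c(0.6, 1, 2, 5, 10), n_photons = 1e5, seed = 1)
#>  thickness_mm I_par I_perp Q_prime se_Q_prime
#>           0.6  4736   1610  0.4928   0.006777
#>           1.0  6622   2589  0.4378   0.008246
#>           2.0  7934   3842  0.3475   0.007456
#>           5.0  8525   4264  0.3332   0.008214
#>          10.0  8827   4438  0.3309   0.004937
```

Thin slabs keep the light polarized (Q' ≈ 0.49 at 0.6 mm); by 5–10 mm Q'
has converged to the plateau (≈ 0.331) characteristic of this medium.
Calibrate the plateau against μ_s' and invert a measurement:

```r
cal <- build_calibration(n_photons = 1e5, seed = 2)
cal
#> Q' calibration at 10 mm (1e+05 photons/point):
#>  mus_prime   q_prime          se
#>        0.5 0.5209853 0.007026285
#>        1.0 0.3956063 0.005521562
#>        1.5 0.3251786 0.004326333
#>        2.0 0.2898063 0.004735450
#>        3.0 0.2553598 0.003871596

tr <- run_transport(make_medium(mus_prime = 1.25), slab_geometry(10), 1e5, seed = 3)
qs <- q_sense_result(tr)
#> measured Q' = 0.3475 +- 0.0063
invert_mus_prime(cal, qs$Q_prime, qs$se_Q_prime)
#> extracted mu_s' = 1.295 mm^-1 (95% interval 1.12 - 1.44)
```

The true value 1.25 mm⁻¹ lies inside the propagated interval. The curve
declines sharply below 1 mm⁻¹ and flattens toward 3 mm⁻¹, where
`invert_mus_prime()` flags low sensitivity.

A command-line front end (`inst/cli/qsense`) exposes the same pipeline as
`sweep-thickness`, `sweep-mus`, `calibrate` and `invert` subcommands.

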