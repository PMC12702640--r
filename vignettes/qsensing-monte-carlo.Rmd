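---
title: "Polarized Monte Carlo transport and Q-sensing: models, assumptions, choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarized Monte Carlo transport and Q-sensing: models, assumptions, choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsense)
```

## The problem

Backscattered light from a turbid medium (tissue, or a lipid-emulsion
phantom mimicking it) mixes two populations: superficially scattered
photons that still carry the illumination's polarization, and multiply
scattered photons from deeper layers that have lost it. Detecting the
co-polarized intensity $I_\parallel$ and the cross-polarized intensity
$I_\perp$ through a linear analyzer separates them. With the model
decomposition $I_\parallel = I_s + I_d/2$ and $I_\perp = I_d/2$
(superficial $I_s$, diffuse $I_d$ split evenly between the channels),

$$ I = I_\parallel + I_\perp,\qquad Q = I_\parallel - I_\perp = I_s,\qquad
   Q' = \frac{I_\parallel - I_\perp}{I_\parallel + I_\perp} = \frac{I_s}{I_s + I_d}, $$

so the normalized statistic $Q'$ is the fraction of detected light that
still remembers the launch polarization. As a slab thickens, $Q'$ decays to
a plateau set by the medium's scattering properties; in the converged
regime the map from the reduced scattering coefficient
$\mu_s' = (1-g)\,\mu_s$ to the plateau $Q'$ is monotone and can be
inverted to *measure* $\mu_s'$.

This package provides the three pieces of machinery behind that
measurement: exact single-sphere Mie optics, a meridian-plane polarized
Monte Carlo for slab reflectance, and the calibration/inversion layer.

## Single-scattering model

A homogeneous sphere of radius $r$ in a host of index $n_{med}$ at vacuum
wavelength $\lambda$ has size parameter $x = 2\pi r\, n_{med}/\lambda$ and
relative index $m$. The Mie series gives complex amplitudes
$S_1(\theta)$, $S_2(\theta)$, from which the four scattering-matrix
elements follow:

$$ s_{11} = \tfrac12(|S_2|^2 + |S_1|^2),\quad
   s_{12} = \tfrac12(|S_2|^2 - |S_1|^2),\quad
   s_{33} = \mathrm{Re}(S_2^* S_1),\quad
   s_{34} = \mathrm{Im}(S_2^* S_1), $$

with the purity identity $s_{11}^2 = s_{12}^2 + s_{33}^2 + s_{34}^2$
(only three elements are independent; the Mueller matrix is
Jones-derivable). The series is summed with the standard Wiscombe term
count and a logarithmic-derivative downward recurrence; the test suite
checks it against a separately written Riccati–Bessel oracle to $10^{-8}$
relative, the Rayleigh closed form at $x = 0.01$, and the purity identity
to $10^{-9}$ relative.

For a polarized photon with Stokes vector $(I,Q,U,V)$, the joint density
of the scattering angle $\theta$ and the azimuth $\psi$ of the scattering
plane is the bivariate phase function

$$ P(\theta,\psi) = s_{11}(\theta)\, I + s_{12}(\theta)\,
   (Q\cos 2\psi + U\sin 2\psi), $$

sampled (together with the $\sin\theta$ measure) by rejection from a
uniform proposal in $(\cos\theta, \psi)$. The envelope constant is the
tabulated maximum of $s_{11}$ times $(I + \sqrt{Q^2+U^2})$ with a 1.01
safety factor; since $|s_{12}| \le s_{11}$ pointwise and $|S_i(t)|^2$ is
convex along a linear interpolation segment, this envelope provably
dominates everywhere, not just at the grid knots.

**Angular tables.** Elements are tabulated on 1000 uniform angles in
$[0,\pi]$ per particle size (configurable). The transport core
interpolates the *complex amplitudes* between knots and forms the Mueller
elements from the interpolated values, so every per-event matrix is
exactly pure and a photon's degree of polarization stays 1 to machine
precision over thousand-event chains. Interpolating the four elements
separately (the more obvious choice) leaves $O(h^2)$ purity violations
that accumulate visibly over long chains.

## The medium

**Size distribution.** Lipid emulsions are polydisperse. The default
distribution emulates the measured droplet sizes of Intralipid-type
emulsions: an exponentially decaying *number* density over diameters
20–700 nm with a 100 nm decay scale, discretised in 20 nm steps.
Literature sizes are diameters; the package resolves them to radii
internally (a monodisperse "200 nm" medium is a 100 nm-radius sphere).
Any (radius, weight) table can be substituted from a file.

**Per-event size draws.** At every scattering event the photon meets a
freshly drawn droplet size and uses that size's scattering matrix. Two
weighting conventions are provided: number-weighted draws (default) and
cross-section-weighted draws (each size's weight multiplied by its Mie
scattering cross section — the physical encounter rate for equal number
densities). The literature description of the procedure does not fix the
convention, so neither is asserted as canonical; the effective
single-scattering anisotropy, and hence the $\mu_s$ that realises a target
$\mu_s'$, is always computed from the convention actually in use. The step
length, in contrast, always uses the *medium-average* $\mu_s$ — the free
path does not change with the particle size drawn at an event.

**Bulk coefficients.** A medium built from a target $\mu_s'$ uses the
distribution-averaged anisotropy $\bar g = \sum_i w_i g_i$ and
$\mu_s = \mu_s'/(1-\bar g)$, so $\mu_s' = (1-g)\mu_s$ holds exactly for
the simulated medium. With number weighting the default distribution has
$\bar g \approx 0.135$: small droplets dominate the draw count, so the
effective phase function is far more isotropic than the
cross-section-weighted bulk anisotropy ($\approx 0.7$) familiar from
integrating-sphere characterisations of lipid phantoms. Both conventions
are available; comparisons with instruments that report bulk $g$ should
use the cross-section mode. The concentration mapping
`il_optical_properties()` implements the empirical wavelength forms for
diluted Intralipid-10% stock ($\mu_s = C\,·\,0.016\,\lambda_{\mu m}^{-2.4}$
per mL/L, $g = 1.1 - 0.58\lambda_{\mu m}$); absorption defaults to zero
(negligible-absorption regime) and can be set positive.

## Transport

Photons launch as a pencil beam at the origin of the top surface with
Stokes $(1,1,0,0)$ — horizontal polarization in the incidence meridian —
at 45° from the normal (the bench geometry; the angle is configurable,
and the symmetry tests use 0°). Free paths are exponential with rate
$\mu_a + \mu_s$; at each interaction the photon dies with probability
$\mu_a/(\mu_a+\mu_s)$ (binary rule, default) or carries a continuous
weight with Russian roulette (variance-reduction mode). A photon dies
when it leaves the slab (top or bottom), is absorbed, or exceeds 1000
scattering events.

Polarization bookkeeping follows the meridian-plane method: the Stokes
vector is referenced to the plane containing the propagation direction
and the depth axis. Each event rotates the reference frame by $\psi$ into
the scattering plane (a $2\psi$ rotation on $(Q,U)$), applies the sphere
Mueller matrix at $\theta$, and rotates back into the new direction's
meridian plane. The implementation carries explicit orthonormal triads
$(v, w, k)$ with $v \times w = k$, which fixes every rotation sign by
construction; at the measure-zero pole configurations ($|k_z| = 1$, where
the meridian is undefined) the rotated scattering frame is carried
forward unchanged. After the Mueller multiplication the Stokes vector is
rescaled so $I$ equals the photon weight — the intensity factor is
already accounted for by sampling the angles from $P(\theta,\psi)$.

Boundaries are index-matched by default (no refraction, no Fresnel
reflection). An optional Fresnel mode applies Snell bending and
polarization-resolved Fresnel reflection/transmission at both surfaces
(total-internal-reflection phase shifts on $U$, $V$ are neglected — the
mode is for sensitivity studies, not default physics).

**Detection.** A photon exiting the top surface is accepted if its exit
point lies within 2 mm of the beam entry and its direction within a cone
about the surface normal, then its Stokes vector is rotated into the
fixed detector frame (parallel axis = lab $x$ projected transverse to the
exit direction, matching the launch polarization axis) and superposed.
The acceptance half-angle default is 30°, modelling a lens-coupled
photodiode above the illumination spot. This choice matters: with a
hemispheric detector (90°), grazing single-scattered exits — light no
physical detector at a distance collects — dominate thin weakly
scattering slabs and *invert* the thin-slab trend of $Q'$ for
$\mu_s' = 0.5\ \mathrm{mm^{-1}}$; a finite cone restores the monotone
decay observed on the bench. Both the radius and the cone are
configurable.

## Observables and errors

$I_\parallel = (I+Q)/2$ and $I_\perp = (I-Q)/2$ are the analyzer
projections of the summed detector Stokes vector, and
$Q' = Q/I$. Photons run in ten consecutive batches; the batch-to-batch
spread of $Q'$ gives its standard error (verified against run-to-run
spread). Sweeps over thickness (the 19-point design: 0.6–1.5 mm in
0.1 mm steps, 2–10 mm in 1 mm steps) and over
$\mu_s' \in \{0.5, 1, 1.5, 2, 3\}\ \mathrm{mm^{-1}}$ reproduce the
qualitative behaviour of bench measurements on lipid phantoms: monotone
$Q'$ decay to a nonzero plateau per medium, plateaus ordered inversely
with $\mu_s'$, and a $Q'(\mu_s')$ curve that declines sharply below
$1\ \mathrm{mm^{-1}}$ and flattens toward $3\ \mathrm{mm^{-1}}$.

## Inversion

`build_calibration()` runs the $\mu_s'$ sweep at a converged thickness
(default 10 mm, the configurable convergence threshold) and refuses
curves that rise anywhere by more than three combined standard errors. A
strictly decreasing fit (isotonic regression plus an epsilon separation
far below the MC noise) feeds a monotone shape-preserving (Hyman) cubic
on the inverse map $Q' \to \mu_s'$.

Uncertainty is propagated by parametric bootstrap: knots redrawn from
their MC errors, the measurement redrawn from its own error combined with
the grid's leave-one-out interpolation error, each draw re-inverted, and
the 95% percentile interval reported (clamped to the calibration domain;
an internal fixed RNG stream keeps the function deterministic). The
interval therefore reflects measurement noise, curve noise including its
leverage through the interpolant, and the coarseness of the five-point
grid. Queries where the local sensitivity $|dQ'/d\mu_s'|$ falls below
0.02 per mm$^{-1}$ (configurable) are flagged low-confidence — the flat
regime near $3\ \mathrm{mm^{-1}}$ is genuinely hard to identify. Values
outside the calibrated $Q'$ range are refused rather than extrapolated.
Extraction assumes the measurement shares the calibration's anisotropy
and absorption; that caveat travels in the curve metadata.

## Problem sizes and what the tests show

Unit and property tests run at $10^4$–$10^5$ photons per cell and the
trend/recovery checks at $10^5$; production sweeps would use the $10^7$
budget of a full study, which the same code paths handle (the core is
compiled, roughly 10⁶ photon·events per second per mm$^{-1}$). Passing
tests demonstrate internal correctness (oracle agreement, conservation,
purity, symmetry nulls, seed determinism) and agreement with the
*qualitative* published behaviour of lipid phantoms. They do not certify
quantitative agreement with any particular bench: the synthetic medium
omits droplet-distribution batch variation, water absorption, polarizer
leakage, detector response, and the finite illumination spot, all of
which shift absolute $Q'$ values.

## Known limitations

- Single wavelength per medium; no dispersion sweeps.
- Laterally unbounded single slab; no layered media or finite dishes.
- Circular polarization is tracked but not launched by default.
- The Fresnel boundary mode neglects total-internal-reflection phase
  shifts.
- Joint inversion of $(\mu_s', g, \mu_a)$ is out of scope; the
  calibration is valid only for media sharing the calibration's
  anisotropy and absorption.
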