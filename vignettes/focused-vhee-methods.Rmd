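---
title: "Focused VHEE dose delivery: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focused VHEE dose delivery: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vheefocus` models the delivery of focused very-high-energy-electron (VHEE,
50–250 MeV) radiotherapy beams: a quadrupole lattice focuses the beam into a
water phantom, and the package predicts where the on-axis dose peaks, how
much dose the entrance region receives, and how beampipe collimation and
magnet settings change both. This vignette explains the physics models, the
numerical choices, and what the synthetic studies do and do not show about
real beams.

## Beam model

Each transverse plane is described by Courant–Snyder (Twiss) parameters
$(\alpha, \beta)$ and the geometric emittance $\varepsilon$, with rms beam
size $\sigma = \sqrt{\varepsilon\beta}$. Magnet strengths follow the
electron rigidity relation $g = E\,K/300$ ($g$ in T/m, $E$ in MeV, $K$ in
m$^{-2}$) and the excitation constant 0.057 T/m per ampere used for the
quadrupole class modelled here. Quadrupoles are hard-edge thick lenses
(cos/sin in the focusing plane, cosh/sinh in the other); there are no fringe
fields, dipoles or longitudinal dynamics. Positive $K$ focuses in $x$;
inverting a magnet's polarity negates $K$.

Twiss reconstruction from quadrupole scans solves the linear system
$\sigma^2_{\mathrm{screen}}(K) = M_{11}^2\sigma_{11} +
2M_{11}M_{12}\sigma_{12} + M_{12}^2\sigma_{22}$ by ordinary least squares in
the sigma-matrix elements, which is deterministic and needs no starting
values; fits with $\sigma_{11}\sigma_{22}-\sigma_{12}^2 \le 0$ are rejected
as non-physical. On noiseless synthetic scans the round trip through the
generator is exact to better than $10^{-6}$ relative; with 1% size noise
and 20 scan points the parameters return within a few per cent.

## Monte Carlo transport

The condensed-history Monte Carlo advances every particle of a sampled
bunch element by element:

* **Vacuum**: the exact thick-lens/drift maps, with the per-particle
  chromatic strength $K\,E_0/E$. Vacuum transport therefore reproduces
  matrix optics to machine precision — this is asserted in the tests.
* **Media** (water, air, PMMA, windows): per step, a multiple-Coulomb-
  scattering kick with the Highland rms angle
  $\theta_0 = \frac{13.6\,\mathrm{MeV}}{\beta c p}\sqrt{t}\,
  (1 + 0.038\ln t)$, $t = \mathrm{d}z/X_0$, jointly sampled with the
  correlated lateral displacement (variance
  $\mathrm{d}z^2\theta_0^2/3$, correlation $\sqrt{3}/2$). Step sizes:
  1 mm in water/PMMA, 5 mm in air, one step through thin windows. Applying
  the Highland formula per step rather than per path underestimates the
  accumulated variance by order 10% (the logarithmic term is evaluated on
  the step); the moment oracle used in the tests makes the identical choice,
  so the comparison isolates sampling errors.
* **Energy**: continuous slowing-down with a constant collisional stopping
  power per material (water 2.0 MeV/cm near 200 MeV) plus the radiative
  loss $E\,\mathrm{d}z/X_0$, which is removed from the particle but *not*
  deposited (bremsstrahlung photons are assumed to escape the narrow
  scoring column). Particles below 1 MeV are stopped.
* **Collimation**: wherever a beampipe is present its aperture is checked
  every step; particles reaching the inner wall are absorbed rather than
  transported through steel. Grazing incidence would give long steel paths,
  so surviving wall-grazers are rare in reality; the approximation slightly
  overestimates collimation losses.

Dose is scored in 1 mm isotropic voxels over a ±5 cm lateral window: each
step inside the phantom deposits its collisional loss at the step midpoint.
The on-axis depth-dose curve sums the central 0.3 cm × 0.3 cm voxel column
and is normalised to 100% at its maximum. The peak depth is the argmax of
the 5 mm moving-average-smoothed curve; where sub-voxel precision matters
(the final-quadrupole scan) the argmax is refined by the vertex of a
quadratic fitted to the raw curve within ±1.5 cm, which brings the
seed-to-seed scatter of the estimate from ~0.7 mm to ~0.1 mm at
$n = 10^5$. The entrance dose is the mean percentage over the first
centimetre. Lateral HWHM values interpolate the half-maximum crossings of
the profile through the slice maximum.

With a *vacuum* phantom (used for medium-comparison studies), particle
counts are scored instead of energy deposits: a fluence proxy that mimics
the films-in-a-medium-free-phantom measurement and keeps the percentage
curves comparable.

## Focusing optimisation

Optimising quadrupole strengths with pure vacuum optics — minimising the
spot size at the target plane — fails in two instructive ways in a
scattering medium. First, scattering moves the realised dose peak
*shallower* than the vacuum waist, by
$\Delta z \approx \frac{\mathrm{d}\sigma_s^2/\mathrm{d}z}{2\theta^2}$
for convergence angle $\theta$: a solution aimed at 15 cm peaks at 10 cm.
Second, the spot-size landscape near a waist is extremely flat, so local
optimisers settle on weakly converging solutions whose on-axis dose barely
rises above the entrance level: deep, low-entrance dose needs a *large*
beam at the phantom entrance squeezed through a *large* angle, which the
plain objective cannot see.

`optimize_strengths` therefore works on an analytic on-axis fluence model:
per plane, the beam variance at depth $z$ is the vacuum envelope
(closed-form drift propagation of the entrance Twiss parameters) plus, in
quadrature, the Fermi–Eyges pencil spread
$\sigma_s^2(z) = \sum_i \theta_{0,i}^2 (h^2/3 + h R_i + R_i^2)$ accumulated
in the phantom medium with CSDA energy degradation; the on-axis fluence is
the inverse product of the rms sizes. The objective maximises the fluence
at the target depth relative to the entrance fluence. The entrance reward
saturates harmonically at the collimation scale (the smallest pipe radius)
and is penalised above it — a beam larger than the pipe is simply cut, so
growing it further buys nothing. The search is deterministic: a fixed
strength grid over all sign patterns seeds Nelder–Mead polishes of a fast
scalar stage (spot size floored by $\sigma_s$ at an aim depth, iterated so
the modelled fluence peak lands on the target), and the candidate whose
modelled peak sits closest to the target (best contrast on ties) wins.
Single-plane focusing — the configuration of fixed user beamlines where
both planes cannot be focused simultaneously — is expressed with
`weight_x` and per-plane entrance weights: the focused plane gets the
fluence objective, the other is kept small and non-diverging.

The model's predicted peak agrees with the full Monte Carlo to a few
millimetres; the residual bias (the model ignores collimation reshaping and
the smoothing of the peak estimator) is visible in the studies as realised
peaks ~0.5–1 cm shallower than requested.

## Preset geometries and study conditions

Two lattices are built in:

* **compact** — five 22.6 cm quadrupoles separated by 25 cm drifts inside a
  stainless-steel pipe (3 mm wall, inner radius 1.9–8.9 cm), an 11 cm air
  gap, and a 30 cm water cube. Beam: 201 MeV, 2 MeV rms spread, round
  0.5 mm sigma. The initial divergence is not part of the stated
  conditions; the default emittance $1.25\times10^{-8}$ m·rad (25 µrad
  divergence at 0.5 mm) is the smallest meaningfully samplable
  approximation of a zero-divergence beam and is exposed through the beam
  block for sensitivity studies.
* **clear_like** — the final six quadrupoles of a fixed user beamline: a
  triplet, a long drift, a doublet, the vacuum pipe ending at a 0.1 mm
  mylar window 139 cm after the last doublet quad, an in-air final
  quadrupole, 12 cm of air, a 0.1 mm Kapton window and a 10 × 14 × 41 cm
  water tank (pipe radius 1.9 cm). Only the distances just listed are
  documented for this machine class; the triplet and doublet spacings
  (0.35 m and 0.77 m) and the 9 m inter-group drift were fixed once as
  plausible values and live in the preset. The upstream strengths for the
  final-quadrupole scan are not documented either: `clear_quad_scan_study`
  reconstructs them at run time by optimising the five upstream quads with
  the final quad pinned to its 240 A strength, targeting the documented
  operating depth of 5.2 cm, with the focused-plane entrance saturating at
  the 3 mm film scale. The scan then varies only the final-quad current.

## What the synthetic studies show — and what they do not

All inputs are synthetic and seeded: Gaussian bunches from Twiss
parameters, quadrupole-scan tables from the forward transfer-matrix model,
calibration sets and film stacks from the inverted dose-response model.
Every generator stores its ground truth, so recovery tests close the loop
without external data. What passing tests demonstrate is *internal*
fidelity: transport equals matrix optics in vacuum, scattering moments
follow the Highland/Fermi–Eyges closed forms, estimators invert their
generators. They do not validate the condensed-history approximation
against a full physics Monte Carlo: secondary electrons, photon transport
and nuclear interactions are out of scope. Two visible consequences: the
entrance dose is overestimated (secondary-electron buildup, absent here,
suppresses the measured surface dose relative to depth), and the
final-quadrupole scan slope comes out steeper (≈ −0.08 cm/A) than the
−0.06 ± 0.01 cm/A a full-physics reconstruction of this class of
experiment reports, while its linearity (adjusted R² ≥ 0.999) and sign are
reproduced.

Problem sizes were chosen so the full study suite runs comfortably on a
single core: $2\times10^5$ particles for compact-lattice dose curves,
$10^5$ per scan point, $10^5$ for moment-level property checks.

## Film dosimetry

Film images are 16-bit RGB scans (300 dpi default) with per-channel
unexposed reference values. Optical density is
$OD = -\log_{10}(PV/PV_0)$ and dose calibration fits
$D = a\,b^{OD} + c$ by Levenberg–Marquardt with unit weights (no per-point
uncertainties are available, so the reported reduced $\chi^2$ is in
residual-variance units). The model is ill-conditioned — $a$ and $c$ are
strongly anti-correlated with $a \approx -c$ — so the fit is initialised
from $c_0 = -\max D$ and a log-linear regression of $\log(D - c_0)$ on
$OD$, with deterministic restarts at perturbed growth rates. All three
channels are fitted; a channel whose reduced $\chi^2$ exceeds five times
the best channel's is flagged unusable (the blue channel typically fails
this test).

Dose maps are analysed the way scanned films are read: a separable 10 px
moving average (0.85 mm at 300 dpi; use a smaller window for coarser
pixels), maximum located by alternating coordinate search to a fixed point
with low-index tie-breaks, HWHM from interpolated half-maximum crossings of
the raw profiles through the maximum. The reported on-axis dose is the
smoothed-map maximum; the 10 × 10 unsmoothed patch average around it is the
standard consistency check (sub-percent agreement on broad spots, large
discrepancies flagging non-representative maxima). Uncertainty components
combine in quadrature.

## Degenerate inputs and numerical conventions

Voxels are half-open $[z, z+\mathrm{d}z)$ with 1-based indices and the
lateral origin at the central voxel centre. Aperture hits are inclusive
($r \ge R$ is absorbed). Equal depth-dose maxima resolve to the shallower
depth; equal map maxima to the lowest index. Empty dose grids, flat
profiles, underdetermined fits and non-physical sigma matrices signal
classed conditions (`vhee_empty_dose`, `vhee_unresolved_width`,
`vhee_underdetermined_fit`, `vhee_nonphysical_fit`) rather than returning
sentinel values. All randomness flows from a single integer seed recorded
in every manifest; identical configuration and seed reproduce every output
byte for byte.
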