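---
title: "Magnetically focussed proton minibeams: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetically focussed proton minibeams: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minibeam)
```

Proton minibeam radiation therapy (pMBRT) irradiates tissue with
submillimetric beams (FWHM <= 1 mm) separated by millimetre-scale gaps,
producing alternating dose peaks and valleys whose ratio (PVDR) correlates
with normal-tissue sparing. This package simulates, at desk scale, whether
and how a clinical pencil-beam-scanning nozzle can produce such minibeams
purely by magnetic focussing, and what dose patterns the resulting
minibeam grids deposit in a water phantom. This vignette documents the
models, their assumptions, the tunable parameters, and the design choices
made where the problem left them open.

## The beam model

The beam at the nozzle entrance is bi-Gaussian in each transverse plane
and characterised by six parameters: position spreads $\sigma_x,\sigma_y$
(mm), angular spreads $x',y'$ (mrad), and position--angle correlations
$r_{xx'},r_{yy'} \in [-1,1]$. The per-plane RMS emittance is

$$\varepsilon_x = \sigma_x\, x' \sqrt{1-r_{xx'}^2}\ \text{(mm mrad)},$$

conserved under magnetic transport (Liouville); the package standardises
on this plain RMS product (no factor $\pi$). $|r|=1$ describes a perfectly
convergent or divergent beam of zero emittance -- the covariance matrix is
then singular, so `sample_particles()` draws the position and sets the
angle deterministically on the correlation line rather than factorising
the covariance. Kinetic energies are Gaussian with fractional spread
(default 1%, typical for cyclotron beams) and truncated at zero by
resampling, a negligible correction at that spread.

## Transport

Transport exists in two modes that are held equivalent by the test suite:

* **Envelope mode** propagates the per-plane $2\times 2$ covariance matrix
  through hard-edge transfer maps. Quadrupoles use the standard
  $\cos/\cosh$ forms with focusing strength
  $k = (B_\text{tip}/a)/(B\rho)$, where $B_\text{tip}$ is the pole-tip
  field, $a$ the aperture radius and $B\rho$ the magnetic rigidity.
  Chromatic effects are captured by averaging the covariance over
  Gauss--Hermite nodes of the energy distribution (7 nodes by default);
  each node propagates with its own rigidity, so the growth of a focal
  spot with energy spread appears without any Monte Carlo.
* **Monte Carlo mode** pushes individual particles through the same maps
  evaluated at each particle's own momentum, which produces chromatic
  aberration naturally.

Multiple Coulomb scattering uses the Highland parametrisation
$\theta_0 = \frac{13.6\,\text{MeV}}{pv}\sqrt{t/X_0}\,
[1+0.038\ln(t/X_0)]$ with radiation lengths $X_0$ of 303.9 m (air) and
36.08 cm (water); thin windows and ionisation chambers are treated as
water-equivalent slabs. Only the Gaussian core is modelled -- no Moliere
tails, no nuclear interactions. In envelope mode a scattering segment of
length $L$ adds the Fermi--Eyges increments
$(\theta_0^2 L^2/3,\ \theta_0^2 L/2,\ \theta_0^2)$ to
(position variance, covariance, angular variance), exact for a uniform
scattering power; in Monte Carlo mode the same total variance is
distributed over sub-steps (default 5 cm) with the standard correlated
angle/displacement sampling, making the two modes agree in expectation by
construction. Energy loss upstream of the phantom is neglected
(< 0.3 MeV/m in air); it only matters in water, where the dose engine
handles it.

## Nozzle geometries

No element positions or material budgets of the clinical nozzle are
publicly printed, so the presets ship *stated assumptions*, all
overridable:

* `icpo_current` (and its three modifications) places the isocentre
  250 cm from the vacuum window, with two ~1 mm water-equivalent
  ionisation chambers and quadrupoles and scanning dipoles in air.
* `optimized` is the compact design: the source sits at the vacuum-tank
  entrance, followed by a short doublet (12 cm quadrupoles, 3 cm aperture
  radius) in vacuum, two thin scanning-dipole kicks, a 0.1 mm WET vacuum
  window and a 0.6 mm WET transmission ionisation chamber, then a 10 or
  30 cm air gap. The focal length (Q2 exit to target) defaults to 100 cm,
  the middle of the 90--110 cm design band.

Two of these numbers deserve their rationale:

* **The front end is short (28 cm).** A beam with $r = -1$ converges by
  itself to a crossover at $z = \sigma/x'$ -- about 1.3 m for the
  reference sources. A quadrupole doublet nets *focusing* in both planes
  (thin-lens composition: $1/f_x + 1/f_y = 2d/(f_1 f_2) > 0$), so it can
  pull a crossover earlier but never delay it in both planes at once.
  The entire focusing section must therefore sit upstream of the
  crossover, i.e. source-to-target must not exceed
  $\sigma/x' \approx 1.3$ m. With a 100 cm focal length that leaves less
  than 30 cm for the doublet.
* **The aperture radius is 3 cm.** At 200 MeV the rigidity is
  2.15 T m; imaging the reference sources onto the target requires a net
  doublet power around 1 m$^{-1}$, which at the 2 T pole-tip limit of
  normal-conducting magnets requires a gradient of order 60 T/m -- hence
  a small bore. At 100 MeV the same doublet is comfortably strong.

The 0.6 mm WET monitoring chamber is a typical budget for a thin
transmission chamber; it is the dominant scattering source in front of
the air gap and therefore directly visible in the minimised beam sizes.

## The quadrupole grid search

`scan_quadrupoles()` evaluates every configuration of the field grid
(default 0--2 T in 0.04 T steps, 51 values per quadrupole, both
focus-plane arrangements: $51\times51\times2 = 5202$ configurations)
and minimises

$$\Omega = (\mathrm{hFWHM}\cdot\mathrm{vFWHM})
 \left(\frac{\mathrm{hFWHM}}{\mathrm{vFWHM}}
 + \frac{\mathrm{vFWHM}}{\mathrm{hFWHM}}\right)
 = \mathrm{hFWHM}^2 + \mathrm{vFWHM}^2,$$

which favours small *and* symmetric spots. The scan is two-stage: the
full grid runs in vectorised envelope mode, then the best configurations
(default 20) are re-simulated by Monte Carlo tracking (default $10^5$
protons) with a Gaussian fit of the target profiles; the minimum is taken
over the refined set. The envelope pre-filter is an efficiency device --
its agreement with tracking is itself a tested property, and the
per-configuration seeds are derived from the base seed and the grid
indices so scans are reproducible with uncorrelated streams. Ties break
towards the lowest $(B_1, B_2)$ pair.

The asymmetric uncertainty of a minimum combines three contributions by
root-sum-square per side: (i) the half-range of the envelope minima over
source variations (default: both divergences scaled by 0.9 and 1.1 --
which variations the reference study used is not stated); (ii) the local
beam-size variation over the 8 neighbouring grid cells, upper side only,
since a discrete grid can only overestimate the true minimum; (iii) the
Gaussian-fit standard error.

FWHM is computed as $2\sqrt{2\ln 2}\,\hat\sigma \approx 2.355\hat\sigma$
from a least-squares Gaussian fit to the Freedman--Diaconis-binned
profile (Levenberg--Marquardt, moment-based starts, falling back to the
sample standard deviation if the fit degenerates). A *minibeam* requires
both transverse FWHM $\le 1$ mm, boundary inclusive.

## Feasibility benchmark and calibration

`feasibility_map()` reproduces the parametrisation benchmark: for each
(divergence, correlation) cell the minimum per-plane FWHM over the
quadrupole grid, minimised over the size axis. The full grid (nine size
pairs spanning 3--15 mm, eight log-even divergences in 0.1--15 mrad,
eleven even correlations in $[-1,1]$, i.e. $9\cdot8^2\cdot11^2 = 69{,}696$
parametrisations -- just under 70,000) is available; the default for
routine testing is a scaled-down grid, since the horizontal and vertical
planes decouple and each plane's map depends only on that plane's
parameters. The exact spacings of the printed axes are not stated, so
even/log-even spacing including the printed endpoints is used.

`calibrate_source()` is the inverse problem: given a measured table of
beam sigmas at five positions around the isocentre (13 energies in the
reference campaign), with the source sizes taken from the first
monitoring chamber, it grid-searches divergence and correlation per plane
to minimise the mean squared relative deviation between simulated and
measured sizes, and reports the mean relative deviation in percent. A
grid search (rather than continuous optimisation) matches the discrete
benchmarking style of the problem; recovery is exact on noise-free
synthetic tables when the truth lies on the grid, and within one grid
step at 1% noise -- both tested.

No real measurement campaign is distributed with the package (none is
publicly available in numerical form); `gen_measured_sizes()` produces
synthetic tables whose generating parameters interpolate the printed
clinical ranges ($\sigma$ 3.2--13 mm, divergence 0.3--2.25 mrad,
correlations across $[-1,1]$) linearly in energy. These tables exercise
the calibration machinery; they do not reproduce the actual facility
data.

## The dose engine

`bragg_depth_dose()` is a Bortfeld-style analytic curve: ranges follow
the power law $R = \alpha E^p$ ($\alpha = 0.0022$, $p = 1.77$; 7.6 cm at
100 MeV, 26 cm at 200 MeV), and the depth dose is the expectation of the
CSDA stopping term $(R'-z)^{1/p-1}$ plus a linear primary-fluence
reduction term ($\beta = 0.012$ cm$^{-1}$, locally absorbed fraction
$\gamma = 0.6$) over Gaussian ranges $R'$ combining mono-energetic
straggling ($0.012\,R^{0.935}$) and the range spread $pR\,\delta_E$
induced by the energy spread. The integrable singularity is removed
exactly by the substitution $t = w^p$ before quadrature (1500 midpoint
nodes). Sampling *ranges* rather than convolving the depth axis matters
at the phantom entrance: every proton deposits dose at $z=0$, so no
kernel mass may be lost at that boundary.

`compute_dose_grid()` superposes the $n\times n$ minibeam grid (default
$5\times5$; centre-to-centre 2.9 mm for the 10 cm air gap, 3.7 mm for
30 cm). The scanning dipoles deflect each beam by offset/distance, so
off-centre beams enter the phantom at an angle and the grid expands
slightly with depth -- visible in the valley filling at the Bragg peak.
Each pencil beam's lateral sigma evolves in water by Fermi--Eyges
integration (0.5 mm steps) of the local Highland scattering power at the
residual energy $E(z) = ((R-z)/\alpha)^{1/p}$; the voxel dose (default
$0.05\times0.05\times1$ mm, as in the reference study) is the separable
Gaussian product summed over beams and weighted by the depth dose. A
voxel Monte Carlo mode (sampled entrance phase space, per-particle
ranges, per-slab scattering kicks, uncertainty from the standard
deviation over repeated simulations, default 50) guards the analytic
approximations at reduced history counts.

`analyze_dose()` follows the reference conventions: the peak is sampled
on the central beam axis, the valley at the fixed transverse midpoint
between the four central beams, PVDR per 1 mm depth slab (reported as
undefined where the valley dose is zero, never as infinity); the
central-beam FWHM versus depth comes from a single-beam grid without the
24 surrounding beams; the Bragg-peak-to-entrance ratio divides the peak
depth-dose curve at the Bragg depth (taken from the depth-dose curve --
the central-axis dose itself is entrance-dominated for a focused
minibeam) by its entrance-slab value. Lateral flatness is
$(D_\max-D_\min)/(D_\max+D_\min)$ over the central 80% of the nominal
field (side $n\times$spacing) on the profile through the beam row; the
reference's field-size definition follows an unavailable external
convention, so this package's definition is its own and
`find_homogenisation_spacing()` is checked for its qualitative
properties (zero for a uniform slab, monotone in beam width), not for
the printed spacings.

## What the tests do and do not show

The synthetic generator and the property suite establish internal
consistency: Monte Carlo against analytic envelopes, emittance
conservation, closed-form drifts and comb PVDRs, calibration round
trips. Passing them shows the machinery is self-consistent and matches
its stated physics -- not that it reproduces a full
condensed-history Monte Carlo. Known gaps against such a code: no
Moliere/nuclear halo (fitted FWHM slightly optimistic; peak-to-entrance
ratios checked at +/-30% for this reason), hard-edge magnets without
fringe fields, assumed geometry budgets, achromatic dipole kicks, and no
secondary particles. The headline beam-size checks therefore carry a
+/-25% band (or the printed uncertainties, where looser).

Problem sizes used by the packaged checks: the acceptance script runs
the full $51\times51\times2$ grid per configuration with Monte Carlo
refinement of the top 20 candidates at $10^5$ protons each, and full
$0.05\times0.05\times1$ mm dose grids; the routine test suite uses the
same grids with smaller refinement counts ($3\times10^4$ protons) and
coarser dose voxels where only qualitative properties are asserted.

## Limitations

Beyond the physics gaps above: the transport is strictly linear and
uncoupled (no skew elements, no apertures or beam loss), the water
phantom is homogeneous, absolute dosimetry is out of scope (all doses
are per-primary arbitrary units), and the 200 MeV minibeam spacing
reuses the 30 cm-gap value since the reference leaves it unstated.
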