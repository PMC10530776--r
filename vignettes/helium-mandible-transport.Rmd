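---
title: "Helium-ion transport in mandible plate phantoms: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helium-ion transport in mandible plate phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ionphantom` simulates therapeutic helium-4 ion beams in plane-parallel
layered phantoms of the lower jaw and derives the observables used to judge
whether a polymeric-biomaterial phantom is dosimetrically equivalent to a
real-tissue one: Bragg peak positions and amplitudes, entrance LET, lateral
and longitudinal range straggle, and displacement-damage (recoil)
statistics. This vignette documents the physics models, the shipped
fixtures, the parameters that matter, and the design decisions taken where
the underlying data or the problem statement left the design genuinely
open.

## The two mandible fixtures

`builtin_phantom()` ships two ten-layer slab phantoms. The tissue variant
stacks skin, parotid gland, SMAS (the superficial musculoaponeurotic
system), masseter muscle, buccal fat, mucosa, saliva, gum, cortical bone
and cancellous bone; the biomaterial variant replaces the soft layers with
PMMA, Paralene_N, polyethylene and water, and both bone layers with Teflon
(PTFE). Compositions and the two density columns (atomic density in
10^22 atoms/cm^3 and mass density in g/cm^3) are entered exactly as
printed in the source compound table, with atomic fractions renormalized
to sum to one (several tissue rows sum to more than 100%).

### Inconsistent tissue rows and the density basis

Some printed tissue rows are internally contradictory: multiplying the
printed atomic density by the printed composition yields a mass density
far from the printed one (the skin row implies a mean atomic mass of
15 amu and an electron density whose Z/A exceeds 1, which no material
can have; the masseter row implies 1.53 g/cm^3 against a printed 1.05).
The package therefore distinguishes two number-density bases:

* **atomic basis** (default of `number_densities()`): the printed atomic
  density split by atomic fraction — the literal table reading, kept for
  inspection and for the self-consistent rows;
* **mass basis** (used by all transport physics): the total number density
  re-derived from the mass density and the mean atomic mass, split by
  atomic fraction. Mass density is the physically primary input of
  slab dosimetry and is the only column that is always usable.

For the self-consistent rows (PMMA, saliva/water, Teflon, parotid, SMAS,
buccal fat, mucosa) the two bases agree to about a percent; for the
corrupted rows the mass basis is the only physical choice. No correction
of the printed values themselves is guessed.

### Layer thicknesses

The source table prints no thicknesses, so they are a configurable
default. 354-376 MeV helium-4 has a CSDA range of roughly 62-69 mm of
water, so the stack must be about 70 mm deep for the scan's Bragg peaks
to stop inside it. The defaults (skin 4, parotid 15, SMAS 4, masseter 19,
buccal fat 10, mucosa 4, saliva 1, gum 3, cortical bone 6, cancellous
bone 6 mm; 72 mm total) keep clinically plausible proportions, give both
fixtures roughly 10% water-equivalent depth margin beyond the 376 MeV
range, and place the scan's peaks in the bone region — the clinically
targeted depth for mandibular tumours. They were fixed by forward CSDA
computation before any cross-phantom metric was evaluated, and every
thickness can be overridden via `builtin_phantom(thickness_mm = ...)` or a
YAML config (`load_phantom()`).

## Stopping physics

Electronic stopping is the relativistic Bethe formula with a Barkas-type
effective projectile charge, elemental mean excitation energies from a
standard table, and Bragg additivity over the per-element number
densities. No shell, higher-order Barkas or density-effect corrections are
applied: those refine stopping at the sub-percent level while the
cross-phantom claims are relative quantities with percent-level
tolerances. Below 2 MeV/u the Bethe logarithm degrades, so stopping is
continued with a velocity-proportional power law (S proportional to
E^0.45) matched at the join; the residual range below the join is under
0.1 mm and does not move the peak at the binning used. The validated
energy window is 0.1-500 MeV with hard rejection outside it. The
simplified kernel consequently peaks at the 2 MeV/u join rather than at
the true ~0.7 MeV/u stopping maximum; the invariants (monotonic decrease,
nuclear-to-electronic ratio below 1e-3) therefore hold above the join.

Nuclear stopping uses the ZBL universal screening function; energy-loss
straggling is Bohr's free-electron variance with a first-order
relativistic correction, sampled as a Gaussian per step.

## Transport scheme

The engine is condensed-history, not collision-by-collision: per step it
applies mean Bethe energy loss, a Bohr straggling perturbation, and a
Highland multiple-scattering deflection (plane-angle accumulation with
the standard logarithmic correction, floored at 0.25). Steps are limited
to 1% fractional energy loss, one depth bin (72 mm / 400 bins = 0.18 mm
by default), and the distance to the next layer boundary, whichever is
smallest, so no step mixes materials.

Nuclear elastic collisions are split at `recoil_split` (1 keV by
default): transfers above the split are sampled discretely — Poisson
event counts from the unscreened Rutherford cross-section restricted to
T > split, element choice proportional to the per-element macroscopic
cross-section (the shares are energy-independent for a 1/T^2 spectrum),
and inverse-CDF transfer sampling up to the kinematic maximum — while
the sub-split continuum down to `recoil_threshold` (10 eV) is deposited
deterministically as a restricted nuclear stopping, attributed to
elements by the same weights. This reproduces both the smooth recoil
background and the rare large transfers that dominate the recoil-energy
variance, at desk-scale cost. Recoils are tallied at their creation
depth and are not themselves transported (as in the reference
binary-collision treatment, secondary transport is out of scope).

Ions terminate below 0.1 MeV; the residual kinetic energy is deposited
locally into the depth-binned recoil channel so that the energy audit
closes exactly (the audit is asserted to 0.5% in tests but closes to
rounding error by construction). Whole-track recoil *statistics*
(`total_recoil_density()`, the per-element contribution table) use
collision products only — discrete events plus the continuum — because
the stopping ion's own residual is not a primary-knock-on energy; this
choice is visible in the one place the two conventions differ, the
distal spike of the depth-binned recoil curve.

Transmitted ions (possible only for thin user phantoms at these
energies) are excluded from range and straggle statistics, with the
excluded count messaged.

## Damage models

The Kinchin-Pease closed form is implemented as the four-band piecewise
function of the PKA energy T: zero below the displacement threshold
`E_d`, one displacement up to `2 E_d` (the printed upper bound of that
band is a typographical slip; the prose fixes it at `2 E_d`), `T/(2 E_d)`
up to the electronic cutoff `E_c`, and saturation `E_c/(2 E_d)` above.
The NRT variant applies the 0.8 efficiency at and above `2.5 E_d` (the
printed third condition is read as `E_v >= 2.5 E_d`, the standard NRT
form — otherwise the function would be doubly defined), and the damage
energy is taken as the PKA energy without a Lindhard partition, a
documented simplification.

`E_d` defaults to 25 eV per element, a standard displacement threshold;
the source text's "1-3 eV" remark matches a lattice *binding* energy, not
a displacement threshold, and is deliberately not adopted. `E_c` defaults
to the energy at which the recoiling atom's Lindhard-Scharff electronic
stopping equals its ZBL nuclear stopping (solved once per element in
reduced units and cached — about 36 keV for oxygen); both are
overridable in `kp_model()`.

A stochastic hard-sphere cascade (`cascade_oracle()`) simulates the
recursive energy-splitting process directly and is used in tests to
verify that the closed form is the correct expectation — it converges to
`T/(2 E_d)` within 5% at T = 100 E_d with 10^4 trials.

## Analysis estimators

The lateral-straggle estimator is implemented exactly as defined for
stopped ions: per ion the two transverse coordinates are averaged in
absolute value *before* squaring, `sigma_y = sqrt(mean(((|y|+|z|)/2)^2))`.
For a circular Gaussian of per-axis width s this converges to
`s * sqrt((1 + 2/pi)/2) ~ 0.905 s`, i.e. it is *not* the conventional
per-axis RMS; `lateral_rms()` reports the conventional quantity alongside
it. Longitudinal straggle is the population standard deviation of the
projected ranges. Bragg peaks are localized by parabolic interpolation
through the maximum bin and its neighbours (about 0.02 mm resolution at
the default binning); entrance LET averages the first 5% of bins. Both
windows are exposed as parameters. Cross-phantom "average difference"
percentages — not defined precisely in the source — are computed as the
mean over the common energy grid of per-energy absolute relative
differences with the tissue scan as denominator, and this convention is
recorded in the output headers.

## What the study reproduction shows — and what it cannot

`reproduce_study()` runs both fixtures over the 12-energy 354-376 MeV
scan (default 10^4 ions per energy rather than the reference 10^5; the
compared metrics are means over 12 energies and are stable at 10^4,
which keeps the full comparison to a few minutes on one core) and
reports computed values against the published references with bootstrap
confidence intervals (ion-level resampling for straggle and recoil
metrics, energy-level for the peak metric).

With the shipped defaults the Bragg-peak equivalence (~1.8% mean
absolute difference), both scan-mean lateral straggles, the tissue
straggle rise and the total-recoil difference land inside their
published tolerance bands. Two quantities do not and are reported as
computed rather than forced:

* the *gap* between the two phantoms' lateral straggle comes out near
  0.09 mm against a published 0.211 mm — a 32% relative straggle
  difference is not reachable from the printed compositions under
  Highland scattering, whose per-mm scattering powers for the two soft
  stacks differ by only 10-15%;
* the biomaterial straggle *rise* across the scan is a few percent
  against a published 36.7% — in this geometry all peaks sit in the
  dense distal Teflon, so the extra range at higher energy is compressed
  into a few millimetres and sigma_y(E) is nearly flat. In plain water
  the same engine shows the expected ~10% rise, so this is a geometry
  consequence, not a transport defect.

More generally, the synthetic layer stack emulates slab composition,
densities and ordering, but not anatomical curvature, voxelized
heterogeneity, nuclear fragmentation (excluded also in the reference
calculation), delta-ray transport, or the unpublished reference layer
thicknesses. Agreement of the relative tissue-versus-biomaterial metrics
therefore supports material equivalence at the slab level; it does not
validate absolute dose in a patient geometry.

## Numerical choices

* Depth binning: 400 uniform bins; peak localization error is well below
  0.25% of depth. Step length is capped at one bin so every deposit maps
  to a single bin at worst half a bin off.
* Interpolation of all per-material physics tables is linear in
  log-energy versus log-value on a shared 320-point grid, so per-step
  lookups are pure matrix indexing.
* Per-energy seeds in `energy_scan()` are `seed + 1000 (i - 1)` modulo
  2^31 - 1, making scans reproducible and a one-energy scan bitwise
  identical to a direct `run_simulation()` call.
* Degenerate inputs are rejected with named errors: empty layer lists,
  all-zero fractions, unknown element symbols, energies outside
  0.1-500 MeV, fewer than 2 stopped ions for straggle statistics,
  all-zero ionization records, and mismatched energy grids in
  `compare_phantoms()` (listing the offending energies).
* A rare near-maximal transfer coinciding with a full condensed step
  could overdraw the ion's energy; deposits are rescaled in that step so
  the audit stays exact.

## Problem sizes used by the shipped checks

The test suite validates transport against the CSDA integral and the
conservation audit with 2000-ion water runs, and runs the full
two-phantom comparison once at 10^4 ions per energy; the acceptance
script recomputes the published comparison at the same scale. These sizes
were chosen as the smallest at which every compared metric's Monte Carlo
error is comfortably below its tolerance band.
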