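---
title: "Methods: pore profiling, permeation counting, and single-channel analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pore profiling, permeation counting, and single-channel analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porepass)
```

`porepass` implements the quantitative layer of a structure/function study
of an MscS-like mechanosensitive channel — a homoheptamer whose anions
enter through side portals in the cytoplasmic cage and leave through a
transmembrane pore gated by an aromatic ring. Three kinds of raw data feed
such a study: static structures (cryo-EM coordinates), coordinate
trajectories (molecular dynamics), and patch-clamp recordings. The package
provides the analyses for all three, plus seeded generators that emulate
each input with known ground truth, so that every estimator can be
validated by parameter recovery rather than by eye.

## Sphere-probe pathway profiling

The pore radius at a station $s$ along the channel axis is defined as the
largest clearance a probe sphere can attain in the plane normal to the
axis at $s$:

$$ R(s) \;=\; \max_{p \,\in\, \Pi(s)} \; \min_i \big( \lVert p - x_i \rVert - r_i \big), $$

where $x_i, r_i$ are atom centers and van der Waals radii. This is the
classic sphere-probe definition used by pore-annotation tools. Two
conventions matter and both are exposed rather than silently preferred:
a profile of a *static* structure (one conformer) and the per-frame
*trajectory* statistics summarised by `profile_envelope()` (pointwise
mean, n−1 standard deviation, min and max after resampling every frame's
profile onto the first frame's station grid). On flexible channels the
simulation-average minimum radius is typically smaller than the static
one; users comparing against either number should pick the matching
convention.

Numerical scheme. The in-plane maximization is non-smooth (a min over
atoms), so each station is solved by multi-start Nelder–Mead: 8 starts,
the previous station's center plus 7 jittered copies drawn within half a
step, all driven by a caller-supplied `rng_seed`, making profiles
bit-reproducible. A continuity constraint (lateral move at most one
`step` per station, enforced by penalty and a final projection) keeps the
walk on one pathway instead of tunnelling through walls; the walk starts
at a seed point — the center of the gate ring for the pore, the
portal-residue centroid for portals — and proceeds outward in both
directions until a station's clearance reaches `escape_radius`
(default 12 Å), which is flagged `open_to_bulk` and terminates that
direction. Defaults: `step = 0.25` Å; atoms are pre-filtered per station
by an axial slab so the clearance evaluation stays linear in nearby atoms
only.

Portal profiles use the same machinery with a different path: the seed is
the geometric center of the four portal-lining residues (the tryptophan
of one subunit with the two phenylalanines and the asparagine of the
adjacent subunit), and the path direction is the horizontal unit vector
from that seed toward the symmetry axis, i.e. within the membrane plane.
Stations are signed distances from the seed (negative = outward).

The axis itself comes from `symmetry_axis()`: the centroid and
minimal-variance principal axis of a ring-like selection (for a flat ring
the smallest-dispersion eigenvector is the ring normal). The sign is
fixed by an extracellular reference selection, because nothing intrinsic
to a coordinate file says which way is out.

Hydrophobicity and the wetting heuristic. `hydrophobicity_profile()`
scores each station by the mean Kyte–Doolittle hydropathy of the residues
with any atom within `contact_cutoff` (default 6 Å) of the station
center; stations lining no residue stay `NA` rather than being
interpolated. The hydration-barrier heuristic then flags the profile if
any station is simultaneously narrow (`radius < r_wet`, default 3.5 Å —
about the radius below which a hydrophobic constriction can dewet) and
hydrophobic (score `> h_crit`, default 0). This is a deliberate,
documented simplification of free-energy-based channel-annotation
predictions: it reproduces the qualitative call (barrier / no barrier) on
clear-cut geometries and makes both thresholds explicit, but it computes
no water free energy and should not be read as one.

## Permeation analysis

`assign_compartments()` turns distance-based constraints to the axis into
one of five labels per (ion, frame): `PORE` (inside the cylinder between
`z_pore_bottom` and `z_pore_top`), `CAGE` below it, `PORTAL` (in a
radial/axial annulus at the cage wall), `BULK_EXT` above the
extracellular boundary, else `BULK_CYT`. Boundary ties resolve by the
fixed precedence PORE > CAGE > PORTAL > bulk, so labels are
deterministic. One convention deserves a note: the type requires
`z_extracellular` strictly above `z_pore_top`, but any finite gap between
them would label an exiting ion cytosolic for a frame and veto the
event; the package therefore places the extracellular boundary
infinitesimally (1e-9 Å) above the pore top in its default geometries,
preserving the strict ordering with a gap of measure zero.

A crossing event (`detect_crossings()`) is a completed passage: portal,
later pore, then extracellular bulk, with no intervening return to the
cytosolic bulk; re-entries restart the per-ion state machine and partial
passages count nothing. The entry time is the first portal frame of the
completed passage and the transit time runs from portal entry to bulk
exit. The implementation is equivalent to matching the per-ion label
string against `P[^CE]*O[^CE]*E` (leftmost, non-overlapping), and the
test suite asserts exact agreement with precisely that independent
regular-expression oracle on random walks, and with the Brownian
generator's own passage log on simulated trajectories.

Conductance uses the charge-transfer estimator
$G = I/V = Q/(t\,V)$ with $Q = n_{\text{events}}\, q\, e$; the sign of
the driving potential is discarded and the result reported in pS. With
the pooled totals printed for the study's all-up simulations — 36
single-charge efflux events in 300 ns at 425 mV — this evaluates to
45.2 pS, i.e. the reported "~50 pS" at its rounding.

Supporting observables follow the same conventions: `z_tracks()` projects
onto the axis after minimal-image unwrapping of per-step displacements
(preventing spurious crossings in periodic boxes); `contact_ladder()`
reports per-residue first-contact times of an entering ion against
charged side-chain nitrogens (default cutoff 4 Å, a typical ion–amine
contact distance) and whether the donor-to-acceptor handover was
unidirectional within the event; `chi1_series()` bins the N–CA–CB–CG
dihedral into trans ($[120°, 180°] \cup (-180°, -120°)$), gauche−
($[-120°, 0°)$) and gauche+ ($[0°, 120°)$); `wetting_occupancy()` is the
fraction of frames with at least `min_waters` water oxygens in an
axial/radial region.

## Electrophysiology

Permeability analysis uses the two-ion Goldman–Hodgkin–Katz relation with
$P_{\mathrm{Na}} = 1$, $P_{\mathrm{Cl}} = $ `ratio`:

$$ E_{\mathrm{rev}} = \frac{RT}{F}\,
   \ln \frac{P_{\mathrm{Na}}[\mathrm{Na}]_o + P_{\mathrm{Cl}}[\mathrm{Cl}]_i}
            {P_{\mathrm{Na}}[\mathrm{Na}]_i + P_{\mathrm{Cl}}[\mathrm{Cl}]_o} $$

and its closed-form inversion. The temperature default is 298.15 K
(RT/F = 25.693 mV) since recordings are made at room temperature;
impermeant constituents (sucrose, HEPES) are ignored, junction potentials
are not modelled (a constant offset can be applied by the caller for
selectivity experiments). The inversion is only defined strictly between
the two Nernst potentials; symmetric solutions leave the ratio
unidentifiable and raise an error rather than returning anything.
`interpolate_erev()` finds the measured reversal potential by linear
interpolation of the bracketing I–V pair, mirroring standard practice.

Single-channel parameters: `leak_subtract()` removes the pre-stimulus
baseline (mean, or a fitted line for drifting patches; idempotent).
`fit_amplitude_histogram()` mirrors the histogram-plus-Gaussians workflow
of acquisition software: currents are binned (default 0.2 pA, bins
aligned so multiples of the bin width are centers), a sum of Gaussians is
fitted to the counts by Levenberg–Marquardt least squares initialized at
the histogram peaks, and the single-channel amplitude is the difference
of the two heaviest adjacent component means. Histogram least squares was
chosen over per-sample EM deliberately, to match how such amplitudes are
measured in practice. Two guarded paths keep the fit honest: traces whose
histogram is a handful of isolated spikes (effectively noiseless) go to
exact count-weighted moments, and traces with fewer resolvable peaks than
requested components are fitted anyway but flagged `degenerate` with a
warning. `slope_conductance()` is ordinary least squares of current on
voltage (slope × 1000 = pS; at least three distinct voltages), and
`deactivation_tau()` fits $I(t) = A e^{-(t-t_0)/\tau} + b$ after the
stimulus end, with the initial $\tau$ from the 1/e crossing; a
bi-exponential option exists because the functional form used for
published time constants is often unstated, but the single exponential is
the default. Flat or non-decaying segments raise convergence errors
(including a post-fit check that the fitted amplitude exceeds twice the
residual noise).

## Synthetic data: what it emulates, and what it does not

The generators define the package's validation conditions.

* `make_toy_channel()` builds stacked-ring pseudo-atom solids with an
  exact analytic profile `ring_radius(z) − atom_radius`, optional portal
  holes, and C7-symmetric variants (any atoms-per-ring divisible by 7).
  These give the profiler an analytic truth to hit (the suite requires
  ≤ 0.05 Å on cylinders) and a convergence study in atom density.
* `simulate_ions()` runs overdamped Langevin dynamics —
  $\Delta x = \mu F \Delta t + \mathcal{N}(0, 2D\Delta t)$ with Einstein
  mobility $\mu = D/kT$ — through a cage/portal/pore wall system, with a
  uniform driving field from a stated potential drop, reflecting walls
  (move rejection with axial/lateral fallbacks), and reservoir
  reinjection to hold the ion count constant. Defaults: D = 200 Å²/ns
  (aqueous chloride scale), dt = 2 ps (the stability condition
  $\sqrt{2D\,dt} \le$ aperture/4 is enforced), 310 K, −425 mV across the
  channel span, and an ion count consistent with a ~0.5 M reservoir in
  the default box. The generator logs its own ground-truth passage list
  with independently written labelling code, so detector-vs-truth closure
  is a genuine two-implementation check.
* `simulate_patch_sweep()` drives `n_channels` two-state Markov channels:
  opening at `open_rate` during a 1 s pressure step, closing at
  $1/\tau_{\text{deact}}$ after it (and optionally during), with open
  current $\gamma (V - E_{\mathrm{rev}})/1000$ pA and Gaussian sample
  noise. `make_iv_dataset()` produces noisy single-channel I–V points.

What passing these tests shows — and does not. Recovery of γ within 2%,
amplitudes within 2% and τ within 5% at SNR 10 (all over 100 seeded
replicates), and exact crossing-count closure, demonstrate that the
estimators are unbiased and correctly implemented under the assumed
models: memoryless gating, Gaussian noise, rigid walls, no explicit
water, no membrane mechanics, no force-field energetics. Real recordings
add filtering artefacts, drift, subconductance levels and multi-channel
overlap; real trajectories add correlated protein motion and ion–ion
interactions. None of those are claimed to be validated here — the
generators are stand-ins for the statistical structure the analyses
assume, not for the physics of the originals.

## Problem sizes and numerical choices used in validation

The shipped test suite profiles toy solids of a few hundred to a few
tens of thousands of pseudo-atoms at 0.25–0.5 Å steps; Brownian runs use
10–60 ions for 1–14 ns at 2 ps steps (20+ seeds for the closure checks);
recovery studies use 100 seeded replicates per parameter. These sizes
were chosen so the whole validation runs comfortably on one CPU while
keeping Monte-Carlo standard errors several times smaller than each
tolerance. Deterministic tie-breaks used throughout: first-encountered
conformer on altloc occupancy ties; smallest station on radius-minimum
ties; first matching annulus on portal overlap; compartment precedence
PORE > CAGE > PORTAL > bulk.

## Known limitations and open choices

* The deposited-structure checks (pore constriction ≈ 3.5 Å seeded at
  the gate ring; portal minima averaging ≈ 2.1 Å) require downloading
  the public coordinates; the corresponding tests perform that download
  and therefore need network access. Which deposited model a measurement
  used should be recorded alongside results, since composite and
  uniform-conformation models differ by ~10% in constriction radius.
* Simulation-average radii are systematically below static-structure
  radii for flexible gates; the package reports both and never converts
  one into the other.
* Fold-change summaries are computed, not transcribed: e.g. a wild-type
  to double-mutant conductance ratio of 270/22.6 = 11.95 is reported as
  such, and a 270/156 ratio computes to 1.7 even where prose might call
  it threefold.
* The probe walk assumes a mostly straight pathway (continuity, not a
  curved spline); strongly kinked channels would need a segmented axis.
* Brownian walls use move rejection rather than true specular
  reflection; with the enforced step bound the difference is confined to
  a sub-step boundary layer.

## A worked validation pass

```{r example}
axis <- channel_axis(c(0, 0, 0), c(0, 0, 1))
toy <- make_toy_channel(seq(-5, 5, 0.5), 6, atoms_per_ring = 28)
prof <- profile_pore(toy$structure, axis, bounds = c(-4, 4), rng_seed = 1)
max(abs(prof$radius - 4.3))   # analytic clearance R - r = 4.3 Å

sim <- simulate_ions(brownian_spec(n_ions = 40, total_time = 4, seed = 3))
ev <- detect_crossings(assign_compartments(sim$traj,
                                           sim$spec$geometry$channel))
nrow(ev) == nrow(sim$passages)   # detector == generator ground truth

sol <- solution_pair(150, 30)
ghk_erev(sol, 9.8)               # -31.3 mV
estimate_conductance(36, 1, 300, 425)$conductance_pS   # 45.2 pS
```
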