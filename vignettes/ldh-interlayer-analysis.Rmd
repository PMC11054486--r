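---
title: "Interlayer structure and carboxylate vibrations in hybrid LDHs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interlayer structure and carboxylate vibrations in hybrid LDHs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldhtraj)
```

# Scope

`ldhtraj` post-processes molecular-dynamics trajectories of layered double
hydroxides (LDHs) whose galleries contain dicarboxylate anions — succinate
(SUC), L-aspartate (ASP), L-glutamate (GLU) — plus interlayer water, with the
stoichiometry `[Mg4Al2(OH)12]A^2- . X H2O` per formula unit.  The questions
it answers are the standard ones for these hybrids: how the
symmetric/antisymmetric (S/AS) carboxylate stretch band separation evolves
with hydration, how the anions orient relative to the sheets, which backbone
conformers they adopt, where polar atoms and water sit along the stacking
axis, and which short-range atom–atom contacts structure the gallery.

The package does not run dynamics.  A synthetic trajectory generator
reproduces the *statistical* structure these analyses consume, so every
estimator can be validated against known ground truth; real trajectories
enter through XYZ/PDB/DCD readers plus a YAML topology.

# Infrared spectra from the dipole correlation function

For a molecule with partial charges $q_i$ and positions $\mathbf r_i(t)$, the
absorption intensity is proportional to the Fourier transform of the dipole
time-correlation function,

$$ I(\omega) \;\propto\; \int dt\, e^{-i\omega t}
   \langle \boldsymbol\mu(0)\cdot\boldsymbol\mu(t) \rangle , \qquad
   \boldsymbol\mu(t) = \sum_i q_i\,[\mathbf r_i(t)-\mathbf r_{\rm com}(t)] .$$

Two conventions matter:

* **Reference point.** The anions carry net charge $-2$, so the dipole is
  origin-dependent; `dipole_series()` uses the molecular center of mass,
  which makes the dipole rigorously translation invariant.  A
  `fragment = "carboxylate"` option restricts the sum to the carboxylate
  C/O atoms (with the fragment's own center of mass as reference) for band
  assignment work.
* **Quantum prefactor.** The classical correlation function misses the
  quantum detailed-balance factor.  No such correction is applied — a
  `prefactor` hook on `mem_spectrum()` lets the user multiply one in — and
  computed carboxylate bands are conventionally translated by a constant
  (typically $-200\ \mathrm{cm^{-1}}$, `apply_shift()`) when compared with
  experiment.  Band *separations* are invariant under that shift, which is
  why the S/AS gap is the robust observable.

## Maximum entropy (Burg) estimation

The transform is estimated by the maximum entropy method: each Cartesian
component of $\boldsymbol\mu(t)$ is fit by an autoregressive model via Burg
recursion (`stats::ar.burg`) and the model power spectral density is
evaluated on a wavenumber grid; the three components are summed.  Compared
with the raw periodogram this gives smooth spectra with well-defined maxima
on short (1 ns-scale) windows.

Numerical choices:

* **Order.** The AR order is the one free parameter.  Default:
  `min(500, n_frames/10)`, exposed everywhere.  Orders far above the
  default can split bands; far below, they blur them.  An order at or above
  `n_frames/2` is refused.
* **Normalization.** Intensity is scaled so the spectrum integrates to the
  series variance over the full Nyquist range (a sum-rule the tests check
  to 5%).
* **Grid and peaks.** Peaks are grid argmaxima — no sub-grid interpolation —
  on a default grid of 800–2000 cm$^{-1}$ in 2 cm$^{-1}$ steps, so reported
  band positions are reproducible and resolution-bounded.  `find_band_gap()`
  reads $\nu_S$ in [1300, 1500] and $\nu_{AS}$ in [1500, 1750] by default
  (on the unshifted, computed scale); a window whose maximum falls on its
  edge is reported as having no interior peak rather than guessed.
* **Degenerate input.** A zero-variance component contributes zero
  intensity; an all-zero-charge molecule yields a zero series with a
  warning, not an error.
* **Invariances.** $|\boldsymbol\mu|$ and $C(t)$ are exactly invariant under
  rigid rotations.  The summed per-component AR spectrum is invariant only
  up to fit error (Burg is nonlinear in the components); it converges to the
  rotation-invariant spectrum as the series grows, and the tests check shape
  correlation and the band gap rather than pointwise equality.

Per-anion spectra are computed and then averaged (`average_spectra()`)
rather than transforming the total-system dipole: cross-anion dipole
correlations are deliberately excluded.  Velocity power spectra
(`velocity_power_spectrum()`) of selected atoms serve band assignment;
velocities can be derived by central finite differences when a trajectory
stores none, but only on request.

# Structural descriptors

* **Orientation.** $\theta$ is the angle between the vector joining the two
  carboxylate carbons and the layer normal, folded into $[0^\circ,90^\circ]$
  via $|v_z|$ so the carbon labelling is immaterial ($\theta = 90^\circ$:
  anion parallel to the sheets).  An anion counts as *parallel* when
  $\theta$ is **strictly** greater than 80.0°; exactly 80.0° is
  intermediate/perpendicular.  Populations pool all (frame, anion) samples;
  whether one should instead average block-wise is not settled usage, and
  frame-pooling is the statistically defensible default.
* **Conformers.** The classifying torsion $\chi$ is the C–C–C–C backbone
  dihedral in succinate and C–C$_\alpha$–C$_\beta$–C$_\gamma$ in the amino
  acids (IUPAC sign convention; the implementation is cross-checked against
  `bio3d::torsion.xyz`).  Wells sit at 180° (anti) and ±60° (gauche); the
  windows are bounded halfway between wells: anti for $|\chi|>120^\circ$
  (with $-120^\circ$ counted anti), gauche+ for $0<\chi\le 120^\circ$,
  gauche− for $-120^\circ<\chi\le 0^\circ$.
* **Number densities.** `number_density_z()` assigns each selected atom to
  its enclosing interlayer (regions between adjacent Mg-sheet centers from
  `detect_slab_geometry()`, which clusters Mg $z$ by deterministic 1-D
  k-means), re-expresses $z$ relative to that region's midplane, and
  averages over frames and regions.  Units are counts·Å$^{-1}$·frame$^{-1}$,
  so the profile integral times the frame count equals the number of
  observations — a conservation law the tests enforce.  Profiles are
  mirror-averaged across the midplane by default (the two surfaces of a
  gallery are equivalent); this is toggleable.
* **Restricted RDFs.** `rdf()` histograms minimum-image pair distances and
  normalizes by the ideal-gas shell expectation at the full-box density.
  In a slab this normalization is only meaningful at short range, so the
  default range stops at 5 Å — about one interlamellar spacing — and the
  results should be read qualitatively (peak positions and trends), not as
  bulk coordination numbers.

# The synthetic generator

`generate_trajectory()` emulates the statistical content of the simulated
systems, not their energetics.

**Composition and geometry.** Per formula unit: 4 Mg + 2 Al cations on a
3.1 Å grid in rigid sheets (Al every third site), 12 hydroxyl O–H pairs (O
at ±1.10 Å, H at ±2.05 Å from the cation plane), one anion, and water.
Sheets sit at the prescribed interlamellar spacing $d$; anions and waters
populate the interior galleries round-robin.  Fractional hydration is
honoured globally — the water count is `round(n_fu * X)`, with the
remainder spread deterministically over formula units — because the
tabulated $X$ values (e.g. 6.5, 4.25, 3.5) are per-anion averages.

**Anions.** Rigid ideal-geometry templates (C–C 1.53 Å, C–O 1.25 Å,
tetrahedral/trigonal angles) with two free degrees of freedom: the
orientation of the carboxylate–carboxylate axis and the classifying torsion
$\chi$.  Partial charges are a fixed documented table summing to $-2$
(carboxylate C +0.7, carboxylate O −0.8, net-neutral amino group,
near-symmetric chain).  The table is deliberately chosen so the anions'
*static* dipole is modest, as for real force-field dianions of this kind;
a large static dipole would make slow reorientation dominate the dipole
dynamics and mask the stretch bands.

**States and switching.** Each anion carries two Markov states: orientation
(parallel with probability `p_parallel`, $\theta$ drawn above 80°;
otherwise $\theta$ uniform over the geometrically allowed part of
$[0^\circ,70^\circ]$) and conformer (per `conformer_fractions`; anti drawn
in 160–200°, gauche in ±(45–75°)).  Dwell times are geometric with mean
`dwell_frames`.  The default is 2000 frames: at the spectra-grade frame
spacing of 0.5 fs that is 1 ps, a realistic reorientation scale, and it
corresponds to roughly 100 frames at the ~20 fs saving intervals typical of
structure-grade sampling.  Transitions are *smooth*: every switch is a
cosine ramp of up to 100 frames in the orientation angles, the torsion and
the center height, because instantaneous jumps would inject a $1/\omega^2$
broadband tail into the dipole spectrum that no continuous trajectory has.
Ramps interpolate $\theta$ between its endpoint values, so a
`p_parallel = 1` system has every per-frame $\theta > 80^\circ$ by
construction.

**Geometric constraints.** The usable half-gap is
$h = (d - 4.0)/2 - 0.3$ Å (sheet half-thickness 2.0 Å plus clearance).
Tilted orientations are drawn only from angles whose exact molecular
$z$-extent (computed for the drawn spin) fits within $h$; in narrow
anhydrous galleries this truncates the perpendicular range, as it should —
and an anion that cannot fit at any allowed tilt is a hard generation error
naming the constraint.  Parallel anions sit as close to one surface as
their extent allows, which is where flat-lying carboxylates reside.

**Vibrations.** The carboxylate oxygens oscillate along their local C→O
bonds as two noise-driven damped modes per group — AR(2) processes with
centre frequencies `nu_S` (in-phase within a group; default 1400 cm$^{-1}$)
and `nu_AS` (out-of-phase; default 1600 cm$^{-1}$), RMS amplitude
`mode_amplitude` (0.08 Å) and relaxation time `damping_time` (500 fs,
i.e. ~10 cm$^{-1}$ half-width, Lorentzian-like).  No band-*shape* realism
is attempted.  Preset systems place `nu_AS` at `nu_S` plus that system's
tabulated band separation so that hydration trends flow through the
pipeline.

**Water.** Each water is either a hydration-shell molecule — placed 2.85 Å
from a randomly chosen carboxylate oxygen, displaced toward the nearer
surface, never inside ±1.8 Å of the midplane — or, with probability
`midplane_water_fraction`, a gallery-centre molecule near the midplane.
Presets use 0.15 for the high-hydration states (where gallery-centre water
is expected) and 0 otherwise.

**Noise and reproducibility.** All non-layer atoms receive Gaussian jitter
of `thermal_sigma` (0.05 Å): rigid-body for the anion backbone — so the
drawn $\theta$ and $\chi$ are held exactly — and per-atom for H, N and
water atoms.  All randomness derives from one seed through per-anion and
per-water-block substreams; identical configurations are bit-identical.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real MD: no force field, so no energetic coupling
between hydration, orientation and conformation (the populations are
inputs, not emergent); no hydrogen-bond network dynamics (water placement
is static statistics plus jitter); no anharmonicity or mode coupling, so
band shapes and relative intensities are schematic; no anion diffusion.
The tests establish that the *estimators* are correct and that the full
pipeline recovers known parameters under realistic confinement geometry,
sampling and autocorrelation.

# Problem sizes and tolerances

The shipped tests and the acceptance script use: $2^{15}$ frames at 0.5 fs
(AR order 200) for the pure-tone spectral oracle; 3 formula units ×
8192 frames (order 400) for band-gap recovery, accepted within
±10 cm$^{-1}$; 4000 single-frame anions for orientation/conformer
recovery, accepted within 3 binomial/multinomial standard errors; 1000
ideal-gas atoms × 100 frames for RDF flatness within 0.05; and 12 formula
units × 50 frames for density-profile conservation and midplane checks.
These sizes make every check sharp at desk scale while each estimator
remains `n`-agnostic.

# Known limitations

* DCD I/O uses single-precision coordinates (format-inherent); XYZ output
  defaults to 3 decimals.  Orthorhombic boxes only.
* The RDF normalization uses the full 3-D box volume in an anisotropic
  slab; beyond ~5 Å it decays by construction and is not reported.
* Burg spectra of very short series (≲ 1000 frames) in the pipeline may
  legitimately fail band-gap extraction ("no interior peak"); spectra-grade
  runs should use several thousand frames.
* The generator's conformer and orientation populations are independent
  Markov chains; correlations between the two (e.g. gauche anions
  preferring parallel states) are not modelled.
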