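---
title: "A 3-D forward model for X-ray dark-field projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 3-D forward model for X-ray dark-field projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkfield3d)
```

## The signal and the model

A Talbot-Lau grating interferometer measures, besides absorption and
differential phase, the *dark-field* signal: the loss of interference-fringe
visibility caused by ultra-small-angle scattering of micrometer-scale
structures. The signal is sampled along a single direction — the
*sensitivity direction* `s`, perpendicular to the grating bars — so an
elongated scatterer such as a fiber produces a signal that depends on the
relative orientation of three vectors: the fiber axis `f`, the X-ray
direction `r`, and `s`.

`darkfield3d` implements a forward model of this signal over full 3-D
geometry. The scatter distribution of a fiber is assumed to be a zero-mean
3-D Gaussian whose covariance is an oblate spheroid: two equal large
eigenvalues $\sigma_\perp^2$ in the plane perpendicular to the fiber axis
and a smallest eigenvalue $\sigma_\parallel^2 \le \sigma_\perp^2$ along it
(`fiber_scatterer()`, `spheroid_from_fiber()`). Only the covariance
structure matters; the Gaussian density itself is never evaluated.

The point signal is

$$ d = d_\mathrm{iso} + d_\mathrm{aniso}\,
   \bigl(\mathbf{s}^\top \mathbf{R}_\alpha \mathbf{f}\bigr)^2, \qquad
   d_\mathrm{iso} = \sigma_\perp^2,\quad
   d_\mathrm{aniso} = -(\sigma_\perp^2 - \sigma_\parallel^2) \le 0 ,$$

where $\mathbf{R}_\alpha$ compensates cone-beam divergence: for a ray `r`
diverging from the central ray `c` by angle $\alpha$, the fiber is rotated
by $-\alpha$ in the plane spanned by `c` and `r`
(`divergence_rotation()`); a parallel beam gives the identity. The inner
product is squared so the signal has period $\pi$ and cannot distinguish
`f` from `-f` — the physical symmetry of the scatter distribution. The
anisotropic part is written as a *reduction* of scatter along the fiber
axis, which keeps the unknown fiber vector directly visible in the model, a
convenient property for any reconstruction built on top of it.

Two evaluation routes for the projection exist (`alignment()`). The
canonical `"plane"` mode projects both the rotated fiber and the
sensitivity onto a virtual plane `E` perpendicular to the ray and takes the
2-D inner product, $\mathbf{s}^\top E E^\top \mathbf{R}_\alpha\mathbf{f}$.
The algebraic shortcut $\mathbf{s}^\top \mathbf{R}_\alpha \mathbf{f}$
(`"direct"`) relies on $E E^\top$ acting as the identity, which holds only
on the subspace perpendicular to the ray. The two modes therefore agree
exactly when $\mathbf{s} \perp \mathbf{r}$ — the usual hardware situation —
and differ by $(\mathbf{s}\cdot\mathbf{r})(\mathbf{r}\cdot
\mathbf{R}_\alpha\mathbf{f})$ otherwise. We make `"plane"` the default and
have `"direct"` refuse non-perpendicular sensitivities (tolerance `1e-9` on
$\mathbf{s}\cdot\mathbf{r}$) rather than silently drop the discrepancy.

Fiber directions are normalized on construction. The squared inner product
would otherwise fold $\lVert f\rVert^2$ into the anisotropic amplitude, so
all scatter magnitude is kept in the two eigenvalues; directions are pure
orientations. In particular the elevated fiber `(1, 1, 1)` of the worked
examples is used as the unit vector $(1,1,1)/\sqrt3$.

## Acquisition geometry

`circle_trajectory()` and `helix_trajectory()` generate view sequences with
a fixed global convention: rotation axis along global `y`, source start at
`(0, 0, sid)`, beam initially along `-z`, right-handed rotation. The
convention is ours to pick — every quantity the experiments report (trace
extrema, constancy, periodicity) is invariant to it. Other choices,
documented because each was genuinely open:

* **Angular grid** is half-open `[start, stop)`, so a full turn at a 1.5°
  increment gives 240 views.
* **Pitch** is the axial advance per full turn ($2\pi$) of the helix.
* **Helix sensitivity** follows the trajectory: the helix tangent's
  component perpendicular to the central ray, renormalized. With zero pitch
  this reduces exactly to the in-plane circle sensitivity.
* Circle sensitivities are either in the rotation plane (`in_plane`) or
  along the rotation axis (`axial`); both are exactly perpendicular to the
  central ray, so `"plane"` and `"direct"` alignment agree on every
  generated view.

`ray_context_at()` produces the per-point geometry: a parallel beam copies
the central ray; a cone beam takes the ray from the source through the
sample point, with $\alpha$ the angle to the central ray. Divergence angles
below `1e-7` rad are treated as parallel — `acos()` cannot resolve smaller
angles from a unit dot product, and the rotation axis `c × r` is
numerically undefined there.

## From point signal to measurement

The measured quantity follows a Beer-Lambert form,
$D = \exp\left[-\int_L d(\mathbf{x})\, \mathrm{d}L\right]$, so $-\log D$
is a plain line integral of the per-voxel scatter (`line_integral()`,
`transmit()`, `neg_log()`).

**Chord-length factor.** A point signal ignores how long the rays travel
*through* the fiber cylinder. For a finite cylinder of radius $\rho$ and
height $\ell$ we scale by the normalized mean chord: with $\gamma$ the angle
between ray and fiber axis,

$$ C(\gamma) = \min\!\left( \frac{1}{\sin\gamma},\;
   \frac{\ell}{(\pi/4)\,2\rho} \right), $$

so $C = 1$ for a perpendicular ray (the mean chord of a circle of diameter
$2\rho$ is $(\pi/4)\,2\rho$), grows as the fiber tilts into the beam, and
saturates when the path reaches the cylinder height. No exact closed form
for the average chord of an arbitrary finite cylinder is available in
elementary terms; this capped-secant model is one admissible choice,
reproducing the qualitative behaviour that matters (the rise can exceed the
eigenvalue ratio for sufficiently elongated fibers). `C ≡ 1`
(`use_chord = FALSE`) is the default for point-fiber experiments.

**Voxel integrator.** `line_integral()` clips the ray to the grid bounding
box and applies the midpoint rule with `n = ceiling(chord/step)` equal
sub-intervals (default step: a quarter voxel), nearest-voxel lookup with
half-open cells, voxel centers at `origin + (i + 0.5) * spacing`. The
contract is convergence — first-order error against an exact traversal,
verified in the tests — not bit-exact path lengths; a Siddon/Joseph-style
exact traversal would change nothing observable at the default step.

**Analytic cylinder projector.** For the rotating-rod experiment the rod is
projected analytically (`ray_cylinder_chord()`, `project_cylinder()`): per
detector pixel, the exact chord of the ray through the finite capped
cylinder times the orientation term of the rod's fiber. The exact chord
replaces the mean-chord approximation, and no voxelization artifacts enter
at the 40-pixel-diameter scale.

## The built-in experiments

Three deterministic drivers reproduce the canonical study conditions; their
defaults *are* those conditions and are not meant to be tuned.

1. `run_trajectory_experiment()` — source-isocenter distance 600,
   source-detector distance 1200 (arbitrary length units), full turn in
   1.5° steps, helix pitch 0.5; eigenvalues 1 and 0.5; fibers `(1,0,0)`
   (in the rotation plane) and `(1,1,1)` (elevated). Signals are evaluated
   for the fiber at the isocenter, where cone and parallel circular beams
   coincide ($\alpha = 0$). The in-plane circle trace swings between the
   two eigenvalues; the axial-sensitivity circle gives a constant trace for
   both fibers; the helix trace loses the $\pi$-periodicity because the
   sensitivity drifts along the trajectory.
2. `run_single_fiber_planes()` — a teflon fiber (eigenvalues 1.5 and 0.3,
   radius 1.79 µm, length 15 µm) swept through the three coordinate
   planes, parallel beam along `z`, sensitivity `(1,0,0)`, chord factor
   on. The xy sweep is a pure orientation sinusoid between the
   eigenvalues; the xz and yz sweeps are dominated by the growing
   intersection length.
3. `run_carbon_rod()` — a rod of diameter 40 (pixel units), eigenvalues
   1.4 and 1, 100 views over 180°, elevation angles 10–50°, central-pixel
   readout, analytic projector. An azimuthal start offset
   (`angle_offset_deg`, default 0) models a rod not aligned with the
   detector plane at the start of a real acquisition. The rod half-length
   defaults to 100 pixel units — long enough that the caps never clip the
   central-ray chord at any of these elevations. Signal magnitudes are in
   arbitrary units; no conversion of variances to physical micro-radians
   is attempted (that requires the actual interferometer setup
   parameters).

## Consistency with the prior 2-D models

Constraining the model to a parallel beam, sensitivity `(1, 0, 0)` and a
single rotation angle recovers the three earlier 2-D projection models
(`check_reduction()`):

* rotation about the optical axis: $A + B\sin^2(\omega - \theta)$;
* azimuthal fiber angle: $A + B\sin^2(\varphi - \omega)$;
* sensitivity along the rotation axis: a constant, the fiber component on
  that axis.

The matched constants are derived symbolically for an arbitrary unit fiber
rather than hard-coded per case: the alignment under either rotation is a
sinusoid $\rho\cos(\omega - \omega_0)$ with $\rho$ the fiber's norm in the
respective invariant plane, giving
$A = d_\mathrm{iso} + d_\mathrm{aniso}\rho^2$ and
$B = -d_\mathrm{aniso}\rho^2$. The tests drive the deviation below
$10^{-10}$ over dense angle grids and randomized fibers. One wrinkle is
inherited knowingly: the inline form of the first reduction is implemented
with the squared inner product, consistent with the constrained point
signal (the unsquared variant cannot produce a $\sin^2$ law). The
axial-sensitivity constancy applies to the orientation term only — with
the chord factor enabled the signal is constant only for small fiber
elevations, and a test demonstrates the breakdown at 40°.

## What the synthetic data do and do not show

`generate_fiber_phantom()` builds seeded random voxel phantoms whose
invariants (`d_aniso ≤ 0`, `d_iso + d_aniso ≥ 0`, unit directions) hold by
construction; it emulates sparse oriented scatterers in an empty volume.
It does not emulate real tissue or composite materials: no partial-volume
mixtures of fiber populations within a voxel, no acquisition noise, no
beam hardening, no visibility physics at the detector, and no conversion
to physical scatter units. Passing tests therefore demonstrate the
geometric and algebraic correctness of the forward model — not that the
model captures every contribution to a measured dark-field image, where
non-scatter origins (unresolved phase gradients, beam hardening) are known
to contribute.

## Numerical choices and problem sizes

* Exact identities are asserted at `1e-10` absolute or tighter; the
  axial-projection constancy at `1e-14`.
* Divergence below `1e-7` rad is parallel (see above); `"direct"` mode
  tolerates `|s·r|` up to `1e-9`.
* The in-plane basis of the projection plane is chosen deterministically
  (cross the ray with the global axis of its smallest absolute component);
  invariance to this choice is tested.
* Degenerate fibers with both eigenvalues zero are valid void voxels with
  `d ≡ 0`.
* Test problem sizes: trajectories of 72–240 views, phantoms up to
  $6^3$–$8^3$ voxels, 1000-draw property loops, 50–100-view rod
  simulations — the full suite and the acceptance script each run in
  about a minute on one core.

## Limitations

The chord factor is a model, constrained only qualitatively; no claim of
exactness is made for oblique finite cylinders (the analytic projector
sidesteps it where exact chords are available). Tomographic
*reconstruction* — inverting this forward model — is out of scope, as are
phase stepping, visibility extraction and detector-level effects.
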