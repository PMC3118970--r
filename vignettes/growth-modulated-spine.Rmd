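---
title: "Growth-modulated spine simulation: model, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-modulated spine simulation: model, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model in one page

`vertegrow` simulates ten years (ages 8–18) of anterior-column spinal
growth under mechanical growth modulation. The state is a kinematic chain
of 17 wedged-cylinder vertebral bodies (T1–L5) and 16 intervertebral
discs; geometry is stored intrinsically (heights, radii, wedge angles,
disc joint angles, a root orientation at the fixed L5 base) and all 3D
poses are reconstructed by forward kinematics, so chain continuity is
exact by construction and *growth is the only geometry-update
mechanism*.

Each integration step runs the four-stage cycle:

1. **Apply forces.** Per-level Schultz loads (cumulative fraction of body
   weight: 14 % at T1, +2.6 % per caudal level) are resolved as vertical
   vectors (gravity mode) or redirected along the sagittal tangent of a
   cubic spline through the vertebral centroids (follower mode, the
   default), re-fit on the current geometry at every cycle.
2. **Measure stresses.** For each of the 34 growth plates the axial force
   and the coronal/sagittal moments of the superior load lines about the
   plate centroid are reduced to an affine axial strain field
   `ε(x, y) = ε₀ + κ_c y + κ_s x` by composite-section equilibrium
   (cortical shell 14 500 MPa, cancellous core 400 MPa). Every
   sensitive-layer element is assigned the axial traction of the bone
   column behind it — a thin soft layer in series must carry the same
   axial traction, which is why the element stress uses the backing-bone
   modulus rather than the 12 MPa sensitive-layer modulus (the
   strain-scaled alternative is available via `stress_output =
   "sensitive"`).
3. **Compute growth.** Each element grows by
   `G_m · dt · [1 + β(σ + σ_m)]` (tension positive, so compression beyond
   the reference magnitude σ_m slows growth), floored at zero because
   growth plates do not resorb; the floor only binds under extreme
   bending.
4. **Update geometry.** Per plate, the element increments are reduced to
   their area-weighted least-squares plane: the intercept adds to the
   vertebral height, the two slopes become coronal/sagittal wedge-angle
   increments. The whole column is then posturally rebalanced: a rigid
   rotation about the L5 base returns the T1 centroid to the vertical
   axis and removes net axial spin. This enforces the boundary
   conditions (L5 fixed, T1 transversely restrained) in a kinematic
   model and defines the canonical "standing radiograph" frame in which
   the projection measures are taken.

Outcomes (coronal Cobb by endplate-inclination extremes, T1–T12
kyphosis, L1–L5 lordosis, per-vertebra axial rotation against the fixed
global sagittal plane) are recorded every two years, matching the usual
clinical follow-up cadence.

## What the geometry generator emulates

All inputs are synthesized. `build_spine()` constructs a column of
360 mm total length at age 8 with linearly graded vertebral heights
(L5/T1 = 1.5), disc heights at one quarter of the mean adjacent
vertebral height, and a smooth, balanced single coronal arc (raised-
cosine lateral bump over ±4 vertebral pitches around the apex) plus
uniform thoracic-kyphotic and lumbar-lordotic sagittal arcs. Joint
angles are calibrated by fixed-point iteration until the *measured*
angles reproduce the requested case within 0.05°, so construction and
measurement are exact inverses of each other.

The six standard cases isolate the contrasts of interest: case 1 (normal
alignment, 30° kyphosis), case 2 (hypokyphotic, 10°), cases 3–6
({10°, 20°} coronal × {10°, 30°} kyphosis, apex T8, lordosis 45°). The
exact case angles are configurable assumptions: what matters for the
comparative experiment is the presence/absence of an initial coronal
curve and of hypokyphosis, not their precise values.

What the generator does **not** emulate: posterior elements, rib cage,
pedicles, facet joints, muscles and ligaments; non-circular vertebral
cross-sections; patient-specific geometry. A `constant_regional` growth
mode (0.8 mm/yr thoracic, 1.1 mm/yr lumbar per vertebra) is provided so
that a user with their own measured geometry can replicate
constant-rate validation protocols, but no patient data ship with the
package.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| β | 0.4 (range 0.4–0.6) | MPa⁻¹ | growth-modulation sensitivity; physiologic range from in-vivo modulation experiments |
| σ_m | 0.5 | MPa | reference compressive growth-plate stress |
| body weight | 400 | N | adolescent of ~40 kg; loads enter only through β·σ products so the comparative conclusions are ratio-based |
| load mode | follower | – | see below |
| velocity curves | normal: 1.4 %/yr at 8 → 2.6 %/yr at 12.5 → 0 at 16.5; AIS: 1.8 %/yr at 8 → 3.2 %/yr at 11.5 → 0 at 17.5 | %/yr of the age-8 length | piecewise-linear knots emulating adolescent spinal growth-velocity curves; the AIS spurt starts earlier, peaks higher, ends later. Configurable. |
| vertebral radii | 10 mm (T1) → 20 mm (L5) | mm | anatomic morphometry. The bending stress that drives wedging scales as r⁻⁴, so this is the model's stiffness scale: thinner columns put the feedback loop into finite-time blow-up, thicker ones freeze it. |
| dt / report interval | 0.25 / 2 | yr | a two-year explicit step of a feedback loop is numerically untrustworthy; dt is a separate, finer parameter and halving it moves the final Cobb by ~1 % |
| grid | 5 radial rings × 20 sectors | – | one ring is the 1 mm cortical shell; doubling the resolution changes the strain solution by <1 % |

**Why follower loading by default.** Without musculature, a purely
vertical load on a kyphotic/lordotic column generates large sagittal
moments that the anterior column alone cannot restrain; in a
growth-feedback model this drives an unphysiological sagittal runaway
(the thoracic profile can invert within a simulated decade). The
follower load — the transmitted resultant kept tangent to the sagittal
curve, as established for ex-vivo spinal loading — removes sagittal
bending by construction while leaving the coronal mechanics (vertical
load lines, lateral lever arms) untouched. Gravity mode is fully
implemented and exercised in the sensitivity suite.

## Numerical choices

* Per-step growth uses the exact analytic integral of the piecewise-
  linear velocity curve over the step, not an endpoint sample, so the
  β = 0 run reduces to the closed-form growth integral to machine
  precision.
* The section solve uses sums over the discrete element grid, making the
  discrete equilibrium residual (stress sums versus applied resultants)
  zero to solver precision at every step — this is asserted in the test
  suite via the audit trail.
* Element positions are exact polar-cell centroids; total plate area is
  conserved exactly.
* Wedge increments are `atan` of least-squares plane slopes, exact for
  affine increment fields.
* Geometry blow-up (any wedge > 45° or Cobb > 90°) halts the run with a
  warning and returns partial, flagged results rather than clipping.
* Everything is deterministic: identical configurations give
  bit-identical results.

## Known limitations

* **Magnitude of the profile contrast.** The growth dynamics of this
  reduced model are *separable*: the Cobb trajectory satisfies
  dθ/dt = G(t)·h(θ, u) where u is the accumulated growth ∫G dt, so the
  final angle depends on a velocity profile only through its total
  integral. With the default curves the AIS/normal integral ratio is
  1.29, which caps the achievable ΔCobb ratio for bounded trajectories
  near 1.5–1.7 (measured: 1.60–1.73 across cases 3–6). Volumetric
  finite-element treatments of the same mechanism report contrast ratios
  of three to five; those arise from load-dependent elastic deflection
  that grows superlinearly as the flexible, disc-coupled column
  approaches its elastic stability limit — physics that this package
  deliberately excludes (elastic displacements are never fed back into
  the geometry). The package therefore reproduces the *direction* and
  the qualitative structure of the profile contrast (AIS arm always
  progresses more, in every β/load-mode/velocity-scale condition), not
  the published magnitudes.
* **Sagittal response.** With follower loading the sagittal moment
  vanishes by construction, so kyphosis changes only through the 3D
  coupling of coronal wedging with axial rotation; this coupling is
  small and, in this kinematic chain, slightly *increases* kyphosis
  (≤1.5° over ten years), whereas hypokyphosis is the clinically
  expected trend. Reproducing thoracic flattening appears to require
  either a posterior tether (anterior overgrowth mechanism) or sagittal
  elastic balance — both outside this model's scope.
* Axial rotation is an emergent kinematic by-product (rotations stay
  below ~3° in the default experiment); no torsional mechanics are
  modelled.
* Cross-sections are circular and constant over time (no radial growth),
  material properties are linear elastic, and disc mechanics enter only
  as geometric spacers and stress-partitioning records.

## Problem sizes

The default experiment is deliberately desk-scale: 40 integration steps
per run, 34 plates × 100 elements per step. The full six-case ×
two-profile comparison runs in a few seconds; the complete sensitivity
grid (3 β × 2 load modes × 3 velocity scales × 4 cases × 2 profiles =
144 runs) in about two minutes on one core.
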