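---
title: "Reference-frame conformational analysis of G-quadruplex trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-frame conformational analysis of G-quadruplex trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4geom)
```

## The problem

Intramolecular G-quadruplexes stack two or more guanine quartets into a
rigid stem; the connecting loops (such as the TTA linkers of human
telomeric DNA) are flexible and adopt several conformations on the
hundred-nanosecond scale. Characterising loop behaviour requires geometric
observables defined *relative to the quartet*, which is itself distorted
and fluctuating: a loop base is "stacked" relative to a plane that buckles,
and the quartet's own non-planarity is an observable in its own right.
`g4geom` provides those observables for multi-model PDB trajectories and
ships a synthetic trajectory generator with exact ground truth so the whole
chain is testable at desk scale.

## Base triads

The elementary object is the base triad. Each observed base is fitted by
rigid least squares (closed-form SVD superposition) of a standard planar
base onto its observed ring heavy atoms — 9 atoms for purines, 6 for
pyrimidines; exocyclic substituents are excluded because they bias the
plane. The embedded standard geometries lie exactly in the XY plane with
the origin at the ring centroid, so the triad is simply the image of the
standard frame: origin = fitted ring center, Z-axis = fitted plane normal.

Two numerical decisions matter here:

* **Reflection safety.** Planar atom sets make the smallest singular value
  of the cross-covariance matrix zero, inviting an improper (det −1)
  solution. The decomposition's smallest singular direction is
  sign-corrected so the rotation determinant is always +1.
* **Degeneracy.** Collinear inputs have no defined plane and are rejected
  rather than silently fitted.

The fit is unweighted (all ring atoms weight 1). The glycosidic syn/anti
state does not affect the triad: it moves the sugar, which is not part of
the fitted atom set.

## Group frames by half-angle association

Two Z-axes are combined by rotating the first by half their mutual angle
about their cross-product axis (Rodrigues rotation). The result is the
geodesic bisector, equivalent to the normalized vector sum for unit inputs
— a property the test suite uses as an independent oracle. A quartet
associates pairs (1,2) and (3,4), then the two intermediates; the group
origin is the arithmetic mean of member origins.

Design choices where the construction was genuinely open:

* **Pairing.** Which bases form the two pairs is arbitrary; the default is
  sequence order, with diagonal pairing available. For members within 10°
  of each other the two schemes differ by under a degree (a tested
  property), so the choice is cosmetic.
* **Orientation.** Fitted normals of anti-parallel quadruplexes
  anti-align. All member Z-axes are flipped into the first member's
  hemisphere before association; members nearly perpendicular to the
  reference (|dot| < 0.1 after flipping) cannot be reconciled and raise an
  error rather than producing a meaningless axis.
* **Parallel limit.** When the cross product vanishes the association
  returns the first axis unchanged (the continuous limit). The inter-axis
  angle is computed as `atan2(|z1 × z2|, z1 · z2)` rather than
  `acos(z1 · z2)`: identical in exact arithmetic, but the arccosine form
  loses half the available precision near parallel axes and would inject
  ~1e-8 noise into downstream projections.

## Stacking geometry

For two groups the inter-plane angle uses the acute convention
arccos(|Z₁·Z₂|) — plane normals are unoriented, and stacking angles of
interest are all well below 90°. The Z-distance projects the center
displacement onto the combined (bisector) axis: d_z = |(O₂ − O₁)·Z₁₂|.
Both are symmetric in argument order and rigid-motion invariant (tested
properties).

The default stacking criterion is 3 Å ≤ d_z ≤ 4 Å and angle ≤ 30°, bounds
inclusive. Tightly stacked pairs in real quadruplex loops can sit at mean
Z-distances of 2.5–2.8 Å, below the strict window; a documented loose
preset (2.5–4.5 Å, ≤ 35°) is provided, and the active criterion is always
carried in the result object. Per-frame means and SDs are plain moments
over all frames — no autocorrelation correction and no silent frame
dropping — and the stacked fraction is the classified share of frames.

## Quartet planarity

RMSD_Z measures the departure of a quartet from planarity: each ring atom's
displacement along the quartet Z-axis, in the quartet's own per-frame frame
(origin O_q, axis Z_q, both recomputed every frame), pooled over all
36 atoms:

RMSD_Z = sqrt( Σᵢ Σⱼ z²ᵢⱼ / Σᵢ Nᵢ ).

Pooling over atoms is the default normalization; averaging the four
per-base RMSDs instead is exposed as `normalize = "per_base"` (the two
coincide for symmetric distortions and differ once a single base dominates).
The atom universe is the ring-atom set used by the fitting step, keeping
the statistic and the frame on the same atoms. Over a trajectory the
distribution of RMSD_Z is summarised by its mode (typical distortion) and
SD (fluctuation).

## Hydrogen bonds

A contact is bonded in a frame when the donor–acceptor heavy-atom distance
is ≤ 3.5 Å and some donor hydrogen keeps D–H···A within 30° of linearity
(≥ 150°). The angle is donor-hydrogen-centered; with several hydrogens on
one donor, any satisfying hydrogen suffices. When the roster carries no
hydrogen, detection falls back to distance only and the result is flagged.
Occupancy is the bonded fraction of (optionally windowed) frames; events
are maximal contiguous bonded runs with no gap tolerance by default (a
configurable `gap` parameter can bridge single-frame dropouts); the mean
lifetime is the mean run length times the frame spacing (default 5 ps, a
common trajectory-writing interval).

## Trajectory RMSD and torsions

Pairwise RMSD matrices and RMSD-to-reference series superpose on one
selection and compute over another (fit on the rigid G-stem, compute over
the loop), the pattern needed to isolate loop motion from global tumbling.
Superposition is delegated to `bio3d::fit.xyz`. Per-pair superposed RMSD is
not a metric; the matrix is reported as-is (symmetrized against numeric
noise). Backbone torsions follow the standard nucleic-acid definitions
(α = O3′(i−1)–P–O5′–C5′, χ via N9/C4 for purines and N1/C2 for
pyrimidines), wrapped to [0, 360) and binned into the canonical rotamer
wells g+ = [0,120), t = [120,240), g− = [240,360).

## The synthetic generator

The generator emulates the features of quadruplex trajectories that the
observables respond to, with exact ground truth:

* **Geometry.** Standard guanines at 90° increments, quartet radius 5.4 Å,
  inter-layer rise 3.3 Å and twist 30° — typical quadruplex stem values,
  used as fixture conventions. Loop bases are placed so that the analyzer's
  own definitions recover the nominal pose exactly: the base center sits at
  d_z along the bisector of the quartet and base normals, with the in-plane
  offset orthogonal to the tilt plane. This closure (generator pose =
  analyzer readout to 1e-6 on noiseless frames) is what makes the fixtures
  trustworthy.
* **Dynamics.** Per-base *rigid-body* noise (translation SD per coordinate,
  rotation SD about the base center) keeps bases internally rigid, so fit
  RMSD stays at zero and the signal is purely pose dynamics — matching what
  the observables measure. Per-atom Gaussian noise is available separately
  to stress the fitter. A two-state Markov chain switches one loop base
  between its nominal and an alternate pose; the chain starts in its
  stationary distribution (stacked probability p_enter/(p_leave+p_enter)),
  so empirical fractions are unbiased at any length.
* **Determinism.** A single integer seed fixes the output bit-for-bit,
  including the written PDB.

What the generator does *not* emulate: force-field energetics, solvent and
ions, sugar–phosphate chemistry (only a minimal backbone scaffold exists
for torsion fixtures), correlated base motions, and periodic-box imaging.
Passing tests therefore certify the geometry machinery, not biophysical
realism; conclusions about real loops still require real trajectories.

## Validation scales and numerical tolerances

The test suite validates each stage against independent oracles: SVD plane
fits for axes, quaternion algebra for rotations, normalized-sum bisectors
for associations, `bio3d` superposition for RMSD, and analytic stationary
distributions for Markov recovery. Problem sizes were chosen as the
smallest that make the statistical assertions sharp: 1000 rotation draws,
200 perturbed quartets, 2000-frame trajectories for noise monotonicity and
moment recovery, 5000 frames for Markov and noise-honesty checks (3
standard errors, with the two-state chain's autocorrelation factor
(1+ρ)/(1−ρ), ρ = 1 − p_leave − p_enter, included in the standard error).

The "near-planar perturbed quartet" fixture uses per-base tilts of SD 1°,
in-plane shifts of SD 0.1 Å and out-of-plane shifts of SD 0.02 Å. The
out-of-plane component is deliberately small: a rigid vertical shift of a
whole base moves the 36-atom best-fit plane but no base normal, so the
axis-association and SVD definitions of "the quartet plane" legitimately
diverge as shifts grow — the comparison is meaningful only in the
near-planar regime it is defined for.

Exact thresholds: orthonormality and bisector identities to 1e-9;
equivariance to 1e-6 (absolute, on coordinates up to tens of Å); quartet
axis vs SVD normal within 2°; pose-recovery closure to 1e-6. Degenerate
inputs (anti-parallel axes, collinear atoms, zero vectors) raise typed
errors rather than returning conventional values, except the parallel-axis
association, whose continuous limit is well defined.

## Known limitations

* Only A/C/G/T; modified bases and RNA are out of scope.
* Multi-model PDB is the only required trajectory format; binary formats
  would need conversion upstream.
* No clustering or PCA of RMSD matrices; the matrix itself is the product.
* The package computes statistics; scientific comparisons (force fields,
  loop-present vs loop-deleted stems) are the user's.
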