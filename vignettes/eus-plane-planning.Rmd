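---
title: "Planning EUS views for registration initialisation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning EUS views for registration initialisation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Endoscopic ultrasound (EUS) images the pancreas and its surroundings from
inside the stomach or duodenum through a small fan-shaped field of view.
Registering those 2D views to a pre-procedure labelled CT or MR volume gives
the endoscopist 3D context, but the registration must be initialised from a
handful of anatomical landmarks clicked during the procedure, and its
accuracy depends strongly — and unintuitively — on where the transducer sits
and how the view is oriented. `eusplan` answers the planning question: *given
this patient's labelled volume, from which positions and orientations will a
landmark-based registration be accurate and robust?*

The answer is simulation-based. For every physically plausible sector view
anchored on the transducer contact surface, the package extracts the
landmarks that view would offer, simulates the registration many times under
a landmark-localisation noise model, and summarises the resulting target
registration error (TRE) distribution. Views are ranked by the 90th
percentile of TREs; a view chosen this way achieves its advertised TRE or
better with 90% probability, which is the robustness statement a clinical
planner needs (a small *mean* TRE does not rule out frequent large misses).

## Registration model

Registration is rigid and *landmark-to-structure*: each intra-procedure
landmark is tagged only with the labelled structure it belongs to (pancreas,
splenic vein, ...), never with a specific point. Organs are represented by
the vertices of their segmentation surface, vessels and ducts by their
centrelines, both as point clouds in world millimetres. The fit alternates
closed-form least-squares rigid estimation (Kabsch/SVD, reflections
excluded) with nearest-point correspondence — as in iterative closest point —
with each landmark constrained to its own structure's cloud at every
iteration. At least three landmarks are required for the six degrees of
freedom; the package enforces this everywhere (plane usability, registration
entry points).

The objective has many local minima, so each registration runs `n_starts`
stochastic starts and keeps the smallest final RMS. A start draws random
correspondence points from the structure clouds, subject to a
rigid-invariance screen: three anchor landmarks (those with the smallest
clouds, i.e. the most localising structures) draw points whose pairwise
distances match the landmarks' own pairwise distances within `init_tol_mm`
(default 3 mm, of the order of the cloud spacing plus the landmark error).
Several such draws are made per start and the one whose fitted pose best
explains *all* landmarks seeds the ICP iterations; a final discrete "polish"
re-tries each landmark's few nearest alternative correspondences, which
removes the off-by-one-cloud-point minima that plain nearest-point
assignment cannot escape. With this initialisation, 100 starts recover a
noiseless ground-truth pose exactly on the reference phantom; with plain
uniform draws the success probability per start is of order 10^-3 and no
practical number of restarts suffices. The first anchor's draw is stratified
across the starts so that they jointly sweep the smallest cloud.

## Sector-view geometry and landmark extraction

A candidate view is a sector plane: apex at a contact-surface vertex, 120
degree fan, 50 mm depth (a standard clinical EUS transducer). The contact
surface is the stomach (and duodenum when labelled), decimated to a mean
vertex spacing of 5.33 mm — about half the transducer width — so vertices
sample transducer positions at the right granularity. At each vertex the base
view points along the inward surface normal and a grid of intrinsic
rotations about the vertex's local frame (two tangents, then the normal,
fixed order) generates the candidate orientations. The default grid is
[-60, 60] degrees in steps of 30 per axis, 125 planes per vertex; a 20
degree step (343 planes) is available by configuration when a finer
orientation sweep is worth the extra cost.

Each plane is rasterised at 0.5 mm pitch by nearest-neighbour sampling of
the labelled volume at pixel centres. Every 8-connected in-sector component
of a structure's cross-section becomes a feature; components below 5 mm^2
are discarded (strictly below: a 5 mm^2 feature is kept), since smaller
cross-sections cannot be identified confidently on EUS. Landmarks are
extracted by topology: vessel/duct features yield their cross-section
centroid; organ features yield the boundary point closest to the mean of the
visible boundary segment (the part of the organ's in-plane contour inside
the sector — pixels cut off by the sector edge do not count as boundary).
Occlusion and acoustics are not modelled; visibility is purely geometric.

## Noise model and TRE estimation

Landmark localisation error is zero-mean isotropic Gaussian, independent per
landmark and per draw. Organ landmarks use a fixed 2 mm per-axis SD — a
deliberately conservative figure for boundary localisation. Vessel/duct
landmarks scale with the visible cross-section: sigma = (w + h) / 12 where
`w`, `h` are the feature's bounding-box width and height, i.e. one third of
the mean half-extent. The rule is exposed as a configurable function
(`noise_model(tube_sigma_rule = ...)`) because reasonable readings of its
bracketing differ; under the implemented reading a 6 x 6 mm cross-section
gives sigma = 1 mm.

Landmarks are generated in the pre-procedure frame, so the ground-truth pose
is the identity and any deviation of the recovered transform is error. Two
TRE metrics are recorded per draw: `tre_plane`, the RMS displacement of the
sector's own pixel grid (1 mm evaluation pitch by default; the display
resolution is irrelevant to an RMS over a plane), and `tre_surface`, the RMS
displacement of the clinical target's vertices (e.g. the pancreas), which
measures accuracy where it clinically matters, possibly far from the view.

Per plane, 1000 Monte-Carlo draws are simulated by default. For plane
*pairs*, landmarks from both planes are pooled and the second plane's set is
additionally displaced rigidly per draw by a tracking-pose error (0.4 mm
positional SD; three per-axis rotations of 0.36 degree SD composed about the
second plane's apex — the per-axis composition is a package choice),
reflecting the relative-pose uncertainty of
a tracked endoscope; 100 draws per pair by default. The pair TRE is
evaluated over the union of the two planes' grids; under this reading a
self-pair with zero tracking noise is distributionally identical to a
single-plane simulation with doubled landmarks, which the test suite checks
by a Kolmogorov-Smirnov test.

## Selection, pair sampling and honest reporting

Planes are ranked by the nearest-rank 90th percentile (sorted sample at
`ceiling(0.9 n)`), ties broken by lower mean then lower id. Pairs are drawn
by a 2D Latin hypercube over the index domain (each index stratum sampled
exactly once per dimension, self-pairs and unordered duplicates removed),
which covers the quadratic pair space uniformly at linear cost; the pipeline
default budget is twice the number of contact vertices examined. Because the
optimisation-time p90 of a winner is optimistically biased (winner's curse),
reported statistics are re-estimated from 1000 independent simulations on a
fresh seed; a seed collision with the optimisation run is refused. The
per-vertex TRE map stores each vertex's *minimum* p90 over its orientations
— the planning-relevant value, since the endoscopist will use the best
orientation available at a position — and flags vertices where no plane
offers three features.

## The reference phantom

All of this is testable without clinical data through a built-in synthetic
scene: a hollow stomach-like ellipsoid shell (the contact surface), an
elongated pancreas-like target directly posterior to it, liver-, kidney- and
gallbladder-like organs, and four vessels of radii 4-7 mm (aorta, vena cava,
portal and splenic vein analogues) within scanning depth of the posterior
stomach wall, voxelised at 1 mm isotropic in a 160 x 150 x 130 grid. Organs
are implicit-function thresholded ellipsoids (optionally shells), tubes are
distance-to-polyline thresholded, later labels win where structures touch
(vessels indent organs, as in real anatomy). The scene is asymmetric by
construction — no non-identity rigid transform maps it onto itself, which
the suite verifies by randomized search — so pose recovery is well posed.
Scales, radii and distances were chosen once to mimic upper-abdominal
anatomy at typical abdominal CT resolution and are not tuning knobs.

What the phantom does *not* emulate: real segmentations have irregular,
deformable shapes, duodenal contact is absent, and the clean ellipsoids make
organ boundaries smoother than CT labels. Passing tests therefore
demonstrate the correctness and internal consistency of the machinery and
the direction of its comparative findings (optimised vs non-optimised, one
vs two planes), not clinical TRE magnitudes on any given patient.

## Numerical choices

* Surfaces: the binary mask is smoothed with a 1-voxel Gaussian and the 0.5
  iso-level is triangulated by marching tetrahedra on the Freudenthal
  decomposition of the voxel lattice. The decomposition is globally
  consistent, so meshes are closed and consistently oriented without
  case-table disambiguation; with pre-smoothing plus linear interpolation a
  digitised sphere's area is reproduced to well under 5%.
* Decimation is uniform-grid vertex clustering; the cell size is the target
  edge length divided by 1.01, an empirical ratio calibrated on
  marching-tetrahedra meshes. A target beyond the mesh extent collapses to
  a minimal tetrahedron with a warning.
* Centrelines: topology-preserving (26, 6) thinning — six directional
  sub-iterations deleting simple non-end points with sequential re-checking
  — yielding a unit-wide skeleton; verified against an independent
  implementation of the same simple-point criteria.
* Nearest-point queries are exhaustive linear scans in compiled code; after
  decimation the clouds are small enough (10^2-10^3 points) that a spatial
  index would not pay for itself at these problem sizes.
* Convergence: ICP stops when the RMS improves by less than 1e-4 mm or at
  100 iterations. Ties in nearest-point queries break to the lowest index.
* All randomness flows from R's global RNG (`set.seed`), including the
  compiled ICP's draws, so every simulation, ranking and pipeline run is
  bit-reproducible from its seed; the run manifest records config and seeds.
* Coordinates are world millimetres with 0-based voxel indices,
  `world = origin + index * spacing`; oblique NIfTI direction matrices are
  rejected rather than silently resampled.

## Problem sizes used in the tests and acceptance script

The suite exercises the full pipeline at desk scale: 8-10 contact vertices
(125 candidate planes each), 15-40 optimisation draws per plane, 100 Latin
hypercube pairs at 25 draws, 500-draw comparisons for the optimal-vs-random
and one-vs-two-plane properties, and 1000-draw re-estimation of the winners.
These sizes keep a full run in minutes while leaving every statistical
property comfortably powered; they are stated here as the package's chosen
study conditions.

## Known limitations

Rigid registration only — organ deformation between CT acquisition and the
procedure is outside the model. Visibility is geometric; shadowing,
attenuation and speckle are not simulated. Landmark extraction assumes the
labelled volume is correct; segmentation uncertainty enters only through the
(conservative) organ noise sigma. The vessel noise rule's bracketing is an
interpretation, kept configurable. Simulated TRE magnitudes depend on the
optimiser's strength: the seeded initialisation here converges more reliably
than a plain stochastic start, so absolute TREs should be compared between
plans produced by this package, not against externally reported figures.
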