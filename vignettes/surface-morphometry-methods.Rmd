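---
title: "Surface-based tube morphometry: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based tube morphometry: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hippomorph implements a surface-based morphometry pipeline for tube-like
subcortical structures such as the hippocampus: binary segmentation masks
(or meshes) are turned into closed genus-zero surfaces, given a common
rectangular parameterization, registered to a template grid, and compared
vertex-by-vertex with multivariate morphometry statistics under a
permutation-corrected group test. This vignette explains each model, the
tunable parameters and why their defaults are what they are, what the
synthetic cohort generator does and does not emulate, and the numerical
choices that keep the pipeline deterministic and robust.

## 1. From masks to surfaces

`reconstruct_surface()` consumes a binary occupancy grid with a
voxel-to-world affine. Topology is secured *before* meshing: one
morphological closing pass, then selection of the largest 26-connected
component (small outlier clusters, as produced by occasional segmentation
errors, are dropped below a configurable voxel count), then an explicit
Euler-characteristic check after meshing. The isosurface itself is
extracted by marching tetrahedra on a 6-tetrahedron cube decomposition at
the 0.5 level of the binary grid; the output is watertight by construction
and needs no case-table disambiguation. Voxels are treated as cell-centred
samples; before isosurfacing the grid is refined 2x by nearest-neighbour
supersampling, which keeps the mesh close to the voxel-boundary surface so
that enclosed volumes track voxel-count volumes (a digital ball of radius
10 voxels reconstructs to within ~1% of the analytic sphere volume).

`simplify_and_refine()` realizes the coarse-to-fine resampling contract:
quadric edge-collapse decimation (link-condition guarded, so the Euler
characteristic is preserved) when the mesh is above target, and Loop
subdivision with closest-point projection back onto the input surface when
below, iterated to land within 1% of the requested vertex count (default
15,000 per side). A symmetric Hausdorff bound (default 1% of the
bounding-box diagonal) is enforced and a quality error raised when it
cannot be met.

`mesh_volume()` integrates signed tetrahedra and reports the absolute
value, so global orientation does not matter; volumes are reported in the
mask's registered space (the affine is accepted from the input header or
configuration, never estimated here).

## 2. Conformal tube parameterization

A closed tube surface is opened at both ends (`compute_cuts()`): vertices
are projected on the first principal axis of their second-moment tensor
and the extreme 2% at each end (`cap_fraction`) are removed as the
connected component containing the end pole, leaving a topological
annulus. Near-isotropic shapes (top-two moment eigenvalue ratio below
1.1) raise an error asking for a manual axis, since no stable cut
direction exists.

`conformal_parameterize()` computes the axial coordinate u as the discrete
harmonic function of the cotangent Laplacian with Dirichlet data 0/1 on
the two cut loops (cotangent weights clamped at a small positive floor for
obtuse-triangle robustness). The angular coordinate v is the conjugate
1-form: the Hodge-rotated gradient of u is integrated in least squares
over the mesh cut open along a u-ascending vertex path, with the jump
across the cut constrained to be exactly constant; dividing by that jump
makes v periodic with period exactly 1, and the parameter domain closes to
unit area at machine precision. On a circular cylinder this reproduces
the closed-form map (u the normalized axial coordinate to ~1e-14, v the
normalized angle to ~1e-13 up to gauge rotation and orientation).

Two gauge choices are needed that the underlying theory leaves free:

* **Rotational gauge.** v is only defined up to rotation. The anchor is
  chosen on the posterior cut loop in the direction of the bend plane
  (estimated from middle-third slab centroids of the centerline against
  the end-to-end chord, a global moment that is robust to local shape
  noise). After grid resampling, `align_grid_gauge()` refines this: every
  ring's in-plane moment major axis is located at sub-cell precision and
  the grid is rotated, ring by ring with smoothing along u, so the major
  axis sits at v = 0. This per-ring step also removes rotational *twist*
  between subjects, which otherwise survives as a correspondence error
  that no feature-based registration reliably removes.
* **Orientation.** The sign of v is fixed by requiring positive signed
  areas of the parameter triangles, so all subjects share chirality.

Orientation-flipped parameter triangles are counted; by default up to
0.2% sliver flips are tolerated (they occur occasionally on strongly
deformed noisy meshes and are harmless to barycentric resampling), more
raise a quality error.

`resample_to_grid()` interpolates positions, the log conformal area factor
and mean curvature barycentrically onto the n_u x n_v analysis grid
(default 100 x 150 = 15,000 nodes; the validation studies in this package
run at 20 x 75 = 1,500). Grid nodes falling into numeric gaps near the
cut seam are filled by nearest-triangle projection and counted; more than
1-2% such nodes is again a quality error.

## 3. Inverse-consistent fluid registration

`fluid_register()` matches the 2-channel feature image -- z-scored log
conformal factor and mean curvature, optionally pre-smoothed by
`feature_sigma` (default 1.5 cells) to suppress curvature speckle from
vertex noise -- using demons-style compositive updates with Gaussian
velocity smoothing (`sigma`, default 3 cells): the standard fluid
approximation. The angular direction is periodic; displacement normal to
the cut boundaries is zero. Because the angular gauge can differ between
subjects by more than the demons capture range, a global circular-shift
initialization is estimated first. Increments are capped at `max_step`
(0.4 cells, the regridding rule), and the total field receives diffusion
regularization (`disp_sigma`, default 3 cells). Forward and backward
problems are solved jointly and symmetrized by averaging each field with
the inverse of the other until composing the two deviates from the
identity by less than `ic_tol` (default 0.1 cells at the 95th
percentile). The mismatch trace is monotone by construction (step
halving), and any non-positive node Jacobian in the final field is an
error.

The deliberately stiff default (`disp_sigma` = 3) is a design decision
worth stating: a flexible field minimizes feature mismatch partly by
stretching template correspondence *over* localized unmatched features
(e.g. an atrophy dimple absent from the template), which inverts the
local area signal. With correspondence pinned by the conformal structure,
the ring-moment gauge, and the rotation initialization, the fluid step
only needs to correct smooth low-frequency residuals, and a stiff field
does that without the artifact. Constants are config-exposed and were
tuned on synthetic cohorts.

## 4. Multivariate morphometry statistics

For each grid face the registration map contributes a 2 x 2 Jacobian J,
computed as the linear map between corresponding *embedded* triangles:
the template face and its image on the subject surface (positions sampled
at the registered parameter coordinates), each expressed in its own
in-plane orthonormal frame anchored to the first edge and then rotated so
the frame follows the image of the parameter-u direction. With this
construction det J measures the true areal change of the surface map --
a uniformly 0.9-scaled subject gives det J = 0.81 and mTBM
(log 0.9, 0, log 0.9) exactly -- rather than a parameter-bookkeeping
quantity. Concretely, J = [w3 - w1, w2 - w1] [v3 - v1, v2 - v1]^-1: the
unique linear map sending the source edge vectors onto the target edge
vectors.

The deformation tensor log sqrt(J J^T) is evaluated per face in closed
form, aggregated to vertices by area-weighted averaging of the tensors
*before* the matrix logarithm (preserving positive-definiteness), and its
three unique entries (m11, m12, m22) joined with the radial distance --
the Euclidean distance from each node of the registered subject surface
to its ring's medial-core centroid -- to form the W x 4 MMS feature
matrix. Per-vertex det J is carried alongside for the directionality
maps. Radial distance is computed on the registered subject geometry at
template correspondence (a config switch for the template-side frame is
not provided; the subject-side choice is the one that measures subject
anatomy).

## 5. Group contrasts and the two-level permutation test

At each vertex the two-group difference of MMS vectors is measured by the
Mahalanobis statistic M = (N_S N_T / (N_S + N_T)) d' Sigma^-1 d with
pooled covariance Sigma, shrunk toward its diagonal while a
Cholesky-based conditioning surrogate exceeds 1e8 (4 x 4 covariances from
small groups can be near-singular). `permutation_pmap()` then runs
group-size-preserving label permutations (default 10,000; identical
across vertices within a repetition), and:

* uncorrected vertex p = (#\{M_perm >= M_obs\} + 1) / (n_perm + 1) -- the
  +1/+1 correction keeps p strictly positive, and ties count toward the
  numerator (conservative; a strict-inequality switch is provided);
* the map-level correction compares the observed p_feature (count of
  vertices with p below alpha = 0.05) against each permutation's own
  p_feature from its leave-self-in rank in the common permutation
  distribution, giving the corrected map-level p.

`ratio_map()` reports R = mean det J(group 1) / mean det J(group 2) at
significant vertices; R > 1 classifies atrophy of group 2 relative to
group 1. `pvalue_cdf()` plots sorted p-values against uniform quantiles;
the maximal vertical deviation above the diagonal summarizes effect
strength. `compare_volumes()` is the scalar benchmark: a two-sided
permutation test on group mean volumes with the same p estimator.

## 6. The synthetic cohort generator

No imaging data ships with the package; every downstream claim is
validated on synthetic cohorts whose ground truth is known. The default
template is an elongated bent tube (length 40 mm, effective radius 5 mm,
total bend 0.6 rad) with an area-preserving elliptic cross-section
(aspect 1.5, major axis in the bend plane) and smoothly tapered rounded
ends. These defaults are deliberate: the dimensions match a human
hippocampus; the ellipse gives every cross-section a well-defined moment
axis, which is what anchors the rotational gauge (a circular tube leaves
rotation to chance); and the rounded ends remove the sharp cap rim at
which tiny differences in cut placement would otherwise flip boundary
rings between very different radii.

Each subject deforms the template by three components applied along
vertex normals: (i) a band-limited random trigonometric field (harmonics
up to order 4 with gently decaying amplitudes and extra weight on the
l = 1 lateral-asymmetry modes; RMS amplitude `subject_variability_sd`,
default 0.3 mm); (ii) the atrophy patch -- an inward displacement of the
group's effect magnitude under a raised-cosine taper (differentiable at
the boundary, so no self-intersection artifacts) centred at (u, v) =
(0.45, 0) with parameter radius 0.3; (iii) isotropic vertex noise
(default 0.05 mm). An optional per-subject lognormal global size factor
(`global_scale_sd`) can emulate native-space size variation; the default
of 0 corresponds to meshes already normalized to a common (MNI-like)
space, matching the pipeline boundary where an upstream affine is assumed
to have removed size. Subjects failing a validity screen (flipped faces
or collapsed rings) are regenerated from a derived sub-seed, and the
count is recorded. Every generator is a pure function of its
specification and seed.

The effect magnitudes (0 / 0.6 / 1.2 mm for NC / HT / HM) were calibrated
once so that the HM-vs-NC contrast reaches map-level significance at the
study group sizes, with the HT effect at half dose; on a 5 mm tube the HM
patch is a ~20% local radial deficit, deep but within the range of
late-stage subfield atrophy. The l = 1 weighting of the variability field
reflects how real cohorts vary (lateral arch differences dominate) and
has a statistical role: the medial-core radial distance responds to an
asymmetric patch partly through the core centroid, and a cohort with
realistic asymmetry variance keeps that global response inside the null
spread instead of letting it masquerade as signal far from the patch.

What the generator does *not* emulate: hippocampal subfield anatomy and
digitations, T1 intensities, or segmentation-specific error modes.
Passing the validation studies therefore demonstrates that the pipeline
recovers localized, dose-graded shape effects under realistic noise and
correspondence uncertainty -- not that it reproduces any particular
anatomical finding.

## 7. Validation studies and the scales they run at

Two replicate studies exercise the full pipeline end to end, at a reduced
analysis scale chosen to keep each study in the minutes range on a single
core: a 20 x 75 grid (1,500 vertices), 1,000 permutations, generation
meshes of 24 x 16 (null) or 30 x 20 (dose) rings x vertices.

* `null_calibration_study()`: 200 independent zero-effect cohorts (two
  groups of 5) through geometry and test; the corrected p must be uniform
  -- rejection rate at alpha = .05 inside its binomial band and a
  Kolmogorov-Smirnov check against U(0,1). Under the null, label
  exchangeability holds for any deterministic pipeline, so the replicates
  use a reduced registration iteration budget.
* `dose_effect_study()`: 20 cohorts of 12/12/12 with the default effect
  magnitudes; summaries are the fraction of replicates with
  p_feature(NC vs HM) >= p_feature(NC vs HT), the median Dice overlap
  between the HM significance mask and the seeded patch support (taper
  weight >= 0.05), the fraction of replicates whose HM contrast reaches
  corrected p < .05, the fraction of in-patch significant vertices the
  ratio map classifies as atrophy, and the CDF-deviation ordering.

The replicate group sizes are a design choice: large enough for the
corrected test to have power at the calibrated effect, small enough that
twenty full-pipeline replicates stay affordable. A known behaviour worth
stating: the multivariate statistic also responds, weakly but
systematically, to the global couplings a focal patch induces (core
centroid shift in radial distance; area renormalization of the conformal
correspondence), so the significance mask is always somewhat larger than
the seeded patch. The Dice criterion sits near 0.5 for exactly this
reason; values far above it would indicate an implausibly clean
separation under this generator.

## 8. Degenerate inputs and tie-breaks

Empty masks, open meshes where closed ones are required, near-isotropic
moment tensors, groups below two subjects, zero-variance volume samples,
and alpha outside (0,1) raise typed errors. Ambiguous argmax choices
(gauge anchor, cut seeds) resolve to the first index; the permutation
test's tie rule is documented above; all RNG flows through explicit
seeds, and re-running any stage with the same configuration is
byte-identical (the pipeline cache is keyed by content hashes of stage
inputs).

## 9. Known limitations

The fluid step is a demons-style approximation with Gaussian velocity
smoothing, not a full viscous-PDE solve; its constants are tuned for
tube-like surfaces at desk scale. Radial distance is medial-core based
and therefore couples a focal deformation to its ring's centroid -- a
property of the statistic, not of the implementation. Covariate
adjustment of contrasts is out of scope (the intended cohorts are
demographically matched). Landmark-constrained registration, spherical
parameterization and groupwise template estimation are not provided.
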