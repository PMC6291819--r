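---
title: "Simulating OCT-guided laser labeling of the internal auditory canal"
author: "lasernav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating OCT-guided laser labeling of the internal auditory canal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a middle cranial fossa approach the surgeon works on the superior
surface of the petrous bone, under which the internal auditory canal
(IAC) runs without any visible surface landmark. An image-guided
workflow can outline the buried canal directly on the bone: a
cone-beam CT (CBCT) scan supports segmentation and planning; spherical
titanium fiducials fixed to the craniotomy edge are visible both in
CBCT and in the optical coherence tomography (OCT) view of a combined
OCT/Er:YAG-laser head; detecting the spheres in both modalities yields
the rigid transform from the planning frame to the laser frame; and the
laser then marks the planned outline on the bone by shallow ablation.
The clinically decisive question is the accuracy with which a planned
(desired) point is actually marked (applied) - sub-millimetre accuracy
is required this close to the cochlea, the superior semicircular canal
and the facial nerve.

`lasernav` rebuilds this workflow at desk scale as a fully synthetic,
seeded simulation with exact ground truth, so that the
accuracy-verification loop - place spheres on the ablated sites,
rescan, compare desired vs applied - can be repeated thousands of
times and decomposed by error source.

## The phantom and what it emulates

`makeCbctPhantom()` builds one synthetic specimen:

* **Bone surface.** A smooth analytic height-field `z = h(x, y)`
  (low-order polynomial plus an optional Gaussian bump). Keeping the
  surface analytic gives exact surface normals, exact lift of planned
  points onto the surface, and an exact reference for the OCT render.
* **Canal.** A tube of radius 0.7 mm running at a constant 1.0 mm
  depth below the surface, with two straight arms meeting at a medial
  apex (the V the marking outlines). The generated solid is a capsule:
  the polyline-distance construction rounds the tube ends.
* **Fiducials.** By default four 1 mm titanium spheres along an arc of
  the (curved) craniotomy edge, consecutive surface-to-surface gaps
  drawn uniformly within 1-2 mm. Arc curvature guarantees the
  non-collinearity that makes both the correspondence search and the
  rigid fit well-posed. Each sphere sits proud of the surface on its
  mount (standoff 0.75 mm between surface and sphere bottom): with the
  marker fully surrounded by air, the intensity-weighted centroid of
  its partial-volume CBCT footprint is an unbiased estimator of its
  center, which is what makes sub-voxel localization clean. The same
  mounting is assumed for the verification spheres, and detection
  subtracts the known mount offset along the surface normal.
* **CBCT render.** 0.3 mm isotropic voxels over a 16.8 mm cube. Air,
  soft tissue (canal interior), bone and titanium are nominal intensity
  levels (0 / 150 / 400 / 1200); the titanium level must exceed bone by
  more than six noise standard deviations so thresholding is
  well-posed (a validity rule of the spec object). Spheres are
  rendered by supersampled partial-volume occupancy (8^3 sub-cells per
  voxel; the rendered mass matches the analytic sphere volume to well
  under 1%); Gaussian noise (SD 20) is added per voxel.
* **OCT render.** The laser/OCT frame is a cube of side 10 mm centred
  on the device origin - the volume over which the OCT view and the
  addressable laser focus overlap. Signal exists only from the outer
  surface down to 1 mm below it in bone, with exponential attenuation
  (2 /mm); titanium spheres appear only as their upper caps (strong
  reflectance, rendered as a narrow triangular band so the axial
  position survives voxel sampling) with a shadow beneath, since
  near-infrared light does not penetrate titanium; multiplicative
  mean-one log-normal speckle (log-SD 0.2) is applied. The hidden
  CBCT-to-laser transform is a small random rotation plus the
  translation a practitioner would choose by aiming the device: region
  of interest centred laterally, bone surface in the lower half, all
  marker caps below the mid-plane of the spectral view.

Everything stochastic flows from one integer seed per phantom;
identical `(spec, seed)` reproduce volumes and ground truth bit for
bit.

What the phantom does **not** emulate: CT beam hardening and metal
artifacts around titanium, OCT wave optics (speckle is statistical,
not interferometric), tissue inhomogeneity, and any deformation
between scans. Passing the accuracy tests therefore demonstrates the
soundness of the geometric pipeline under controlled noise, not the
performance of any scanner on real bone.

## Detection

**CBCT.** Two-stage Otsu thresholding (air/bone, then bone/titanium on
the upper tail), 26-connected components via the voxel adjacency
graph, a plausibility filter on the equivalent-sphere diameter (within
50% of the expected 1 mm), then an intensity-weighted centroid over the
component dilated by two voxels (weights floored slightly above zero to
suppress noise). On noise-free phantoms the centroid lands within a
few micrometres of truth; the tested contract is 0.1 voxel (0.03 mm).

**OCT.** Per A-scan column the sub-voxel surface height is the
intensity centroid around the topmost above-threshold voxel. Cap
columns are separated from bone columns by Otsu on the maximum
adjacent-pair sum along the column - a peak measure chosen because the
two-sample sum across a triangular band is independent of the sampling
phase, where the single-voxel peak is not. A close-up view containing
no bone at all is recognised by its unimodal peak distribution and
treated as all-cap. Cap columns are clustered by lateral adjacency and
each cluster's surface points are fitted with a sphere of **known**
radius (0.5 mm) by Gauss-Newton least squares: the visible cap alone
constrains the radius poorly, so fixing it to the physical value is the
stable choice. A free-radius fit (algebraic initialisation, then
geometric refinement) is available and recovers the 1 mm diameter
within a few micrometres on noise-free renders - that is the package's
check that the render and the fit agree about the marker size.

**Correspondence.** Inter-marker distances are rigid-motion
invariants, so the labeling is found by exhaustive search over all
injective assignments (at most 6 markers keeps this exact), minimising
the squared discrepancy between distance matrices. Two assignments
within 1e-6 mm^2 of one another raise an ambiguity error: a navigation
system must refuse a symmetric marker arrangement rather than guess.

## Registration and error measures

The rigid fit is the closed-form least-squares solution (centroid
alignment plus SVD of the cross-covariance with determinant-sign
correction - the Kabsch solution), chosen over iterative optimisation
because it is deterministic and initialisation-free. Collinear moving
points raise a degenerate-configuration error. The fiducial
registration error (FRE) is defined as the RMS of residual norms; the
plain mean is reported alongside because headline "mean error" figures
in this field rarely say which summary they are. Target registration
error (TRE) is evaluated at the planned targets against the hidden true
transform; tests pin it to the closed form `2 sin(theta/2) d` for pure
rotations and to O(sigma) convergence as fiducial noise vanishes.

## Planning

"Directly above the canal edge in the surgeon's line of sight" is
operationalised as a silhouette: project the segmented canal mask along
a configurable view direction (default vertical, required within 60
degrees of the mean surface normal), take the two extreme transverse
coordinates per station along the medial axis, lift both edge polylines
to the bone surface along the view direction, resample at 0.5 mm
arclength (a spacing near the ablation spot scale; the number of
marks used in the original cadaver work is not reported), and order
the result as one path: lateral -> medial apex -> lateral. The
segmentation itself is a reproducible stand-in for interactive
workstation segmentation: band thresholding at the canal's soft-tissue
intensity, morphological closing, largest connected component.

## Ablation model

The crater model is deliberately empirical, reflecting what is actually
reported for the device: each cycle removes 0.3 mm of bone depth, the
focus spot travels at 4 mm/s (path time = executed polyline length /
speed), the addressable workspace is a centred 10 mm cube, and usable
incidence is 45-90 degrees between surface plane and beam. Points
violating workspace or incidence are flagged and skipped, never
silently executed. Beam-pointing execution noise is a configuration
knob (default 0; the accuracy study enables 0.05 mm isotropic SD) so
that the error budget can attribute error to execution separately from
imaging and detection.

## The accuracy study

`runAccuracyStudy()` repeats the whole loop per replicate: fresh
fiducial arrangement and hidden transform -> CBCT + OCT render ->
detection in both modalities -> correspondence -> rigid fit -> canal
segmentation and planning -> transfer -> constraint check -> ablation
-> verification. Verification mirrors the physical procedure: spheres
are placed at a spaced subset (minimum 2 mm separation, so the spheres
stay distinct in the scan) of the achieved marks, a fresh CBCT is
rendered, the spheres are re-detected, the mount offset is removed,
and each measurement is assigned to its nearest planned point. The
desired-vs-applied comparison is made in the CBCT (plan) frame,
mapping physical marks back through the **true** transform - the frame
choice is ours; the original report does not state in which frame it
compared. Failed replicates (detection failure, ambiguity) are counted
and reported as a failure rate, never dropped from the denominator.

Problem sizes are a deliberate choice: the study renders CBCT at its
native 0.3 mm (56^3) and OCT on a 0.08 mm grid (125^3) rather than the
0.03 mm single-view default, which keeps a 200-replicate study around
five minutes on one CPU while leaving OCT cap localisation errors (a
few micrometres) far below the error sources under study. All physical
parameters - marker size and spacing, workspace, noise, depth per
cycle - are unchanged by this scaling.

With every error source enabled the pooled mean desired-vs-applied
error of the default study sits well under the 0.3 mm bound that the
workflow needs to meet (the standing acceptance test asserts
`mean <= 0.3 mm` over 200 replicates at a fixed seed; `errorBudget()`
decomposes the mean by source, and a pure-fiducial-noise TRE
simulation verifies the near-linear scaling of error with noise).

## Numerical choices and degenerate inputs

* Voxel convention: 0-based indices, index-to-world maps to voxel
  centres, axis-aligned volumes; one convention stated once and tested
  everywhere.
* Supersampled occupancy uses sub-cell centres; symmetric sub-cell
  layout makes the rendered sphere exactly symmetric when the centre
  sits on a voxel centre (a tested invariant).
* Surface solves (OCT height per column, lifting plan points) use a
  vectorised Newton iteration with an analytic derivative and a slope
  floor of 0.2 to guard near-grazing geometry.
* Sphere fits cap their Gauss-Newton iterations and fall back to the
  algebraic solution if the normal equations become singular; clusters
  whose lateral extent is below 0.6 of the marker radius are dropped
  with a warning as too ill-conditioned to fit.
* Ties and ambiguity are errors, not guesses (correspondence); surplus
  detections are trimmed to the expected count with a warning, and
  missing detections are surfaced, never padded.

## Known limitations

The simulation shares one frame convention between planner and device
and therefore cannot expose calibration errors of a real system. The
binary background render (no partial volume for bone and canal edges)
makes segmentation slightly cleaner than clinical CBCT. Fiducial
mounting geometry is idealised; a real sphere seated in an ablated
crater would need a crater-depth-dependent offset model. The error
budget treats sources as independent when summing in quadrature, which
is a heuristic, and the OCT speckle model is statistical rather than
physical.
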