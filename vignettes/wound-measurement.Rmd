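---
title: "Measuring chronic wounds from stereo-derived point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring chronic wounds from stereo-derived point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundmetrics)
```

## The measurement problem

Chronic wounds (vascular ulcers, pressure sores, diabetic foot ulcers) are
monitored through a handful of morphological parameters: maximal depth,
perimeter, surface area, the area of the wound footprint, the two main
axes, the cavity volume, and the composition of the wound bed in the
red–yellow–black scale (granulation, slough, necrosis). Manual techniques
— rulers, acetate tracing, cotton-tip depth probing, saline filling — are
invasive, painful and operator dependent. `woundmetrics` implements a
contactless alternative: a calibrated stereo camera pair yields a dense
coloured point cloud of the wound and surrounding skin; everything else
is computed from that cloud, the reference-camera image, and a coarse
contour supplied by the clinician. A miniature projector, calibrated
against the reference camera, closes the loop by projecting the previous
visit's wound outline back onto the patient for follow-up.

The processing chain is:

1. **Stereo geometry** (`rectifyPair`, `disparityNCC`,
   `triangulateRectified`): rectification reduces matching to a row
   search; block matching with normalized cross-correlation and
   sub-pixel parabola refinement produces a disparity map; triangulation
   with `Z = f b / d` lifts it to 3D. The lateral and depth resolutions
   follow `dX = 2 D tan(FOV_H/2)/C_H`, `dY = 2 D tan(FOV_V/2)/C_V` and
   `dZ = D^2/(f b)` (`reconstructionResolution`).
2. **Segmentation** (`refineContour`, `expandROI`, `liftTo3d`): a
   region-based two-phase active contour (Chan–Vese) refines the coarse
   user polygon; the wound region is grown by 50% of its area to collect
   surrounding skin; both masks are lifted to labelled 3D points through
   the pixel provenance map.
3. **Surface reconstruction** (`fitSOMMesh`): a self-organizing map whose
   nodes are the vertices of an `r x c` quad grid and whose weights are
   3D coordinates is trained on the wound points. The grid topology
   gives a hole-free mesh; the averaging in the learning rule suppresses
   reconstruction noise.
4. **Clinical parameters** (`computeReport`): the skin plane `π` is the
   total-least-squares plane through the skin points in Hessian normal
   form `p · n0 − d0 = 0`; depth is `sup_x (n0 · x − d0)` over mesh
   vertices; the perimeter comes from Moore-neighbour tracing with
   Jacob's stopping criterion; the 3D area sums the per-quad
   cross-product areas; the projected area applies a 2D alpha-shape to
   the plane-projected points; the main axes are the extents along the
   two principal directions; the volume integrates the region enclosed
   between the mesh and the plane.
5. **Tissue classification** (`slicSuperpixels`, `classifyTissue`): SLIC
   superpixels over the wound, k-means on their mean CIELAB chroma
   `(a, b)` seeded with the clinician's picks, and area-weighted
   composition over the 3D surface.
6. **Registration + AR** (`triangulateFiducials`, `rigidLsq`,
   `renderProjectorOverlay`): the fiducials of a small checkerboard
   marker are triangulated in both visits; the rigid transform
   `p_curr ≈ R p_prev + T` is solved in closed form (SVD); the previous
   perimeter is mapped into the current frame and rasterized on the
   projector's image plane.
7. **Reliability statistics** (`accuracyPct`, `coefVariation`, `icc21`,
   `repeatabilityCoeff`): accuracy as signed percent deviation,
   precision as coefficient of variation `σ/|x̄|`, inter-rater agreement
   as ICC(2,1), and the repeatability coefficient `2.77 s_w` from
   one-way ANOVA.

## Synthetic phantoms as the validation bench

Physical test objects with known geometry are replaced by analytic
phantoms (`makePhantom`): **A**, a hemispherical cavity of radius 6 mm
(the hardest case — its rim wall is vertical); **B**, a trapezoidal
footprint (20/12 mm bases, 18 mm long) with a linear depth ramp from 0
to 7.5 mm, ending in a cliff the camera cannot see past; **C**, a
half-ellipsoid 18 × 11 mm, 4 mm deep, with three tissue classes; **D**,
a seeded random smooth boundary with a bumpy depth field rescaled to a
5.4 mm maximum. Ground truth is closed form for A–C and ~10^6-sample
numerical integration on a fixed 0.025 mm grid for D. One convention
matters: the ground-truth 3D area is the area of the height-field graph
over the footprint. Vertical cliff walls (phantom B's deep edge) are
excluded, because a camera looking along the optical axis cannot sample
them; the continuously sloped wall of a hemisphere is included, because
it is sampled (if sparsely) by the image grid.

`sampleCloud` emulates the reconstruction: grid sampling at the lateral
pixel pitch (default 0.2 mm), Gaussian noise on the depth coordinate
(default σ = 0.1 mm) where disparity noise concentrates, an optional
rigid pose, and the pixel provenance map. The defaults are finer than
the raw single-pixel depth resolution of a far working distance because
the correlation matcher and the SOM average many pixels per surface
element; the fixtures are meant to exercise the *pipeline*, not to model
the sensor's physics. What the phantoms do **not** emulate: curved or
deformable skin, specular highlights and exudate, occlusions and
undermining, texture-dependent matching failures. Passing this bench
therefore validates the geometry and the algorithms, not clinical
performance on real wounds.

`simulateRaterStudy` repeats the full pipeline over raters × phantoms
with per-cell working distance, device tilt, contour jitter and sensor
noise, feeding the reliability statistics the same study shape used for
multi-operator device assessments.

## Numerical and design choices

**Vector-valued contour refinement.** The two-phase Chan–Vese model is
applied to the RGB vector image (region mean colours) rather than to
grayscale intensity: bright yellow slough has nearly the same luminance
as light skin, and an intensity-only model pushes it outside the wound.
The evolution uses the morphological discretization (sup-inf/inf-sup
smoothing operators alternating with the region-competition flip), which
is unconditionally stable and deterministic; `mu` maps to the number of
smoothing passes per iteration. Convergence is declared when the
fraction of flipped pixels stays below `tol` for three consecutive
iterations.

**SOM schedules.** Grid 64 × 64 for the wound mesh; learning rate decays
exponentially 0.5 → 0.01 and the Gaussian neighbourhood radius
`max(r, c)/2 → 1` over 10 epochs of the shuffled cloud; the grid is
initialized as a planar lattice spanning the two leading principal
directions of the cloud, which keeps the topology unfolded (a fold
check in the PCA parameter plane triggers one jittered restart). With
fewer points than nodes the map simply interpolates — useful for small
wounds at coarse pitch — so that case warns instead of failing.
Training draws are importance-weighted by the local 3D area element
(`pixelAreaWeights`): image-grid sampling foreshortens steep walls, and
without the weighting the map starves them of nodes and underestimates
the 3D area badly.

**Rim handling, the main accuracy lever.** Three digitization effects
bias boundary-referenced quantities low by about half a sample pitch
each: masks select pixel *centres* inside the wound, converged SOM
border nodes sit at the centroid of their data cells, and the traced
boundary runs through the outermost inside pixels. The package
compensates at the rim: `rimAnchorPolygon` places the wound rim at the
half-pixel crack between the last inside and first outside pixel —
exactly at the skin-plane crossing of that segment when the surface is
continuous across it, and with only the in-plane half-pixel offset when
the depth jump exceeds three local depth steps (a cliff). The mesh
border is snapped onto this polygon, the perimeter is the length of its
projection onto the skin plane (the wound *opening*, the clinically
reported quantity), the projected area adds the half-pitch boundary
band, and the main axes add one pitch to each extent. All corrections
sit behind `correction = TRUE` and are disabled in the property tests
that compare against raw point-set oracles.

**Areas and volume.** The 3D area uses the per-quad cross-product rule
(half the sum of the two opposite-corner cross products), which agrees
with a two-triangle decomposition to first order and exactly on planar
quads. The projected area uses an in-package incremental Delaunay
triangulation with an alpha filter (triangles with circumradius above
alpha removed); alpha defaults to twice the median nearest-neighbour
spacing and grows automatically (with a warning) to the smallest value
whose complex covers every point. Exact co-circularity of grid-sampled
points is broken by a deterministic O(1e-6)-relative jitter. The volume
clamps above-plane vertices onto the skin plane and integrates the
region between the mesh and its orthogonal projection by the prism rule
(signed projected triangle area times mean depth) — exact for the
piecewise-linear surface, independent of the scene's absolute position,
and equivalent to capping the mesh rim onto the plane as a watertight
solid.

**Degenerate inputs.** Collinear skin points, empty masks, uniform
images, clouds of identical points, fewer than three fiducials, and
zero-variance rater matrices all raise errors with explicit messages;
a wound entirely above the skin plane clamps depth and volume at zero
(hypergranulation is out of scope).

## Problem sizes used in the validation bench

The accuracy/precision bench runs phantoms A–D at 0.2 mm pitch with
σ = 0.1 mm over 10 seeds (40 full pipeline runs); the noiseless depth
checks sample B and D at 0.1 mm (~3 × 10^4 wound points); the AR
simulation uses 100 Monte-Carlo trials of 0.2 px fiducial noise at
200 mm working distance. These sizes keep a full validation run within
a few minutes on one core while leaving the Monte-Carlo standard errors
an order of magnitude below the tolerances being checked.

## Known limitations

* The stereo matcher is a plain NCC block matcher; repetitive texture
  or low-texture skin defeats it. The pipeline consumes clouds from any
  source through `woundCloud`, so a better matcher can be swapped in.
* Perimeter and axes are measured on the wound opening; undermining and
  tunneling below intact skin are invisible to any optical method.
* Multi-component wounds are reduced to the largest connected region.
* The rim-crack anchoring assumes the skin immediately outside the
  traced boundary is skin-plane-like; heavily raised or rolled wound
  edges (epibole) would bias the rim placement.
* ICC confidence intervals and Bland–Altman plots are not provided.

## A complete example

```{r example, eval = FALSE}
phantom <- makePhantom("A")          # hemispherical cavity, r = 6 mm
report <- measurePhantom(phantom, spacing = 0.2, noiseSigma = 0.1,
                         seed = 1)
report
reportValues(phantom@truth)

# reliability of simulated raters on two phantoms
study <- simulateRaterStudy(list(makePhantom("A"), makePhantom("C")),
                            nRaters = 5, seed = 1)
summarizeStudy(study)
```
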