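---
title: "Methods: Laplace-based tracking, strain and ventriculometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Laplace-based tracking, strain and ventriculometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvstrain)
```

`lvstrain` quantifies left-ventricular (LV) function in segmented
short-axis cine MRI of small-animal hearts, where commercial feature
tracking tools often fail on the low-resolution, low-SNR data.  Its parts
are: (i) a Laplace-equation point-correspondence engine used both for wall
thickness and for frame-to-frame tracking; (ii) Lagrangian strain curves
with slope metrics; (iii) global ventriculometrics; (iv) tagged-MRI
template tracking; (v) a class-imbalance segmentation loss with evaluation
metrics; and (vi) a deforming-LV phantom with closed-form ground truth that
validates the whole chain.  This vignette states the models, their
assumptions, the tunable parameters, and the numerical choices made where
the design was open.

## Laplace correspondence

Given two nested closed contours (endo- and epicardial borders of one
frame, or the same border in two successive frames), the harmonic
potential $\gamma$ with $\nabla^2\gamma = 0$ is solved on the band between
them, with Dirichlet values 0 on the inner and 1 on the outer boundary.
Streamlines of $\nabla\gamma$ are orthogonal to every equipotential line
and connect the boundaries one-to-one, which is the correspondence used
everywhere in the package.

Numerics and parameters:

* **Discretisation.** Second-order central differences; the Jacobi
  iteration replaces each interior pixel by the mean of its four
  neighbours.  Convergence is declared when the largest per-pixel change
  in a sweep is below `tol` ($10^{-6}$ on the 0-1 scale by default,
  `max_iter` 10,000 for raw grids, 20,000 in the contour pathway).  A
  red-black Gauss-Seidel sweep is available; it reaches the same fixed
  point in roughly half the iterations and the tests assert agreement.
* **Dirichlet convention.** Inner/earlier contour = 0, outer/later = 1, so
  streamlines run outward across the wall and forward in time.
* **Rasterisation and super-sampling.** Contours are rasterised by
  point-in-polygon tests at pixel centres on a grid refined by an integer
  factor (default 3).  The factor matters: boundary staircase bias scales
  like half a (refined) pixel times the local potential gradient, and we
  found even factors align staircase facets with the grid axes, leaving
  streamline-length errors of several percent on the annulus oracle where
  a factor of 3 leaves ~0.3%.  High-accuracy uses (the annulus closed-form
  check) use a factor of 8.
* **Streamline tracer.** Fixed-step Euler integration (0.25 px) of the
  normalised bilinear-interpolated gradient, terminating at
  $\gamma \ge 1-10^{-3}$ (or on entering the far boundary region).  The
  endpoint is then projected onto the target polygon.  The projection is a
  deliberate design choice: tracked points remain exactly on the segmented
  contour at every frame, so radial termination bias cannot accumulate
  over the 16 chained frame-to-frame correspondences of a cycle.
* **Crossing contours.** Successive-frame contours may intersect (they
  routinely do for the epicardium, whose radial motion is smaller than the
  translation).  The correspondence then falls back to radial re-sorting:
  each seed's angle about its own contour's centroid indexes the target
  radius profile about the target's centroid.  Centroid alignment makes
  this map exact for rigid translation.  The fallback is logged per frame
  pair in the tracking result (`modes`).
* **Degenerate inputs.** Identical contours give the identity map with
  zero lengths; overlapping Dirichlet masks or an empty interior raise
  errors; a flat field stalls the tracer with an explicit error.

The solver is validated against closed forms: a linear ramp between
parallel plates, and the annular potential $\log(r/r_1)/\log(r_2/r_1)$
with radial streamlines of length $r_2 - r_1$.

## Wall tracking and Lagrangian strain

`track_wall()` resamples the frame-1 contours to `n_points` (default 60)
equally spaced by arc length, starting at a configurable reference angle
so indices agree across layers, then chains correspondences through the
cycle.  The analysis window defaults to frames 1-17, within which the
strain cycle of the mouse acquisitions completes; the window is clamped to
the available frames.

**Mid-wall definition.** The mid layer is the arithmetic midpoint of
corresponding endo/epi points at *every* frame, including frame 1.  An
alternative initialisation on the $\gamma = 0.5$ equipotential is
available (`mid_method = "equipotential"`), but it is not the default:
the equipotential ring of an annulus sits at the geometric mean radius
while midpoints sit at the arithmetic mean, and mixing the two (reference
frame on one definition, later frames on the other) injects a spurious
strain offset of about $((\bar r/g)^2-1)/2 \approx 0.03$ for the default
mouse wall into every frame after the first.  With the midpoint definition
the tracked mid layer is exactly the image of the reference mid layer
under any radially linear deformation.

Strain is referenced to the first analysis frame (value exactly 0 there).
For circumferential strain, the segment length at point $k$ is the
distance between its ring neighbours $k-1$ and $k+1$; for radial strain,
the distance between paired points of two layers (endo-mid or mid-epi).
The default convention is Green-Lagrange,
$\varepsilon = (L_t^2 - L_0^2)/(2L_0^2)$, with an engineering option
$(L_t - L_0)/L_0$; the two agree to first order and the tests bound their
difference at small strain.  Pointwise strain is averaged over points
(pointwise-then-mean; the alternative order is not offered), globally or
within angular sectors whose membership is fixed at frame 1.  The full
tensor $E = (F^\top F - I)/2$ from local point triples is exposed as
`lagrangian_tensor()`; only the normal components feed the curves, as
shear curves are not part of the reported outputs.

`slope_metrics()` reports the peak (extremum of $|\varepsilon|$, so one
definition serves negative circumferential and positive radial curves),
the systolic slope S1 (secant from the window start to the peak frame) and
the diastolic slope S2 (secant from the peak to the window end); a
least-squares variant fits each limb instead.  A peak on the window edge
flags the curve as monotone and leaves S2 undefined.

## Sector model and ventriculometrics

The standardised 17-segment model partitions each slice level into 6
(basal), 6 (mid-cavity) or 4 (apical) angular sectors counterclockwise
from a user-supplied reference angle; the apex tip (segment 17) is never
analysed.  No anatomical landmark detection is attempted - the reference
angle is an input.  The default slice-to-level mapping is three basal,
three mid-cavity, and the remainder apical.

Cavity volume per frame is the multi-slice discrete Simpson form: cavity
area times slice spacing, summed over slices.  End diastole/systole are
the volume maximum/minimum (earliest frame on ties).  From these: SV =
EDV - ESV, EF = SV/EDV x 100%, and LVM = $\rho\,V_m$ with
$\rho = 1.05\ \mathrm{g/cm^3}$ and $V_m$ the epicardial-minus-cavity
volume at end diastole.  SV and LVM normalisations (body mass, surface
area) are computed when denominators are supplied; no surface-area formula
is built in.

Wall thickness is the streamline length of the endo-epi correspondence
converted to mm; normalised thickening is $(th_{ES} - th_{ED})/th_{ED}$
(the normalisation convention is recorded in the output metadata), with
zero-thickness points excluded.  The per-subject table reports segments
1-16.  A generalised Gauss-Markov random field smoother regularises noisy
pointwise maps by minimising
$\sum_s |x_s - d_s|^p + \gamma^p \sum_{s\sim r} |x_s - x_r|^p$
over the contour-neighbour graph (ring adjacency within a slice, matched
points across slices), by cyclic coordinate descent - exact per-coordinate
minimisation at $p = 2$, line search otherwise, with a monotone
non-increasing objective.  Defaults $p = 2$, $\gamma = 1$; the tests check
the $p=2$ solution against a direct linear solve.

## Tagged-MRI tracking

Tagging imprints a saturation grid whose deformation reveals intramural
motion.  Points are tracked by maximum Pearson correlation between the
3x3 template centred on the current position in frame $n$ and every 3x3
patch inside the 5x5 search window of frame $n+1$; Pearson (normalised)
correlation is used for invariance to tag fading.  Ties break towards the
smallest displacement, then row-major order, so flat regions yield zero
motion.  Tracking is integer-pixel by default, bounding the per-frame
displacement at 1 px per axis; a parabolic sub-pixel refinement of the
correlation peak is available behind a flag.

Two properties of this (deliberately simple, window-based) tracker
matter for interpreting results and were characterised on the phantom:

* It cannot follow sustained sub-pixel drift: a memoryless integer match
  rounds each frame's displacement, so a constant velocity $v$ accrues
  bias $|v - \mathrm{round}(v)|$ px per frame.  Tracking is therefore
  reliable where per-frame motion is close to 0 or to 1 px - which is the
  regime the tagged validation phantoms are scaled to.
* Pearson correlation is invariant to affine intensity maps, so a locally
  planar pattern (a pure sinusoid sampled over 3x3 px at long tag
  periods) is matched ambiguously.  The rendered tags therefore use a
  sharpened profile (`sharpness` exponent, default 4) emulating the
  non-sinusoidal saturation bands of SPAMM tagging, and tag periods of
  5-11 px, so a template spans genuine curvature.  Seeds are placed at
  tag-line crossings, as an expert reader would.

The rotation check compares angular (arc) positions - the rotation signal
itself; the Euclidean error additionally contains the second-order radial
in-pull $r(1 - \cos\theta)$, about 1.2 px at the test radius over a
17-frame cycle, which an integer tracker cannot resolve and which does not
affect rotation or circumferential-strain readouts.  Strain from tagged
tracks reuses the cine strain code path on the tracked positions.

## The deforming-LV phantom

The phantom is a mid-ventricular annulus (defaults: endo radius 1.0 mm,
epi 1.6 mm, 0.015 mm pixels on a 256 x 256 grid, 17 frames) subjected to
the five motion classes of a beating ventricle, composed about the LV
centre in order: radial compression/thickening, rotation plus torsion,
simple shear, translation.  The radial map is linear across the wall -
endo radius scaled by $\lambda(t)$, wall thickness by $\mu(t)$ - and
torsion grows linearly from endo to epi, so the composite has a
closed-form inverse (`phantom_inverse()`, exact to machine precision; an
8-step fixed-point refinement is used only when a wedge modulation is
combined with rotation or torsion).  Peak amplitudes default to mouse
scale: $\lambda_{\min} = 0.8$, $\mu_{\max} = 1.3$, 5 deg rotation, 8 deg
torsion, shear 0.05, ~0.1 mm translation.  The temporal profile is a
raised cosine rising to peak systole at frame 8 and returning to 0 at
frame 17; a linear ramp is available for constant-rate test motions.

Masks are rasterised exactly by pulling pixel centres back through the
inverse map; contours are forward-mapped polygons; tagged images evaluate
the reference tag pattern at the pulled-back position.  Ground-truth
strain applies the pipeline's own strain formulas to exactly-mapped
reference points, so tracker and truth estimate the same quantity.

An optional angular wedge multiplies the compression/rotation/torsion
amplitudes by a factor inside a stated arc, with a raised-cosine taper
(default 10 deg) back to 1 outside it: tissue cannot deform
discontinuously, and a sharp edge would make chord-based strain at the
edge unbounded.  Sector tests suppress motion in one 60 deg wedge and
check confinement.

What the phantom does *not* emulate: MR physics (coil shading, tag
fading, k-space artefacts, noise correlation), papillary muscles,
non-annular cross-sections, through-plane motion and 3-D torsion between
slices, and segmentation error in the input contours.  Passing the
phantom validation therefore demonstrates the correctness of the
correspondence, tracking and strain machinery on known motion - not
robustness to segmentation noise on real data, which enters this pipeline
only through the quality of the supplied masks.

## Segmentation loss and evaluation metrics

For training LV segmentation networks under heavy class imbalance (LV
pixels are a small minority), the package evaluates, as pure array math:
the pixel-summed binary cross-entropy $L_{BCE}$ (probabilities clipped to
$[10^{-7}, 1-10^{-7}]$; an optional mean reduction exists for
training-scale comparability); the sensitivity-specificity loss
$L_{ss} = 2 - (\text{sens} + \text{spec})$ with soft counts, which scores
each class through its own ratio and is invariant to the imbalance ratio;
and the combination $L = \alpha L_{BCE} + \beta L_{ss}$ with
$\alpha + \beta = 1$, defaulting to $\alpha = 0.2$, $\beta = 0.8$ (the
optimum of a 0:0.1:1 grid search in the original study).  Inference
post-processing is Otsu thresholding, retention of the largest
4-connected component, and interior hole filling - deterministic and
idempotent.  DSC (percent) and the Hausdorff distance (mm, over boundary
pixels) evaluate mask agreement; two empty masks are defined to agree
(DSC 100, HD 0).  The network itself (architecture, initialisation,
optimiser, augmentation) is out of scope here: only the loss and its
identities are testable at desk scale.

## Agreement statistics

`curve_agreement()` compares two curves by Pearson correlation, mean
squared error and Bland-Altman bias with 95% limits of agreement
(bias $\pm$ 1.96 SD of the differences; the differences vector is kept in
the report so any downstream normality test can be applied).  With
`normalize = TRUE` each curve is divided by its own maximum absolute
value and the MSE of the normalised curves is also reported in percent -
the scale on which normalised strain-curve agreement is customarily
quoted.

## Validation problem sizes

The test suite and the acceptance script use: the full default phantom
(256 x 256, 17 frames, 60 tracked points per layer) for end-to-end strain
recovery; 128 x 128 ambient grids with radii 10/20 px for the annulus
closed forms (super-sampling 4-8); 96-160 px phantoms for per-motion-class
strain checks; 304 px and 112 px tagged phantoms for rotation and
compression tracking; and small synthetic arrays for the loss,
ventriculometric and agreement identities.  These sizes were chosen so
each check isolates one mechanism at full numerical fidelity while the
whole suite runs in about a minute.

## Known limitations

* Slices are treated independently (no through-plane Laplace solving or
  3-D torsion).
* The integer tagged tracker rejects sustained sub-pixel drift and
  over-steps diagonal motion by up to ~0.4 px/frame; its outputs are
  meaningful where per-frame motion is near 0 or 1 px, and for angular
  readouts.
* The sector model needs a user-supplied reference angle; there is no
  landmark detection.
* Longitudinal strain is out of scope (needs long-axis views), as are
  DICOM ingestion and any training of segmentation networks.
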