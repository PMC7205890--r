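# lvstrain

Automated left-ventricular (LV) function and strain analysis for segmented
short-axis cine MRI and tagged MRI of small-animal hearts.  Mouse cardiac
MRI has low resolution and poor SNR, where commercial feature-tracking
tools routinely fail; `lvstrain` instead derives wall motion from the
*geometry* of the segmented borders, so strain, wall thickening and global
function all come from a single cine acquisition.

## What it computes, and how

**Point correspondence by the Laplace equation.**  Between two nested wall
contours the harmonic potential solving ∇²γ = ∂²γ/∂x² + ∂²γ/∂y² = 0 is
computed with Jacobi iterations of the second-order central-difference
stencil (inner boundary γ = 0, outer γ = 1).  Streamlines of ∇γ are
orthogonal to every equipotential and pair the boundaries one-to-one.
Applied to the endo/epi borders of one frame the streamline length is the
wall thickness; applied to the same border in successive frames it tracks
wall points through the cardiac cycle.

**Lagrangian strain.**  Tracked points on the endo, mid and epi layers
give circumferential strain from neighbour segment lengths and radial
strain from inter-layer distances, in the Green–Lagrange convention
ε = (L² − L₀²)/(2L₀²) (engineering optional), referenced to frame 1 and
analysed over frames 1–17, globally, per layer, and per sector of the
standardised 17-segment model (6 basal / 6 mid-cavity / 4 apical; the apex
segment is excluded).  Each curve is summarised by its peak, systolic
slope S1 and diastolic slope S2.

**Global ventriculometrics.**  Cavity volumes by slice-area summation
(discrete Simpson), EDV/ESV at the volume extremes, SV = EDV − ESV,
EF = SV/EDV × 100 %, and LV mass LVM = ρ·V_m with ρ = 1.05 g/cm³, where
V_m is the epicardial-minus-cavity volume at end diastole.  Wall
thickening (ES − ED)/ED is reported per segment, optionally smoothed by a
generalised Gauss–Markov random-field energy.

**Tagged MRI.**  Points are tracked by maximum normalised correlation of a
3×3 template within a 5×5 search window between successive frames; strain
re-uses the cine code path.

**Segmentation loss.**  The class-imbalance loss L = α·L_BCE + β·L_ss
(α + β = 1, defaults 0.2/0.8), where L_ss = 2 − (Sensitivity +
Specificity) with soft counts, plus Otsu binarisation with
largest-component and hole-filling post-processing, DSC and Hausdorff
metrics.

**Validation phantom.**  A synthetic annular LV deforming by translation,
rotation, torsion, shear and radial compression over 17 frames, with a
closed-form inverse motion map and analytic ground-truth strain, drives
the end-to-end tests.

## Worked example

Track the default composite-motion phantom and compare the recovered
mid-wall circumferential strain with the analytic ground truth:

```r
library(lvstrain)
spec <- phantom_spec()                  # 256^2 px, 17 frames, mouse scale
ph   <- generate_phantom(spec)
tw   <- track_wall(ph$contours, n_points = 60)
cs   <- circumferential_strain(tw, layer = "mid")
round(cs$values, 4)
#>  [1]  0.0000 -0.0042 -0.0158 -0.0323 -0.0503 -0.0662 -0.0770 -0.0809
#>  [9] -0.0785 -0.0718 -0.0613 -0.0483 -0.0342 -0.0208 -0.0097 -0.0024
#> [17]  0.0002
slope_metrics(cs)[c("S1", "S2", "peak", "peak_frame")]
#> $S1        -0.011553      strain per frame, window start -> peak
#> $S2         0.00901067    strain per frame, peak -> window end
#> $peak      -0.08087099    peak systolic shortening
#> $peak_frame 8
curve_agreement(cs, analytic_strain(spec, "circumferential", "mid"),
                normalize = TRUE)
#> <agreement_report> n = 17, CorCoef = 1.000, MSE = 2.837e-06 (0.00% normalised),
#>                    bias = 0.001373 [-0.0005999, 0.003345]
```

The curve dips to a peak shortening of −0.081 at frame 8 (end systole)
and returns to ~0 by frame 17; the tracked curve correlates with the
analytic truth at CorCoef 1.000 with a normalised MSE well below 1 %.
Global function from the phantom's own label masks:

```r
masks <- array(0L, c(spec$size, spec$size, 1, spec$n_frames))
for (t in 1:spec$n_frames) masks[, , 1, t] <- ph$masks[[t]]
st <- segmentation_stack(masks, pixel_spacing = spec$spacing, slice_spacing = 1)
global_indices(st)
#> <global_indices> EDV 3.1 uL, ESV 2.0 uL, SV 1.1 uL, EF 36.0%, LVM 0.0051 g
```

(A single mid-ventricular slice of a phantom whose cavity radius shrinks
to 0.8× gives EF = 1 − 0.8² = 36 % exactly.)

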