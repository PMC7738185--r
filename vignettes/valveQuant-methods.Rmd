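---
title: "valveQuant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{valveQuant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valveQuant)
```

valveQuant quantifies remodeling of tricuspid valve anterior leaflet
tissue across scales: organ-level morphology, tissue-level thickness and
mechanics, matrix-level collagen content and fiber architecture,
cell-level nuclei morphology and protein expression. Every analysis
stage is paired with a seeded synthetic-data generator carrying known
ground truth, so the full pipeline can be validated end to end without
any experimental data. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
validation does and does not demonstrate.

## Biaxial mechanics

A planar biaxial test stretches a square leaflet specimen along its
circumferential and radial axes while recording axial forces,
rake-to-rake distances, and the positions of four ink fiducial markers
arranged in a roughly 3 x 3 mm grid at the specimen center. The
stress-free reference configuration is the floating specimen.

**Deformation gradient.** For each frame we seek the 2 x 2 linear map
`F` (plus translation) minimizing the squared misfit between mapped
reference markers and observed deformed markers. Centering both marker
sets on their centroids eliminates the translation, leaving the closed
form `F = (Xd' Xr)(Xr' Xr)^-1`. The right Cauchy-Green tensor
`C = F'F` then yields the stretches. We report stretches along the
device axes (the square roots of the normal components of `C`), not
eigen-stretches, because specimens are mounted with their material axes
aligned to the device axes. The rms marker misfit is reported as a
per-frame quality measure, and frames with `det F <= 0` are flagged
invalid.

**Membrane tension.** For thin planar tissue we use membrane tension
(force per unit deformed edge length, N/m) instead of stress: the axial
force divided by the rake-to-rake distance of the *orthogonal*
direction in the deformed configuration. With forces in mN and lengths
in mm the ratio is already in N/m.

**Cycle segmentation and preload.** Loading cycles are segmented by
alternating extrema of the force on the controlled axis after zigzag
simplification: turning points are pruned until every remaining swing
exceeds 10% of the force range (configurable). This is robust to
sensor noise, which otherwise litters the trough regions with spurious
extrema. The analyzed segment is the final downstroke (last peak to the
following trough). A 10 mN preload defines the tension origin: tension
is computed from `force - preload` and frames below preload are
dropped.

**J-curve metrics.** Each tension-stretch curve is summarized by four
metrics: toe stiffness, calf stiffness, transition stretch and (for the
pair) the anisotropy index.

* *Toe window.* The toe line is fitted by least squares over the lowest
  15% of the curve's stretch range (configurable via `toeFraction`).
  We deliberately define this window on the stretch axis rather than
  the tension axis: for realistic leaflet parameters (toe slope of a
  few N/m per unit stretch, transition stretch 1.1-1.3), the whole toe
  segment spans only tenths of a N/m, so any fixed tension window wide
  enough to be noise-robust would leak into the heel and calf and bias
  the slope. A stretch-fraction window stays inside the toe segment
  whenever the transition stretch exceeds the chosen fraction of the
  stretch range, which holds across the parameter grid we validate on.
* *Calf window.* Tension in [16, 20] N/m, i.e. "near" the 20 N/m
  evaluation tension, configurable. If the curve does not reach the
  window the top 20% of its tension range is used and the result
  flagged `reducedTension`.
* *Transition stretch.* The curve point nearest the intersection of the
  toe and calf lines. Because "nearest" is unit-dependent, distances
  are computed after scaling both axes by the curve's range. Parallel
  toe/calf lines (a straight curve) make the transition undefined; it
  is flagged rather than guessed.
* *Anisotropy index.* The ratio of circumferential to radial stretch at
  20 N/m, via monotone interpolation of each curve. Values below 1 mean
  the tissue is circumferentially stiffer; the default synthetic
  parameters produce an index of about 0.9.

The synthetic constitutive law is piecewise linear in stretch (toe
slope, calf slope, transition stretch), so metric recovery has an exact
analytic truth; an optional C1 quadratic blending window is available
for smooth-heel curves.

## Morphometry and thickness

**Leaflet morphology.** Area by the shoelace formula on the calibrated
outline polygon; width as the distance between the two commissure
points; height as the maximal extent of the outline perpendicular to
the commissure chord. The height construction is a geometric
interpretation of measurements drawn on calibrated photographs; it is
configurable because other conventions (annulus midpoint to free edge)
are defensible. Self-intersecting outlines are rejected.

**Contour fitting.** Section contours are parameterized by normalized
cumulative chord length and each coordinate fitted as a function of
that parameter. The default is an interpolating natural cubic spline:
it is exact on the digitized points and makes the whole thickness
computation rigid-motion invariant to machine precision (a smoothing
parameter chosen per coordinate by cross-validation would break exact
equivariance). Cross-validated or fixed-spar smoothing splines are
available for noisy digitizations.

**Thickness.** At 100 (default) equally spaced arc-length stations
placed at interval midpoints `(i - 0.5)/N` along the atrialis curve,
the normal ray is cast toward the ventricularis polyline; thickness is
the distance to the first crossing (nearest crossing if a folded
section produces several). Stations whose rays miss (end effects) are
dropped and counted, with a warning past 20%. Chordae and annular
muscle are handled as input exclusion intervals on the arc length, not
by automated detection. Region summaries average stations over
arc-fraction thirds: near-annulus, belly, free edge. Midpoint stations
make the three thirds contain equally spaced stations, so region means
of smooth profiles converge at second order; region-mean comparisons
should use station counts divisible by 3.

## Regional IHC quantification

The band between the fitted atrialis and ventricularis curves is split
into 3 equal arc-length segments x 10 transmural layers. Layers are
built by linear blending of matched arc-length stations on the two
curves ("interpolated" transmural layers); each of the 30 regions is a
quadrilateral strip polygon. Pixels are assigned to the first region
polygon containing their center, which guarantees an exact partition:
region pixel totals sum to the band total minus exclusions, a property
the test suite asserts exactly.

Positivity is a pluggable rule. Synthetic sections encode positivity as
a 0/1 label channel, so quantification is exact by construction and the
planted per-region fractions are recovered to pixel rounding. For real
chromogen images the rule is stain separation with the standard
hematoxylin/DAB vectors (Ruifrok-Johnston color deconvolution) followed
by a threshold on the DAB optical density (Otsu if unspecified). The
published analyses this mirrors did not document their positivity rule,
which is why the rule is a replaceable component; raising the threshold
can only lower positive percentages (asserted as a monotonicity test).

Fold-change maps summarize each region cell as the TIC group mean of
positive-pixel percentages over the CTL mean (median available), with
log2 fold change for display; positive values mean higher expression in
the diseased group. Cells with a zero denominator are flagged
(`infinite` or `bothZero`), never silently zeroed. Nuclei density is
connected-component count over region area, with nuclei assigned by
centroid.

## Fiber orientation through depth

Collagen images are analyzed with the structure tensor: intensity is
first normalized by saturation-percentile clipping (0.35% tails by
default, mirroring common image-enhancement practice), gradients are
taken with derivative-of-Gaussian kernels (sigma 1 px), and the tensor
components are smoothed with a Gaussian window (sigma 2 px). We use
derivative-of-Gaussian rather than central-difference gradients because
the latter's anisotropic frequency response biases orientation
estimates of rasterized fibers by several degrees toward the
diagonals; with DoG kernels the bias on synthetic parallel-line images
is below 0.1 degrees. Each pixel contributes its axial orientation to a
1-degree histogram weighted by coherency; a constant image yields the
uniform density with a `zeroCoherency` flag.

Axial orientations live on a 180-degree-periodic domain, so von Mises
fitting uses the classical angle-doubling device: doubled angles are
fitted on the full circle by maximum likelihood, where the mean
direction gives mu (halved back to [0, 180)) and kappa solves
`I1(k)/I0(k) = R` with `R` the mean resultant length (solved by
`uniroot`; R below 1e-4 is declared uniform with kappa 0, and R beyond
the kappa cap of 500 is flagged `capped`). Binning at 1 degree
attenuates `R` by under 0.01%, negligible against sampling error at
the validated sizes.

Stacks are assembled by normalizing each stack's slice depths to
[0, 1] (atrialis = 0), interpolating every histogram bin onto a common
depth grid, averaging across stacks and renormalizing. Depth-third
summaries average fitted kappa over D1 = [0, 1/3) (nearest the
atrialis), D2 = [1/3, 2/3), D3 = [2/3, 1], lower-inclusive. Slices are
weighted equally; coherency-weighted averaging is available but not the
default, since the original procedure's weighting is not documented.

## Nuclei morphometry

Nuclei images are thresholded (Otsu by default, fixed threshold for
synthetic label images), labeled into connected components, and each
component summarized by its equivalent ellipse from second central
moments (with the 1/12 per-pixel variance correction): orientation from
the principal axis, NAR as the square root of the eigenvalue ratio.
Circularity is `4 pi area / perimeter^2` with a Vossepoel-Smeulders
corrected chain-code perimeter, capped at 1 because discretized
perimeters of small convex blobs undershoot the true perimeter (the
common particle-analysis convention). Per-population fits use the axial
von Mises machinery for orientation and normal moments for NAR and
circularity.

## Collagen assay

Standard curves are ordinary least-squares lines of absorbance (560 nm)
against known collagen mass, with R^2 reported. Sample absorbances
(triplicate mean) invert the curve to the mass in the plated well, then
scale through the dilution chain: 100 uL water per 10 mg wet tissue for
homogenization, 100 uL homogenate hydrolyzed with 100 uL NaOH and
neutralized with 100 uL HCl (3-fold dilution), 10 uL plated. Because
the homogenate concentration is fixed per mg of tissue, the content in
ug per mg wet tissue equals 3x the well mass regardless of wet mass;
the wet mass is retained for the audit trail and for configurable
chains. Absorbances outside the standard range are flagged
`extrapolated`; negative interpolated masses floor at zero with a flag.

## Proteomics DE filter

The differential-expression chain over a label-free intensity matrix:

1. keep proteins with at least two non-missing replicates in *every*
   group (missing values are treated as absent, no imputation — the
   replicate filter implies presence/absence semantics);
2. normalize each sample by its total intensity (total protein
   content), which makes all downstream results invariant to
   per-sample scaling;
3. fold change as the ratio of group means (median available) of
   normalized intensity;
4. Wilcoxon rank-sum test per protein (exact for pooled n <= 20
   without ties);
5. flag proteins with |log2 FC| >= 1 (fold change 2).

The default significance criterion is fold-change-only with p-values
reported alongside. This is a deliberate design decision: with three
replicates per group — the design this mirrors — a two-sided exact
rank-sum test cannot fall below p = 0.1, so no protein could ever pass
a p < 0.05 gate; rather than guess how the original analysis suite
reached significance, the package exposes `criterion = "fc_and_p"`,
one-sided testing, and asymptotic p-values explicitly, and records the
criterion used in the result attributes.

## Statistical dispatcher

Every cross-group comparison goes through one rule: Shapiro-Wilk on
each sample (gate at p >= 0.05, configurable); if both pass, an F-test
of variances (same gate) chooses between Student's and Welch's t-test;
if either fails, the Wilcoxon rank-sum test. Reported central summaries
are the mean for samples that passed normality and the median
otherwise. Constant samples, where Shapiro-Wilk is undefined, route to
the rank-sum test with a flag, and fully tied comparisons return p = 1.
Tests are two-sided unless a direction is declared explicitly per
comparison — one-sided testing is never a default. Correlations use
Pearson unless either variable is declared ordinal (e.g. regurgitation
grades) or fails the normality gate, in which case Spearman is used.

Pre-testing normality before choosing a test is known to perturb
operating characteristics slightly; `typeErrorCalibration()` measures
the dispatched procedure's empirical type-I error and power by
simulation. At n = 15/15 the null rejection rate is consistent with the
nominal 0.05 (0.049 across 20,000 replicates in our runs), and power
at a 1.5 SD shift with n = 10/10 is about 0.88.

## Synthetic cohorts and what they show

`simulateCohort()` draws per-subject parameter bundles from group-level
ground truths with log-normal between-subject variability (default CV
10%) applied to thickness, leaflet scale, fiber concentration, collagen
content and stiffness. Group effects are planted by scaling the
diseased group's truth: the default validation uses thickness x 1.4,
area x 1.3 and atrialis-third fiber concentration x 1.5 at n = 10 per
group — effect magnitudes of the order reported for tachycardia-induced
cardiomyopathy remodeling. `runPipeline()` simulates, quantifies every
modality per subject, aggregates per-region values within subject
before any group test (the subject is the statistical unit), and
dispatches the comparisons.

The acceptance checks run this end to end: at the sizes above the three
planted effects are detected with the correct sign in over 90% of 200
seeded replicates, and null cohorts reject at the nominal rate. The
replicate runs use deliberately economical problem sizes (60-point
contours, 42 thickness stations, 9 depth slices of 2,000 fibers,
36-vertex outlines); these were chosen as the smallest sizes at which
the per-stage estimators are comfortably unbiased, and single-subject
analyses default to larger sizes.

Synthetic data emulate the *structure* of the real measurements —
J-shaped anisotropic loading curves, annulus-to-free-edge thickness
gradients, region-structured staining, depth-varying fiber dispersion,
elliptical nuclei, log-normal intensities — but not their nuisance
processes: no rake friction or tissue viscoelasticity, no chromogen
color variation or slide artifacts, no speckle or depth attenuation in
the imaging, no peptide-level missingness structure. Passing tests
therefore demonstrate that the estimators recover known truths under
realistic noise and effect sizes, not that any specific biological
dataset would be free of those nuisance effects.

## Degenerate inputs and numerical conventions

* Collinear reference markers: error; `det F <= 0`: flagged invalid.
* Curves that never reach the 20 N/m evaluation tension: metrics at the
  reduced tension with a `reducedTension` flag.
* Straight (toe = calf) curves: transition flagged undefined.
* Normal rays that miss the opposite contour: station dropped and
  counted, warning past 20%.
* Empty grid regions: flagged and excluded from fold-change maps.
* Uniform orientation histograms: kappa 0, mu undefined; single-bin
  histograms: kappa capped at 500 with a flag.
* All randomness is seeded; generators derive child seeds from the
  master seed and a stream label, so adding a modality never perturbs
  another modality's draws, and repeat runs are bit-identical.
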