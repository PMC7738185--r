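# valveQuant

Multiscale quantification of heart-valve leaflet tissue, built for
studies of tricuspid anterior leaflet remodeling (for example in
tachycardia-induced cardiomyopathy, where diseased leaflets grow,
thicken, stiffen and accumulate collagen relative to controls). The
package is aimed at cardiovascular biomechanics groups who collect
planar biaxial tests, histological sections, immunohistochemistry,
two-photon image stacks, colorimetric collagen assays and label-free
proteomics on the same tissue, and want one tested, reproducible
pipeline from raw measurements to group comparisons.

## What it computes

* **Biaxial mechanics** — the deformation gradient `F` per frame by
  least squares over the four fiducial markers (centered closed form
  `F = (Xd'Xr)(Xr'Xr)^-1`), stretches from `C = F'F`, membrane tension
  `T = force / orthogonal deformed rake distance` (N/m), extraction of
  the final downstroke, and four J-curve metrics: toe stiffness, calf
  stiffness (slopes of the lower/upper quasi-linear regions), transition
  stretch (curve point nearest the toe-calf line intersection), and the
  anisotropy index λ_circ(20 N/m) / λ_rad(20 N/m), where values < 1
  mean circumferentially stiffer tissue.
* **Morphometry** — leaflet area (shoelace), cusp width (commissure to
  commissure) and height; spline-normal thickness profiles between the
  atrialis and ventricularis contours with near-annulus / belly /
  free-edge region means.
* **Regional IHC** — a 3 x 10 region grid (length thirds x transmural
  layers), positive-pixel percentages per region with a pluggable
  positivity rule (label channel or H-DAB color deconvolution +
  threshold), and TIC/CTL log2 fold-change heat maps.
* **Fiber microstructure** — coherency-weighted structure-tensor
  orientation histograms per depth slice, axial von Mises fits (angle
  doubling; κ from `I1(κ)/I0(κ) = R`), and D1/D2/D3 depth-third
  concentration summaries; nuclei orientation, aspect ratio and
  circularity from moment-equivalent ellipses.
* **Assays & omics** — collagen content (µg per mg wet tissue) from
  560 nm absorbances through a linear standard curve and the
  homogenization/hydrolysis dilution chain; a proteomics DE filter
  (replicate filter → total-intensity normalization → fold-change 2 →
  exact rank-sum test).
* **Statistics** — the normality-gated dispatcher used throughout:
  Shapiro–Wilk on each sample, F-test of variances, then Student's t,
  Welch's t or Wilcoxon rank-sum as appropriate; Pearson/Spearman
  selection for correlations.
* **Synthetic data** — seeded generators with known ground truth for
  every input above (`simulateBiaxRecord`, `simulateSectionGeometry`,
  `simulateIHCImage`, `simulateFiberStack`, `simulateNucleiField`,
  `simulateIntensityMatrix`, `simulateCohort`), so the whole pipeline
  is testable without any experimental data.

## Worked example

Single-specimen mechanics on a synthetic record with known constitutive
truth (toe/calf/transition = 8/150/1.12 circumferential, 5/100/1.20
radial):

```r
library(valveQuant)
truth <- groundTruth(seed = 1)
rec <- simulateBiaxRecord(truth, nSamples = 400)
ds  <- extractDownstroke(rec)
jm  <- jcurveMetrics(ds$circ, ds$rad)
```

```
circ: toe 8.00, calf 150.00 N/m per stretch, transition 1.119
rad:  toe 5.00, calf 100.00 N/m per stretch, transition 1.200
anisotropy index at 20 N/m: 0.897
```

The noise-free record is recovered exactly; the anisotropy index below
1 reflects the circumferentially stiffer default tissue.

End-to-end cohort analysis with planted disease effects (thickness
×1.4, area ×1.3, atrialis-third fiber concentration ×1.5, collagen
×1.4; 10 subjects per group, 10% between-subject variability):

```r
cfg <- pipelineConfig(seed = 7, nCtl = 10, nTic = 10,
                      effects = list(thickness = 1.4, area = 1.3,
                                     kappaD1 = 1.5, collagen = 1.4))
report <- runPipeline(cfg)
report
```

```
CohortReport (seed 7, config d046a226)
  subjects: 20 (0 failed)
              measure nCtl nTic meanCtl meanTic ratio        chosenTest   pValue significant
                 area   10   10  4.7440   6.265  1.32         student_t 1.00e-04        TRUE
            thickness   10   10  0.8480   1.198  1.41         student_t 7.29e-06        TRUE
              kappaD1   10   10  3.7040   6.071  1.64           welch_t 1.51e-06        TRUE
              kappaD2   10   10  3.1870   3.434  1.08         student_t 1.54e-01       FALSE
             collagen   10   10 34.9800  49.900  1.43 wilcoxon_rank_sum 2.17e-05        TRUE
  ...
```

(abridged; the full table has one row per measure). The recovered
ratios sit at the planted effects, the unplanted measures (kappaD2,
kappaD3) stay non-significant, and each row records which test the
dispatcher chose. `validateSuite()` runs a quick machine-readable
self-check of every module's core invariant.

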