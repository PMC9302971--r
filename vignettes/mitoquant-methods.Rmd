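---
title: "Quantifying mitotic chromosome dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitotic chromosome dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

## Scope

`mitoquant` measures five fluorescence-microscopy assays of chromosome
congression, segregation, and their downstream consequences, of the kind used
to characterize chromokinesin (e.g. KIF22) function:

1. **Polar ejection forces** on monopolar spindles, as the distance from the
   spindle pole to the maximum of the radial DNA-stain intensity profile.
2. **Anaphase chromosome-mass separation** from pole-to-pole line profiles,
   including recongression trajectories, Gaussian FWHM mass broadness, and
   the pole/centromere distance decomposition (anaphase A vs B).
3. **Nuclear morphology** by convex-hull solidity with a control-derived
   percentile threshold for abnormal shape.
4. **FRAP** normalization and recovery summaries.
5. **Exponential proliferation** models with division-failure scenarios.

Every assay has a paired synthetic generator that produces ground-truth
labelled inputs, so the complete measurement chain is testable without raw
imaging data.

## Geometry and calibration

Pixel indices are 0-based and a pixel's *center* sits at integer coordinates;
ROI geometry (points, circles, segments) is continuous in that frame. Every
physical distance is pixel distance times `pixel_size` (µm/px) — there is no
other unit conversion anywhere. Calibration is never defaulted: an image
stack with neither an explicit `pixel_size_um` argument nor a YAML sidecar
is an error. The sidecar (written by `write_image_stack()`) carries pixel
size, timestamps, channel, and the intensity scale used for 16-bit TIFF
encoding, because baseline TIFF tags do not transport these reliably across
readers.

## Intensity primitives

*Circular ROI means* use the pixel-center membership rule: a pixel belongs
to the circle iff its center does. This makes every measurement exactly
reproducible by per-pixel enumeration, which is how the tests check it.

*Line profiles* are sampled by bilinear interpolation along the segment,
endpoint-inclusive. The sample count is `round(L / spacing) + 1` (spacing
1 px by default), so samples are *evenly* spaced at approximately 1 px. The
alternative — marching in exact 1 px steps and appending the endpoint —
breaks the reversal symmetry `profile(p1, p2) == rev(profile(p2, p1))` for
non-integer segment lengths; symmetry matters because downstream separation
measures must be invariant under swapping the pole labels.

*Background handling* comes in two forms, matching how such experiments are
processed. For expression-level readouts, the mean background (from a
cell-free region) is subtracted from the mean signal over a thresholded
mask; the integrated-density formulation reduces to exactly this difference
of means. For marker sharpening before profiling, the image's own wide
Gaussian blur (`sigma` default 30 px) is subtracted and negatives are
clipped to zero. The published description of this step garbles the radius
phrasing; we treat the printed 30 pixels as the Gaussian sigma and expose it
as a parameter, since the distinction is not recoverable from the text.
Clipping prevents negative intensities from corrupting argmax-based peak
finding. For blurs wider than the image, the image is edge-replicated
before filtering so the operation stays defined on small crops.

## Polar ejection force assay

Pixels within 12.5 µm of the pole are binned by center distance into annuli
`[k·w, (k+1)·w)` with `w` one pixel by default, matching the 1-px annuli of
the standard radial-profile plugin; the readout is the bin center of the
maximal mean intensity. Ties break toward the smaller radius — the
conservative (lower-force) call. Empty annuli are reported `NA`, never zero,
so they cannot win the argmax. No smoothing is applied by default (the
published procedure reports raw maxima); a moving-average option exists for
noisy data. The implementation is held bin-for-bin equal to a brute-force
per-pixel oracle in the tests.

## Anaphase separation analysis

The profile along the pole-to-pole segment is split at half the pole
separation — the geometric midpoint, not an intensity centroid, matching the
half-spindle construction — and the global intensity maximum of each half
marks its chromosome mass. Ties break toward the midpoint. Mass separation
is the distance between the two maxima; per half-spindle, mass-to-pole
distances complete the identity
`left + separation + right = pole separation` exactly. Whether the profile
line should extend beyond the poles is ambiguous in the source description;
we use the pole-to-pole segment, since all measured maxima lie between the
poles. Anaphase onset is an input annotation (frame index), as in the
original visual identification. Distances "at t minutes" are read at the
nearest acquired frame (earlier frame on ties), never interpolated.

Mass broadness is the FWHM of a four-parameter Gaussian
(`A, mu, sigma, offset`) fitted to a half-profile by Levenberg–Marquardt
least squares; the offset is included because profiles sit on a nonzero
baseline, and the fit is flagged not-OK when it fails to converge or when
`sigma` exceeds half the profile length. `fwhm = 2·sqrt(2·ln 2)·sigma` by
definition, and the tests confirm the fitted ratio to six significant
figures.

## Synthetic data: what it emulates, and what it does not

Generators are deterministic given their seed and their truth tables are
exact functions of the spec, independent of rasterization.

* **Monopolar images**: a Gaussian ring of chromatin intensity around the
  pole, radius = the true pole-to-chromatin distance. Control-regime
  fixtures use 3.7 µm rings and collapsed-force fixtures 1.6 µm, the two
  regimes the assay is designed to distinguish.
* **Anaphase movies**: two isotropic Gaussian masses at ±d(t)/2 about the
  spindle midpoint, plus pole and centromere marker channels. Real
  chromosome masses are irregular, but the measured quantity is a peak
  position, which is insensitive to shape detail. One genuine physical
  constraint matters: the sum of two Gaussians is bimodal only when their
  separation exceeds twice their width, and the inward bias of the two
  peaks is negligible only when `d > ~4·sigma`. Fixtures whose trajectories
  dip to 2 µm therefore use `mass_sigma = 0.5` µm so the measurement
  remains well-posed at the dip; fixtures that stay above ~6 µm can use the
  broader 1.5 µm masses.
* **Nucleus masks**: a cosine-modulated ellipse radius
  `r(θ) = r_ellipse(θ)·(1 − depth·max(0, cos(kθ + φ)))`, chosen because its
  continuous solidity has a cheap, high-accuracy oracle (shoelace over
  convex hull of dense boundary samples). Rasterized solidity converges to
  the polygon truth as pixel size shrinks; at 0.1 µm/px the residual is
  below 0.02.
* **FRAP traces**: frames at 5 s intervals for 25 s before the bleach (last
  pre-bleach frame at t = 0) and at 20 s intervals to 10 min after, with a
  single-exponential mobile/immobile recovery whose clock starts at the
  first post-bleach frame — so the first post-bleach sample equals the
  bleach depth exactly. Real recoveries need no single-exponential form;
  the model is the minimal one able to produce all the regimes the assay
  summarizes (complete interphase recovery, ~18% metaphase bleach with
  ~25% recovery, and intermediates).
* **Growth curves**: exact exponentials with multiplicative mean-zero
  Gaussian noise (counts are positive and errors scale with magnitude);
  default CV 5%, sampling every 4 h for 96 h, seeding around the
  10,000–20,000 first-frame filter window.

Noise everywhere is additive Gaussian clipped at zero (images, FRAP) or
multiplicative (counts); no photophysics, point-spread rendering, or
segmentation-confusing clutter is simulated. Passing tests therefore
demonstrate correctness of the *measurement* chain, not robustness to every
real-world imaging artifact.

## Nuclear morphology

Solidity is mask area over the area of its filled convex hull. The hull is
taken over pixel centers and its filled area is the count of lattice points
on or inside it, computed by an exact per-row scan of the convex
cross-section. Counting boundary lattice points makes the measure invariant
under translation and 90° rotation and keeps solidity ≤ 1 by construction;
point-in-polygon routines that treat boundary points inconsistently break
the rotation invariance at the third decimal.

The abnormality threshold is the 5th percentile of the control population's
solidity, by linear interpolation between order statistics (the common
spreadsheet convention, `stats::quantile` type 7). The convention matters —
published thresholds from equivalent experiments vary in the third decimal
(0.939, 0.950, 0.922 across datasets) — and thresholds are never
transferable between datasets, which is why `control_threshold()` requires
at least 20 controls and the classification records its provenance.
"Abnormal" is *strictly below* threshold; ties are normal. By construction,
a control population classified against its own threshold yields ~5%
abnormal calls (within one count, given continuous solidity values).
Segmentation is Otsu thresholding, hole filling, connected components, an
area filter in µm², and exclusion of border-touching nuclei by default.

## FRAP

Background is subtracted frame-by-frame, and the trace is normalized to the
background-subtracted intensity of the *first frame imaged* (not the
pre-bleach mean; a `prebleach_mean` option exists for noisy traces). The
first normalized sample is exactly 1, and the normalization is invariant
under common gain or offset applied to both channels. No double
normalization against the unbleached ROI is applied — the unbleached trace
is carried for QC only — and no diffusion model is fitted: the summaries
are the immediately-post-bleach percentage and the recovery percentage at a
stated time (220 s by default), both read at acquired samples.

## Proliferation models

Curves are normalized to the time-0 count; wells outside the
10,000–20,000 first-frame window are excluded (inclusive bounds — "between"
resolved inclusively). Doubling time is estimated by OLS of
`log2(normalized)` on time over the first 48 h, before growth plateaus;
this is exactly unbiased on noiseless exponentials and recovers τ within
10% in ≥95% of replicates at 5% count noise. Pooling (stacking wells into
one fit) is the default for a condition-level estimate; an endpoint-ratio
estimator is available as a cross-check. The prediction model is
`b^(T/τ)` with `b = 2 − f` for a fraction `f` of cells persistently failing
to divide each cycle: with τ = 20.72 h this gives 4.98 at 48 h when all
cells divide, 2.18 when 60% fail, and 3.42 when 30% fail — the three
division-failure scenarios the model exists to compare.

## Problem sizes and numerical choices

The analysis scripts and tests run on 256×256 px images (0.1 µm/px), 10–20
cells per condition, 11-frame anaphase movies, populations of 300–1000
synthetic nuclei at 0.15 µm/px, and 100-replicate noise studies — sizes at
which every distribution the pipeline summarizes is stable while the whole
suite stays interactive. Gaussian fits are initialized from the argmax and
profile moments with `sigma` bounded positive; degenerate inputs (constant
profiles, empty masks, empty annuli, non-positive normalization references)
raise errors rather than returning sentinel values. All tie-breaks
(profile maxima toward the midpoint, radial maxima toward the pole,
time lookups toward the earlier frame) are deterministic and documented on
the functions that apply them.

## Known limitations

* Pole and centromere coordinates are inputs; there is no automatic pole
  tracking or anaphase-onset detection.
* The synthetic nuclei are star-convex by construction; fragmented or
  multi-lobed-with-overhang morphologies (solidity measured correctly on
  them regardless) are not generated.
* FRAP summaries do not estimate mobility constants; only recovery
  percentages are reported.
* No plateau/confluence modelling beyond truncating the doubling-time fit
  at 48 h.
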