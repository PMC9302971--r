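# mitoquant

Quantification of mitotic chromosome dynamics, nuclear morphology, and cell
proliferation from fluorescence microscopy.

Chromokinesins such as KIF22 push chromosome arms away from spindle poles
(polar ejection forces) during congression and must be switched off in
anaphase for chromosomes to segregate. Labs studying this biology quantify
it through a recurring set of image measurements: radial DNA-intensity
profiles around monopolar spindle poles, line profiles through both spindle
poles to track separating chromosome masses, convex-hull solidity of
daughter nuclei, FRAP recovery of chromatin-bound protein, and exponential
fits to proliferation curves. `mitoquant` implements that measurement chain
as a tested R package, together with synthetic-microscopy generators that
produce ground-truth-labelled inputs, so every stage is verifiable without
raw imaging data.

## The measurements

| Assay | Readout |
|---|---|
| Polar ejection force | distance from the pole to the maximum of the radial DNA profile inside a 12.5 µm circle |
| Anaphase segregation | distance between the two half-spindle intensity maxima of the pole-to-pole profile, per frame; Gaussian FWHM mass broadness; mass-to-pole decomposition |
| Nuclear morphology | solidity = area / convex-hull area; abnormal ⇔ below the control 5th percentile |
| FRAP | background-subtracted trace normalized to the first frame; % post-bleach and % recovery at 220 s |
| Proliferation | doubling time τ by log-linear fit over 0–48 h; predicted counts `b^(T/τ)` with `b = 2 − f` for a non-dividing fraction `f` |

## Worked example

```r
library(mitoquant)

# simulate a monopolar cell with chromatin pushed 3.7 um from the pole
g <- generate_monopolar(monopolar_spec(ring_radius = 3.7, noise_sd = 100))
prof <- radial_profile(g$image, point_roi(127.5, 127.5), max_radius_um = 12.5)
distance_to_max(prof)
#> [1] 3.65

# anaphase recongression: separation dips to 2 um at 7 min after onset
recongress <- function(t) {
  if (t <= 3) 2 * t else if (t <= 7) 6 - (t - 3) else 2 + (t - 7)
}
a <- generate_anaphase(anaphase_spec(recongress, mass_sigma = 0.5,
                                     n_frames = 11))
s <- separation_series(a$chromosomes, a$poles, onset_frame = 1)
distance_at(s, 7)
#> [1] 2

# division-failure predictions at 48 h with a 20.72 h doubling time
sapply(c(0, 0.6, 0.3), function(f)
  round(predict_count(48, b = fraction_to_factor(f), tau = 20.72), 2))
#> [1] 4.98 2.18 3.42
```

The 3.65 is the ring radius recovered to within one 0.1 µm annulus; the 2 is
the recongression minimum read at the acquired 7-min frame; 4.98 / 2.18 /
3.42 are the predicted normalized cell counts when every cell divides,
when 60% fail to divide each cycle, and when 30% fail.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
full study flow on synthetic data — simulate, then measure each assay —
writing tidy CSVs and provenance manifests under `results/`:

```sh
Rscript analysis/01_simulate_fixtures.R
Rscript analysis/02_polar_ejection.R
Rscript analysis/03_anaphase_segregation.R
Rscript analysis/04_nuclear_morphology.R
Rscript analysis/05_frap.R
Rscript analysis/06_proliferation.R
```

## Package layout

- `R/` — measurement chain (`imaging_core`, `polar_ejection`,
  `anaphase_profiles`, `nuclear_morphology`, `frap_analysis`,
  `proliferation_models`) and the synthetic generators (`synthetic_data`),
  plus CSV/TIFF/YAML I/O helpers.
- `vignettes/mitoquant-methods.Rmd` — the model and design notes: geometry
  conventions, tie-breaks, what the generators emulate and what they do
  not, and known limitations.
- `tests/testthat/` — unit, property, and end-to-end recovery tests backed
  by independent brute-force oracles.
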