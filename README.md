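# cartmorph

Quantitative and semiquantitative evaluation of articular cartilage in the
rabbit anterior cruciate ligament transection (ACLT) model of
osteoarthritis, with a synthetic-study generator that makes the whole
pipeline verifiable by parameter recovery.

## Who this is for

Preclinical osteoarthritis studies grade cartilage damage three ways:
India-ink macroscopic grading (grades 1–4 per joint compartment), the
modified OARSI semiquantitative histology rubric (structure 0–11,
chondrocyte density 0–4, cluster formation 0–3), and computer-based
histomorphometry of stained sections. `cartmorph` implements all three,
plus the group-comparison statistics such studies report, for a three-arm
design (treatment A, treatment B, untreated control; n = 11 per arm).
Because real section data are rarely shareable, the package ships a
generator of complete synthetic studies with exactly known truth, so every
measurement and scoring stage has recovery tests.

## The measurements

From the two digitized boundaries of a section (articular surface and
tidemark, micrometre coordinates) over a 7-mm weight-bearing region of
interest (ROI):

- **Thickness**: mean of 20 measurements cast perpendicularly to the
  surface at equally spaced points, from the real surface along the local
  normal of the *idealized* smooth surface to the tidemark.
- **Area**: trapezoidal integration of the surface–tidemark separation over
  the evaluation window.
- **RMS surface roughness** against the idealized surface — a low-order
  polynomial fitted to the flanking normal cartilage only:

  RMS = sqrt( (1/N) Σᵢ (Y_idealized,i − Y_real,i)² )

- **Normalized roughness**: RMS / thickness, reported ×1000.

Rasters can also be round-tripped: `render_section_image()` draws a
section (with an optional 1-mm ruler bar), `calibrate_scale()` recovers
µm/px from the bar, and `extract_boundaries()` segments the band back into
a profile.

Statistics follow the standard protocol: Shapiro–Wilk normality per group;
one-way ANOVA with Tukey's HSD when Levene's test accepts variance
homogeneity and Dunnett's C (decision-only critical differences) when it
rejects; Kruskal–Wallis with Bonferroni-adjusted pairwise Mann–Whitney
tests for ordinal endpoints; mean ± SEM and median (IQR) summaries.

## Worked example

```r
library(cartmorph)

study <- simulate_study(study_config(profile_compartments = "MF"), seed = 7)
study
#> <cart_study>
#>   33 animals (channa n=11, control n=11, glucosamine n=11); 132 sections
#>   33 boundary profiles; master seed 7

m <- measure_study(study)
dplyr::summarise(dplyr::group_by(m, group),
  thickness = mean(thickness_um), area = mean(area_um2),
  norm_rough = mean(normalized_roughness))
#>   group       thickness    area norm_rough
#> 1 channa           253. 101045.       21.4
#> 2 control          153.  55648.       38.2
#> 3 glucosamine      220.  79798.       34.8

rep <- analyze_study(study, measurements = m, scores = score_study(study))
glance(rep)[1:5, c("endpoint", "method", "p_value", "posthoc")]
#>   endpoint             method         p_value     posthoc
#> 1 thickness_um         One-way ANOVA  0.0000328   Tukey HSD
#> 2 area_um2             One-way ANOVA  0.0000035   Tukey HSD
#> 3 normalized_roughness One-way ANOVA  0.0000187   Tukey HSD
#> 4 histology_total      One-way ANOVA  0.00000027  Tukey HSD
#> 5 macro_total          Kruskal-Wallis 0.0000136   Mann-Whitney (bonferroni)
```

Reading the output: the untreated control arm has thinner (153 vs
253/220 µm), smaller-area and rougher (normalized roughness 38 vs 21/35)
cartilage than the treated arms, and every structural endpoint separates
the groups strongly (ANOVA/Kruskal–Wallis p < 1e-4). `tidy(rep)` lists
the per-pair post hoc results; `autoplot()` methods plot profiles and
comparisons.

`run_pipeline(config, seed, out_dir)` executes
simulate → measure → score → analyze end-to-end, writing `animals.csv`,
`profiles/*.json`, `morphometry.csv`, `scores.csv`, `report/stats.json`,
`report/report.md` and a `manifest.json` with file hashes; reruns with the
same seed are byte-identical. A thin CLI lives at
`inst/scripts/cartmorph.R`.

## Package layout

- `R/presets.R`, `R/simulate.R` — group presets and the synthetic-study
  generator (ground truth bookkeeping, block randomization, RNG
  substreams).
- `R/profile.R`, `R/morphometry.R`, `R/render.R` — profile container,
  thickness/area/roughness measurement, raster round trip.
- `R/scoring.R` — OARSI rubric and India-ink grading.
- `R/stats.R` — gated comparison pipeline with `tidy()`/`glance()`.
- `R/io.R` — YAML/CSV/JSON I/O and `run_pipeline()`.
- `vignettes/cartmorph-methods.Rmd` — the model, calibration rationale and
  numerical choices.
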