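---
title: "Methods: synthetic cartilage studies, histomorphometry and the gated statistics pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cartilage studies, histomorphometry and the gated statistics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartmorph)
```

## What the package models

`cartmorph` evaluates articular cartilage degeneration in the rabbit
anterior cruciate ligament transection (ACLT) model of osteoarthritis, at
three levels:

1. **Quantitative histomorphometry** of the medial femoral condyle: cartilage
   thickness, cartilage area and RMS surface roughness measured from the
   digitized articular surface and tidemark of a stained section over a 7-mm
   weight-bearing region of interest (ROI).
2. **Semiquantitative scoring**: the modified OARSI histology rubric
   (structure 0–11, chondrocyte density 0–4, cluster formation 0–3, summed
   per compartment and over the four joint compartments MF/LF/MT/LT to a
   0–72 total) and the four-grade India-ink macroscopic scale (summed to a
   4–16 joint total).
3. **Group statistics** for a three-arm study (Channa striatus extract,
   glucosamine sulphate, untreated control; n = 11 per arm): Shapiro–Wilk
   normality assessment, one-way ANOVA with a Levene-gated choice between
   Tukey's HSD and Dunnett's C post hoc for continuous endpoints,
   Kruskal–Wallis with Bonferroni-adjusted pairwise Mann–Whitney tests for
   ordinal endpoints, and mean ± SEM / median (IQR) summaries.

Because no real section images or animal tables ship with the package, a
synthetic-study generator produces complete cohorts with exactly known
ground truth. Every downstream stage is validated by parameter recovery:
the generator's preset truths must be recovered by the measurement and
scoring code to within three times the empirical standard error over many
simulated cohorts.

## The measurement model

A profile consists of two polylines in micrometre coordinates, digitized at
≤ 5 µm spacing: the articular **surface** and the **tidemark** (the boundary
between calcified and uncalcified cartilage). `x` runs along the section,
`y` toward the joint space.

**Idealized surface.** Roughness is deviation from health, so it needs a
reference: the *idealized smooth surface*, a least-squares polynomial
(degree 2 by default) fitted only to the surface points of the two flanking
stretches of normal cartilage outside the ROI and evaluated across it. A
quadratic captures condylar curvature without following lesions; the degree
is a parameter for unusual geometries.

**Thickness** is the mean of 20 measurements made perpendicularly to the
surface at equally spaced points (bin midpoints) across the ROI. The
perpendicular direction is the local normal of the *idealized* surface —
normals of the raw fibrillated surface are noise-dominated and would make
the measurement irreproducible. Each measurement casts a ray from the real
surface along that normal to its nearest intersection with the tidemark
polyline; if the ray misses (extreme edge geometry) the implementation
falls back to the vertical distance at that abscissa and reports the count.

**Area** is the region bounded by surface, tidemark and two verticals,
computed by trapezoidal integration of the vertical separation. The
independent cross-check in the tests is the shoelace formula on the closed
boundary polygon.

**RMS surface roughness** over the N digitized ROI surface points:

$$\mathrm{RMS} = \sqrt{\tfrac{1}{N}\sum_{i=1}^{N}
  \left(Y^{\mathrm{idealized}}_i - Y^{\mathrm{real}}_i\right)^2}$$

**Normalized roughness** is RMS divided by mean thickness. The bare ratio
is ~0.02–0.05 for osteoarthritic cartilage; the package reports it ×1000
(a reporting convention, switchable via the `scale`/`normalized_scale`
arguments), so typical values read 20–50.

## What the generator emulates

`simulate_study()` creates 33 animals assigned to the three arms by block
randomization in blocks of six, each with four compartments of descriptors
and (for configured compartments) full boundary profiles, plus a serum
panel (COMP, COX-2, PGE2; lognormal, clipped to the 1.56–100 ng/ml assay
range). Each animal runs under its own RNG substream spawned from the
master seed, making studies byte-identical for a fixed `(config, seed)`.

### Geometry

* **Base curve**: a shallow parabola with a 15-mm apex radius of curvature.
  The curvature makes surface normals genuinely non-vertical (slopes up to
  ~0.33 at the flank ends), so the perpendicular-measurement code cannot
  silently assume vertical rays. A parabola rather than a circular arc
  keeps the base curve inside the span of the degree-2 idealized fit: a
  circle's quartic term would add a >20 µm systematic residual at the ROI
  centre when extrapolating a flank-only quadratic — an order of magnitude
  larger than the 5–7 µm roughness signal being measured.
* **Fibrillation**: a sum of 3–8 random-phase sinusoids (wavelengths
  200–2000 µm), faded to zero at the ROI edges over a 250-µm cosine taper
  so the flanks stay clean for the idealized fit.
* **Lesions**: cosine-tapered depressions; erosions as broad depressions
  spanning their surface extent, fissures as sprays of narrow (40–80 µm)
  notches across theirs.
* **Exact truth**: the combined deviation field is rescaled analytically so
  its realized ROI RMS equals the animal's true roughness exactly, and the
  tidemark is offset along the inward base-curve normals so the mean
  perpendicular separation over the ROI equals the animal's true thickness
  exactly. Recovery tests therefore measure estimator error, not generator
  sloppiness.

### Calibration of the default presets

The default presets place the generator truth at the group summaries of an
eleven-rabbit-per-arm ACLT study:

* **Thickness** (µm): control 155.73, Channa 242.82, glucosamine 211.73;
  between-animal sd = reported SEM × √11. Thickness is drawn from a
  **gamma** distribution with that mean and sd: at the control's
  coefficient of variation (~0.42) a normal would put ~1% of animals below
  zero thickness and truncation would bias the group mean by ~+4 µm —
  half the recovery tolerance.
* **Normalized roughness** (×1000): control 45.10, Channa 22.18,
  glucosamine 33.82. The generator draws the *ratio* per animal (gamma,
  sd = SEM × √11) and sets the true RMS to `ratio × thickness / 1000`.
  Drawing RMS independently of thickness would bias the group mean of the
  ratio upward by ~20% (`E[1/t] > 1/E[t]` at these spreads); drawing the
  ratio itself makes the preset value the exact truth.
* **Roughness vs lesion severity.** Erosions of 1/3–2/3 of a ~150 µm
  cartilage depth would by themselves produce RMS deviations of 15 µm and
  more, which is inconsistent with normalized roughness of 22–45 ×10⁻³
  (RMS ≈ 5–7 µm). Real section series show the same tension between
  ordinal erosion grades and micrometre-scale roughness statistics. The
  generator resolves it by treating the per-animal roughness as the total
  deviation budget: carved lesions are capped at 70% of the budget (in
  mean square) and the sinusoid field fills the remainder. Histology
  *scoring* uses the uncapped descriptors, so ordinal severities are
  unaffected.
* **Area.** Printed group areas of ~0.6–1.0 ×10⁵ µm² are geometrically
  inconsistent with 7 mm × 150–240 µm ≈ 1.4 ×10⁶ µm². The package computes
  geometrically correct areas; each preset carries a centered evaluation
  window (`area_window_um` = area truth / thickness truth ≈ 372–402 µm)
  over which the trapezoidal area recovers the group's area truth. Both
  facts — correct geometry and the calibrated target — are preserved; the
  discrepancy is documented rather than hidden.
* **OARSI components.** Per-compartment totals: control MF 7.27, MT 5.82,
  LT 7.45 with LF = 7.73 chosen so the four-compartment total is 28.27;
  Channa 4.36/2.55/3.82 with LF = 5.00 (total 15.73); glucosamine has only
  MF 3.64 and the 17.55 total on record, so LF/MT/LT are set to
  6.00/3.60/4.31 — between the other two arms per compartment and summing
  to the total. Each compartment mean is split 55/30/15 across structure,
  density and clusters; structure scores follow a binomial(11, mean/11)
  law over the 12 rubric rows realized as (depth, extent) descriptors,
  density a binomial(4, mean/4) over the five categories, and cluster
  counts a Poisson whose rate is solved so the expected banded score is
  exact. Expected totals are therefore exact by construction.
* **India-ink grades.** Per-compartment grade probabilities were chosen so
  that each compartment's median matches the reference pattern (Channa
  1/1/1/1, glucosamine 3/2/2/2, control 3/3/2/2) *and* the modal cohort
  median of the four-compartment total is 4 (Channa), 9 (glucosamine) and
  10 (control) for n = 11 cohorts. This joint calibration was done once by
  simulation when the presets were designed and the probabilities are
  frozen in `default_presets()`.
* **Serum.** No group means are on record for the assays; the presets use
  plausible ng/ml values inside the assay range with control COMP two
  treatment-sds above the treated arms (the direction reported for
  cartilage degradation in untreated OA) and no group differences for
  COX-2 and PGE2.

### What the generator does *not* emulate

Surgical variation, healing dynamics over the 8-week course, spatial
correlation between compartments within a joint, section-preparation
artifacts (folds, stain gradients), and the huge printed between-animal
area dispersions (which are incompatible with strictly positive areas).
Passing recovery tests therefore demonstrates that the estimators are
unbiased and correctly scaled under the modelled data structure — not that
they are robust to every artifact of real histology.

## Dose conversion

Treatment doses follow body-surface-area conversion from the human daily
dose: `dose_mg_per_kg = human_total_mg / human_mass_kg × species_factor`,
with rabbit factor 3.6. A 1000 mg/70 kg human dose gives 51.4 mg/kg. The
glucosamine arm's conventional 77.5 mg/kg is carried as given in the
presets' documentation: neither 15 000 mg (→ 771.4) nor 1500 mg (→ 77.1)
reproduces it exactly under factor 3.6, so the package records the value
without endorsing a derivation.

## Statistical pipeline choices

* **Gates.** Shapiro–Wilk per group at α = 0.05 decides normality
  (graphical checks are plots, not gates); Levene's test with
  **mean**-centering (the convention of mainstream one-way homogeneity
  gates; median-centering would be the Brown–Forsythe variant) decides
  between Tukey and Dunnett's C.
* **Dunnett's C** is decision-only: for groups i, j the critical difference
  is `q · sqrt((s_i²/n_i + s_j²/n_j)/2)` with `q` the mean of the
  studentized-range quantiles `q_α(k, n_i−1)` and `q_α(k, n_j−1)`. The
  package reports the critical differences and flags, and leaves p values
  `NA` rather than fabricating pseudo-p's.
* **Ordinal endpoints** (macroscopic totals) use Kruskal–Wallis with tie
  correction and pairwise Mann–Whitney tests, exact when small and
  tie-free, continuity-corrected normal approximation otherwise. The
  adjustment for "repeated Mann–Whitney with adjusted p values" is
  Bonferroni ×3 by default — the simplest conservative choice for three
  pairs — and is a config option (`adjust`).
* The OARSI histology total (a sum of twelve 0–18 components) is analysed
  as continuous, matching field practice; the macroscopic total (sum of
  four 4-level grades) as ordinal.
* A helper `sample_size_two_means()` implements the standard two-mean
  normal-approximation formula. For Δ = 0.32, σ = 0.5, α = 0.05, power
  0.90 it returns ~52 per group; small published n's for such parameters
  are not recoverable from this formula, and the helper is informational
  only.

## Numerical choices and degenerate inputs

* Ray–tidemark intersection uses exact 2×2 segment solves restricted to a
  ±1 mm lateral window; misses fall back to vertical distance with an
  `inform()` note and a count in the output.
* The idealized fit centres x before fitting a raw polynomial
  (conditioning) and un-centres the coefficients for reporting.
* Profile validation rejects non-monotone x, boundary crossings
  (surface below tidemark) and non-finite coordinates with classed errors;
  all-tied statistics inputs, empty ROIs, zero thickness and non-positive
  doses raise classed errors rather than NaN propagation.
* Extent ties at exactly 50% classify as ≥ 50% (the rubric writes ≥).
* Rendering refuses pixel sizes that would make the band thinner than
  3 px; segmentation requires exactly one connected tissue component and
  reports the count otherwise.

## Problem sizes used in validation

Recovery tests and the acceptance script use 50 simulated three-arm
cohorts (n = 11 per arm, MF profiles at 4 µm digitization) for the
continuous endpoints, 200 descriptor-only cohorts for the macroscopic
medians, and 2000 null replicates for the familywise type-I error of the
gated pipeline (observed ≈ 0.05, required ≤ 0.07). These sizes give
empirical-SEM bands of roughly 1–2% of the recovered means, chosen as the
package's own validation design.

## Known limitations

* Segmentation handles only the synthetic raster dialect (one band, bright
  background); it is not a histology segmenter.
* Dunnett's C flags cannot be turned into exact p values; reports that
  quote p values for C-gated comparisons are approximating.
* The generator's lesion geometry is stylized (cosine depressions); it is
  calibrated for measurement statistics, not for visual realism.
* Between-compartment correlation within an animal is limited to sharing
  the animal's thickness/roughness truth; descriptors are drawn
  independently per compartment.
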