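---
title: "Methods: CARS image quantification of yolk transport and oocyte lipid delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CARS image quantification of yolk transport and oocyte lipid delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormcars)
```

## The measurement problem

Yolk lipoprotein is the main lipid carrier from the *C. elegans* intestine
into developing oocytes. When oocyte uptake is impaired — as in the
PUFA-synthesis *fat* mutants — secreted yolk accumulates in the
pseudocoelomic cavity. Both phenomena are visible label-free: CARS imaging
at the CH₂ lipid stretch (~2845 cm⁻¹) reports lipid density, with the
amide-I protein band (~1665 cm⁻¹) confirming the lipoprotein nature of the
accumulations and the non-resonant band (~2200 cm⁻¹) acting as a negative
control. `wormcars` quantifies such frames and, because raw microscopy of
live worms is not redistributable, ships a synthetic scene generator whose
planted ground truth lets the whole chain be validated by parameter
recovery.

## Segmentation of pseudocoelomic accumulations

All thresholding operates on the dimensionless **ratio image**: each pixel
divided by the mean intensity of a user-drawn surrounding-buffer ROI
(`ratio_image()`). This removes laser-power and detector-gain differences
between sessions. Accumulation pixels are those with ratio in
`[ratio_low, ratio_high]`, default **1.47–3.12**: the band brackets the
contrast of genuine yolk accumulations while excluding buffer (ratio ≈ 1)
and the much brighter hypodermal lipid droplets (ratio ≈ 4.4), which would
otherwise contaminate the counts. Thresholding is applied per pixel inside
the *pseudocoelom-eligible* mask; intestine, embryos and body wall are
excluded up front by the mask, mirroring the manual organ exclusion of the
original protocol — organ segmentation is explicitly out of scope here.

Thresholded pixels are grouped into connected components with
**8-connectivity** (default; the sources are silent on adjacency, and
8-connectivity keeps diagonal-touching pixels of one polygonal blob in one
component). Components smaller than `min_area = 10` µm² are discarded —
the detection limit of the ratio-threshold method, which the package
re-derives empirically (below). Components clipped by the eligible-mask
boundary are kept with their visible area: discarding them would bias
strain comparisons against worms whose accumulations abut excluded organs.
No smoothing or denoising precedes thresholding. Component statistics are
computed on the ratio raster; the per-component `mean_ratio` is reported
for comparability with contrast-based summaries even though the
segmentation itself is per-pixel.

The implementation labels components through an 8-neighbour pixel adjacency
graph (`igraph`); the test suite checks it against an independent
flood-fill oracle on 200 random rasters, exactly.

### Size distributions and the area-contribution curve

Pooled component areas from a cohort are binned in uniform
`bin_width = 20` µm² classes (0–20, 20–40, …). Occurrences divided by the
number of worms give the per-worm frequency of each size class; frequency
times the class's **representative area** gives the area contribution. The
representative area is the **bin midpoint**: the natural phrase "each
binned area size" is ambiguous between midpoint and lower edge, and the
midpoint choice makes the curve's integral an unbiased estimate of the mean
total accumulation area per worm (exact whenever the areas sit on
midpoints; in general within `n_bins × bin_width/2 × max frequency`, which
the tests assert). `contribution_fraction_below()` integrates the curve up
to a cutoff, pro-rating the straddling bin.

### Detection limit

`detection_limit()` plants convex polygonal blobs of known rasterised areas
(ladder 2–40 µm², step 0.25) at the small-accumulation mean contrast 1.69
on noisy frames (multiplicative CV 0.05, 20 replicate seeds) and reports
the smallest planted area recovered in ≥ 95% of instances. The contrast is
fixed at the class mean deliberately: the experiment probes *size*
sensitivity; a blob whose contrast falls below `ratio_low` is invisible at
every size, which is a property of the band, not of the size threshold
under test. The acceptance suite asserts that the measured limit is
consistent with the ≥ 10 µm² sensitivity of the method.

## Per-oocyte quantification

**Integrated CARS.** For an oocyte mask with its nucleus sub-mask, the
background *B* is the mean intensity over the **nucleus** (dominated by the
non-resonant signal of non-lipid cell content), and the statistic is
Σ √(max(*I* − *B*, 0)) over all oocyte pixels. The square root linearises
the quadratic dependence of the coherent signal on scatterer concentration,
so the statistic scales with the oocyte's lipid content. Two numerical
choices: values below background are clamped to zero before the square root
(pixels dimmer than the nucleus carry no lipid information), and the
background description in the source protocol admits a second reading —
a *separate* background subtracted *from* the nucleus mean — which is
documented but not implemented; with the nucleus as the darkest
intracellular reference the two readings coincide in practice.

**Integrated GFP.** Fluorescence is linear in fluorophore concentration, so
no square root: Σ max(*I* − *B*, 0) over the oocyte, with *B* the mean of a
GFP-negative reference region.

**Offsets and the carrier–lipid fit.** Both signals are reported as
differences to the worm's −5 oocyte, which carries essentially no
detectable carrier and therefore serves as the per-worm offset
(`delta_signals()`). The coupling between carrier and lipid is an ordinary
least-squares fit of the **position means** of ΔCARS on ΔGFP
(`carrier_lipid_fit()`), not of pooled per-worm points: position means are
what the staging design estimates, and per-worm pairing would mix
within-worm noise into the structural relation. A positive intercept
measures carrier-independent lipid delivery (yolk complexes invisible to
the GFP tag). The fit is validated against a closed-form OLS oracle at
1e-9 relative tolerance.

**Geometry.** `axes_from_mask()` takes the orientation from the mask's
second moments and returns the pixel extents along the principal axes.
A raw second-moment ("equivalent-ellipse") axis estimate was considered and
rejected: it overestimates a rectangle's side by 2/√3 ≈ 15%, whereas
principal-axis extents are exact for rectangles, disks and ellipse masks
and rotation-invariant — the closest reproducible analogue of a manual
caliper measurement. Volumes use the cylinder model
*V* = π·*L*·(*W*/2)², the standard geometric idealisation for proximal
oocytes.

**Normalisation.** `normalize_lipid()` divides strain/position means (and
SEMs) by a reference cell, defaulting to wild-type N2 at position −1 — the
natural anchor (most mature oocyte of the control strain); the original
normalisation reference is not stated.

## Reproduction metrics

The ovulation rate of an assay row is
(eggs laid + finally retained − initially retained) / (hours × gonad arms),
in oocytes · arm⁻¹ · h⁻¹ — **per gonad arm** throughout; per-worm rates are
2× under the default two arms. Negative rates (impossible biologically)
are returned with a warning rather than clamped: they flag inconsistent
counts. The mean dwell time at an oocyte position is the inverse of the
ovulation rate, so the lipid-delivery rate across a transition is the
content increment times the ovulation rate; the rates telescope — the sum
over transitions divided by the rate equals the −5→−1 content gain — which
the tests assert at 1e-12. Normalisation of delivery tables supports two
conventions: per matching wild-type transition (default) or everything
against the wild-type −2→−1 rate; both are exposed because the reference
convention is not fixed by the source material.

## Statistics

Group comparisons use the two-sided **Welch** unequal-variance test — the
test family is an assumption of this package (the original analyses do not
name one); Welch is robust to the unequal spreads seen across strains, and
the suite checks its p-values against a permutation oracle on small groups.
Star codes follow the conventional \*, \*\*, \*\*\* thresholds. No
multiple-testing correction is applied by default, matching the descriptive
use of the comparisons; `stats::p.adjust` composes trivially where a family
correction is wanted. Strain-level correlation reports use Pearson's r of
**strain means** against egg number (the design has one point per strain
condition), with named-strain exclusion for leave-one-out re-analysis.
Band co-localisation is the per-pixel Pearson r of two bands within a blob
mask.

## The synthetic generator

`strain_preset()` returns the full parameter set for nine strains (N2,
*fat-1*…*fat-4*, and *fat-2* supplemented with 18:1n9 / 18:2n6 / 18:3n6 /
18:3n3). Two classes of constants coexist and are marked in the registry
source: **measured values** stored verbatim — accumulation/buffer contrasts
2.53 ± 0.59 (large) and 1.69 ± 0.22 (small), lipid-droplet contrast
4.39 ± 0.21, strain ovulation rates (2.5, 2.0, 0.5, 1.4, 1.25, … per arm
per hour), the 50% −2→−1 lipid step in every strain, the 25% *fat-2* lipid
deficit in the −1/−2 oocytes, delivery-rate ratios across strains, and a
−1 oocyte geometry giving ~2 × 10⁴ µm³ — and **calibrated values** chosen
once where no numbers are reported: per-strain blob-count and lognormal
blob-size distributions (tuned qualitatively so the wild-type measured
dominant size class falls in 20–60 µm², with mutants shifted larger),
a 5% per-axis oocyte-dimension CV, a 10% worm-level lipid scale CV, buffer
plateau 400 counts, and nucleus plateau 300 counts on the 12-bit scale.

Scenes are 512 × 512 px over a ~141 × 141 µm² field (pixel edge
141/512 ≈ 0.2754 µm — chosen so blob areas of tens of µm² span hundreds of
pixels; pixel counts are a package choice, not a reported value).
Accumulations are random convex polygons (5–8 vertices) with per-blob
contrast sampled from the large/small statistics (blobs ≥ 40 µm² draw from
the large class); lipid droplets are small disks confined to a hypodermal
band; oocytes are staged ellipses with nuclei rendered at the background
plateau. The oocyte cytoplasm intensity is set by inverting the integrated
statistic: Σ √(*I* − *B*) over the oocyte equals a fixed gain times the
planted lipid content, making the square-root statistic the
linear-in-content quantity by construction. The GFP channel renders
carrier = (lipid − offset)/slope, with the offset tied to the −5 content so
the −5 carrier is exactly zero. Noise is **multiplicative Gaussian**
(speckle-like) with the stated CV, followed by integer quantisation and
clipping to [0, 4095]; there is no additive read-noise term (no noise model
is reported; multiplicative speckle is the dominant CARS artefact). Ground
truth stores the *realised* post-quantisation targets, so noiseless renders
recover planted contrasts and integrated-CARS targets exactly — an
invariant the suite asserts at machine precision. A shared smooth texture
field (amplitude 0.15) gives blobs correlated internal structure across
the 1665/2845 bands, supporting co-localisation analysis; texture is
zero-mean per blob, so planted mean contrasts are preserved.

What the generator does **not** emulate: optics (no point-spread function,
no depth attenuation, no non-resonant interference beyond a constant
offset band), organ autofluorescence, motion artefacts, or touching/
overlapping accumulations (placement enforces separation so ground-truth
components are unambiguous). Passing recovery tests therefore shows the
*quantification chain* is correct and unbiased under the stated noise
model — not that segmentation would be this clean on real frames, where
eligibility masks and buffer ROIs are drawn by hand.

Reproduction assays are simulated per worm as a Poisson number of newly
ovulated oocytes with mean rate × arms × hours, split binomially between
laid and retained, so the assay formula recovers the newly ovulated count
exactly and the rate estimator is unbiased (asserted over 300 simulated
cohorts).

## Problem sizes and runtime choices

Validation runs use cohorts of 17–20 rendered worms per strain (matching
the n = 17 cohort of the carrier–lipid design), 30-blob contrast panels,
200-worm assay cohorts, and 20 replicate seeds × 153 ladder areas for the
detection-limit experiment; these sizes put Monte-Carlo error comfortably
inside the stated tolerances (2 SE bands for contrast and ovulation
recovery, ±5 percentage points for the lipid-step and deficit recoveries,
10% for the volume) while keeping a full run in tens of seconds on one
core.

## Known limitations

* Eligibility masks, buffer ROIs and oocyte/nucleus ROIs are inputs;
  nothing is auto-detected, by design.
* Intestinal yolk particles and lipid droplets are not distinguished — the
  underlying imaging cannot separate them, and the package does not try.
* The large/small accumulation classes have no defined boundary in the
  source material; the package reports continuous sizes and uses a 40 µm²
  boundary only inside the generator's contrast sampling.
* The ratio-threshold band is parameterised per band but defaults assume
  the 2845 cm⁻¹ lipid band, where the signal-to-noise is best.
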