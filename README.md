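# wormcars

Label-free quantification of CARS (coherent anti-Stokes Raman scattering)
microscopy images of *Caenorhabditis elegans*, for studying yolk-lipoprotein
transport and lipid delivery into developing oocytes.

In worms with defective oocyte yolk uptake, secreted yolk lipoprotein
accumulates aberrantly in the pseudocoelomic cavity. Both the accumulations
and the lipid being delivered into oocytes can be imaged without labels at
the CH₂ lipid stretch (~2845 cm⁻¹), with the amide-I protein band
(~1665 cm⁻¹) and the non-resonant background (~2200 cm⁻¹) as controls.
`wormcars` implements the image-quantification pipeline around that idea,
and a seeded synthetic scene generator so every stage can be validated by
closed-loop parameter recovery without raw microscopy data.

## What it computes

* **Accumulation segmentation.** Each pixel is expressed as the intensity
  ratio *I*/⟨*I*<sub>buffer</sub>⟩ against a surrounding-buffer ROI. Pixels
  with ratio in a fixed band (default 1.47–3.12) inside the
  pseudocoelom-eligible region are grouped into 8-connected components;
  components smaller than 10 µm² are discarded. Per-component area, mean
  ratio and centroid are reported, plus size histograms and the
  **area-contribution curve**: per-worm frequency of each 20 µm² size class
  times the class midpoint, whose integral is the mean total accumulation
  area per worm.
* **Per-oocyte lipid content.** For staged oocytes −5…−1, the integrated
  CARS signal is Σ √(*I* − *B*) over oocyte pixels, with the background *B*
  the mean intensity of the oocyte nucleus (the square root linearises the
  quadratic concentration dependence of the coherent signal). The
  GFP-tagged yolk carrier is integrated linearly, Σ (*I* − *B*), against a
  GFP-negative background region. Signals are offset against the −5 oocyte
  (which carries no detectable carrier) and the carrier–lipid coupling is an
  OLS fit of mean ΔCARS on mean ΔGFP across positions.
* **Oocyte geometry.** Length/width from the principal-axis extents of the
  oocyte mask; cylinder-model volume *V* = π·*L*·(*W*/2)².
* **Reproduction metrics.** Ovulation rate
  (laid + retained<sub>final</sub> − retained<sub>initial</sub>) /
  (hours × gonad arms), lifetime egg number, and per-transition lipid
  delivery rates ΔC(−n→−(n−1)) × ovulation rate, with wild-type
  normalisation.
* **Statistics.** SEM, Welch two-group comparison with star coding, Pearson
  correlation reports of strain metrics against egg number (with
  leave-one-strain-out), and per-pixel band co-localisation.

The generator ships presets for N2, *fat-1*…*fat-4*, and PUFA-supplemented
*fat-2* strains, planting the measured contrast statistics
(2.53 ± 0.59 and 1.69 ± 0.22 for large/small accumulations, 4.39 ± 0.21 for
hypodermal lipid droplets), staged lipid profiles with the 50% −2→−1 step,
strain ovulation rates, and multiplicative imaging noise on 12-bit frames.

## Worked example

```r
library(wormcars)

p  <- strain_preset("N2")
ws <- render_worm(p, seed = 42)     # three bands + GFP + labels + truth
ws
#> <worm_image_set> strain N2, seed 42
#>   512 x 512 px, 0.2754 um/px; bands: 1665, 2200, 2845 + GFP

q <- quantify_accumulations(ws)     # ratio image -> threshold -> components
q$total_area
#> [1] 140.3798

oo <- quantify_oocytes(ws)
oo[oo$position == -1, c("integrated_cars", "length", "width", "volume")]
#>   integrated_cars   length    width   volume
#> 5        188411.2 48.74414 22.85742 20001.69
```

The −1 oocyte's planted integrated-CARS target for this worm was 188116
(recovered to 0.16% under 5% multiplicative noise), and its cylinder-model
volume lands at the ~2 × 10⁴ µm³ expected of a mature wild-type oocyte.
Fitting the carrier–lipid coupling on a 17-worm cohort:

```r
coh <- quantify_cohort(p, 17, seed = 100, components = "oocytes")$oocytes
d   <- do.call(rbind, lapply(split(coh, coh$worm_id), delta_signals))
fit <- carrier_lipid_fit(tapply(d$delta_gfp,  d$position, mean)[1:4],
                         tapply(d$delta_cars, d$position, mean)[1:4])
fit
#> <carrier_lipid_fit> slope 0.608, intercept 3911, R^2 0.9999
```

The positive intercept is the carrier-independent share of lipid delivery —
delivery that the GFP-tagged carrier cannot see.

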