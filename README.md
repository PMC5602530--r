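# pdrim

Detection and quantification of the **perihematomal diffusion-restriction
rim (PDR)** in hyperacute intracerebral hemorrhage MRI, with a synthetic
multimodal phantom generator and the accompanying cohort statistics.

## The problem

Within the first six hours of a spontaneous intraparenchymal hemorrhage
(IPH), the clot is surrounded by vasogenic perihematomal edema (PHE) —
FLAIR-hyperintense, with *elevated* apparent diffusion coefficient (ADC).
At or just outside the outer edema border, most large hyperacute bleeds
additionally show a thin rim that is hyperintense on b1000
diffusion-weighted images and *hypointense* on the ADC map. Quantifying that
rim is a reading-room procedure: contour the clot on T2\*/SWI (correcting
the ~20% susceptibility "blooming" against FLAIR), contour the whole lesion
on FLAIR, subtract to get the edema, mirror the lesion into the healthy
hemisphere, and threshold the ADC map against the mirror tissue. `pdrim`
automates the full procedure for neuroimaging researchers, and ships a
phantom generator so every stage is testable without patient data.

The core detection rule, per voxel `v` in the edema and a thin shell outside
its border:

```
ADC(v)   <= median_mirror(ADC)   - 1.5 * SD_mirror(ADC)     (hypointense ADC)
b1000(v) >= median_mirror(b1000) + 1.5 * SD_mirror(b1000)   (hyperintense b1000)
```

followed by 26-connected component filtering (≥ 0.05 cc) and a positivity
call at ≥ 0.1 cc. Derived measurements: ROI volumes in cc,
P25/mean/median/P75 ADC statistics, and relative ADC
(`rADC = median ADC of ROI / median ADC of mirror`).

## Worked example

Generate a phantom with a ground-truth rim, run the full segmentation, and
quantify:

```r
library(pdrim)

case <- makePhantom(defaultPhantomSpec(), seed = 42)
out  <- segmentCase(case@volumes, brainMask(case),
                    pipelineConfig(seed = 42), verbose = TRUE)
#> ADC cutoff applied: <= 695.42 (mirror median 790.80 - 1.5 x SD 63.58)
#> b1000 cutoff applied: >= 107.57
#> positivity cutoff applied: >= 0.10 cc (volume 18.83 cc)

out$quant
#> LesionQuant: PDR-positive
#>   IPH  volume 6.85 cc, ADC median 788.3 (P25 707.8, P75 896.9)
#>   PHE  volume 21.58 cc, ADC median 1033.4 (P25 948.4, P75 1112.4)
#>   PDR  volume 18.83 cc, ADC median 617.5 (P25 587.6, P75 648.8)
#>   rADC: IPH=0.997, PHE=1.307, PDR=0.781

diceCoefficient(out$masks$PDR, truthMask(case, "pdr"))
#> [1] 0.909
```

Reading the output: the mirror region (the lesion reflected into the healthy
hemisphere) has median ADC 790.8 and SD 63.6 (units 10⁻⁶ mm²/s), so the rim
threshold lands at 695.4. The detected rim's median ADC of 617.5 sits in the
low-600s range characteristic of hyperacute rims, far below the clot (788)
and the edema (1033); the rADC column shows the same ordering relative to
healthy tissue — rim at 78% (always < 90%), edema at 131% (always > 110%).
The Dice overlap of 0.91 against the generator's ground-truth rim shows the
threshold rule recovers the rim voxel-for-voxel, not merely the positivity
call.

Cohort-level statistics reproduce a published contingency result exactly
from its table counts (males/females × rim-positive/negative):

```r
pearsonChi2(matrix(c(34, 22, 20, 7), 2))
#>  Pearson's chi-squared test (2x2, uncorrected)
#>  X-squared = 1.4303, df = 1, p-value = 0.2317
```

and `analyzeCohort()` runs the whole battery (Mann–Whitney U, chi-squared,
Fisher exact, Kruskal–Wallis, Pearson correlation, multivariate logistic
regression) on any cohort table with the patient-record schema, synthetic
(`makeCohort()`) or real (`readCohort()` / `readCohortSAV()`).

A thin command-line front end with `simulate`, `segment`, `stats` and `run`
verbs is installed at `inst/scripts/pdrim-cli.R`.

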