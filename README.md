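# retinotex

Texture and optical-property analysis of segmented retinal OCT images.

Thickness is the standard OCT readout, but reflectance is what an OCT
device actually measures. In neurodegenerative disease — multiple
sclerosis (MS) in particular — the inner retinal layers thin, and their
*optical* properties (how strongly and how irregularly they reflect)
change too, sometimes before or independently of measurable thinning.
`retinotex` implements a complete, tested pipeline for quantifying those
changes from segmented macular radial scan sets, together with a
synthetic phantom/cohort generator and the mixed-model statistics needed
to compare healthy eyes, MS eyes without optic neuritis (MSON−) and MS
eyes with optic neuritis (MSON+).

It is aimed at researchers working with layer-segmented OCT exports
(a reflectivity image per scan plus eight boundary curves: ILM,
RNFL/GCL+IPL, GCL+IPL/INL, INL/OPL, OPL/ONL+IS, ONL+IS/OS, OS/RPE,
RPE/choroid) who want per-layer, per-region metrics beyond thickness.

## What it computes

For every intraretinal layer (RNFL, GCL+IPL, INL, OPL, ONL+IS, OS, RPE,
plus the GCC composite = RNFL + GCL+IPL) in each macular region
(foveolar disc of diameter 0.375 mm; foveal, parafoveal and perifoveal
annuli of outer diameters 1.85, 2.85 and 5.85 mm; and the pooled
"across all" region):

- **Thickness** — mean boundary distance × axial pixel spacing (µm).
- **GLCM contrast** — second-order texture: with gray-level
  co-occurrence probabilities *p(i, j)* over nearest-neighbour offsets,
  contrast = Σ (i − j)² p(i, j).
- **Fractal dimension** — each A-scan's within-layer reflectance
  profile has power spectrum P(ω) ~ ω^−β; a least-squares fit of
  ln P(ω) against ln ω gives β, and FD = (5 − β)/2. Rougher profiles
  give higher FD.
- **Total reflectance** — per column k, TR_k = MR_k · H_k/Δy (the sum
  of reflectivities in the layer interval); reported as
  10·log₁₀(mean TR) in dB.
- **Layer index** — LI_k = MR_k · H_k / I_sa, where I_sa is the
  99th-percentile reflectivity of the scan; a gain-free measure of
  reflectance × thickness.

Reflectance metrics are computed after complex-diffusion speckle
denoising, vessel-shadow exclusion (shadowgram over the outer retinal
band), and normalization of each scan to its mean RPE reflectance
(NRPE), which makes every reflectance-derived metric invariant to
global intensity gain. Scan sets are gated on quality first: signal
strength must exceed 6 and the percent SD of the foveal center point
thickness across the six radial scans must be ≤ 10% (SQF = 1).

Group comparisons use a linear mixed model per (layer, region, metric)
cell — `value ~ group + (1 | subject)` with a random intercept per
subject to absorb inter-eye correlation — with Wald pairwise contrasts
and the strict significance threshold p < 0.001.

## Worked example

Generate a phantom eye, gate it, extract its feature table, then
simulate a three-group cohort at published effect sizes and compare:

```r
library(retinotex)

ph <- generatePhantomEye(phantomSpec(seed = 1))
ph$scanSet
#> RadialScanSet: eye phantom, 6 scans of 1024 x 512 px, dy = 2 um, 6 mm
computeSQF(ph$scanSet)
#> QualityReport: CPT sd% = 0.00, SQF = 1, min signal strength = 9

ft <- extractFeatures(ph$scanSet)   # denoise -> shadows -> NRPE -> metrics
subset(ft, layer == "RNFL" & region == "across_all")
#>        eye         subject group layer     region               metric  value
#> 16 phantom phantom_subject     H  RNFL across_all         thickness_um 39.846
#> 17 phantom phantom_subject     H  RNFL across_all          contrast_au  8.203
#> 18 phantom phantom_subject     H  RNFL across_all fractal_dimension_au  1.462
#> 19 phantom phantom_subject     H  RNFL across_all       layer_index_au 18.621
#> 20 phantom phantom_subject     H  RNFL across_all total_reflectance_db 12.706
```

The RNFL thickness (39.8 µm) recovers the phantom's planted geometry
(43 µm peripherally, tapering into the foveal pit) to within one axial
pixel; the contrast is low because the phantom's texture is smooth at
the default settings; FD ≈ 1.46 reflects the planted RNFL spectral
exponent; TR and LI are in RPE-normalized units.

```r
cohort <- generateCohortFeatures(cohortSpec(
  groups = referenceGroupSizes(),      # 29 / 31 / 36 eyes
  params = referenceCohortParams(metrics = "total_reflectance_db",
                                 layers = "RNFL"),
  rho = 0.5, seed = 1))
summarizeGroups(cohort$features)
#>   group layer     region               metric  n  mean    sd     se
#> 1     H  RNFL across_all total_reflectance_db 29 21.72 1.249 0.2319
#> 2 MSON-  RNFL across_all total_reflectance_db 31 20.20 1.372 0.2465
#> 3 MSON+  RNFL across_all total_reflectance_db 36 18.31 1.574 0.2624

mixedModelCompare(cohort$features)
#>   layer     region               metric           pair estimate    se  p_value
#> 1  RNFL across_all total_reflectance_db     H vs MSON-     1.53 0.386 7.68e-05
#> 2  RNFL across_all total_reflectance_db     H vs MSON+     3.35 0.377 6.11e-19
#> 3  RNFL across_all total_reflectance_db MSON- vs MSON+     1.82 0.371 9.03e-07
#>   significant method
#> 1        TRUE    lmm
#> 2        TRUE    lmm
#> 3        TRUE    lmm
```

All three pairwise RNFL total-reflectance contrasts replicate at
p < 0.001: the MSON+ group loses ~3.3 dB of RNFL reflectance relative
to healthy eyes, and even MSON− eyes differ from controls.

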