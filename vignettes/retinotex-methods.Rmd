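---
title: "Methods: layer-resolved texture and optical properties of macular OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layer-resolved texture and optical properties of macular OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinotex)
```

## The measurement model

A macular radial scan set is six B-scans through the foveal center,
each a matrix of reflectivities (rows: axial depth from the vitreous,
columns: lateral position over a 6 mm transverse span) with eight
segmented boundary curves delimiting seven layers. `retinotex` takes
the segmentation as given — boundary detection is out of scope — and
quantifies each layer within concentric macular regions: the foveolar
disc (diameter 0.375 mm) and the foveal (0.375–1.85 mm), parafoveal
(1.85–2.85 mm) and perifoveal (2.85–5.85 mm) annuli, all half-open in
radial distance, plus a pooled "across all" region. In the foveolar
disc the inner layers (RNFL, GCL+IPL, GCC, INL, OPL) are displaced
concentrically by the pit anatomy and are not measured; only ONL+IS,
OS and RPE get foveolar values.

### Coordinates and the rounding rule

Boundary positions are fractional row offsets from the image top, and
boundary intervals are half-open `[top, bottom)`. Pixel row `r`
(1-based) belongs to a layer iff `top <= r - 0.5 < bottom`, i.e. a
pixel follows the layer that contains its center. This rule is the
only one that makes the seven per-column pixel counts *partition* the
ILM-to-RPE/choroid span exactly, so no pixel is counted twice and none
is dropped between layers; the property is enforced by a test.
Thickness itself uses the exact fractional distance
`(bottom - top) * axial spacing`, not the rounded pixel count. Columns
whose resolved pixel interval is empty are dropped from a region of
interest; an empty region yields `NA`, never 0 (0 is a valid contrast).

### Preprocessing order

Denoise, then locate vessel shadows, then normalize: speckle would
bias every texture statistic, so it is removed first; vessel shadows
attenuate the signal beneath retinal vessels and would both corrupt
reflectance metrics and depress the normalization reference, so they
are excluded before the reference mean is taken.

* **Complex diffusion denoising.** The image evolves under
  `dI/dt = div(c grad I)` with complex conductance
  `c = exp(i*theta) / (1 + (Im(I)/(k*theta))^2)`; the imaginary part
  behaves like a smoothed Laplacian, so `c` collapses near edges and
  diffusion smooths only within homogeneous tissue. Defaults: 10
  iterations, time step 0.2 (explicit stability requires <= 0.25),
  `theta = pi/30`, and an edge scale `k` of 0.1 x image maximum. The
  divergence form with half-point conductances conserves the image
  mean exactly, and the filter is scale-equivariant (denoising `c*X`
  gives `c*`denoised `X`), which the gain-invariance tests rely on.
* **Vessel shadowgram.** `s(k)` is the mean reflectivity of column `k`
  over the ONL+IS-through-RPE band — everything beneath the inner
  vasculature. Columns with `s(k) < 0.75 * median(s)` are flagged and
  each flagged run is dilated by one column per side. The threshold
  factor is a free parameter (no published rule exists); 0.75 sits
  between typical shadow depths (0.3–0.6 of surround) and the ±10%
  texture-driven variability of the denoised shadowgram. Detection is
  only meaningful *after* denoising: on the raw phantom the band mean
  swings by ±25% column to column.
* **NRPE normalization.** Every pixel is divided by the scan's mean
  RPE reflectivity over non-shadow columns, making the RPE band mean
  exactly 1. Device gain, focus and media opacity scale the whole
  image and cancel; the operation is idempotent. Normalization is per
  scan (not per eye): whether the original workflow normalized the six
  scans jointly is unreported, and per-scan normalization is the
  choice that makes each scan self-contained.
* **Quality gate.** Center point thickness (CPT) is the ILM-to-OS/RPE
  distance at the fovea column; a set is accepted iff the percent
  sample SD of the six CPTs is at most 10% (SQF = 1) and the minimum
  signal strength exceeds 6.

## The metrics

* **Thickness (µm).** Mean fractional boundary distance x axial
  spacing over the region's columns. Thickness uses *all* region
  columns; the reflectance metrics exclude shadow columns.
* **GLCM contrast (a.u.).** ROI reflectivities are quantized to 64
  equal-width bins over the fixed range `[0, q99 of the scan]` (the
  top bin absorbs the overflow); a symmetric co-occurrence matrix over
  the offsets (0,1) and (1,0) counts pairs with both pixels inside the
  ROI; contrast is the mean squared level difference. Quantizing
  against a scan-relative range keeps the statistic gain-invariant.
  64 levels with pooled axial+lateral nearest neighbours is the
  standard medical-imaging GLCM configuration; both knobs are exposed.
* **Fractal dimension (a.u.).** Per column, the within-layer profile
  is mean-detrended, its discrete power spectrum is fit as
  `ln P ~ -beta ln omega` over all positive frequencies up to Nyquist,
  and `FD = (5 - beta)/2`; the region value is the unweighted mean
  over admissible columns. Profiles shorter than 8 samples or with
  zero variance are skipped, and zero-power bins are dropped from the
  fit (at least two points required). No taper window is applied:
  profiles are short (tens of samples) and the mean-detrend already
  removes the DC term the power law excludes. Column averaging is
  unweighted — weighting by profile length would couple FD to
  thickness, which the metric is meant to complement.
* **Total reflectance (dB).** Per column the layer's reflectivity sum
  (equivalently mean reflectance x thickness in pixels); the region
  value is `10 log10` of the *linear* mean over columns. Averaging in
  the linear domain before the dB conversion is the physical choice
  (energies add linearly); the alternative (mean of per-column dB) is
  not used.
* **Layer index (a.u.).** Column sum divided by `I_sa`, the scan's
  99th-percentile reflectivity, averaged over columns. The thickness
  term is taken in pixel units, which reduces the index to a
  normalized column sum — the reading forced by the defining identity
  between the mean-reflectance form and the sum form.

Per eye, each metric is computed per scan and averaged over the six
radial scans. The "across all" value is computed on the union of the
included regions' columns (column-weighted), which is the only
definition consistent with the per-region means; inner layers draw
from the three annuli only, outer layers also from the foveolar disc.
GCC metrics are computed on the composite ILM-to-GCL+IPL/INL interval
rather than by combining sub-layer results (for thickness the two
agree exactly; for nonlinear metrics they need not).

## The synthetic data

### Phantom eyes

`generatePhantomEye()` builds six radial B-scans (512 columns over
6 mm, 1024 axial pixels at 2 µm — time-domain-device-like sampling)
from a radially symmetric geometry: each layer has a peripheral
thickness (defaults near published healthy parafoveal/perifoveal
means) and the four inner layers taper to zero at the fovea under a
raised-cosine pit of width 1.5 mm. Reflectivity is
`base level x (1 + 0.3 x 1/f^beta texture) x speckle`:

* the texture of each layer is 1/f^beta noise along each A-scan, built
  by inverse-transforming exact `omega^(-beta/2)` amplitudes with
  random phases (the Nyquist bin keeps the prescribed amplitude with a
  random sign — a random *complex* phase there would leak an O(0.03)
  bias into the FD estimator purely from that degenerate bin);
* speckle is multiplicative gamma noise with unit mean (shape 10 by
  default, i.e. ~32% SD) — the pipeline removes speckle, so the
  generator must create some for the denoiser to remove;
* vessel shadows multiply everything beneath the ILM of the affected
  columns by a depth factor (defaults: two runs of 5 and 4 columns,
  ~60/47 µm, at factor 0.45 — realistic vessel-shadow widths at
  11.7 µm per column; shadows much narrower than that are physically
  implausible and would be erased by any denoiser).

Output is quantized to the 16-bit integer grid and boundaries to 1e-3
rows, so a written phantom round-trips bit-exactly through the TIFF +
CSV + JSON interchange format. The ground-truth sidecar records the
*analytic* per-layer/per-region thickness (from the thickness profile,
not the image), the planted shadow columns and the per-layer
exponents.

What the phantom does **not** emulate: optics (coherence effects,
depth-dependent attenuation, defocus), motion and tilt, anatomical
asymmetry between radial directions, pathology (microcystic edema),
or boundary-segmentation error (the segmentation is exact by
construction). Passing the recovery tests therefore demonstrates that
the measurement code is faithful, not that segmentation noise on real
data would be tolerated.

### Cohorts

`generateCohortFeatures()` draws eye-level metric values directly: per
cell and group each subject receives a `N(0, rho*sigma^2)` intercept
and each eye an independent `N(0, (1-rho)*sigma^2)` residual about the
group mean, so two eyes of one subject correlate at `rho` (default
0.5; the real inter-eye correlation is unreported). Printed "±"
dispersions in published group tables are treated as standard errors
by default and scaled to eye-level SDs by `sqrt(n_eyes)` — at ~0.5 µm
for ~35 µm means they are implausibly small for between-eye SDs — and
the flag `dispersionIsSE` exposes the alternative.
`referenceCohortParams()` bundles published across-all group summary
statistics for all five metrics and eight layers (several printed
perifoveal thickness rows in the source table are visibly misaligned
and are not bundled).

## Statistics

Each (layer, region, metric) cell is fit independently by REML:
`value ~ 0 + group + (1 | subject)` via `lme4`, with pairwise Wald
contrasts (`2 * pnorm(-|est/se|)`) and the strict threshold
`p < 0.001` serving as the multiplicity control. Fitting cells
independently (rather than one joint model over regions) matches the
table-per-metric reporting structure. With one eye per subject the
random intercept is estimated at zero and the contrasts coincide with
one-way ANOVA, which a test verifies. Two guarded degeneracies fall
back to Welch tests on subject means, with a warning: a failed mixed
fit, and a residual variance estimated at (numerically) zero — e.g.
exactly duplicated eye rows — where the REML variance partition
degenerates and the Wald SEs would claim spurious precision, while
subject means still carry all the information.

## Known limitations

* **FD of very thin layers.** At 2 µm axial sampling the RPE (~13 µm,
  6–7 pixels) falls below the 8-sample minimum profile length, so its
  fractal dimension is undefined on the default phantom; the original
  device/software stack evidently resolved thin layers more finely.
* **Speckle flattens steep spectra.** White speckle adds a flat
  spectral floor, biasing beta downward (FD upward) most for the
  smoothest layers; with realistic speckle the planted FD ordering of
  the two steepest layers inverts unless the image is denoised first.
  Conversely, the nonlinear diffusion smooths dim layers more than
  bright ones (its edge scale is global), so after denoising FD
  confounds base reflectivity with slope. The FD-ordering property is
  therefore validated in the texture-dominated regime (negligible
  speckle), and per-profile FD recovery is validated exactly on pure
  power-law profiles.
* **Replication of the weakest published contrasts.** At the published
  SE-scaled effect sizes, the H vs MSON− RNFL thickness separation has
  a Wald z of ~3.5, i.e. ~60% power at alpha = 0.001 — a single study
  realization can pass (the observed p was just under the threshold)
  but most replicates will not. The replication tests therefore assert
  near-certain replication only for the H vs MSON+ contrasts (z of
  7–9), and the acceptance endpoints are defined on those.
* **Problem sizes in the test suite.** Estimator calibration uses 200
  profiles of length 64 per exponent; metric oracles use 50 random
  phantoms; the full-loop test uses one default-size phantom eye
  (6 x 1024 x 512); FD ordering uses 20 reduced phantoms
  (512 x 128); replication and null calibration use 50 and 500
  simulated cohorts. These sizes give comfortable statistical margins
  for every asserted property while keeping the suite fast.
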