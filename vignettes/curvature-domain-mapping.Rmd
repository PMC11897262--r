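---
title: "Curvature-domain mapping with CBV-sensitive laminar fMRI: methods"
author: "vasodomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-domain mapping with CBV-sensitive laminar fMRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vasodomains)
```

## The problem and the measurement model

Area V4 is hypothesised to contain alternating mesoscale domains preferring
curved versus straight contours, columnar across cortical depth. Gradient-echo
BOLD is a poor probe of such organisation because its signal is weighted
toward large draining veins at the pial surface and beyond. SS-SI VASO
acquires pairs of volumes in an interleaved fashion: a *nulled* volume in
which blood signal is suppressed by inversion recovery (so an activation-driven
CBV increase displaces tissue water and *lowers* the signal), and a
*not-nulled* volume with conventional BOLD weighting. The nulled volume is
still multiplicatively contaminated by BOLD; dividing the nulled by the
not-nulled series ("dynamic division", BOCO) removes that contamination.

This package implements the full analysis — preprocessing, GLM and
block-peak preference mapping, equi-volume laminar analysis, and modularity
quantification — and, because no raw acquisition is distributed, pairs it
with a generative simulator whose ground truth makes every stage falsifiable.

## The simulator

For voxel $x$ at volume-pair $i$ (pair repetition time $TR = 2.610$ s), let
$p(x) \in [-1, 1]$ be the column's curvature preference (constant across
depth by construction). Each stimulus block drives the voxel by its
condition match, $(1+p)/2$ for RF0 (circles) and $(1-p)/2$ for RF4 (rounded
squares), times a haemodynamic response $h(t)$. The signals are

$$\text{notnulled}_i = S_0 \bigl(1 + \Delta_\mathrm{BOLD}\, w_\mathrm{vein}(x)\, D_\mathrm{BOLD}(x, \tau_i)\bigr)\, g(\tau_i), \qquad
\text{nulled}_i = \bigl(1 - \Delta_\mathrm{CBV}\, m(x)\, D_\mathrm{CBV}(x, \sigma_i)\bigr) \cdot \tfrac{1}{2}(\text{notnulled}_i + \text{notnulled}_{i+1}),$$

with $\tau_i$ the not-nulled readout times, $\sigma_i = \tau_i + TR/2$ the
mid-pair nulled readouts, $g$ an optional shared linear drift (default
0.1% per run, exercising the GLM ramp), and independent Gaussian thermal
noise added to both series. Key choices:

* **Interleaved contamination.** The nulled volume is read out midway
  between two not-nulled readouts, so its BOLD contamination is modelled as
  the linear interpolant of the bracketing not-nulled factors. Under this
  piecewise-linear model the preprocessing chain (temporal upsampling ×2
  with linear interpolation, duplication of the first nulled timepoint,
  voxelwise division) inverts the contamination *exactly*: at zero noise the
  corrected series equals the simulator's CBV component at every sample
  aligned with a nulled readout, to within one floating-point ulp (a
  multiply–divide round trip cannot be bit-exact in IEEE arithmetic). This
  is why linear interpolation is the default upsampling kernel — cubic
  splines are available and also preserve constants and ramps, but forfeit
  the exact-inverse property. The first four (non-steady-state) pairs are
  excluded from this identity since the chain overwrites them.
* **Vascular maps.** Microvascular responsiveness $m$ is 1 in gray matter
  and 0 elsewhere: the corrected VASO response is confined to cortex. The
  venous weight rises linearly from 0.3 at the white-matter boundary to 1
  at the CSF surface and persists (×1.2) into the first CSF voxel above
  each column — BOLD activation therefore spreads beyond the cortical
  ribbon, VASO activation does not.
* **Haemodynamics.** A raised-cosine rise peaks (normalised to 1) exactly
  6 s after stimulus onset for both contrasts, settles exponentially onto a
  0.8 plateau until offset, then returns to baseline over 6 s (BOLD) or
  10 s (CBV — delayed vascular compliance). The boxcar GLM is deliberately
  unconvolved: CBV and BOLD do not share a response shape, so no single
  kernel would be appropriate.
* **Response amplitudes.** $\Delta_\mathrm{CBV} = 0.02$ and
  $\Delta_\mathrm{BOLD} = 0.04$: BOLD responses are stronger than VASO, as
  expected from its venous amplification. The acquisition does not pin
  these values down; they are calibration choices of the simulator.

### Noise calibration

The quality floors are temporal SNR 25 for the corrected VASO branch and 40
for the BOLD branch. For a single series of mean $S_0$,
$\sigma = S_0/\mathrm{target}$ gives exactly the target tSNR. The corrected
VASO series is a *ratio* of two independently noisy series, so to first
order its noise variance is doubled:
$\mathrm{tSNR}_\mathrm{BOCO} \approx S_0 / (\sigma\sqrt{2})$. Calibrating
against a BOCO-branch target therefore uses
$\sigma = S_0/(\mathrm{target}\cdot\sqrt{2})$
(`calibrate_noise(S0, target, series = "boco")`). The default configuration
uses one thermal $\sigma$ for both series,
$\min\!\bigl(S_0/40,\; S_0/(25\sqrt 2)\bigr) = S_0/40$: the BOLD branch then
sits at its floor and the VASO branch clears its own
($40/\sqrt{2} \approx 28 > 25$). Two further effects shift the measured
values benignly: midpoint upsampling correlates adjacent samples (raising
measured tSNR by $\approx 15\%$), and stimulus-locked signal variance lowers
it slightly. Measured medians at the defaults are $\approx 32$ (VASO) and
$\approx 43$ (BOLD) over gray matter.

### Domain patterns and geometry

The default patch is an elongated $48 \times 16 \times 10$ grid of 1.2 mm
voxels — a flattened V4-like ROI is elongated, and the collapse axis of an
isotropic patch is ill-defined (the PCA step warns in that case). The
gray-matter slab is 3.6 mm thick, giving three symmetric depth samples
(1/6, 1/2, 5/6) so that the default three equi-volume depth bins are all
populated. Ground-truth domains default to binary stripes
$p = \mathrm{sign}\,\sin(2\pi u/\lambda)$ with $\lambda = 1.6$ mm — the
mesoscale regime, deliberately close to the published domain scale while
still above one voxel; the generator warns that $\lambda < 2$ voxels is
under-sampled, which is the point of the default: domain periods near the
voxel size are at the resolution limit, and quantitative recovery tests use
$\lambda \in \{3.6, 4.8, 7.2\}$ mm where the 1.2 mm sampling supports the
fit. (True 0.5 mm domains would only be representable on the ×6-upsampled
geometry.) A `blobs` pattern (thresholded band-pass noise at scale
$\lambda$) provides a non-striped alternative; both are columnar by
construction.

## Preference mapping

Per voxel and block, the peak response is the mean signal from 5.22 to
31.32 s after block onset (past the 6 s rise; the windows are multiples of
the upsampled sampling interval) minus the mean over the final 10.44 s of
the preceding rest. The corrected VASO series is sign-inverted first, since
a CBV increase is a signal decrease. The preference map is the Welch
two-sample t across RF0-block versus RF4-block amplitudes (7 vs 7 at the
default design), positive toward curvature, and deliberately
un-thresholded. A GLM difference contrast over the two boxcars is exposed
alongside as a cross-check; at zero noise both recover the sign of $p$ at
every gray-matter voxel. Degenerate inputs are handled explicitly: zero
variance with zero difference gives $t = 0$; zero variance with a nonzero
difference gives $\pm\infty$ (sign still meaningful).

## Laminar analysis

On the synthetic geometry, curvature $\kappa$, thickness $T$ and the flat
chart $(u, v)$ are analytic, so equi-volume depths use the local-wedge
closed form: with $r_1 = 1/|\kappa|$ and $r_2 = r_1 + T$, the cumulative
volume fraction at equidistant depth $d$ is
$\bigl((r_1 + dT)^2 - r_1^2\bigr)/(r_2^2 - r_1^2)$ where the sheet is
convex toward CSF, mirrored otherwise, with the $\kappa \to 0$ limit equal
to $d$ — verified against the exact equal-area radii of an annulus. The
discrete iterative layering used on real cortical meshes is out of scope;
the closed form is exact for the parametric geometry. Flat maps bin
gray-matter voxels into $(u, v)$ cells (first cell centred on the smallest
coordinate; empty cells stay missing); depth profiles flatten each
equi-volume bin separately, and the columnarity index is the mean pairwise
correlation between depth-bin maps — a descriptive summary, not a
calibrated statistic.

## Modularity and sensitivity/specificity

The collapse axis is the first principal component of the unweighted ROI
cell coordinates (what enters the PCA is a design choice; coordinates make
the long axis of the ROI the banding axis, and the method assumes linear
banding — curved banding would blur the profile). Cell values are averaged
in projection bins and a sinusoid is fitted by scanning periods between
twice the bin width and the profile extent, solving amplitude and phase
linearly at each candidate; $R^2$ is reported against the mean-only model.

Per voxel, with $v = (t_{RF0}, t_{RF4})$ from stimulus-vs-baseline
contrasts: sensitivity is $\lVert v \rVert$; specificity is
$1 - \cos^{-1}(\hat v \cdot \hat w)/45^\circ$ where $\hat w$ is the axis of
the larger component after rectifying negatives to zero. Rectification
keeps the two-condition geometry inside the $45^\circ$ scale so the index
lands in $[0, 1]$; equal responses score 0 (equally tuned = not specific),
a zero vector scores 0 by definition, and a signed variant is available
behind `rectify = FALSE`. At the study defaults the BOLD branch shows about
twice the median sensitivity of VASO (venous weighting), while the VASO
specificity distribution spans the wider range — the noisier corrected
series wobbles the response angle more, and BOLD's vein weighting scales
both conditions of a voxel equally, so it does not degrade BOLD's angular
tuning in this model.

## What the synthetic conditions do not show

The simulator omits, by design: spatial point-spread and tangential venous
blurring (BOLD contamination is purely voxelwise-multiplicative — so the
*profile cleanliness* advantage of VASO over BOLD seen in real data, which
stems from BOLD signal spreading across columns, is not reproduced here;
with matched thermal noise the two branches' collapsed-profile $R^2$ are
statistically indistinguishable), physiological noise and motion, k-space /
EPI artefacts, inflow effects, and real folded-cortex reconstruction.
Passing tests establish that the *analysis* is correct against a known
ground truth and that the qualitative BOLD/VASO asymmetries the vascular
model does encode (sensitivity ordering, specificity spread, CSF extension)
are recovered — not that real 3 T data will behave identically.

## Problem sizes and numerical choices

Defaults used throughout the tests: $48 \times 16 \times 10$ voxels, 369
volume pairs per run (738 after upsampling), four runs averaged; the tiny
fixture ($16 \times 16 \times 8$, two blocks per condition, two runs)
exercises the full pipeline in about a second. Division guard: denominator
samples below 5% of the voxel's temporal mean inherit the previous ratio
(1 at the start); corrected values are clipped to $[0, 2]$; all-zero
denominators are flagged rather than repaired. Time-window comparisons use
a $10^{-6}$ s tolerance so that windows that are exact multiples of the
sampling interval do not straddle samples. All randomness flows from one
integer seed; per-run seeds are derived arithmetically, and identical
configurations reproduce simulations bit-for-bit.

## Worked call

```{r example}
cfg <- run_config(seed = 1)           # study defaults
m <- run_pipeline(cfg, out_dir = "out")
write_report(m, file.path("out", "report.md"))
m$tsnr_gm_median                       # branch QC medians
m$profile_fits$vaso                    # collapsed-profile sinusoid fit
m$sens_spec_summary                    # BOLD vs VASO indices
```
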