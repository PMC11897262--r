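# vasodomains

Mapping mesoscale **curvature-preference domains** in visual cortex with
CBV-sensitive laminar fMRI — as a fully synthetic, testable R pipeline.

Mid-level visual area V4 is thought to organise responses to contour
curvature into alternating columnar domains: patches preferring curved
contours interleaved with patches preferring straight ones. Probing this
organisation with fMRI at clinical field strength requires a contrast that
is not dominated by surface draining veins. SS-SI VASO (Vascular Space
Occupancy) acquires interleaved *nulled* (blood-nulled, CBV-weighted) and
*not-nulled* (BOLD-weighted) volumes; a CBV increase during activation
*decreases* the nulled signal, and dividing the nulled by the not-nulled
series removes the multiplicative BOLD contamination ("BOCO"). This package
implements that analysis end to end, together with a calibrated simulator
that stands in for raw scanner data, so that every stage is verifiable
against a known ground truth.

## What the package provides

| module | contents |
|---|---|
| stimulus design | radial-frequency patterns `r(θ) = r0 (1 + A sin(ωθ + Φ))` (RF0 = circles, RF4 = rounded squares), contrast-reversing renders, and the block timeline (33 rest pair-TRs of 2.610 s, then fourteen 31.32 s on–off blocks) |
| synthetic data | parametric cortical patch (flat or folded) with columnar preference domains `p ∈ [−1, 1]`, depth-increasing venous weighting that leaks into CSF-adjacent voxels, plateau-shaped haemodynamic responses peaking 6 s after onset (CBV returns later), and thermal noise calibrated to branch tSNR floors of 25 (VASO) / 40 (BOLD) |
| preprocessing | contrast separation, non-steady-state replacement (first 4 volumes), temporal upsampling ×2, first-nulled-timepoint duplication, dynamic division with guard/clipping, run averaging, tSNR QC |
| activation mapping | unconvolved 4-column GLM (DC, ramp, RF0/RF4 boxcars), stimulus-vs-baseline t maps, and block-peak preference maps (Welch t, positive = curvature preference) |
| laminar geometry | closed-form equi-volume cortical depths, ×6 anatomical upsampling (1.2 mm → 0.2 mm), flat-map projection, depth-bin profiles with a columnarity index |
| modularity metrics | PCA lead-axis collapse with sinusoid fit, and voxelwise sensitivity `‖v‖` / specificity `1 − cos⁻¹(v̂·ŵ)/45°` indices compared between BOLD and VASO |

## Worked example

```r
library(vasodomains)

cfg <- make_fixtures("tiny", seed = 1)   # 16x16x8 patch, 4 blocks, 2 runs
m   <- run_pipeline(cfg)                 # ~1 s; add out_dir= to write NIfTI/TSV
print(m)
```

```
vasodomains pipeline manifest
  stages: timeline -> geometry -> domains -> simulate -> preprocess -> qc -> map -> layers -> quantify
  GM median tSNR: VASO 32.0, BOLD 42.9
  vaso profile: period 4.78 mm, R^2 0.910
  bold profile: period 4.86 mm, R^2 0.977
```

Reading this: the corrected-VASO and BOLD branches clear their tSNR floors
(25 and 40); the ground-truth stripe period of this fixture is 4.8 mm, and
the PCA-collapse sinusoid fit recovers it on both contrast branches with a
strongly periodic profile (R² ≈ 0.9) — the signature of modular domain
organisation. The manifest also carries the voxelwise
sensitivity/specificity comparison (`m$sens_spec_summary`): BOLD shows
roughly twice the median sensitivity of VASO (vein-weighted signal), while
the VASO specificity distribution spans the wider range. `write_report(m,
"report.md")` renders these tables; at full scale use
`run_pipeline(run_config(seed = 1), out_dir = "out")`, and
`inst/cli/vasodomains.R` wraps the same calls for shell use.

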