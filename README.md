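# octaq — quantitative assessment of microvasculature in OCT angiography

`octaq` is an R implementation of a full quantification pipeline for
optical coherence tomography angiography (OCTA) of soft tissue such as the
oral mucosa. OCTA derives motion contrast from N repeated OCT frames at
each position, imaging blood flow without contrast agents. The package
turns a raw 4D acquisition (Z × X × Y × N) into per-layer vascular metrics:

1. **Angiography reconstruction** — a windowed eigen-decomposition (wED)
   clutter filter: within local windows, the N×N inter-frame covariance of
   mean-removed frames is eigen-decomposed and the leading (static-tissue)
   component projected out; the voxel intensity is the RMS amplitude of the
   remaining, flow-driven signal. A per-voxel variance baseline is included
   for comparison.
2. **Automatic depth-of-interest (DOI) selection** — the depth profile
   (mean intensity per depth slice) yields an end depth (deepest slice
   still at the profile mean) and a separation depth (the global intensity
   peak); DOI 1 spans the top to the separation, DOI 2 the separation to
   the end, and each is collapsed by maximum intensity projection.
3. **Vessel masking and skeletonization** — a binary angiography mask
   (BAM) built from a scaled global Otsu gate validated by Hessian
   (Frangi-type) vesselness seeds, thinned to a one-pixel binary vessel
   skeleton (BVS), cut into branch-free segments at junctions.
4. **Metrics** — per en face projection:

   | metric | definition | unit |
   |---|---|---|
   | VAD | vessel area density: `100 · Σ BAM(x,y) / (X·Y)` | % |
   | VSD | vessel skeleton density: `100 · Σ BVS(x,y) / (X·Y)` | % |
   | VDI | vessel diameter index: mean over skeleton pixels of `2·disEu(x,y)` (twice the Euclidean distance to the vessel edge), × lateral pixel size | µm |
   | TI  | per-segment tortuosity: `(SegmentLength / EuclideanDistance − 1) × 100` | — |
   | WTI | weighted tortuosity index: `Σ VDIₙ·(Lₙ/Eₙ − 1) / Σ VDIₙ × 100`, per-segment diameters as weights | — |

   plus moving-kernel heatmaps of local density, diameter and tortuosity,
   scan–rescan repeatability (coefficient of variation, population SD) and
   cohort summaries (mean, SD, Student-t 95% CI).
5. **Synthetic phantoms** — seeded two-layer tubular vessel networks with
   analytic ground truth (area, diameter, tortuosity, layer boundary),
   speckle and temporal decorrelation, so every stage is testable without
   clinical data.

## Worked example

End-to-end recovery on a seeded noise-free phantom (the generator draws
vessel counts, radius and tortuosities; the evaluator runs depth detection,
projection, masking, skeletonization and all four metrics):

```r
library(octaq)
rec <- evaluate_phantom_recovery(phantom_spec(seed = 7, speckle_scale = 0,
                                              gaussian_sd = 0))
rec$report
#> metrics_report [full]: VAD 49.21%, VSD 3.78%, VDI 155.04 um, WTI 6.36 (10 segments)
```

The phantom's analytic truth for that seed is VAD 49.21%, diameter
11.91 px = 156.34 µm, mean segment TI 6.46; the detected layer separation
was exact (0 slices off) and the mask Dice against ground truth 1.000 —
i.e. the measured VAD is exact, VDI is within 1.3 µm (0.1 px), and WTI is
within 0.1 of the analytic tortuosity.

The statistics layer reproduces published reference values from their
printed inputs:

```r
coefficient_of_variation(c(49.58, 50.05))   # scan-rescan VAD pair
#> 0.004717  (printed CV: 0.0047)
cohort_ci(43.32, 8.12, 32)                  # cohort mean/SD/n -> 95% CI
#>    n  mean   sd ci_lower ci_upper
#> 1 32 43.32 8.12 40.39243 46.24757   (printed: 40.39, 46.25)
```

A full 4D acquisition is processed with

```r
cfg <- pipeline_config(input = "scan.raw", out_dir = "out", doi = "both")
reports <- run_pipeline(cfg)
```

which writes, per DOI, the en face projection, BAM, BVS, TI skeleton map,
three heatmaps, metric reports (JSON + CSV), the resolved configuration and
a log. A thin command-line front end with subcommands (`reconstruct`,
`doi`, `quantify`, `heatmap`, `repeatability`, `phantom`, `pipeline`) is
installed at `inst/cli/octaq.R`.

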