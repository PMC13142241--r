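# extravas

Quantifies how efficiently adoptively transferred immune cells (CAR-NK,
CAR-T, NK cells) escape the tumor vasculature, from multi-channel 3D
fluorescence z-stacks of optically cleared tumors. Tissue clearing preserves
the vessel network of an intact tumor slab, so a confocal stack with nucleus,
effector-cell and lectin-labelled vessel channels (optionally a TUNEL
apoptosis channel) records the full 3D geometry of cells relative to vessels
— and extravasation becomes measurable instead of anecdotal.

For each cell population the package computes:

- **Relative extravasation fraction** — 100 · V<sub>out</sub> /
  (V<sub>in</sub> + V<sub>out</sub>), where V<sub>in</sub>, V<sub>out</sub>
  are the segmented population volumes inside and outside the filled vessel
  mask (voxel masking, then re-segmentation of each part);
- **Extravasated / intravascular cell counts** — nucleus spots associated
  with the population surface, classified by whether the nucleus center lies
  inside the vessel mask;
- **Escape distance** — the distance containing a cumulative 95% (default)
  of extravascular cells;
- **CPDmax / CPD50 / CPA50** — maximum cell penetration depth from the
  nearest vessel surface, half of it (structural), and the number of
  extravascular cells within that half-depth. Applied to a TUNEL population
  the same operation yields CDDmax / CDD50 / CDA50, the cytotoxicity-depth
  analogues;
- **Region aggregates** — mean ± sample SD across imaged regions, and fold
  changes between groups.

The geometric core is an exact anisotropic Euclidean distance transform
(per-axis physical voxel spacing — essential at typical 8 µm z-steps with
~1 µm pixels), plus 3D surface segmentation, LoG nucleus spot detection and
voxelwise in/out masking, implemented in compiled code and validated against
brute-force oracles.

Because raw cleared-tumor stacks are rarely shareable, the package includes a
synthetic acquisition generator (`simulate_tumor_volume()`) producing
tube-like vasculature, perivascular effector cells with exponential distance
decay, PSF blur and Poisson–Gaussian noise — with exact ground truth
(compartments, distances, in/out volumes) for end-to-end validation.

## Worked example

```r
library(extravas)

cfg <- simulation_config(seed = 7)      # 256 x 256 x 24 voxels at (8, 1.14, 1.14) um
sim <- simulate_tumor_volume(cfg)
sim$truth
#> <ground_truth>
#>   800 cells (240 intravascular, 560 extravascular)
#>   true volumes: in 116413 um^3, out 290850 um^3 (fraction 71.4%)

report <- run_pipeline(sim$stack, pipeline_config())
glance(report)
#> # A tibble: 1 x 11
#>   population V_in_um3 V_out_um3 fraction_pct n_extravasated n_intravascular
#>   <chr>         <dbl>     <dbl>        <dbl>          <int>           <int>
#> 1 effector    126238.   308930.         71.0            536             216
#> # escape_um 83.6, cpd_max_um 112.1, cpd50_um 56.0, cpa50 449, threshold 74.3
```

Reading: of the segmented effector signal, 71.0% of the volume lies outside
the vessel mask (ground truth: 71.4%), 536 cells are classified extravasated
(truth: 560); 95% of them lie within 83.6 µm of a vessel surface; the deepest
cell sits 112 µm out, and 449 extravascular cells lie within half that depth
(CPA50). `tidy(report)` returns the per-cell table (centers, distance,
compartment), `autoplot(report)` the distance profiles, and
`write_report(report, dir)` persists per-cell CSV, binned profiles and a
versioned metrics JSON.

Group comparisons use the same arithmetic as published tables:

```r
aggregate_regions(c(37, 60, 37), "cpd50", "um")   # mean 44.7, sd 13.3
fold_change(7717, 2311)                           # 3.3
marker_positive_fraction(273, 711)                # 38.4
```

Thin command-line wrappers over these functions live in `inst/scripts/`
(`simulate.R`, `quantify.R`, `aggregate.R`).

## Vignette

`vignettes/extravasation-quantification.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, what the
simulator does and does not emulate, and the numerical conventions
(quantile type, bin conventions, connectivity, tie-breaking).
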