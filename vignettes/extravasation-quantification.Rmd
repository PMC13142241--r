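---
title: "Quantifying immune-cell extravasation in cleared 3D tumor volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immune-cell extravasation in cleared 3D tumor volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extravas)
```

## The measurement problem

Adoptively transferred effector cells (CAR-NK, CAR-T, unmodified NK cells)
reach a solid tumor through its vasculature, but only the cells that cross the
vascular endothelium — *extravasate* — can engage tumor cells in the
parenchyma. Optical tissue clearing preserves the vasculature of an intact
tumor slab, so a multi-channel confocal z-stack (nuclei, effector cells,
lectin-labelled vessels, optionally a TUNEL apoptosis stain) records the full
3D spatial relationship between every effector cell and the vessel network.

`extravas` turns such a stack into a small set of scalar endpoints:

* the **relative extravasation fraction**
  $100 \cdot V_\text{out} / (V_\text{in} + V_\text{out})$, where
  $V_\text{in}$ and $V_\text{out}$ are the segmented volumes of the cell
  population inside and outside the filled vessel mask;
* **extravasated and intravascular cell counts**, classifying each
  nucleus-center by compartment;
* the **escape distance** at a cumulative quantile (default 95%) of the
  extravascular distance distribution;
* the penetration endpoints **CPDmax** (maximum extravascular cell distance),
  **CPD50** (defined structurally as CPDmax/2) and **CPA50** (the number of
  extravascular cells with $0 < d \le \text{CPD50}$), and the same operation
  applied to an apoptotic population (CDDmax/CDD50/CDA50).

## Pipeline and its assumptions

`run_pipeline()` executes, per stack:

1. **Channel conditioning** — anisotropic Gaussian smoothing with physical
   sigma `smoothing_detail_um / 2` per axis, then morphological white top-hat
   background subtraction under an ellipsoidal structuring element of
   `background_sphere_um` physical diameter. The top-hat keeps structures
   narrower than the sphere and removes everything wider, so the sphere must
   exceed the *vessel* diameter; the 40 µm default clears the 24–32 µm tubes
   of the bundled simulator. Axes whose voxel pitch exceeds the smoothing
   detail are left unsmoothed (with a warning): at an 8 µm z-step the default
   2 µm detail only acts in-plane, which mirrors how such data are actually
   processed.
2. **Vessel mask** — intensity thresholding (Otsu by default; a manual
   absolute threshold is honoured for parity with interactively tuned
   analyses), 26-connected component labelling, size filtering, a 3D closing
   at the smoothing detail, then 3D hole filling. Filling makes the lumen
   count as intravascular: the lectin labels the endothelium, so a cell
   travelling inside a vessel must not be scored as "outside".
3. **Distance map** — an exact anisotropic Euclidean distance transform of
   the mask complement (separable lower-envelope algorithm with per-axis
   physical spacing). Voxels inside the mask are 0; the map is 1-Lipschitz in
   physical units and is validated against a brute-force oracle in the test
   suite.
4. **Nucleus spots** — scale-normalized Laplacian-of-Gaussian detection at
   sigma `spot_diameter_um / (2*sqrt(3))` per axis, 26-neighbourhood maxima,
   greedy minimum separation of one spot diameter, and a quality cutoff.
   "Quality" is the normalized LoG amplitude — a reproducible stand-in for
   the undocumented quality score of commercial software, so the numeric
   default (10) is kept but calibrates differently. The cutoff is raised
   automatically to 5 robust standard deviations of the response noise
   (scaled MAD) when that exceeds the floor; this automates the interactive
   practice of raising the threshold until background noise is excluded, and
   is inactive on clean data.
5. **Association** — a nucleus belongs to a population when its center lies
   within `proximity_um` (default 5 µm, closed bound) of that population's
   segmented surface, measured point-to-voxel through a distance transform of
   the surface foreground. Distance is taken from the spot *center*, not the
   spot sphere, matching the point-like semantics of nucleus detection; a
   spot near several objects is counted once and attributed to the nearest.
6. **Compartments and profiles** — each cell samples the vessel distance map
   at the voxel nearest its center: inside the mask ⇒ intravascular with
   distance 0, outside ⇒ extravascular with the sampled distance. Distances
   are histogrammed into half-open bins (default 10 µm width — the bin width
   used in published profiles is never printed, so it is configurable and
   recorded in every report) and cumulated; the escape distance is the
   empirical inverse-CDF (type-1) quantile of the raw distances, with a
   bin-resolution variant for parity with plotted cumulative curves.
7. **Volume masking** — the population channel is split voxelwise by the
   vessel mask (the two parts reconstruct the input exactly; this identity is
   tested bitwise), each part is re-segmented at one shared absolute
   threshold, and the summed object volumes give $V_\text{in}$ and
   $V_\text{out}$. Re-segmenting masked channels follows the "mask, then
   re-surface" procedure of interactive analysis; using one absolute
   threshold for both parts makes the volumes add up to the unmasked
   segmented volume exactly. A cell straddling the vessel wall therefore
   contributes volume to both compartments, while the count-based metric
   assigns it wholly by its nucleus-center; both views are reported.

Every threshold actually used is recorded in the report, and the pipeline is
deterministic for a fixed configuration.

### Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `smoothing_detail_um` | 2.0 | µm | surface smoothing (sigma = detail/2) |
| `background_sphere_um` | 40 | µm | top-hat structuring element diameter; must exceed the vessel diameter |
| `spot_diameter_um` | 5 | µm | expected nucleus size |
| `spot_quality_min` | 10 | – | quality floor; auto-raised to 5× response noise |
| `proximity_um` | 5 | µm | nucleus-to-surface association bound (closed) |
| `bin_width_um` | 10 | µm | profile bin width |
| `cumulative_quantile` | 0.95 | – | escape-distance quantile |
| `min_object_voxels` | 5 | voxels | smallest surface object kept |

The XY pixel pitch of an acquisition is deliberately a required input, never
inferred: stacks carry `voxel_size_um = (z, y, x)` explicitly, with a 0-based
voxel-center coordinate convention stated once and used everywhere —
the physical coordinate of voxel index *i* is *i* × pitch. This removes the
half-voxel ambiguities that otherwise contaminate distance values.

## The synthetic-volume generator

No imaging data are distributed with the study this workflow targets, so
validation rests on `simulate_tumor_volume()`, which produces stacks with
exact ground truth:

* **Vasculature** — piecewise-linear random-walk centerlines swept with a
  per-vessel radius (mean 12 µm, sd 2 µm by default), a deliberately simple
  tube model that still yields the dense-but-partial vascular coverage seen
  in cleared tumors, and whose straight-tube special case has an analytic
  volume for testing. It is not an angiogenesis model.
* **Cells** — `floor(n_cells × (1 − f))` cells uniform inside the vessels;
  the rest outside at distances drawn from an Exponential(`decay_length_um`)
  law by rejection against the true distance map, reproducing the
  distance-decaying perivascular density of effector cells. Default decay
  length 30 µm, consistent with escape distances of a few tens of µm.
  Centers are jittered by under half a voxel so the recorded compartment and
  distance of every cell remain exact. A `cell_placement = "uniform"` mode
  provides spatially homogeneous fields for detector benchmarks.
* **Rendering** — cells and nuclei as uniform spheres (5 µm and 2.5 µm radius),
  vessels as solid tubes, convolved with an anisotropic Gaussian PSF
  (default sigma 3 µm axial, 1 µm lateral), plus constant background, Poisson
  shot noise and additive Gaussian read noise. The axial semi-axis of a
  rendered sphere is clamped to half the z-step: at an 8 µm z-step a 2.5 µm
  nucleus falling between sampling planes would otherwise vanish, whereas the
  thick optical section of a low-NA objective keeps it visible in real data.
  Ground-truth volumes $V_\text{in}/V_\text{out}$ are measured on the same
  rendered noiseless sphere union clipped by the vessel mask, so truth and
  pipeline quantify the same physical quantity.

The default geometry is a 256 × 256 × 24 tile at (8, 1.14, 1.14) µm voxels —
a downscaled version of a 1024 × 1024, ~300 µm-deep acquisition at an 8 µm
z-step; the full size runs through the identical code path. The downscaled
default keeps a simulated pipeline run near ten seconds, which is the problem
size used throughout the tests and the acceptance script.

**What passing simulation tests do and do not show.** The generator emulates
geometry, sampling anisotropy, optics blur and detector noise. It does not
emulate ECM texture, vascular leakiness, depth-dependent attenuation,
refractive-index artifacts, or autofluorescence. Recovery results on
simulation therefore validate the *algorithmic* chain (segmentation →
distances → masking → endpoints) under known truth, not the biological
fidelity of any specific acquisition.

Noise is characterized by SNR = (peak − background) / `gaussian_sd` on the
noiseless render; robustness tests run at SNR 5 with shot noise disabled so
the nominal SNR is exact.

## Numerical choices

* Distances: exact EDT (no chamfer/approximate metrics); empirical type-1
  quantile for the escape distance (no interpolation — the convention is
  configurable and recorded); half-open distance bins `[kw, (k+1)w)`.
* CPA50 uses a *closed* upper bound ($d \le$ CPD50), so boundary ties count;
  CPD50 = CPDmax/2 is structural, not configurable. CPA50 counts
  extravascular cells only, consistent with published values that lie below
  the extravasated totals; intravascular cells are reported separately.
* Otsu is the default threshold because reference analyses tuned thresholds
  manually (values that are never printed); manual absolute thresholds are
  supported for parity, and exact parity with any interactively segmented
  dataset is not claimable.
* 26-connectivity for foreground components (matching the surface continuity
  of tubes); 6-connectivity for the background flood fill in hole filling.
* Degenerate inputs: empty foreground segments to an empty surface set (not
  an error); an empty vessel mask is an error for distance mapping (no
  reference surface); populations without extravascular cells yield defined
  counts and `NA`/null endpoints in reports.
* Aggregation across regions reports the arithmetic mean and the sample
  standard deviation (n − 1); rounding happens only at report time (one
  decimal for µm and percentages, integers for counts).
* Region-level depth maxima are maxima of *cell* (spot) distances, not of
  segmented surface distances; totals count associated nuclei, not surface
  objects — both conventions are stated here because the reference
  description is ambiguous.

## Known limitations

* Distance is sampled at the nucleus-center voxel; at an 8 µm z-step this
  quantizes distances by up to half a step in z.
* The volume-based fraction inherits the noise of re-segmenting masked
  channels; with adaptive (Otsu) thresholds the in/out volumes are only
  approximately conservative, exactly conservative with absolute ones.
* Densely packed intravascular nuclei closer than one spot diameter merge
  into single detections, which biases intravascular counts low by a few
  percent in crowded vessels.
* Geodesic (obstacle-aware) distances, vessel-graph topology and
  time-resolved tracking are out of scope.
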