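---
title: "Quantifying hepatic macrophage niches and lipid droplet volumes: methods"
author: "macquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hepatic macrophage niches and lipid droplet volumes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macquant)
```

# Scope and model

`macquant` implements two quantification workflows for liver imaging data:

1. **Multiplex immunofluorescence quantification.** Macrophages are
   detected on the pan-macrophage marker F4/80, classified into three
   subsets by two further markers — CLEC4F⁺TIM4⁺ resident Kupffer cells
   (ResKC), CLEC4F⁺TIM4⁻ monocyte-derived Kupffer cells (moKC), and
   CLEC4F⁻ recruited macrophages (C4negMac) — and counted per tissue zone,
   where zones are Desmin-high vs Desmin-low regions (stellate-cell
   activation / fibrotic niches vs normal parenchyma) with large vessels
   (Desmin⁺CD31⁺ structures) excluded from all statistics.
2. **FIB-SEM lipid-droplet volumetry.** Per-voxel droplet probability maps
   (as emitted by a segmentation network) are post-processed by a fixed
   recipe — probability threshold, removal of connected components smaller
   than 27 voxels (a 3×3×3 cube), morphological opening with a spherical
   structuring element of radius 2 voxels — and the total droplet volume
   is extracted.

Every stage is deterministic. The only stochastic component in the package
is the synthetic-data generator, which is governed by a single integer
seed.

# Detection

The detection stage reproduces a tile-based script: the F4/80 channel is
split into tiles, each tile is median-filtered and thresholded, the binary
tiles are assembled into one full-size mask, connected components are
labelled globally, holes are filled, and components below a minimum area
are discarded. Each surviving component becomes one cell detection.

Two design points deserve emphasis:

* **Merge-exact tiling.** Filtering a tile in isolation would make results
  near tile borders depend on the tile grid. Each tile is therefore
  filtered together with a halo of *real image pixels* of width equal to
  the median radius and cropped back afterwards; reflection padding is
  only ever applied at true image borders. Per-tile filtering is then
  pixel-identical to whole-image filtering, and with a fixed or global-Otsu
  threshold the detection set is provably invariant to the tile size. The
  per-tile-Otsu mode intentionally reproduces tile-dependent behaviour
  (each tile gets its own threshold) and is exempt from that invariance.
* **Global assembly before filtering.** Area filtering is applied after
  the full-size mask is assembled and labelled, never per tile, so cells
  split by a tile border can never lose fragments to a per-tile filter.

Numerical conventions, fixed so that exact tests are possible:

* a pixel/voxel at exactly the threshold is **foreground** (`>=`);
* objects use 8-connectivity by default, and hole filling traverses the
  background with the complementary 4-connectivity (the standard
  digital-topology pairing); both are configurable;
* the median window is the digital disk $\{(i,j) : i^2+j^2 \le r^2\}$,
  which has odd cardinality, so the median is always an order statistic
  of the window and never an average;
* border-touching cells are retained and flagged (`touches_border`), not
  dropped — downstream users decide.

Defaults (`detectionParams()`): tile size 256 px, median radius 2 px,
global-Otsu threshold, minimum area 100 px (25 µm² at 0.5 µm/px), hole
filling on. The Otsu threshold is computed by `EBImage::otsu` over 256
bins of the observed intensity range.

Note that a median filter is not area-preserving on strongly curved
boundaries: it slightly reshapes small disks. Tests that assert exact
digital-disk areas therefore run with the filter disabled; with the filter
on, counts are still exact for disks of radius ≥ 3 px.

# Classification

Per-cell features are the arithmetic mean of each channel over the cell
mask (median optional). The gate is hierarchical, mirroring the order of
a flow-cytometry gating tree: cells are split on CLEC4F first, and TIM4
is only consulted for CLEC4F-positive cells:

| CLEC4F | TIM4 | label |
|---|---|---|
| ≥ θ_C4 | ≥ θ_T4 | ResKC |
| ≥ θ_C4 | < θ_T4 | moKC |
| < θ_C4 | any | C4negMac |

Marker thresholds are derived per marker by 1D Otsu over the per-cell
means (default), or supplied as fixed values, or taken as a quantile of
the cell means. The 1D Otsu is an exhaustive scan over midpoints of
consecutive sorted unique values maximising between-class variance; it
refuses to run on fewer than 3 cells. No cross-image intensity
normalisation is applied by default — the least surprising behaviour when
thresholds are image-derived anyway.

# Zoning and vessel exclusion

The Desmin channel is Gaussian-smoothed (σ = 4 px default), thresholded,
cleaned by a disk closing (radius 3 px), and high components smaller than
`min_hi_area` (500 µm²) are relabelled low. The result is a per-pixel
partition: 0 = excluded (vessel), 1 = Desmin-low, 2 = Desmin-high; the
three zone areas always sum exactly to the image area.

One numerical choice matters here: when the threshold is Otsu-derived it
is computed on intensities **winsorized at the 0.99 quantile**. Vessel
walls are rare but extremely bright in Desmin; left in place they capture
the Otsu split (the histogram is trimodal) and the patch/parenchyma
boundary is lost. Vessels are not this stage's job — they are removed by
the dedicated exclusion step, which sets vessel pixels to label 0
regardless of zone. The reference route for the vessel mask is an external
(manually drawn) mask; `autoVesselMask()` — pixels above the 0.99 quantile
in *both* Desmin and CD31, dilated, small components dropped — is provided
as an explicitly experimental convenience and says so at run time.

Cells are assigned to the zone under their centroid pixel (cheap and
deterministic; the alternative, majority overlap, would differ only for
cells straddling a boundary). Cells whose centroid falls on an excluded
pixel drop out of **all** percentages.

# Composition statistics

For each image the package reports, per class $c$:

$$\mathrm{pct\_of\_total\_macs}(c) = 100\,\frac{N_c}{\sum_{c'} N_{c'}},
\qquad
\mathrm{pct\_in\_zone}(c, z) = 100\,\frac{N_{c,z}}{N_c},\; z \in \{\mathrm{Hi}, \mathrm{Lo}\}$$

over non-excluded cells. Sums are exact by construction (integer counts,
one division). Empty denominators yield *missing* percentages, never 0 —
a zero would silently misread downstream. An image with zero non-excluded
cells produces a zero-count table, missing percentages and a warning.

Cross-animal statistics (group t tests etc.) are out of scope: the
single-image composition table is this package's product.

# Droplet post-processing

Stages in order, matching the recipe's stated sequence:

1. `thresholdProbability` — foreground iff probability ≥ cut (default
   0.5, the canonical probability cut).
2. `removeSmallComponents` — components under 26-connectivity (default;
   6/18 selectable) with fewer than 27 voxels are removed. The floor is
   inclusive: a 27-voxel component survives, a 26-voxel one does not.
3. `sphericalOpening` — erosion then dilation with the digital Euclidean
   ball $\{v : \lVert v\rVert_2 \le 2\}$ (33 voxels). Voxels outside the
   volume count as background, so the opening also trims objects touching
   the stack border. An anisotropic element (ball in physical units from
   the per-axis voxel size) is available behind a flag; the default is
   isotropic in voxel units, matching the recipe's voxel-unit phrasing.
4. Labelling and volume extraction, in voxels and in µm³ via the
   (anisotropic) voxel size in nm — default 5 nm per axis, anchored to a
   5 nm FIB milling step.

Properties the test suite enforces: every stage is anti-extensive
(foreground never grows), the size floor holds exactly at the removal
stage (the subsequent opening may legally shrink components below it),
total volume is non-increasing in the threshold, the opening is
idempotent, and on small volumes the whole pipeline equals an independent
brute-force implementation (flood-fill labelling, erosion/dilation by the
set definition).

Two behaviours of digital morphology are worth knowing when interpreting
volumes:

* Among balls of radius 1–5, radius 2 is the smallest digital ball the
  opening leaves voxel-identical (the element cannot fit inside a radius-1
  ball). Larger digital balls are *not* in general fixed points: their
  surface voxels need not be coverable by translates of the element
  (a radius-4 ball loses ~28% of its voxels).
* Consequently the pipeline systematically under-reports the volume of
  small, sphere-like objects by a few percent even on perfect input. This
  is a property of the recipe, not of this implementation.

# The synthetic-data generator

`tissueSpec()`/`generateTissueImage()` emulate a liver field of view:

* cells are hard disks (radius ~ N(6, 1) px, clipped at 3) placed by
  rejection sampling with a 2 px inter-disk clearance, so rendered masks
  are disconnected under 8-connectivity and detection counts are exact;
  an impossible density fails loudly with the achievable count;
* class-dependent marker intensities (foreground +180 over background 10,
  arbitrary units) follow the marker logic above; the non-macrophage
  "distractor" class keeps F4/80 at background and is invisible to
  detection by construction;
* Desmin-high patches (disks, radius 120 px) elevate the Desmin
  background ×3; CLEC4F⁻ macrophage placement density in high vs low
  tissue follows the enrichment ratio ρ (default 4, i.e. recruited
  macrophages concentrate in the activated niches; ρ = 1 plants them
  uniformly);
* vessels are annuli co-bright (+200) in Desmin and CD31 with a
  signal-free lumen, mimicking the large-vessel morphology used for
  manual exclusion; the full vessel disk is ground-truth excluded;
* noise is additive Gaussian, clipped at 0 (default sd 5; the noisy
  recovery tests use sd 18 = 10% of the foreground intensity).

The default field is 1024×1024 px at 0.5 µm/px with 500 macrophages
(200/150/150 ResKC/moKC/C4negMac) and 50 distractors. Identical spec +
seed gives bit-identical images and truth tables.

`dropletSpec()`/`generateDropletStack()` emulate probability maps:
non-overlapping spheres, Gaussian-blurred and rescaled to peak 1, plus
additive noise, clipped to [0, 1]. The blur default is σ = 0.5 voxel:
this gives a ~1-voxel boundary transition, as a well-trained network
emits, while keeping the 0.5 level set within the curvature term
$\sigma^2\kappa < 0.1$ voxel of the true surface — a larger blur would
systematically shrink every droplet at the 0.5 threshold, defeating the
generator's purpose of well-behaved thresholding. Ground truth is the
exact lattice-point count of each digital ball. Optional *adversarial
components* are compact blocks of exactly requested voxel counts, planted
pairwise-separated by more than twice the opening diameter, to probe the
size-filter boundary (26 vs 27 voxels).

What the generator does **not** emulate: realistic point-spread functions,
spectral bleed-through, intensity gradients and vignetting, touching or
overlapping cells, non-disk cell shapes, and 3D confocal geometry. Green
tests on synthetic data therefore certify the *algorithmic contracts*
(exactness, invariances, recovery under known noise), not performance on
acquired slides — on real data, marker thresholds and the Desmin
segmentation will need per-study inspection.

# Problem sizes used by the test suite

The suite validates on sizes chosen to make exhaustive oracles practical:
brute-force median filtering on 18×14 images, set-definition morphology on
≤ 32³ volumes (20 random volumes for pipeline-vs-oracle equality), tiling
invariance on a 512² field across tile sizes {64, 128, 256, untiled},
ground-truth recovery on the default 1024² field with 500 macrophages, and
invariant sweeps over 50 seeds on 160² fields / 12³ volumes.

# Known limitations

* Touching cells are merged (the detection deliberately performs no
  watershed splitting, matching the reproduced script).
* The per-tile-Otsu mode is tile-size dependent by design.
* Otsu thresholds are 256-bin approximations of the exhaustive scan;
  for well-separated populations the resulting masks are identical.
* GeoJSON polygons are crack boundaries of pixel masks (area exactly the
  pixel count, vertices on pixel corners); they are faithful but not
  smooth.
* The droplet pipeline's volume bias for small spheres (see above) is
  inherent to the recipe; per-component volumes are reported as an
  extension so users can inspect the size distribution.
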