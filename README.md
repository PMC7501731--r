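# macquant

Quantification of hepatic macrophage subsets in multiplex
immunofluorescence images, and lipid-droplet volumetry in FIB-SEM
probability maps.

## The problem

In fatty liver disease the resident Kupffer cell niche is progressively
colonized by recruited macrophages. Imaging-based quantification of that
process needs three things done reproducibly: (1) detecting macrophages on
the pan-macrophage marker F4/80 across large tiled acquisitions, (2)
classifying each cell by its CLEC4F and TIM4 expression —
CLEC4F⁺TIM4⁺ resident Kupffer cells (**ResKC**), CLEC4F⁺TIM4⁻
monocyte-derived Kupffer cells (**moKC**), CLEC4F⁻ recruited macrophages
(**C4negMac**) — and (3) counting each subset inside Desmin-high
(stellate-cell-activated) versus Desmin-low tissue zones, with large
Desmin⁺CD31⁺ vessels excluded. A companion workflow post-processes 3D
lipid-droplet probability maps from FIB-SEM volumes into droplet volumes.

`macquant` implements both workflows as deterministic, parameterised
stages with S4 containers (`MultiplexImage`, `CellDetections`, `ZoneMap`,
`DropletResult`), plus a synthetic-data generator that produces both image
types with exact ground truth so that every stage is testable end to end.

## The core procedures

**Detection** (tile → median filter → threshold → assemble → label → fill
holes → area filter): tiles are filtered with a halo of real image pixels,
so the detection set is provably identical for any tile size under fixed
or global-Otsu thresholding. A pixel at the threshold is foreground
(`>=`); objects are 8-connected, hole filling uses the complementary
4-connected background.

**Classification** (hierarchical marker gate, thresholds θ from per-cell
mean intensities):

    CLEC4F >= θ_C4 and TIM4 >= θ_T4  ->  ResKC
    CLEC4F >= θ_C4 and TIM4 <  θ_T4  ->  moKC
    CLEC4F <  θ_C4                   ->  C4negMac

**Zoning**: Gaussian-smoothed Desmin channel → threshold (Otsu on
winsorized intensities) → disk closing → small high regions absorbed;
vessel pixels forced to the excluded label. Composition per class c and
zone z: `pct_of_total_macs(c) = 100·N_c/ΣN`, `pct_in_zone(c,z) =
100·N_{c,z}/N_c`, over non-excluded cells; empty denominators give
missing values, never 0.

**Droplets** (threshold ≥ 0.5 → remove components < 27 voxels (3×3×3) →
morphological opening with a spherical structuring element of radius 2
voxels → volumes): volumes are reported in voxels and µm³ using the
per-axis voxel size (default 5 nm).

## Worked example

```r
library(macquant)

# a synthetic liver field with exact ground truth: 500 macrophages,
# Desmin-high patches enriched for CLEC4F- macrophages (rho = 4), vessels
sim <- generateTissueImage(tissueSpec(seed = 42))

det <- detectMacrophages(sim$image, detectionParams(min_area = 20))
det <- classifyCells(extractFeatures(det, sim$image))
zm  <- applyVesselExclusion(segmentDesminZones(sim$image), sim$vesselMask)
det <- assignZones(det, zm)
det
#> CellDetections 'synthetic-42': 500 cells (C4negMac=150, moKC=150, ResKC=200)

quantifyComposition(det)[, c("zone","class","count",
                             "pct_of_total_macs","pct_of_class_in_zone")]
#>   zone    class count pct_of_total_macs pct_of_class_in_zone
#> 1  all    ResKC   200                40                   NA
#> 2   Hi    ResKC    38                NA                   19
#> 3   Lo    ResKC   162                NA                   81
#> 4  all     moKC   150                30                   NA
#> 5   Hi     moKC    24                NA                   16
#> 6   Lo     moKC   126                NA                   84
#> 7  all C4negMac   150                30                   NA
#> 8   Hi C4negMac    51                NA                   34
#> 9   Lo C4negMac    99                NA                   66
```

All 500 planted macrophages are recovered and the planted 40/30/30 subset
split is reproduced exactly; the configured enrichment of CLEC4F⁻
macrophages in Desmin-high zones is visible (34% of them sit in the high
zone versus 16–19% of the Kupffer-cell subsets).

```r
dsim <- generateDropletStack(dropletSpec(nDroplets = 10,
                                         stackShape = c(96, 128, 128),
                                         seed = 42))
res <- runDropletPipeline(dsim$stack, dropletParams())
res
#> DropletResult: 10 components, 14087 voxels, 0.001761 um3 total
sum(dsim$truth$voxels)     # exact lattice volume of the planted spheres
#> [1] 14448
```

All 10 droplets are found; the measured total volume sits 2.5% below the
lattice truth — the expected small bias of the opening stage on
sphere-like objects (see the methods vignette).

A thin command-line front end over the same functions is installed at
`inst/scripts/macquant.R` (subcommands `simulate`, `detect`, `classify`,
`zones`, `quantify`, `droplets`, `run`).

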