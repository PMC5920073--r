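# ld3d — lipid droplet quantification in 3D confocal stacks

`ld3d` quantifies lipid droplets (oil bodies) and cells in confocal
z-stacks of oilseed cotyledon storage tissue, the imaging setting used to
compare high-oil and low-oil *Brassica napus* breeding lines. It is aimed
at plant lipid researchers who have Nile-Red fluorescence stacks (plus a
bright-field boundary channel or curated cell outlines) and want the
standard 3D morphometrics without interactive segmentation.

From a calibrated stack (default 0.159 × 0.159 × 0.38 µm/voxel) the
pipeline computes:

* **VTLD/VTSF** — total droplet volume over scanning-field volume, where
  every volume is a voxel count × Δx·Δy·Δz;
* **VLD/VSC** — per-cell lipid volume fraction over *integrated* cells
  (cells touching no face of the field);
* **TNLD** — droplet count per cell, via droplet-to-cell assignment by
  majority voxel overlap;
* **CS** — inter-cell interval: minimum surface-to-surface distance
  between adjacent cells across the intercellular matrix;
* per-droplet volumes and equivalent diameters d = (6V/π)^(1/3), with the
  "unusually large" (d > 5 µm) and small (V < 100 µm³) size classes.

Segmentation is deterministic: global Otsu (or fixed) threshold → 3D
connected components (26-adjacency) → physical size filter → optional
marker-controlled watershed splitting of touching droplets; cells come
from a label TIFF or a seeded 3D watershed on the bright-field channel.
Distance computations are anisotropy-aware throughout. A ground-truthed
synthetic field generator (Voronoi cell tessellation, lognormal sphere
droplets, PSF blur, shot + read noise) backs every stage with recovery
tests; see `vignettes/ld3d-methods.Rmd` for the models and choices.

## Worked example

```r
library(ld3d)
field <- generate_field(preset_spec("ho_like", seed = 1))       # synthetic HO-like field
q <- quantify_field(field$fluorescence, field$truth$cell_labels)
q$field
#>   vtsf_um3 vtld_um3 vtld_vtsf_ratio n_cells n_integrated mean_cell_spacing_um n_spacing_pairs
#> 1   425984 16337.59      0.03835258       9            9              5.22468              20
head(q$cells[, c("cell_id", "vsc_um3", "vld_vsc_ratio", "tnld", "n_large")], 3)
#>   cell_id  vsc_um3 vld_vsc_ratio tnld n_large
#> 1       1 31820.59    0.05119524   67       5
#> 2       2 33241.16    0.05527447   61       4
#> 3       3 27599.65    0.06510092   73       5
```

A field of ~430 000 µm³ holds nine complete cells; this high-oil-like
preset carries ~3.8 % droplet volume at field level, 5–7 % per cell over
~60–75 droplets per cell, with ~5 µm between neighboring cell surfaces.

The same machinery as a study workflow (simulate a panel of 3 HO + 3 LO
lines × 3 fields, quantify every field from its files, compare groups):

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_quantify.R
Rscript analysis/03_compare.R
#> group comparison (Welch on line means):
#>   vld_vsc_pct    HO 5.668 vs LO 2.784, t = 6.06, p = 0.0048
#>   tnld           HO 70.519 vs LO 29.148, t = 7.92, p = 0.0044
#>   vtld_vtsf_pct  HO 3.833 vs LO 1.486, t = 9.39, p = 0.0026
#>   cs_um          HO 4.667 vs LO 6.961, t = -12.47, p = 0.0003
```

The high-oil group shows a higher per-cell lipid fraction, more droplets
per cell, a higher field fraction and narrower cell intervals — the four
orderings that separate high- from low-oil material. Tables land under
`results/report/` (line summaries as mean ± SD over replicate fields,
Welch comparisons, violin-ready droplet sizes).

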