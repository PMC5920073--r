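---
title: "Quantifying lipid droplets in 3D confocal stacks: models, parameters and validation"
author: "ld3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid droplets in 3D confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ld3d)
```

## The measurement problem

Oilseed cotyledon cells store neutral lipids in droplets (oil bodies) a
few micrometers across. Confocal sectioning of Nile-Red-stained tissue
yields a z-stack — typically 800 × 800 px at 0.159 µm/px in-plane and
0.38 µm between slices, spanning one cell layer (~26 µm) — from which one
wants, per field and per cell, the quantities that discriminate high-oil
from low-oil material:

* **VTLD/VTSF** — total droplet volume over total scanning-field volume;
* **VLD/VSC** — summed droplet volume over cell volume, per cell (the
  per-cell lipid volume fraction);
* **TNLD** — the droplet count per cell;
* **CS** — the inter-cell interval: the gap across the intercellular
  matrix between adjacent cell surfaces;
* droplet size classes: the "unusually large" class (equivalent diameter
  strictly over 5 µm) and the small class (volume strictly under 100 µm³).

All volumes are voxel counts multiplied by the voxel volume
Δx·Δy·Δz (9.607 × 10⁻³ µm³ at the default calibration). Diameters are
equivalent-sphere diameters, (6V/π)^(1/3): droplets are modeled as
spheres, and no caliper measure is defined for a voxel set. Both size
thresholds are strict inequalities, so boundary objects (exactly 5 µm,
exactly 100 µm³) fall in neither flagged class.

## Pipeline

`quantify_field()` composes the stages; each is exported separately.

1. **Preprocessing** (off by default, available for noisy acquisitions):
   median or Gaussian denoising with a per-axis voxel window, and
   per-slice (2D) Gaussian background subtraction for depth-varying
   shading. The background scale should sit well above the droplet
   diameter scale; the function warns below 10 µm.
2. **Droplet segmentation**: a single global threshold — Otsu on a
   256-bin histogram over the full volume range by default, or a fixed
   level recorded in the run config — followed by 3D connected components,
   a physical minimum-volume filter, and optional marker-controlled
   watershed splitting of touching droplets. Droplets use 26-adjacency so
   bright blobs do not fragment on diagonal contact. The minimum-volume
   default (0.05 µm³ ≈ 5 voxels at the confocal calibration) suppresses
   single-voxel noise specks; it is a pipeline choice, not a biological
   threshold.
3. **Cell segmentation**: cells come either from a supplied label TIFF
   (the primary route — cell outlines in real material are often drawn or
   curated by hand) or from the bright-field channel by seeded watershed:
   the smoothed stack is cut at a wall intensity level (Otsu by default),
   seeds are regional maxima of the anisotropy-aware distance transform of
   that mask, and the flood runs on smoothed intensity under 6-adjacency.
   Voxels below the cutoff stay background: the intercellular matrix is
   label 0, never absorbed into cells, because VLD/VSC must exclude it and
   CS is measured across it.
4. **Assignment and metrics**: each droplet goes to the cell holding the
   plurality of its voxels (ties to the smallest id; majority-background
   droplets stay unassigned). Per-cell metrics use **integrated cells**
   only — cells touching no face of the field bounding box — because
   partial cells understate VSC; the field-level VTLD counts every droplet
   voxel regardless.

### Numerical choices

* Distance transforms (droplet splitting, watershed seeding, cell
  spacing) run on squared Euclidean distance computed exactly per axis
  with the physical pitch folded in; with Δz ≈ 2.4 Δx, voxel-unit
  distances would visibly bias marker placement.
* Otsu ties are broken toward the lowest cut; component labels are
  numbered in first-encounter raster order; the watershed breaks priority
  ties first-come-first-served. Every stage is therefore deterministic,
  and a rerun of a pipeline is byte-identical.
* An Otsu threshold on a constant volume is an error (no separable
  classes), as is a calibration mismatch between combined volumes —
  never a silent resample.
* Fewer than two cells leaves CS missing (`NA`), not zero.

### Cell spacing

The interval between two cells is operationalized as the minimum
voxel-center-to-center distance between the two label sets, minus one
mean in-plane pitch (a first-order correction from center-to-center to
edge-to-edge), floored at zero; pairs farther apart than `max_gap_um`
(default 15 µm) are not adjacent and contribute nothing. The field CS is
the unweighted mean over adjacent pairs. This is an automatable surrogate
for a manual 3D measurement tool; it is documented, deterministic and
oracle-tested on slab constructions, but not claimed identical to manual
practice. In near-square tessellations, corner-adjacent pairs meet near
√2 × the wall width and pull the mean a few percent above the facing-wall
gap; the validation suite therefore checks wall-width recovery on facing
pairs specifically.

## The synthetic field generator

No imaging data accompany the measurements this package reimplements, so
the generator is the package's ground truth and its defaults *are* the
study conditions:

* a field of 256 × 256 × 40 voxels at 0.5 × 0.5 × 0.65 µm — a
  128 × 128 × 26 µm block holding one layer of ~9 complete cells, the
  in-plane extent and depth of the real acquisitions at a coarser pitch
  chosen so a full field stays around 2.6 M voxels;
* a jittered-grid Voronoi tessellation in physical coordinates; a voxel
  is intercellular matrix when its two nearest-seed distances differ by
  less than the wall width (each region recedes half a wall from the
  bisector) or when it lies within half a wall of a field face, so every
  cell is integrated. Wall widths of ~4 µm (high-oil) and ~6 µm
  (low-oil) bracket the intervals reported for real material;
* spherical droplets with lognormal diameters (median ≈ 3.4–3.6 µm,
  log-SD 0.32, truncated to 1.5–8 µm), voxelized by the center-in-sphere
  rule — no partial-volume weighting, matching what a threshold-style
  segmentation can recover, with the discretization error quantified by
  a brute-force oracle (≈ 4 % volume error at r = 5 µm, shrinking with
  radius);
* per-cell droplet counts Poisson-distributed around the preset mean
  (70 per cell for high-oil-like lines, 30 for low-oil-like — inside the
  29–124 range observed per cell in real material);
* rendering: two-level images (droplet 180 / background 20; bright-field
  cell 160 / wall 30) blurred by an anisotropic Gaussian PSF specified in
  µm and converted per-axis to voxels (0.35 µm axial, 0.15 µm lateral),
  then Poisson shot noise, additive Gaussian read noise (SD 3), clipping
  at zero and rounding to integer counts;
* one top-level seed drives tessellation, placement and rendering;
  identical spec and seed reproduce a field byte-for-byte.

Droplet surfaces are kept at least 1 µm apart by default — beyond the
voxel diagonal, so distinct droplets are never 26-adjacent and the truth
labels are unambiguous. That separation is the honest price of exact
ground truth: rejection-sampling placement then cannot reach the 19–22 %
per-cell volume fractions of real high-oil material, and the presets land
at roughly 5–7 % (high-oil-like) versus 2–3 % (low-oil-like). Every
*ordering* the real data show — higher VLD/VSC, higher TNLD, higher
VTLD/VTSF, narrower CS in the high-oil group — is preserved, and those
orderings, not the absolute fractions, are what the validation asserts.
An `allow_contact` mode places touching droplets to exercise watershed
splitting separately from segmentation correctness.

What the generator does **not** emulate: depth-dependent attenuation and
refractive-index effects, non-spherical or clustered droplets, textured
cell interiors, and uneven illumination (available separately through the
preprocessing tests). Passing recovery tests on synthetic fields
demonstrates the pipeline's arithmetic and its robustness to the modeled
noise, not performance on real acquisitions.

## Line panels and statistics

The comparison design mirrors a breeding-line study: three high-oil-like
and three low-oil-like lines whose droplet counts (60/70/80 vs 26/30/34
per cell) and wall widths (3.6/4.0/4.4 vs 5.6/6.0/6.4 µm) spread within
the group the way real lines spread, with three replicate fields per line
differing only in seed. Line summaries are mean ± SD (sample SD, n − 1 —
the printed ± values in the source material cannot be back-computed
unambiguously, so the convention is declared here) over replicate fields;
groups are compared with a Welch unequal-variance t test on line means —
no homoscedasticity assumption is warranted — with an exact permutation
test available as a cross-check. No multiple-testing correction is
applied across the four metrics, matching the reporting style this
package emulates.

With single fields per line, the spacing contrast is underpowered (the
between-pair variability of CS is large relative to a 2 µm group
difference); three replicates per line bring all four metrics below
p = 0.05 while keeping a six-line panel under two minutes of compute.
Test and validation problem sizes (full 256 × 256 × 40 fields for
recovery and contrast, 10³ volumes for oracle equivalence) were chosen so
the whole suite runs in a few minutes on one CPU.

## Storage conventions

Stacks and label volumes travel as multi-page grayscale TIFF, pages in
z order, with a JSON sidecar carrying calibration and channel/kind tags
(sidecar metadata, when complete, overrides caller-supplied calibration).
Intensity stacks are stored as 16-bit integers; label volumes choose
8/16-bit integer or 32-bit float (fixed 2²⁴ scale) storage by maximum
label, so round trips are lossless up to 2²⁴ − 1 labels and labels above
that are a refused overflow. One printed per-voxel constant in the source
material (1.11 × 10² µm³) is irreconcilable with its own printed pitches
(0.159 × 0.159 × 0.38 ≈ 9.6 × 10⁻³ µm³) and is treated as a typographic
error: volumes here always use Δx·Δy·Δz.

## Known limitations

* The global threshold assumes roughly uniform droplet brightness;
  strongly depth-attenuated real stacks would need the illumination
  correction plus a per-slice or adaptive threshold this package does not
  provide.
* Watershed cell segmentation expects dark, closed walls; broken walls
  merge cells. Supplying curated cell labels is the supported fallback.
* CS is a pairwise-minimum surrogate; it is not a mean over manually
  drawn intervals and can differ from manual practice on concave or
  corner-dominated geometries.
* The stack is assumed to span one cell layer; cells clipped in z are
  simply excluded from per-cell metrics by the integrated-cell rule,
  which is stricter than any partial-coverage correction.

## A worked example

```{r example, eval = FALSE}
spec <- preset_spec("ho_like", seed = 1)
field <- generate_field(spec)
q <- quantify_field(field$fluorescence, field$truth$cell_labels)
q$field            # VTSF, VTLD, VTLD/VTSF, cell counts, mean CS
head(q$cells)      # per-cell VSC, VLD, VLD/VSC, TNLD, large-droplet count
head(q$droplets)   # per-droplet volume, diameter, flags
```

The scripts under `analysis/` run the same machinery as a three-step
study — simulate the six-line panel, quantify every field from its files,
compare the groups — and `scripts/acceptance.R` recomputes the headline
quantities from scratch with a single seed.
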