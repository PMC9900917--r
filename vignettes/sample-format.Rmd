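---
title: "The srtkit sample format: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The srtkit sample format: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srtkit)
```

# The problem

A spatially-resolved transcriptomics (SRT) dataset couples a
full-resolution tissue image — often tens of thousands of pixels on a
side — with thousands of spatial points (Visium spots, segmented cells)
and thousands of features per point (gene expression, cluster labels).
Interactive use needs two properties that raw platform outputs lack:

1. **Spatial laziness** — showing a field of view must cost only the
   image tiles inside it, at a resolution matched to the zoom level.
2. **Feature laziness** — displaying one gene must cost only that gene's
   values, not the whole expression matrix.

Both reduce to the same primitive: *a byte-range read against a file
whose layout puts an addressable index up front.* `srtkit` converts
platform outputs into a folder of files designed around that primitive,
and exposes the range reader as an explicit, byte-counting contract so
laziness can be asserted in tests rather than assumed.

# The sample folder

A sample is a folder with a deterministic `sample.json` manifest
describing three kinds of resources:

* **images** — tiled multi-resolution pyramids;
* **overlays** — ordered point sets (`id,x,y` CSVs) in level-0 pixel
  coordinates;
* **feature groups** — chunked per-feature stores bound to an overlay by
  name; feature row *i* always refers to overlay row *i*.

Coordinates and features are deliberately separated: many feature groups
can share one overlay, so spot positions are stored once however many
genes are attached to them. One physical scale, `microns_per_pixel`
(µm per level-0 pixel), connects pixel geometry to physical units.

The manifest is written with sorted keys and fixed number formatting
(6 significant digits), so equal metadata always produces byte-identical
files — convenient for content hashing and required by our
determinism tests. All invariants (positive scale, unique overlay names,
every feature group naming exactly one overlay, circle overlays carrying
a physical diameter) are enforced by the constructors on both write and
read.

# Image pyramids

## Level plan and downsampling

Level 0 is the full-resolution image; level *k* has dimensions
`ceil(w / 2^k) x ceil(h / 2^k)`. Planning stops at the first level whose
larger dimension fits in one tile, so the coarsest view is a single
fetch. The factor-2 ceiling scheme and the 2×2 **block mean** resampler
(odd edges average the 2, or 1, pixels that exist; results rounded
half-up to the integer range) follow standard cloud-optimized GeoTIFF
overview practice: the mean is the simplest resampler that neither
aliases badly nor invents values outside the data range.

We number levels with 0 as the *finest* resolution, the convention of the
overview-pyramid file format itself. Viewer UIs often label the coarsest
displayed level 0; since the manifest records `n_levels`, either
enumeration is recoverable.

## File layout

The pyramid is a classic little-endian tiled TIFF: one directory (IFD)
per level, overviews flagged as reduced-resolution subfiles, channels as
separate planar samples, tiles of a fixed edge (default 512 px, must be a
multiple of 16 — a JPEG/TIFF alignment requirement). The defining
"cloud-optimized" property is that **all IFDs and their offset/length
tables occupy one contiguous region at the start of the file**, so a
reader learns every tile's byte span from a handful of small reads at
known positions, then fetches tiles individually.

Two codecs are supported per the two use cases:

* `lossless` — zlib deflate per tile; level 0 reconstructs bit-exactly.
  The default, and the right choice for quantitative imagery.
* `jpeg` — one baseline JPEG stream per tile, quality 1–100 with
  **default 90**, the conventional quality for brightfield histology
  where 8-bit photographic content dominates and a ~10× size reduction
  matters. JPEG is refused for 16-bit data (the baseline codec is 8-bit
  only).

No installed R package writes tiled TIFFs with overview directories, so
the container serialization is implemented here; the codecs themselves
are the system zlib (`memCompress`) and libjpeg (via the `jpeg`
package). Tests verify the files against an independent reader (Python
`tifffile`) rather than trusting the writer's own parser.

## Reads and byte accounting

`open_pyramid()` parses the header region through a `range_reader`;
`read_tile()` fetches exactly one tile's span per channel;
`plan_viewport()` selects, by rectangle intersection in level-0
coordinates, the tiles a viewport needs; `read_region()` stitches them.
Every byte passes through the reader's counter, giving the invariants the
tests assert: a single-tile read costs the header plus one tile; disjoint
region reads are additive; a cached reader re-fetches nothing.

## Gaussian prefilter

Scanned Visium images often carry high-frequency scanner artifacts that
survive block-mean downsampling as shimmering. The converter therefore
Gaussian-filters the image before building the pyramid; the conventional
setting is **radius 4**, which we interpret as the Gaussian standard
deviation in pixels (the term "radius" is ambiguous between σ and kernel
half-width in common imaging tools; σ is the stricter reading since a
σ-4 kernel truncated at 4σ spans the half-width-4 kernel entirely). The
kernel is separable, truncated at 4σ, unit-sum, with reflected borders;
radius 0 is the exact identity.

# Chunked feature stores

The lazy unit is **one feature** — the store exists so that selecting one
gene in a viewer fetches one record. Each feature's nonzero entries are
serialized as plain `row,value` CSV lines (1-based rows into the
overlay; values at 6 significant digits), deflate-compressed
independently, and concatenated into `<group>.bin`. A JSON sidecar
`<group>.index.json` lists `{name, offset, length, n}` per feature in
written order, plus the code→label table for categorical groups. Opening
a group costs the index; reading a feature costs its record. Coarser
chunks (several features per record) would amortize better for bulk
scans but break the one-interaction-one-fetch correspondence, which is
the property this format optimizes.

Quantitative features drop exact zeros and densify back with zero fill,
so `densify(read(write(sparsify(M))))` is the identity column by column —
up to the 6-significant-digit wire precision, which bounds the relative
round-trip error at 5×10⁻⁷. Categorical features store integer codes
with `NA` fill, and return factors over the stored label table.

Spot-level counts are transformed with the natural `log(1 + n)` before
storage — the standard variance-stabilizing display transform. The base
and the unit pseudocount are our choice (conventions differ); raw counts
remain recoverable as `expm1`. No library-size normalization is applied:
it is not obviously wanted for display, and silently normalized values
would be harder to audit than raw `log1p` counts. MERFISH per-cell counts
are stored raw, as transcript counts from imaging platforms are
conventionally consumed unlogged.

# Converters

**Visium.** Tissue positions parse from both Space Ranger dialects
(headerless or headered 6-column CSV); the file stores pixel *row*
before pixel *column*, so x and y swap on input. Only `in_tissue = 1`
spots are kept. The physical anchor is the known 55 µm spot diameter:
`microns_per_pixel = 55 / spot_diameter_fullres`, the standard Visium
scale convention. The overlay is circle-geometry with
`diameter_um = 55`, restricted to barcodes present both in the count
matrix and among in-tissue positions, *in count-matrix order* — the
filtered matrix drives the features, and keeping its order makes
feature row *i* equal overlay row *i* by construction. A counts barcode
absent from the positions file (any tissue state) is an error, not a
silent drop. Counts come from the MatrixMarket triplet directory
(`Matrix::readMM`); the HDF5 variant is out of scope to keep the format
surface plain-text.

**MERFISH.** Cell centroids arrive in microns; the platform provides a
3×3 micron→mosaic-pixel affine with bottom row (0, 0, 1), which we apply
as `pixel = M %*% c(x, y, 1)`. A 2×3 file is accepted and promoted. The
manifest scale is derived from the affine's linear part
(`1 / sqrt(|det M₂ₓ₂|)` µm/px), which is exact for the
scale-plus-translation transforms these platforms emit. Cell id
mismatches between the two tables are reported as set-difference counts.

# Annotations

Annotations are ordered `(label, geometry)` records — freestanding
points, circles with physical µm diameters, polygons — in the frame of an
overlay or the image. The native CSV (`label,geometry,data`, polygon data
as `x1 y1;x2 y2;…` at 6 significant digits) round-trips exactly;
external point/shape tables import with the row-major axis convention
(`axis-0` → y, `axis-1` → x). Binary ROI containers are out of scope.

`assign_labels()` gives each overlay point the label of the **first**
containing record: record order is user-meaningful, and first-wins means
later additions never corrupt earlier work. Circles match by Euclidean
distance ≤ diameter/2 after µm→px conversion (so a 55 µm spot at
1 µm/px captures to 27.5 px exactly); polygons by an even-odd
ray-crossing test with **boundary points counted inside** — a
deterministic tie-break that guarantees a point on a domain border is
always labeled rather than platform-dependently dropped. Points are
marks, not regions, and never capture. The even-odd implementation is
cross-checked against an independent winding-number oracle in the tests;
for the simple (non-self-intersecting) polygons the format allows, the
two rules agree everywhere off the boundary.

# Synthetic fixtures

The generators emulate the *formats*, not the biology: smooth-blob
images with noise, hexagonal spot lattices at
`spot_diameter × 100/55` center spacing (mimicking 55 µm spots at 100 µm
pitch), per-gene log-uniform rates in [0.5, 50] with counts
`Bernoulli(density) × (1 + Poisson(rate))` so the nonzero fraction lands
at the target density, and out-of-tissue rows interleaved to exercise
filtering. Defaults (50 spots × 20 genes at 5% density for Visium,
100 cells × 30 genes for MERFISH with a scale-2.1-plus-translation
affine, 1000×1000 px images) are sized so the full conversion pipeline
runs in seconds while still spanning multiple tiles and sparse records.
Every generator is a pure function of its seed, producing byte-identical
files on regeneration.

Because fixtures contain no spatial expression structure, passing tests
demonstrate format fidelity, geometric correctness and lazy-read bounds —
not that downstream biology (clustering, domain detection) would look
right. They also keep all test data generated at run time; nothing
binary ships with the package.

# Numerical choices and degenerate inputs

* Wire precision is 6 significant digits for manifest numbers, feature
  values and annotation coordinates; overlay coordinate CSVs use full
  `%.17g` precision because converter tests assert geometric recovery to
  1e-9 px.
* Block-mean and Gaussian results round half-up (`floor(x + 0.5)`) back
  to the integer pixel range.
* Empty feature lists, all-zero features, zero-point overlays and empty
  annotation sets are all valid and round-trip.
* Degenerate polygons (< 3 vertices or zero area) are rejected at
  construction; boundary tolerance in the point-in-polygon test is
  1e-12, scaled by edge extent.
* `validate_sample()` returns findings as data (a character vector) and
  never throws: a validation tool that aborts on the first defect cannot
  report the second.

# Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` exercise: 3×1024×1024 and
1×4096×4096 pyramids (the latter has 256 level-0 tiles, the scale at
which the single-tile fetch fraction drops near 1%), feature stores of
2000 points × 500 genes at 5% density, 50-spot × 20-gene Visium and
100-cell × 30-gene MERFISH conversions, 20,000 point-in-polygon
comparisons and 100 randomized annotation round trips. These sizes make
the lazy-read fractions meaningful (the indexed part of each file is
small relative to the payload) while keeping the whole suite inside a
half-minute run.

# Known limitations

* Classic TIFF offsets are 32-bit; pyramids beyond ~4 GiB would need
  BigTIFF, which the writer does not emit.
* JPEG tiles are 8-bit grayscale per planar channel; no chroma-subsampled
  RGB path.
* The HTTP range reader is a thin optional client; no retry or
  parallel-fetch logic.
* No normalization options on the Visium transform; no z-stack handling
  beyond single-plane inputs; no polygon simplification on import.
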