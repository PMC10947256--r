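---
title: "Measuring vein density from starch-stained leaf images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vein density from starch-stained leaf images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kranzvein)
```

## The measurement problem

Vein density — total vein length per unit leaf area, reported here in
µm mm⁻² — is a central trait of C4 leaf anatomy: a denser vein network means
a larger bundle-sheath fraction. In C4 species the bundle sheath accumulates
starch preferentially, so iodine staining of cleared tissue renders the vein
network as dark strands on a light background. `kranzvein` segments such
images and converts the segmented network into a density measurement.

The package assumes:

* strands are *darker* than the background (an `invert_foreground = FALSE`
  switch handles inverted polarity);
* the image scale is known and supplied as `pixel_length_um` — nothing is
  read from microscope metadata;
* density is the only quantity of interest; vein order, width and areole
  geometry are out of scope.

## The pipeline, stage by stage

**Greyscale.** RGB input is reduced with the standard luminance weights
0.2989 R + 0.5870 G + 0.1140 B. Greyscale input is min–max rescaled to
[0, 1]; subsequent stages are contrast-normalizing anyway, so this only
fixes the working range.

**Contrast enhancement (CLAHE).** Contrast-limited adaptive histogram
equalization with a clip limit of 2 and an 8 × 8 tile grid, the conventional
defaults of image-processing toolkits; both are exposed in the
configuration. Its role is to flatten illumination gradients and staining
unevenness so that a single global threshold works later. The backing
implementation requires tile-divisible dimensions, so images are
replicate-padded to the next multiple and cropped back. Images smaller than
about two pixels per tile fall back to global histogram equalization with a
warning.

**Mean blur.** Every pixel becomes the arithmetic mean of its
(2*w* + 1) × (2*w* + 1) window; the default *w* = 20 gives a 41 × 41 kernel.
We read the half-width formula as authoritative and treat the kernel as
41 × 41 (an even 20 × 20 window has no centre pixel). This step is what
makes starch staining usable: starch grains are punctate, and the blur
merges them into strands of near-uniform intensity while flattening
background texture. Borders are replicate-padded — zero padding would darken
the margins and bias the threshold below. The filter is computed exactly
with a summed-area table, so it matches a direct windowed mean to floating
point accuracy, borders included.

**Binarization (Otsu).** The threshold maximizes the between-class intensity
variance over 256 histogram bins; ties break toward the lower cut, and the
threshold value is the upper edge of the last background bin so that
`pixels > t` is exactly the upper class. A constant image has no variance to
split; it yields an all-zero mask flagged as degenerate, and the image is
reported with density 0 and `flagged = TRUE` rather than aborting a batch.
A `threshold_override` in [0, 1] bypasses Otsu entirely for pathological
staining.

**Complement.** After thresholding, the bright background is the foreground
class; the complement makes the dark-stained veins foreground. The step is
controlled by `invert_foreground` (default `TRUE`).

**Skeletonization.** Veins-as-foreground masks are thinned to one-pixel-wide
curves. The thinner is two-subpass directional thinning in compiled code,
with two deliberate choices:

* deletion candidates are selected from a subpass snapshot (which keeps the
  skeleton well-centred in the strand) but each deletion is re-validated on
  the current image, because a purely parallel update erases a 2 × 2
  component entirely and would not preserve topology;
* a final *redundancy-pruning* sweep removes every non-end-point pixel whose
  foreground neighbours form a single mutually 8-connected group. Such
  pixels (staircase corners, thick diagonal knots, junction cores) carry no
  path information but masquerade as branch points; left in place they
  fragment edges and bias the pixel-count length estimate. Each removal is
  individually connectivity-safe, so components and holes survive.

Thinning erodes the ends of a strand toward its medial axis — a 5-px-wide
bar of length 100 skeletonizes to about 96–98 pixels, and independent
thinning implementations agree. This is the dominant (small, negative) bias
of the length estimator; it scales with strand width over strand length.

**The skeleton graph.** Skeleton pixels with one 8-neighbour are end points;
pixels with three or more are junction pixels, and mutually touching
junction pixels merge into one *branch point* (thinning leaves small
junction clusters, so treating raw junction pixels as separate branch points
would invent topology). Edges are pixel paths walked between branch points
and end points; a junction-free cycle is stored as one closed edge with
coincident terminals. Geodesic edge length is counted from the branch point
itself, as a geodesic-distance transform between the terminals would give:
the pixels beyond the junction cluster plus one step per branch-point
terminal. Under this convention a straight 50-px line is one edge of length
50, a 3-px stem hanging from a crossbar is a spur of length 3, and abutting
edges never double-count pixels. Coordinates are 1-based `(row, col)` — the
R matrix convention.

**Spur trimming.** Thinning artefacts appear as short spurs (branch point →
end point). Every spur strictly shorter than `trim_factor` pixels is
deleted, together with junction-cluster pixels left redundant by the
deletion; removal can demote a branch point and expose a new spur, so
deletion and re-detection iterate to a fixed point. The strict inequality
makes `trim_factor = 0` the identity. Trimming is idempotent and monotone in
the trim factor, and the test suite holds it to exact set equality with a
brute-force pixel-walking oracle.

**Automatic trim factor.** When an image produces an unusually noisy
skeleton the user's trim factor is replaced by one derived from the data:
if spur pixels exceed `auto_trim_trigger_fraction` (default 0.15) of all
skeleton pixels, the trim factor becomes the mode of the spur-length
multiset plus one — "plus one" so the modal spurs themselves fall under the
strict-< rule — with ties in the mode broken toward the smaller length. The
spur-pixel *fraction* was chosen as the trigger because it is scale-free;
0.15 is above anything a clean image produces (a few percent) and below what
speckled segmentations produce. The table records whether the automatic
value was used and what it was.

**Commissural-vein removal (monocot mode).** Grass leaves carry short
transverse commissural veins between the longitudinal veins; they are not
wrapped in bundle sheath, stain inconsistently, and are conventionally
excluded from Kranz vein density. Two operational definitions circulate:
the shortest branch at a degree-3 junction, and a short Euclidean span
between two branch points. The package implements the Euclidean rule as
canonical — an edge is removed when both terminals are (distinct) branch
points and the straight-line distance between them is below
`monocot_branch_length_to_keep` — because it is explicitly parameterized
and reproducible. Spur edges are never touched by this operation, and a
keep-length of 0 disables it. The threshold must sit between the
longitudinal-vein spacing (the span of a commissural vein) and the distance
between successive junctions *along* a longitudinal vein; because spurious
junctions shorten the latter, monocot runs benefit from a generous trim
factor (the validation runs use 40 px).

**Density.** With `n` skeleton pixels, pixel size `p` µm and an `h × w`
raster: length `L = n·p` µm, area `A = h·w·p²·10⁻⁶` mm², density `VD = L/A`
µm mm⁻². Pixel count, not √2-weighted path length, is the canonical length
estimate; a diagonal-corrected variant is available via
`skeleton_length(method = "diagonal")` as a diagnostic only. The area always
uses the dimensions of the raster actually measured; a mismatch with the
configured `x_pixels`/`y_pixels` flags the row but does not abort.

## The configuration surface

Fourteen keys, five mandatory:

| key | default | meaning |
|---|---|---|
| `input_path` | — | image file or directory |
| `trim_factor` | — | spur-deletion threshold, px |
| `pixel_length_um` | — | scale, µm per pixel side |
| `x_pixels`, `y_pixels` | — | expected raster size |
| `mode` | `auto` | `monocot` adds commissural removal |
| `monocot_branch_length_to_keep` | 0 | Euclidean span threshold, px; 0 disables |
| `blur_w` | 20 | mean-filter half-width |
| `clahe_clip_limit` | 2 | CLAHE clip |
| `clahe_tile_grid` | `8,8` | CLAHE tiles (rows, cols; one key) |
| `threshold_override` | unset | fixed threshold instead of Otsu |
| `invert_foreground` | true | complement after binarization |
| `auto_trim_trigger_fraction` | 0.15 | spur fraction that triggers auto trim |
| `output_dir` | `kranzvein_output` | results, overlays, metadata |

The batch driver (`run_batch()`) processes every image in a directory,
writes `results.csv`, per-image overlays and a machine-readable
`run_metadata.json`, logs and skips unreadable files, and is fully
deterministic — no stage is stochastic, so identical inputs give
bit-identical tables. The manual check is deferred and file-based:
`apply_review()` marks rejected images in an `excluded` column instead of
deleting rows, preserving the audit trail.

## What the synthetic generator emulates — and what it does not

`vein_spec()`/`generate_veins()` produce stained-leaf look-alikes with
*exact* ground truth: dark curvilinear strands of finite stroke width on a
bright noisy background with a linear illumination ramp. Two topologies are
modelled:

* **parallel** — wavy longitudinal rails joined by horizontal commissural
  rungs, the grass-leaf geometry;
* **reticulate** — wavy primaries joined by oblique staggered secondaries
  that close areoles, a dicot-like geometry.

Design choices worth knowing:

* *Geometry is deterministic in the geometric parameters; the seed drives
  only the noise field.* This separates "what network is there" from "what
  the camera adds", so recovery errors across seeds measure segmentation
  noise, not geometry variance.
* *Ground truth is the analytic centreline arc length* (pixel-covering
  convention: a straight strand of N collinear pixels measures N), not a
  pixel count of the rendered mask — so recovery tests bound the bias of
  the pixel-count estimator itself.
* *Parallel rungs are aligned across rail pairs.* With staggered rungs the
  junction spacing along interior rails halves and drops below any
  keep-length that still exceeds the rung span, making commissural removal
  geometrically impossible to parameterize; aligned rungs keep the two
  length scales separated, which is also the biologically sensible regime
  (commissural veins are short relative to the spacing of junctions along
  a longitudinal vein).
* Defaults emulate a 100× brightfield frame: 1392 × 1040 px at 0.65 µm/px,
  vein spacing ≈ 100 µm, stroke 5 px, background 0.85 vs vein 0.25, noise
  sd 0.03, 8% illumination ramp.

The generator deliberately does **not** model: bundle-sheath cell texture,
out-of-focus blur, staining gradients along a strand, broken strands, or
developmental venation patterns. Passing the recovery tests therefore
demonstrates that the segmentation chain and length estimator are unbiased
on clean, well-stained geometry at realistic noise — it does not certify
performance on poorly stained tissue, which is exactly what the deferred
manual check is for on real data.

## Numerical choices and degenerate inputs

* Otsu threshold: 256 bins, ties toward the smaller cut; validated by
  exhaustive search over all 255 cuts on random images (exact agreement).
* Mean blur: exact summed-area implementation, replicate borders; validated
  against the direct O(k²) mean everywhere including borders.
* Strict `<` everywhere a trim/keep threshold is compared, so 0 disables.
* Degenerate inputs: empty masks skeletonize to empty and are flagged at
  density 0; constant images flag at binarization; corrupt files are logged
  and skipped; a dimension mismatch warns, flags, and continues with the
  actual dimensions so one bad frame cannot abort a batch.
* Thinning end-erosion is the main systematic bias (negative, ≈ half the
  strand width per free end). At full frame size it is ≈ 1–3% of total
  length; on small test frames (256 px) it reaches ≈ 10–15%, which is why
  the small-frame smoke tests use a wider tolerance than the full-size
  validation.

## Validation problem sizes

The test suite validates the Otsu and trimming implementations against
brute-force oracles (100 random 16 × 16 images; 50 random skeletons up to
64 × 64), checks the commissural contract on ladder fixtures (5–20 rungs,
rung span 10 px, keep-length 15 px), and measures end-to-end recovery on
20 parallel + 20 reticulate full-size frames (1392 × 1040, stroke 5 px,
noise sd 0.03): the acceptance bar is ≥ 90% of frames within 10% of the
analytic density and a median signed bias within ±5%. `scripts/acceptance.R`
recomputes all of these from scratch for any seed. Observed behaviour at
these sizes: parallel frames recover within ≈ ±2%, reticulate within
≈ −4 ± 2% (oblique secondaries suffer slightly more end erosion and
diagonal undercount), and the monocot contract holds within ≈ 5%.

## Known limitations

* Pixel-count length underestimates diagonal runs by up to √2; mostly
  mitigated by the near-axial geometry of real leaf strands and partially
  offset by staircase overcounting. The diagonal-corrected diagnostic
  quantifies this per image.
* Strand gaps are not bridged; a broken strand contributes its full length
  but two extra end points.
* The commissural rule is geometric, not anatomical: any short
  branch-point-to-branch-point connection below the keep-length is removed,
  including genuine short laterals.
* Single-process execution; batches scale linearly (≈ 1.5 s per 1392 × 1040
  frame).
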