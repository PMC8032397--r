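---
title: "Curating EM patch corpora and probing encoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating EM patch corpora and probing encoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cellular electron microscopy (EM) produces image data that is wildly
heterogeneous: 2D micrographs and 3D volumes, 8/16/32-bit signed and
unsigned pixel types, isotropic and anisotropic voxels, regular and
inverted intensity polarity. Before such a collection can feed
representation learning, it must be reduced to a uniform corpus of small
2D patches, and — because adjacent sections of a high-resolution volume
are nearly identical and large swaths of many images are empty resin —
the corpus must be pruned of near-duplicates and of frames that carry no
cellular information. `cemcurate` implements that curation pipeline as a
tested library plus a thin command-line wrapper, together with probing
tools that quantify what an image encoder learned. Everything is
exercisable on seeded synthetic fixtures; no microscopy data is required
to run or test the package.

## Standardization

Each source (one micrograph or one volume) passes through:

1. **Intensity normalization** — a global per-source affine min–max map
   onto [0, 255] with floor rounding. Inputs already in 8-bit range pass
   through unchanged; constant sources map to zero. This is the simplest
   faithful reduction of mixed pixel types; optional percentile clipping
   (`clip_percentiles` in the configuration, default off) is available
   for sources with hot pixels.
2. **Byte budget** — volumes larger than 5 GB (1 byte/voxel after
   normalization) are strided by the smallest uniform integer factor on
   all three axes that meets the budget. A stride, rather than an
   interpolating resample, keeps noise statistics and avoids inventing
   intensities.
3. **Plane planning** — volumes with voxel spacing metadata are sliced
   along xy, xz and yz when the axial spacing is close to the lateral
   spacing; "close" is formalized as `|z − mean(x, y)| / mean(x, y) <
   0.2`, strict. Anisotropic volumes (and volumes without metadata) are
   sliced along xy only, since their orthogonal sections are
   geometrically distorted.
4. **Tiling** — every section is cropped into non-overlapping 224×224
   windows. A remainder strip of at least 112 pixels yields one extra
   *edge-anchored* full window (its overlap with the grid is later
   eaten by deduplication); narrower strips are discarded. Whole images
   between 112 and 224 pixels on an axis are reflect-padded (mirror, no
   edge duplication — no flat zero borders that would later look like
   padding frames); anything under 112 emits nothing. Offsets are
   0-based `(y0, x0)` with half-open windows.

Every patch carries full provenance (source, plane, slice index,
offsets, edge/pad flags) in a JSON-lines manifest, one record per line.

## Deduplication

Each patch is hashed with a difference hash: exact area-averaging down
to 8 rows × 9 columns, one bit per horizontal neighbour pair
(`left < right`, row-major), 64 bits total. Two design points are fixed
deliberately: the resize kernel is exact area averaging (so hashes are
portable across machines), and the strict comparison carries a `1e-9`
tolerance so exactly tied cells — a constant patch — give bit 0 rather
than floating-point noise.

Hashes are compared only *within* one source dataset; comparing across
sources would merge legitimately similar content from unrelated
experiments. Pairs at Hamming distance strictly below 12 are edges of a
graph whose connected components are the near-duplicate groups
(single-linkage transitivity: a chain A–B–C groups even when A and C are
far apart — the well-defined closure of "sets of hashes within the
cutoff"). One exemplar per group survives, drawn uniformly at random by
a single seeded generator over groups ordered by smallest member id, so
the selection does not depend on traversal order.

## Informativeness filtering

A Random Forest (500 trees) classifies patches as informative or not
from four image-level statistics:

- `lbp_std` — standard deviation of the uniform local-binary-pattern
  code map (3×3 neighbourhood, codes 0–9, border excluded);
- `entropy_std` — standard deviation of the local Shannon entropy (bits)
  over a radius-7 disk;
- `geomean_median` — median of a 5×5 geometric-mean filter computed on
  intensities + 1 (avoids log 0);
- `canny_mean` — fraction of edge pixels from a Canny detector
  (smoothing σ = 1, hysteresis thresholds at 0.1/0.2 of the maximum
  gradient magnitude).

These window sizes are frozen into the trained model's
`feature_config` and enforced at prediction time. The retention rule is
`probability ≥ 0.5`, with the tie counting as informative so the
boundary is deterministic. Ground truth for synthetic data follows the
area rule: a patch is uninformative when 80% or more of its pixels lie
in uniform-intensity regions, when its intensity standard deviation
falls below the contrast floor (8 intensity units), or when the
generator flagged it as an artifact frame. A deep classifier can be
substituted through the same `patch → probability` interface; the
package itself ships only the Random-Forest path.

## What the synthetic generator emulates — and what it does not

Informative patches are textured mid-gray cytoplasm (smooth Gaussian
random fields) with 2–6 dark-membraned elliptical organelles and
speckle noise; uninformative kinds are bright resin, low-contrast
fields, ≥80% zero-padding frames, and saturated stripe artifacts.
Volumes evolve a latent structure field slice-to-slice as an AR(1)
process (`drift` = 0 duplicates slices exactly; drift ≲ 0.15 keeps
adjacent slices within hash distance 12). Corpora plant a configurable
fraction of near-duplicates (speckle re-noise of an earlier patch) and
uninformative frames; the defaults are 5 000 patches, 40% duplicates,
30% uninformative.

One generator choice deserves a note: perfectly flat noisy frames have
*noise-driven* difference hashes — essentially 64 coin flips — so two
flat frames, or a flat frame and its re-noised copy, would not land
within any sensible Hamming cutoff. Real uniform regions are not
perfectly flat; resin frames therefore carry a faint (≈4 intensity
units) shared illumination gradient, which keeps them uniform for the
80% rule while making uniform frames hash-stable and heavily
deduplicated, as uniform crops are in practice. Padding frames keep an
exactly-zero border, so their planted duplicates may fail to merge;
this is accepted and visible in the dedup report.

None of this claims biological realism. Passing tests on these fixtures
demonstrates that the pipeline's mechanics (geometry, hashing, grouping,
seeding, thresholds) are correct and that the four statistics separate
*constructed* informative/uninformative classes; it does not certify
classifier accuracy on real micrographs, where the labeled-set AUROC
must be re-measured.

## Probing an encoder

Any encoder enters through a small contract: `pooled(image)` returns a
D-vector (a global-average-pooled representation), and optionally
`feature_maps(image)` returns C square maps at a declared output stride.
Removing downsampling stages to obtain finer strides is the caller's
responsibility.

**Invariance.** Per-neuron firing thresholds are the 99th percentile of
responses to 1 000 images of iid uniform noise on [0, 255] (the maximum-
entropy choice over the 8-bit range). For each neuron, Z is its top
`⌈0.1·n⌉` probe images (the strict 90th-percentile reading; ties break
by response then index), and a neuron is *selective* iff every image in
Z fires above its threshold — non-selective neurons are excluded. The
mean firing rate at a distortion level is the fraction of Z still firing
after the distortion, averaged over selective neurons; it is exactly 1
at the identity level. Distortions are parameterized so that the
identity is 0 for rotation/blur/noise and 1 for
brightness/contrast/scale: rotation uses reflect padding with exact
permutations at 90° multiples, brightness is multiplicative, contrast
scales about the image mean, scale is a centre zoom.

**Selectivity.** Feature maps are bilinearly upsampled to the image
size and correlated with a binary ground-truth mask by Point-Biserial
correlation (identically, Pearson against the 0/1 mask; a zero-variance
map is an error, not NaN). The mean of the k = 32 most correlated maps,
min–max rescaled to [0, 1] and thresholded at 0.3, gives a binary
segmentation scored by IoU (defined as 1 when both masks are empty).

**Occlusion.** Windows of 61 px every 30 px are zeroed one at a time;
a window's importance is the *drop* in pooled-vector dot-product
similarity to a reference view, `s_full − s_occ`. The grid — 6×6 for a
224-pixel image — is min–max normalized per image (a constant grid maps
to zeros) and bilinearly upsampled for overlay.

## Numerical choices and degenerate inputs

- Constant inputs: normalize to zeros; hash to all-zero bits; LBP/
  entropy/Canny statistics are exactly zero; `point_biserial` raises an
  error on a zero-variance map rather than returning NaN.
- All mirror boundaries reflect without duplicating the edge pixel.
- Seeds: every stochastic operation takes an explicit seed; a corpus
  seed fans out to per-stage seeds through a base-31 rolling hash of a
  stage label (`derive_seed`), so stages are reproducible in isolation.
  The corpus default is 42.
- The per-source pairwise Hamming comparison is exact (vectorized via
  cross-products of the bit matrix); sources up to ~10⁵ patches are
  practical, and an approximate index could be slotted in without
  changing the grouping semantics.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script study conditions are: a 5 000-patch
synthetic corpus (40% planted duplicates, 30% uninformative, seed 42);
labeled filter sets of 1 000–2 000 patches with a 75/25 split, with
holdout AUROC required ≥ 0.95 across five seeds; 1 000 random image
sizes for the tiling oracle; 100 fuzzed hash sets (n ≤ 500) for the
grouping oracle; and 20 seeded fixtures for planted-filter recovery.
These sizes were chosen so the whole suite runs comfortably on a single
CPU while leaving each property statistically meaningful.

## Known limitations

- The filter's reported quality is a property of the synthetic classes;
  real-data quality requires a real labeled set.
- Deduplication guarantees that *cross-group* pairs are at or beyond
  the cutoff; inside a former group, surviving exemplars of different
  chains may still be closer (a property of single linkage).
- The MRC reader covers modes 0/1/2/6 of the MRC2014 layout — the
  common EM cases — not the full standard.
- Video containers and remote chunked-volume access are out of scope;
  local random-patch sampling from volumes stands in for the latter.
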