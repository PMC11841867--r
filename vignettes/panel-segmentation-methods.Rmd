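---
title: "Methods: compound-figure classification and panel segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compound-figure classification and panel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelseg)
```

## The problem

A large share of figures in the biomedical literature are *compound*: a
single raster canvas holding several sub-images (panels). Retrieval and
modality-classification systems index panels, not whole figures, so the
figure must first be (i) recognized as single- or multi-panel and (ii)
split into its panels. `panelseg` implements a hybrid rule-based pipeline
for this, together with the overlap-based evaluation protocol used in the
compound-figure-separation literature and a synthetic montage generator
so everything is testable without access-controlled figure collections.

## The model

### Image type identification

The input is converted to grayscale with the luminance weighting
$I = 0.2989R + 0.5870G + 0.1140B$ (rounded half-up; the formula states no
rounding rule, so we fix one), and a symmetric border of `border_trim`
(default 2 px) is removed so the figure's own frame cannot register as a
separator. Row and column projection profiles are computed,

$$H(i) = \tfrac{1}{N}\sum_j I(i,j), \qquad V(j) = \tfrac{1}{M}\sum_i I(i,j),$$

in *mean-normalized* form: each sum is divided by the orthogonal
dimension so profile values live on the 0–255 intensity scale regardless
of image size. The separator candidates are the near-white positions

$$\mathrm{HLV} = \{\, i : H(i) > T \,\}, \qquad
  \mathrm{VLV} = \{\, j : V(j) > T \,\},$$

with $T = f \cdot 255$ and $f$ = `intensity_fraction` (default 0.95).
The comparison is strictly greater: a row exactly at $T$ is not a
separator. Normalization plus a fractional threshold was a design choice:
the threshold is never stated numerically in the source formulation, and
white gutters have mean intensity 255 exactly, so any $f$ close to 1
works and is insensitive to image size.

The decision rule is a pair of thresholds on the index counts:

* **single-panel** — both axes have at most `threshold_single` (default
  0) separator indices: no inter-panel border anywhere;
* **regular multi-panel** — the larger per-axis *effective* line count is
  at most `threshold_comp` (default 5), reflecting the observation that
  panel grids have at most about five straight inter-panel borders per
  axis;
* **irregular multi-panel** — otherwise.

### Effective line counts

Counting raw indices reproduces the published worked examples (a grid
with HLV = \{119\}, VLV = \{153, 309\} is regular; a mosaic whose white
bands span 22 row indices and 167 column indices is irregular), but it
makes the regular label depend on gutter *width*: a clean 2 × 2 grid with
10-px gutters would contribute 10 indices per gutter and tip over the
threshold. The framework therefore collapses each contiguous run of
separator indices no wider than `max_separator_width` (default 20 px)
into one logical line before applying the regular test, while runs wider
than that — page-scale white regions rather than ruled separators —
contribute their raw index count. The default of 20 px encodes what a
ruled separator or gutter plausibly is at publication resolution; both
raw and effective counts are recorded on the returned object, and the
worked examples above are reproduced unchanged (effective counts 1 and 2
for the grid; the mosaic's 40/86/41-wide bands stay raw, keeping 167).

A genuine limitation, documented rather than patched: an irregular mosaic
with *no* white gaps at all yields empty index sets and is
indistinguishable from a single-panel figure under this rule.

### Regular segmentation

The axis with more separator indices is cut first (ties go to vertical).
Cutting discards each separator *run* and keeps the spans between runs —
cutting at individual indices would manufacture sliver "panels" inside
wide gutters. Every segment is then shrunk by 1 px on all four sides (the
per-segment boundary trim of the underlying formulation), segments
thinner than `min_panel_extent` (default 16 px) are dropped, and each
surviving segment is re-analyzed recursively: its own profiles are
recomputed and it is cut along whichever axis they indicate, until no
separator remains or `max_recursion_depth` (default 4) is reached. All
regions are reported in original-image coordinates, and crops are taken
from the original (color) image.

### Irregular segmentation

Irregular mosaics have no straight full-width separators, so the
irregular branch works from connected regions of content instead:

1. **Otsu threshold** — the split $t$ maximizing between-class variance
   of the 256-bin histogram (ties to the lowest $t$); pixels $\le t$ map
   to 0, pixels $> t$ to 255.
2. **Polarity normalization** — compound figures sit on page-white
   backgrounds, which binarize as foreground. If the majority of border
   pixels are foreground the binary image is inverted so panels, not the
   page, are foreground. (The source formulation is silent here; without
   this step connected-component analysis would label the background.)
3. **Morphological closing** — dilation then erosion with a rectangular
   `kernel_rows x kernel_cols` element (default 29 × 29), each defined as
   the max/min over the window clipped at the image border. This fills
   intensity holes inside panels so each panel becomes one solid
   component.
4. **8-connected component labeling** with per-component bounding box and
   area. 8-connectivity (rather than 4) merges diagonally touching panel
   content more robustly.
5. **Area filter** — components whose foreground area exceeds
   `area_fraction` (default 0.02) of the image area are emitted as
   panels; the threshold is *relative* because the original is an
   unquantified empirical constant, and a fraction transfers across image
   sizes. Bounding boxes are cropped from the original image, not from
   the closed mask. Overlapping bounding boxes are not merged, and
   components touching the border are not trimmed.

If nothing survives the filter the whole image is returned as a single
flagged region with a warning rather than an empty result.

### Evaluation protocol

A predicted panel is *correct* when its intersection with a ground-truth
panel strictly exceeds two-thirds of the **ground-truth** area (the
denominator is always the truth box). Matching is greedy one-to-one:
truths in order take the unmatched prediction with the largest overlap,
ties to the earlier prediction; sub-threshold best overlaps leave both
sides unmatched. With $N_c$ correct panels among $N_e$ extracted and
$N_t$ true panels,

$$P = N_c / N_e, \quad R = N_c / N_t, \quad F_1 = \frac{2PR}{P+R},$$

with the degenerate conventions $P = 0$ when $N_e = 0$, $R = 0$ when
$N_t = 0$, $F_1 = 0$ when $P + R = 0$. The published protocol is manual,
so the automatic one-to-one rule is this package's design choice — the
simplest rule consistent with counting each sub-image at most once.

## The synthetic generator

Real evaluation corpora for this task are access-controlled, so
`generate_montage()` emulates the three layout classes with known ground
truth:

* **single** — one full-canvas panel;
* **grid** — `rows x cols` panels separated by uniform gutters at
  intensity 255 (a 1 × 1 "grid" has no gutters and is labeled
  single-panel, which is what it is);
* **irregular** — 2–6 panels in 1–3 horizontal bands, each panel
  independently shrunk and offset by up to `jitter_px` (default 12 px),
  on a white canvas.

Panel content defaults to Gaussian noise with mean 120 and sd 30 on the
8-bit scale — dark textured content on a white page, the statistics under
which a global Otsu threshold cleanly separates panels from background.
Two generator defaults are worth stating explicitly:

* the irregular minimum gap is 32 px. A 29 × 29 closing bridges any gap
  of 28 px or less, so mosaics violating this would be merged by
  *construction* of the method; the generator encodes the method's own
  working assumption that stitched mosaics have generous whitespace.
* grid montages are flush with the canvas edge (no outer white margin),
  matching the border-free figures the classifier's single-panel rule
  presumes; the 2-px border trim absorbs residual frame effects.

What the generator does **not** emulate: text labels and captions inside
panels, JPEG compression artifacts, gradient backgrounds, dark or
background-free figures (explicitly out of scope for this family of
methods), and non-rectangular panel boundaries. Passing tests on
synthetic montages therefore demonstrate correctness of the mechanics —
profile analysis, cutting, thresholding, labeling, scoring — not
field performance on real publisher figures.

## Numerical choices and degenerate inputs

* Grayscale rounding is half-up, then clamped to [0, 255].
* Otsu on a constant image is a degenerate histogram: threshold 0 with a
  warning.
* `choose_direction` with both index sets empty raises a classed
  condition (`panelseg_no_separator`) rather than guessing an axis.
* Coordinates are 0-based throughout the public interface, crops
  half-open, separator runs inclusive; manifests serialize exactly this
  convention and round-trip losslessly.
* All randomness in the generator is seeded per `montage_spec`; the
  caller's RNG stream is saved and restored.

## Problem sizes used in the test suite

The oracle-equivalence tests run 200 random 32 × 32 images against an
exhaustive Otsu search, 100 random binaries against a naive double-loop
closing oracle, and 30 against a flood-fill component oracle. The
recovery studies use 100 seeded grid montages (rows, cols ∈ 1..4,
gutters 5–20 px) and 100 seeded irregular mosaics (2–6 panels) at the
generator's default 480 × 480 canvas. These sizes keep the full suite in
the low minutes on one CPU while exercising every branch; they are also
the sizes `scripts/acceptance.R` reports.

## Known limitations

* Gap-free irregular mosaics classify as single-panel (see above).
* Panels lighter than the page background defeat the polarity rule.
* Wide *ruled* separators (> `max_separator_width`) inflate the raw
  index counts and can push a regular grid into the irregular branch;
  the parameter is exposed for atypical layouts.
* The regular branch assumes separators span the full width/height of
  the (sub-)image; staircase layouts are handled only insofar as
  recursion on sub-images exposes straight separators.
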