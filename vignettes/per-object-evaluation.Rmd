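---
title: "Per-object evaluation of instance segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-object evaluation of instance segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segmetrics)
```

## The evaluation model

A segmentation benchmark compares a *test* label image — one unique positive
integer per segmented object, background 0 — against a *ground-truth* image,
typically hand-painted. The ground truth encodes objects with a small set of
distinct non-zero intensities chosen so that no two touching objects share a
value; by the four-color map theorem four values always suffice, which is why
hand-segmentation protocols paint with four intensities. The actual values do
not matter and are discovered from the image (`intensity_classes()`), so any
number of classes from one upward is accepted — the simulated validation
images below use one or two.

Two evaluations are computed on the same pair:

**Pixel level (traditional).** Both images are binarized (any positive value
becomes 1) and pixels are tallied: TP where both masks are 1, FP where only
the test mask is 1, FN where only the ground-truth mask is 1. True negatives
enter no formula and are not tracked.

**Object level.** Each intensity class of the ground truth is split into
connected components (4- or 8-connectivity; 8 by default, matching common
cell-mask practice, and selectable because the convention is not universal).
Components receive canonical ids 1..K ordered by ascending class and then by
scan order (column-major) of their first pixel — the ordering is arbitrary
but must be deterministic for reproducible reports. Every ground-truth object
is then matched to the test object whose label occurs most often within its
footprint; background pixels do not vote, an object lying entirely over test
background is unmatched, and exact ties resolve to the smallest test label
(again purely for determinism). For a matched pair, TP is the overlap pixel
count, FP is the matched test object's size minus TP, and FN is the
ground-truth object's size minus TP. Image-level object counts are TP summed
over objects, FP = total test foreground − total TP, FN = total ground-truth
foreground − total TP; this charges unmatched (spurious) test objects as FP
and counts every test pixel at most once even when one test object matches
several ground-truth objects. (At the per-object level such a shared test
object is charged fully to each of its ground-truth matches — the per-object
formula is applied literally; both behaviors are intentional and documented.)

Precision, Recall and F-measure are computed from each count triple, with
every 0/0 denominator defined as 0. The published behavior only forces this
for Precision (an all-background image against itself scores 0); we apply
the same convention uniformly to Recall and F-measure for consistency, and
flag it here because other conventions (NaN, 1) exist.

Useful identities that the test suite asserts exactly: TP + FN equals the
ground-truth foreground size and TP + FP the test foreground size (pixel
level, per object, and image level); pixel precision of (A, B) equals pixel
recall of (B, A); object-level TP never exceeds pixel-level TP; and when
matching is bijective, per-object precision and recall transpose under
swapping the ground-truth and test roles.

## Parameters that matter

- `connectivity` (4 or 8, default 8): how intensity classes split into
  objects. A checkerboard of one class is one object under 8-connectivity
  and one object per cell under 4.
- `split_test_components` (default `FALSE`): by convention a test image uses
  one distinct value per instance, so values are relabeled 1..n in ascending
  order without splitting; enable this when a test labeling reuses values
  across disconnected objects.
- `min_class_pixels` (default 1 = off): warn when a discovered ground-truth
  class occupies fewer pixels than this; tiny classes usually mean stray
  paint strokes.

Metrics are kept at full floating precision; rounding (e.g. to 2 or 4
decimals) happens only in formatting, never in the stored results.

## The synthetic validation fixtures

`segmetrics` regenerates every class of simulated validation image in code,
so no external data is needed:

- `make_constant()` — all-foreground / all-background 256 x 256 fields,
  pinning the output range (Precision 1 for identical foreground, 0 for the
  all-background self-comparison).
- `make_half()` — the four half-white/half-black images. Complementary
  halves score Precision 0, orthogonal halves 0.5 (exactly one shared
  quadrant), self-comparisons 1.
- `make_adjacent_pair()` — two grayscale images of two adjacent objects
  (intensities 100 and 200) sharing one connected footprint but split by
  differently placed internal boundaries. Pixel-level Precision is 1 for any
  such pair while the object level exposes the misassigned pixels. The
  published version of this fixture used two circles whose exact geometry
  (radii, split curve) is not recoverable, so the generator is parametric:
  the qualitative structure (pixel level 1, object level < 1, perfect
  self-comparison, precision/recall transposition under role swap) is what
  is asserted, and a 10 x 10 rectangle split at columns 5 vs 7 provides
  hand-enumerable per-object values (50/70, 1; 1, 0.6; image level 0.8).
- `make_cell_field()` — a randomized field of non-overlapping discs
  (defaults: 256 x 256 frame, 12 discs of radius 6–14 px, one touching
  pair — sizes typical of cell-scale microscopy), four-colored by
  `four_color_relabel()` (greedy coloring of the object-adjacency graph,
  largest object first, palette 50/100/150/200 extended only if greedy needs
  more). The test labeling applies controlled perturbations — 1-pixel
  dilation into background, 1-pixel erosion, deletion, merging — to objects
  kept at least 4 px clear of each other so the implied per-object TP/FP/FN
  are exact by construction. The generator returns that truth table, and
  the suite requires the evaluator to reproduce it exactly.

What the fields deliberately do **not** emulate: intensity texture and
noise, out-of-focus boundaries, concave or overlapping cells, and
hand-annotation error. Passing these tests therefore demonstrates
correctness of the counting and matching machinery on known geometry, not
segmentation difficulty on real micrographs.

## Numerical and design choices

- Connected components run per intensity class via a pixel-adjacency graph;
  the enumeration order is fixed (class, then scan order) so ids, CSV rows
  and tie-breaks are reproducible byte-for-byte.
- Whether the evaluation should treat each distinct ground-truth intensity
  as one object or run connected components per intensity is a genuine
  design fork; components are chosen because the four-color encoding only
  makes sense if values are reused across separate objects.
- Images are validated as non-negative integer matrices; floating-point
  input is accepted only when exactly integral, since labels are identities.
- Label I/O: 16-bit grayscale TIFF is the lossless default (integer-exact
  round trip); 8-bit PNG is available for labels ≤ 255. Labels above 65535
  are readable but not writable by the integer encodings of these formats.
- RGB instance images convert to labels by mapping distinct color triples,
  ordered lexicographically, to sequential ids; black is background. More
  than 65535 distinct colors is rejected as a likely photograph.
- Problem sizes in the test suite: exhaustive-oracle comparisons run on
  hundreds of random scenes of up to 20 x 20 pixels and 5 objects — small
  enough to brute-force every (object, label) overlap, large enough to hit
  every matching branch; full-scale checks use the 256 x 256 fixtures.

## Known limitations

- One object class at a time (e.g. the cell mask); multi-class outputs must
  be evaluated per class.
- 2-D images only; no 3-D stacks, no soft/probabilistic masks.
- A ground truth is required; the method is supervised by construction.
- Per-object iteration is slower than a purely pixel-level comparison; the
  CLI prints wall-clock timing for reference but no performance is asserted.

```{r example}
pr <- make_adjacent_pair(10, 10, shape_rect(1, 10, 1, 10),
                         split_vertical(5), split_vertical(7))
ev <- evaluate_segmentation(pr$a, pr$b)
ev
tidy(ev)
```
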