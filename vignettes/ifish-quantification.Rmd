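---
title: "Quantifying single-cell heterogeneity in IFISH images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell heterogeneity in IFISH images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifishquant)
```

## The measurement problem

IFISH sections carry up to five co-registered fluorescence channels: a
DAPI nuclear counterstain (mandatory), protein stains located in the
nucleus (e.g. ER) or the membrane (e.g. HER2), and FISH probes that mark
DNA loci as small bright spots. The quantities of interest are per-cell:
marker intensities comparable across samples, membrane completeness, and
locus copy number. Tissue makes this hard in specific ways: nuclei touch
and overlap, membranes are frequently incomplete, autofluorescence varies
across the field, and spot signal can sit barely above background.
`ifishquant` addresses each of these with an explicit, testable
mechanism, and ships a scene generator that reproduces exactly these
failure modes with known ground truth.

## Preprocessing and background model

Channels are loaded bit-exact from TIFF; a display copy may be
contrast-adjusted by clipping 1% of pixels at each intensity tail
(`autoadjust`), but **all quantification reads the unadjusted copy** —
the adjusted image only feeds contrast-hungry visual checks. Two
background estimates are available:

* a **global mean** over a user-supplied background mask
  (`global_background`), subtracted with clamping at zero since a
  negative corrected intensity has no physical meaning;
* a **per-nucleus ring background** (`ring_background`): the mean over
  the annulus between morphological dilations of each nucleus by 2 and
  6 px, excluding all nucleus pixels. This tracks local
  autofluorescence and is what makes nuclear-stain intensities
  comparable across cells and samples.

The annulus is built with a disk structuring element (the element shape
is a free choice; a disk treats all directions equally), and the mean —
not the median — is used deliberately: the annulus is small (a few
hundred pixels) and the estimate should respond to genuinely elevated
local background. Margins are fixed in pixels at every magnification,
with a configuration override; we found no principled scale rule for
them, and the annulus is anyway clipped against neighbouring nuclei.
When neighbours occlude the annulus completely, the estimate falls back
to the global mean with a warning.

## Nuclear segmentation

The foreground mask is an Otsu threshold of the sum of two [0,1]-scaled
images: the intensity itself and its local entropy over a 9×9 disk
(entropy is computed by binned indicator convolutions, 16 bins). The
sum of min–max-normalized images is one of several defensible ways to
"combine" entropy and intensity; we chose it for symmetry and state it
explicitly rather than claim it is canonical.

Nuclei come from an **iterative H-minima watershed**. A watershed with
suppression depth *h* absorbs every basin whose peak-to-saddle height is
below *h* (we use `EBImage::watershed`, whose `tolerance` is exactly
this depth). Deep suppression undersegments clumps; shallow suppression
shatters textured nuclei. The iteration resolves this tension: *h* is
swept down a linear ladder (5 rungs) from 30% to 10% of the foreground
dynamic range — expressing depths as fractions makes the whole
segmentation invariant to affine intensity rescaling, which the test
suite asserts exactly. At each rung, fragments are triaged by a linear
discriminant (linear on purpose — the model must not overfit the small
training sets this domain affords) over 10 dimensionless shape features;
`optimal` fragments are frozen and removed, and the remainder is re-run
at the next rung. After the ladder, `oversegmented` fragments are
repaired by the union-scoring merger:

$$S_F(c^j) = F(c^j) - \frac{1}{n_j}\sum_{i=1}^{n_j} F(c^j_i), \qquad
  S = \sum_F S_F, \qquad c^* = \arg\max_j S(c^j),$$

where $c^j$ ranges over unions of the fragment with subsets of its
neighbours within 5 px, and $F$ runs over solidity and the negated
relative deviation from the theoretical area. A union is accepted only
on a positive maximum; otherwise the fragment stands. Ties break toward
fewer members, then lower enumeration index, so results are
deterministic. The powerset is enumerated exactly up to 8 neighbours
(≤256 subsets); beyond that the same score drives greedy pairwise
merging — the exact enumeration is only meaningful at small
neighbourhood sizes, and more than 8 mutual neighbours of one fragment
does not occur in practice at these densities.

"Theoretical" area and perimeter are magnification-level references:
at 60x the expected nucleus covers 2500–10000 px, summarized by the
geometric mean (5000 px) since the range is multiplicative; 40x and 20x
scale by the magnification ratio squared. Fragments below 500 px (60x
scale) are discarded at the end. All labeling is 8-connected; output
labels are consecutive positive integers with 0 as background.

The default triage models are trained at load time from the synthetic
fragment generator (300 balanced fragments, fixed internal seed), so
they are identical in every session and retrainable from any labeled
set; a serialized binary model would be neither inspectable nor
portable. Training classes are constructed geometrically: ellipses near
the theoretical area (`optimal`), fused ellipse pairs (`undersegmented`),
caps and slivers well under the theoretical area (`oversegmented`).

For sparse or low-contrast fields there is a **seeded** mode
(`seeded_watershed`): the user supplies seed coordinates (CSV in batch
use) and regions grow from them by seeded region growing over the
intensity landscape.

## Membrane territories

Territories combine geometry and signal. Geometrically, each pixel
belongs to the nucleus *region* (not centroid) nearest in Euclidean
distance (`voronoi_partition`, per-label distance transforms, ties to
the lowest label). With membrane signal present, regions instead grow
from nuclei over the membrane channel (`EBImage::propagate`) with
pixels at or above the channel's 95th intensity percentile excluded
from growth — bright ridges act as watershed barriers, so boundaries
lock onto rings. The ridge pixels themselves are then attached to their
adjacent region, because the ring *is* the membrane being measured. A
constant channel degenerates, by construction, to the pure Voronoi
partition. Membrane intensity is measured over the territory's inner
boundary band (2 px), and the band's coefficient of variation serves as
a completeness proxy: a broken ring mixes ring and background pixels
and so varies more — on generated scenes the broken-ring cells are
cleanly separated by this statistic.

Active-contour refinement (`refine_contours`) is morphological
Chan–Vese (global inside/outside means) or a localized variant
(Gaussian-windowed means, 15 px window); a refinement that would evict
the owning nucleus from its region is rejected and the region reverts.
Refinement ships disabled (`iterations = 0`) because on ring-like
staining the barrier-constrained growth already sits on the boundary;
the refinement exists for diffuse cytoplasmic staining.

## Spot detection and copy number

Candidates are connected regions where the sign-inverted
Laplacian-of-Gaussian response exceeds 15% of the frame's peak response;
the scale is tied to the minimum spot size
($\sigma = \sqrt{s_{\min}/\pi}/\sqrt2$, i.e. matched to the radius of
the smallest admissible spot). Candidates are confirmed by coincidence
(within 2 px) with 3×3 regional maxima of the Sobel gradient magnitude
at ≥25% of the frame's strongest gradient: a genuine
diffraction-limited spot raises a steep rim, a broad autofluorescent
mound does not. Spot **area** is measured as the half-maximum area —
pixels above the midpoint between the region's peak and the frame
median — which decouples area from the LoG threshold and is what makes
the area–copy-number relation linear. Spots are filtered by minimum
size (15 px at 60x, scaled by magnification squared) and intensity
(fixed or Otsu-automatic over candidate means), and optionally triaged
by a spot-shape LDA (`optimal` / `too_small` / `too_large`) for
low-contrast probes.

Copy number per cell is `round(total area / 20 px)`; the relation
saturates around 400 px, beyond which (or beyond 21 copies) the cell is
coded 22, one more than the largest countable value — a sentinel for
"amplified". The per-cell total uses all retained spots (all detected,
or all `optimal` when the classifier is enabled); summing only
classifier-approved spots is the stricter reading and the one we adopt.
Spots are assigned to the nucleus containing their centroid; spots
outside every nucleus stay unassigned rather than being silently
dropped.

## Records, classification, maps

`map_segments` links compartments one nucleus ↔ one membrane ↔
contained spots, and refuses (with the offending labels) a state where
one membrane contains two nuclei — that is an editing error the user
must resolve, not a case to auto-repair. Manual correction is
available programmatically (`edit_labels`): cut along a rasterized
polyline, glue, trash, paint, erase, applied in order and
deterministically, accepting JSON edit scripts in place of GUI tools.

Cell typing is a **one-vs-all linear SVM** (cost 1, features
standardized on the training subset) over nuclear morphology,
optionally extended with adjusted intensities and spot area. One-vs-all
is implemented explicitly (one binary margin per class, argmax of
decision values). Classes are limited to 4 in strict mode, with a batch
override. Global thresholds (`apply_thresholds`) use inclusive
comparisons (value ≥ cutoff is positive) — the boundary convention is
arbitrary but must be fixed and documented. Topology maps colour each
cell's footprint by the bounded ratio $a/(a+b)$ of two adjusted
intensities; the bounded form (rather than $a/b$) keeps the colour map
stable when either stain vanishes, with 0.5 as the balanced midpoint
and undefined ratios (both zero) rendered neutral grey. Intensities are
not re-normalized per stain before the ratio: the map is meant to show
the measured balance, and any cross-stain normalization is the user's
explicit choice.

## Evaluation metrics

`match_segments` classifies objects from the pairwise overlap matrix:
a predicted object covering the majority of ≥2 gold objects marks them
undersegmented; ≥2 predicted objects mostly inside one gold object mark
it oversegmented, counting one `Nover` per *extra* predicted object; a
gold object overlapped by exactly one predicted object at Jaccard ≥ 0.5
is correct. Leftovers are false positives/negatives. The Jaccard-0.5
qualifying rule and the per-extra-object `Nover` convention are our
concrete reading of the match taxonomy (the threshold is configurable);
both are enforced against an independent brute-force matcher in the
tests. Precision, recall and F follow the standard object-level
formulas. Shape fidelity is the quotient of perimeter–area ratios of
matched objects; perimeter is measured as the exposed pixel-face count
(crack length) rather than a boundary-pixel count, because face count
is exactly additive under scaling (a $n\times n$ square has perimeter
$4n$, so doubling the linear size exactly halves P/A) — this exactness
is asserted in the tests.

## The scene generator: what it does and does not emulate

`generate_scene` renders, deterministically per seed: elliptical nuclei
with a parabolic DAPI profile (bright centre, dim rim), placed by dart
throwing with an adjacency mechanism (a touching cell is planted with
centre distance at 88–98% of the radius sum) so clumps present genuine
watershed saddles; membrane rings at the cell-territory border with a
contiguous arc deleted to the requested completeness; FISH spots as
Gaussian blobs whose half-maximum area equals the per-spot reference
area, with amplified cells rendered as one contiguous cluster above the
saturation area; constant, linear-gradient or smooth-random-field
background; Gaussian read noise and optional Poisson photon noise.
Default conditions: nuclei at the theoretical area for the
magnification (±8%), 20% adjacency probability, complete membranes,
Poisson(4) spots per cell, 5% background, read noise 0.01 on the unit
scale.

What it deliberately does **not** emulate: chromatic aberration and
channel cross-talk, sectioning artefacts (partial nuclei), true 3-D
overlap projected into the plane, tissue texture inside nuclei, and
spot z-stack structure (inputs are maximum projections). Consequently,
passing recovery tests demonstrates that the algorithms are correct and
well-calibrated for their geometric and photometric assumptions — not
that real FFPE tissue will segment at the same F-scores; on tissue, the
editing and seeded-segmentation paths exist precisely because no
automatic pipeline survives contact with every artefact.

## Numerical choices and degenerate inputs

* Constant channels: `autoadjust` warns and returns its input;
  `foreground_mask` warns and returns an empty mask; membrane growth
  falls back to Voronoi; active contours stop (no contrast).
* Quantiles in `autoadjust` use type-1 (inverse-ECDF) so the clip
  points are actual sample values.
* `watershed` sees masked-out pixels as exact zeros; masked-in zero
  pixels are nudged to `1e-9` so they are not mistaken for background.
* All argmax selections (merger subsets, SVM classes) carry explicit
  deterministic tie-breaks.
* Every RNG use is seeded; library code never touches the global RNG
  stream without restoring it (`with_seed`).

## Problem sizes used in validation

The shipped tests validate: metric identities on constructed counts;
merger and matcher equivalence against brute-force oracles (200 random
neighbourhoods, 100 perturbed scenes); nuclear recovery on 50-cell 40x
scenes (seeds 1–10, free-standing and 20%-adjacent; object F ≥ 0.9 and
≥ 0.75 respectively); exact copy-number recovery for 1–10 planted spots
per nucleus on 60x scenes (≥90% of nuclei) with amplified cells coded
22; ring-background recovery within 5% per nucleus on constant and
gradient fields; SVM accuracy ≥95% on separable two-population scenes
with accuracy rising, on average over 100 resamples, with training-set
size 2→20; and bit-level reproducibility of batch runs. These sizes
were chosen as the smallest scenes that still exercise the packing,
saturation and contrast regimes each mechanism exists for.

## Known limitations

Strictly 2-D; copy numbers from maximum projections undercount
overlapping z-separated spots. The magnification scaling of spot and
fragment size thresholds assumes square pixels and proportional optics.
The merger is single-pass over oversegmented fragments (no fixed-point
iteration); in principle a merge could enable another, but on tested
densities a second pass never changed the result. The membrane model
measures a ridge band, not a sub-compartment decomposition of
membrane vs cytoplasm.
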