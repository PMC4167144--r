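# ifishquant

Quantification of single-cell genomic and phenotypic heterogeneity from
IFISH tissue images.

Combined immunofluorescence and fluorescence *in situ* hybridization
(IFISH) stains protein markers (e.g. membrane HER2, nuclear ER) and DNA
loci (e.g. the *HER2* gene and the centromere-17 reference probe) on the
same tissue section, so each cell's phenotype and copy-number state can be
read together, in place. Turning such images into per-cell numbers
requires accurate segmentation of three compartments — nuclei, membranes
and FISH spots — plus background correction for autofluorescence, which
varies from sample to sample and even across one field. `ifishquant` is a
scriptable R implementation of that pipeline for tumor-tissue images,
aimed at image-analysis and cancer-genomics researchers who need batch,
reproducible quantification rather than an interactive GUI.

## What it computes

**Nuclear segmentation.** The cellular foreground is found by Otsu
thresholding a combined local-entropy + intensity image. Nuclei are
extracted by an iterative H-minima watershed: the suppression depth *h*
is swept from 30% down to 10% of the foreground dynamic range; at each
rung, fragments are triaged by a linear discriminant over 10 shape
features (solidity, area, perimeter, axis lengths, axis ratio,
circularity, area–perimeter ratio, and deviations from the theoretical
nucleus area and perimeter), and only `optimal` fragments are frozen
before the rest is re-segmented at a shallower depth. Fragments triaged
`oversegmented` are repaired by scoring every union *c* of a fragment
*f* with a subset of its neighbours:

    S(c) = sum over features F of [ F(c) − (1/n) Σᵢ F(cᵢ) ]

with F ∈ {solidity, −|A − A\*|/A\*}, keeping the best positive-scoring
union (the fragment is kept unchanged when none exists). Fragments below
500 px (at 60x) are discarded.

**Membranes.** Each nucleus claims a territory by a Voronoi partition
constrained by intensity: regions grow from nuclei over the membrane
channel with pixels above the 95th intensity percentile acting as
watershed barriers, so boundaries lock onto bright ridges (the HER2 ring
phenotype). Optional Chan–Vese / localized active-contour refinement.

**FISH spots.** Laplacian-of-Gaussian candidates confirmed by local
maxima of the Sobel gradient, filtered by minimum size (15 px at 60x)
and intensity, optionally triaged by a spot-shape linear discriminant
(for low-contrast probes such as centromere 17). Copy number per cell is
`round(area / 20 px)`, linear up to 21 copies; totals at or beyond the
~400 px saturation plateau are coded 22 ("amplified").

**Per-cell records.** Raw, globally background-adjusted, and
per-nucleus ring-adjusted intensities (annulus 2–6 px outside each
nucleus), nuclear morphology, membrane-band coefficient of variation (a
completeness proxy), spot areas and copy numbers — exported as CSV.
Cells can be classified with a one-vs-all linear SVM from a user-labeled
subset, thresholded into marker-positive/negative categories, and drawn
as topology maps of the relative ratio a/(a+b) of two stains.

**Evaluation.** Predicted vs gold-standard label maps are scored with
object-level counts N_t (correct), N_under, N_over, N_FP, N_FN and

    P = N_t / (N_t + N_FP + N_over)
    R = N_t / (N_t + N_FN + N_under)
    F = 2PR / (P + R)

plus a perimeter–area shape-fidelity quotient for matched objects.

A synthetic scene generator (`scene_spec()` / `generate_scene()`)
renders packed elliptical nuclei, broken membrane rings, FISH spots and
amplified clusters, spatially varying background and Poisson–Gaussian
noise, with exported ground truth — every stage of the pipeline is
testable without external data.

## Worked example

```r
library(ifishquant)

sc  <- generate_scene(scene_spec(n_cells = 12, magnification = 60,
                                 seed = 3, spots_fixed = 1:6))
res <- process_stack(sc$stack)      # nuclei, membranes, spots, cells
max(res$nuclei)
#> [1] 12
precision_recall_f(match_segments(res$nuclei, sc$nuclei))
#> P R F
#> 1 1 1
head(res$cells[, c("cell_id", "area", "ER_ring_adj", "HER2_raw",
                   "HER2_band_cv", "n_spots", "HER2_FISH_copies")], 4)
#>   cell_id area ER_ring_adj HER2_raw HER2_band_cv n_spots HER2_FISH_copies
#> 1       1 5309       0.377    0.667       0.0593       5                5
#> 2       2 6019       0.514    0.483       0.5595       2                2
#> 3       3 5136       0.379    0.636       0.0399       6                6
#> 4       4 4234       0.356    0.424       0.6621       4                4
```

All 12 planted nuclei are recovered (object F-score 1); the planted 1–6
spots per cell come back as copy numbers 1–6 via the 20 px/copy
relation; the two cells shown with high `HER2_band_cv` (0.56, 0.66) are
the ones rendered with broken membrane rings — the coefficient of
variation over the membrane band separates complete from incomplete
staining. Thresholding then bins cells into the four
ER±/HER2± categories:

```r
rules <- rbind(threshold_rule("ER", 0.2, "ring"),
               threshold_rule("HER2", 0.1, "global"))
table(apply_thresholds(res$cells, rules)$category)
#> ER+/HER2+
#>        12
```

Batch processing is driven by a YAML parameter file
(`run_batch("params.yaml")`, or the CLI in `inst/cli/ifishquant.R`:
`ifishquant.R run --params params.yaml`); each image yields a bundle
with label-map TIFFs, per-cell CSV, a JSON manifest of every parameter
used, and a log. Oversized images are processed as overlapping tiles
and stitched.

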