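---
title: "Superpixel cartography of H&E slides: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superpixel cartography of H&E slides: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(slidecarto)
```

# The problem and the model

A whole-slide image (WSI) is a gigapixel scan of a stained tissue
section. Dense tissue-class maps of such slides feed quantitative
pathology: tumour burden, invasive margin, microenvironment composition.
The classical approach tiles the slide into fixed patches and classifies
each one. `slidecarto` implements a two-stage alternative:

1. **Oversegment** the slide into superpixels that follow stain
   boundaries, so that each superpixel is plausibly one tissue type.
2. **Classify a bounded random subset** of the patches inside each
   superpixel and **fuse** the patch probabilities into one superpixel
   label with a confidence.

The central assumption is homogeneity: because superpixels adhere to
stain boundaries, the patches within one superpixel mostly share a
class, so a small random sample of them suffices. The same assumption is
the method's main failure mode — structures much smaller than a
superpixel (fine necrotic foci, thin inflamed seams) cannot be resolved,
whatever the classifier does.

## Stain model

Brightfield absorption follows the Beer–Lambert law, so stains are
linear in optical density, $OD = -\ln(I/I_0)$, with $I_0$ the white
background intensity (255 by convention here). Colour deconvolution
solves $od = c \cdot M$ per pixel for the stain concentrations $c$,
where the rows of $M$ are unit-norm stain OD vectors. The default $M$ is
the standard Ruifrok–Johnston H&E basis; an H-DAB basis is provided for
IHC material, and any 3×3 matrix can be supplied. The third
("residual") row is completed orthogonally to H and E — with a full-rank
square matrix the per-pixel solve is exact, and tests verify the
round trip H/E → OD → RGB → H/E to 1e-6. Intensities are floored at
$I_0/255$ before the logarithm so black pixels map to a large finite OD.
Concentrations are capped at zero by default (`clip_negative = TRUE`);
the cap is released in algebraic tests.

## Superpixels: SLIC in [H, E, x, y]

SLIC is a localised k-means. Each pixel of the analysis plane carries a
feature vector $[H, E, x, y]$ — stain concentrations instead of the
usual Lab colour, which concentrates the clustering on histologically
meaningful contrast. Distances are

$$d^2 = (H - H_c)^2 + (E - E_c)^2 + \left(\frac{m}{S}\right)^2
        \left[(x - x_c)^2 + (y - y_c)^2\right],$$

with grid interval $S = \sqrt{N_{px}/k}$ and compactness $m$. Centres
start on a regular grid (no gradient perturbation — initialisation is
deterministic, so identical inputs give identical segmentations), each
iteration searches a $2S$ window per centre, and a connectivity pass
reassigns orphan fragments to their dominant neighbouring superpixel so
every label is one connected component (iterated to a fixed point, at
most 5 passes).

Parameter choices, all exposed in `superpixel_config()`:

| parameter | default | unit | rationale |
|---|---|---|---|
| `avg_size_px` | 3600 | analysis px | a square superpixel covers 0.2 × 0.2 mm at 3.54 µm/px; the trade-off between boundary fidelity and patch-budget savings |
| `sigma` | 5 | analysis px | Gaussian smoothing against jagged contours |
| `iterations` | 10 | – | SLIC converges visually within 10 local k-means rounds |
| `compactness` | 0.1 | – | spatial-vs-stain weight; see below |
| `background_fraction` | 0.5 | – | a superpixel at least half white is background |

The superpixel count follows $k = \mathrm{round}(N_{bbox}/3600)$, floored
at 1, where $N_{bbox}$ is the pixel count of the tissue bounding box.

Two details are genuinely open design choices rather than given
quantities. First, the relative scaling of stain and spatial features:
the H and E channels are standardised to unit variance per slide before
clustering, and `compactness = 0.1` then gives stain contrast roughly a
10× head start over geometry — small enough that boundaries follow
stains, large enough that uniform regions split into regular tiles.
Second, the order of smoothing and deconvolution: smoothing is applied
to the *stain channels*, since those are the features actually
clustered; smoothing RGB first and deconvolving after would mix stains
across the blur kernel.

## Patch assignment, sampling and fusion

The native plane is tiled by non-overlapping 224 × 224 px patches
anchored at the tissue bounding box (partial edge tiles dropped). The
patch side must be divisible by the analysis downsample (224/16 = 14) so
each patch corresponds to an integer 14 × 14 analysis block. A patch is
assigned to the superpixel covering the largest share of its block iff
that share is ≥ 0.5 and the superpixel is not background; a tie at the
maximum goes to the lower superpixel id (deterministic). Superpixels
with more than `patch_limit = 10` assigned patches contribute a uniform
random subset of 10, drawn without replacement from a per-superpixel RNG
stream derived from the global seed and the superpixel id — so the
sample is reproducible and independent of processing order. Superpixels
with zero assigned patches (small or elongated ones) become
`UNCLASSIFIED` and render like rejected area.

Fusion averages the patch softmax vectors and takes the argmax; the
vote-difference confidence divides the gap between the top-two patch
vote counts by the patch count. The fused label always comes from the
averaged vector, even when it disagrees with the vote plurality; argmax
ties break to the lowest class index everywhere. Rejection is strict:
confidence < 0.1 rejects, exactly 0.1 keeps. The default threshold 0.1
balances retained area against error pruning; 0.45 is a useful
visualisation preset that highlights every ambiguous superpixel.

## Evaluation and endpoints

Evaluation is pixelwise at the analysis resolution. Only pixels with
both a ground-truth class and a predicted class count: code 0
(background/unannotated), 254 (unclassified) and 255 (rejected) are
excluded on either axis. Per-class metrics treat each class one-vs-rest;
zero denominators yield `NA` rather than 0.

The tumour-area rule: binarise tumour cells, necrosis and mucus; close
the tumour map (disc radius 10 px ≈ 35 µm); merge every necrosis/mucus
connected component touching a tumour component (contact = overlap after
a 1-px 8-connected dilation); close then open the union (radii 10/5 px);
fill holes per component, so the final area is the one enclosed by each
outer contour. The disc radii are design defaults — the operations are
prescribed, their kernels are not — and are exposed in the
configuration.

The invasive margin extends the tumour mask by the margin half-width $w$
(default 500 µm, converted via the plane's µm/px), intersects with
non-tumour tissue to form the outward basis, then extends the basis by
the same $w$ back across the boundary, capping the outward reach at $w$.
The result is a band of half-width $w$ straddling the tumour boundary
into both sides; tests verify it against an independent
distance-transform oracle within 1 px. The second extension distance is
not separately specified anywhere, so it defaults to $w$; the cap keeps
the band symmetric, which is what "stretching out into both sides"
means geometrically.

## The synthetic test bed

`make_phantom()` draws an analysis-resolution label map (Voronoi
tessellation or a two-class vertical split), stamps white background (a
frame and fissure lines), upsamples 16× and renders native RGB through
the Beer–Lambert law from per-class mean H/E densities plus Gaussian
texture noise (sd 0.04 OD). The default seven classes mirror a
colorectal legend with distinct H/E pairs. Defaults are native
3584 × 3584 px (analysis 224 × 224 px, about 13 superpixels at the
default size, ~16–18 assigned patches per superpixel) — large enough to
exercise every resolution conversion, small enough that experiment
suites over tens of seeds run in minutes on one CPU. These phantom sizes
are the package's desk-scale study conditions; all multi-seed
experiments in the tests and in `scripts/acceptance.R` use them.

`oracle_classifier()` classifies a patch by the distance of its mean
deconvolved (H, E) to the class centroids, through a softmax with
temperature 0.025 — sharp enough to be ≥ 0.99 confident on pure-class
patches given the minimum centroid separation (~0.25 OD) of the default
legend. Its noise model is standard symmetric label noise: with
probability ε the patch's vector is replaced by a smoothed one-hot on a
class drawn uniformly from *all* K classes, so per-patch accuracy is
$1 - \varepsilon + \varepsilon/K$ (at ε = 1 it is 1/K). A
confusion-matrix mode substitutes an arbitrary row-stochastic error
structure.

What the phantoms do **not** emulate: nucleus-level texture, stain
variation between slides, scanner artefacts, out-of-focus regions, and
— most importantly — tissue classes whose spatial statistics differ
from Voronoi cells (infiltrating single cells, thin seams). Passing the
phantom suite therefore demonstrates the correctness of the machinery
(segmentation, counting, fusion, morphology, bookkeeping), not clinical
classification performance, which is entirely a property of the
user-supplied patch classifier.

## Numerical and interface conventions

* Rasters are plain R arrays/matrices; coordinates are 1-based and
  bounding boxes inclusive, as in every R imaging package. Label 0 is
  reserved for out-of-bounding-box area, class codes start at 1,
  sentinels are 0/254/255.
* Slides are held in memory as arrays (a desk-scale choice); patch
  extraction is per-superpixel through `extract_patch()`, so a windowed
  region reader can replace the in-memory backing without touching the
  pipeline.
* Degenerate inputs have defined behaviour: empty tissue is an error in
  `tissue_bounding_box()`; a bounding box smaller than one patch yields
  an empty grid with a warning; an empty probability set is an error
  mapped to `UNCLASSIFIED` by the caller; an empty confusion matrix is
  an error flagged as "no jointly labelled pixels"; a tumour-free class
  map returns a zero-area mask.
* Probability vectors are validated to sum to 1 within 1e-6; stain rows
  are unit-norm within 1e-6; fusion agrees with naive summation to
  1e-12 in tests.

## Known limitations

* Structures smaller than the superpixel scale are systematically
  missed; shrinking `avg_size_px` trades this against runtime and
  boundary noise.
* The SLIC feature space is purely H&E; other stains need a different
  matrix and possibly different compactness.
* The tumour-area morphology radii are tuned for 3.54 µm/px; other
  analysis resolutions should scale them.
* The pipeline is single-threaded and in-memory; true gigapixel slides
  need a region-streaming reader behind `select_plane()`.
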