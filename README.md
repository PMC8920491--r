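# slidecarto

Superpixel-based whole-slide tissue cartography for H&E histology in R.

Gigapixel whole-slide images (WSIs) of stained tissue are routinely mapped
into dense tissue-class "cartographies" — per-region labels such as tumour
cells, muscle, mucosa, necrosis or mucus — that downstream analyses turn
into clinically meaningful endpoints: total tumour area, the invasive
margin, and the composition of the tumour microenvironment. Classifying
every fixed-size patch of a WSI is accurate but slow and produces blocky
boundaries. `slidecarto` implements the alternative: segment the slide
into *stain-aware superpixels* first, classify only a small random subset
of patches inside each superpixel, and fuse those patch predictions into
one superpixel label with an attached confidence. The package is aimed at
computational-pathology researchers who want the full pipeline — or any
individual stage — as plain R functions operating on ordinary arrays.

## Method

* **Stain deconvolution.** RGB intensities are converted to optical
  densities, `OD = -log(I / I0)`, and unmixed with the Ruifrok–Johnston
  H&E basis into haematoxylin (H) and eosin (E) concentration channels.
* **Superpixels.** A modified SLIC clusters pixels of the 16×-downsampled
  analysis plane (nominally 3.54 µm/px) in `[H, E, x, y]` space — stain
  features replacing the usual Lab colour — after Gaussian smoothing
  (σ = 5) of the stain channels; 10 k-means iterations. The superpixel
  count is `k = pixelCount(boundingBox(foreground(WSI))) / 3600`, so an
  average superpixel covers 3600 analysis pixels (≈ 0.2 × 0.2 mm).
  Superpixels that are at least 50 % white pixels are background.
* **Patch fusion.** The native plane is tiled into non-overlapping
  224 × 224 px patches; a patch belongs to a superpixel when that
  superpixel covers ≥ 50 % of it. At most 10 randomly chosen patches per
  superpixel are sent to a pluggable classifier, and the superpixel label
  is the argmax of the averaged softmax vectors,
  `L_SP = argmax_c (1/N) Σ_n p_n`.
* **Confidence and rejection.** The vote-difference confidence
  `Cdiffvotes = (v1 − v2)/N` (top-two patch vote counts over patch count)
  flags ambiguous superpixels; those below 0.1 are assigned to a
  rejection class and excluded from the map and its evaluation.
* **Endpoints.** From the class map the package derives the tumour-area
  mask (closing of the tumour-cell map, merging of adjacent necrosis and
  mucus components, closing + opening, hole filling), IoU / Dice overlap
  (`Dice = 2·IoU/(1+IoU)`), an invasive-margin band of configurable
  half-width straddling the tumour boundary, and composition ratios
  (tumour / necrosis / mucus fractions of a reference region).

Because clinical slides cannot be redistributed, the package ships a
first-class synthetic module: `make_phantom()` renders multi-class tissue
mosaics through the Beer–Lambert law from per-class H/E densities (with
white background and fissures) together with exact ground truth, and
`oracle_classifier()` provides a patch classifier with configurable label
noise. Every stage of the pipeline is tested against these phantoms.

## Worked example

A three-class phantom with large regions (native 3584 × 3584 px at
0.22 µm/px; analysis plane 224 × 224 px), classified by the noise-free
oracle:

```r
library(slidecarto)

spec <- phantom_spec(region_scale = 180, n_region_classes = 3, seed = 42)
ph   <- make_phantom(spec)
res  <- run_cartography(ph$pyramid, oracle_classifier(spec, seed = 42),
                        pipeline_config(seed = 42))
res$manifest[c("k", "n_assigned", "n_classified")]
#> $k              13
#> $n_assigned     212
#> $n_classified   90
```

Thirteen superpixels cover the tissue; of 212 assigned patches only 90
are classified under the 10-patch budget. Evaluating the class map
against the phantom's ground truth and deriving the tumour endpoints:

```r
metrics(confusion(ph$gt, res$class_map))$accuracy
#> [1] 0.9753

ep <- run_endpoints(res$class_map, gt = ph$gt, tissue = res$tissue)
ep$tumor$area_mm2          # 0.078 mm^2 in 1 component
c(ep$overlap$iou, ep$overlap$dice)
#> [1] 0.906 0.951
ep$composition$tumor_ratio
#> [1] 0.810
```

97.5 % of evaluated pixels are correctly labelled; errors sit on region
boundaries where superpixels straddle two tissue types. The tumour mask
derived from the prediction overlaps the mask derived from the ground
truth at IoU 0.906 / Dice 0.951, and 81 % of the reference tumour region
is active tumour-cell class. With the default seven-class phantom the
same pipeline reports lower per-class recall for classes occupying very
small regions — the documented cost of the coarse superpixel size.

A thin command-line front end wraps the same functions:

```sh
exec/slidecarto simulate --out scratch/demo --seed 42
exec/slidecarto segment  --input scratch/demo/phantom.tiff --out scratch/demo
exec/slidecarto evaluate --classmap scratch/demo/classmap.png \
                         --gt scratch/demo/gt.tiff --out scratch/demo
```

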