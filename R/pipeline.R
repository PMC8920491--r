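#' Pipeline configuration
#'
#' Collects every tunable of the cartography pipeline with the reference
#' defaults: analysis at downsample 16, white threshold 220, average
#' superpixel size 3600 px with Gaussian sigma 5 and 10 SLIC iterations,
#' 224-px patches assigned at >= 50% coverage, at most 10 random patches
#' per superpixel, and rejection of superpixels with vote-difference
#' confidence below 0.1. Unknown arguments are rejected.
#'
#' @param downsample Analysis downsample factor.
#' @param white_threshold Background intensity threshold (0..255).
#' @param stain Stain matrix (default H&E).
#' @param superpixel A [superpixel_config].
#' @param patch_size Native patch side in px.
#' @param coverage_threshold Minimum superpixel share of a patch block.
#' @param patch_limit Maximum classified patches per superpixel.
#' @param seed RNG seed for patch sampling (and noisy oracle streams).
#' @param classes Named integer vector of class codes ([default_classes()]).
#' @param rejection_threshold Confidence threshold (strict less-than).
#' @param closing_radius,opening_radius Tumour-area disc radii in px.
#' @param margin_width_um Invasive-margin half-width in microns.
#' @param batch_size Patches per classifier call.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(downsample = 16, white_threshold = 220,
                            stain = stain_matrix_he(),
                            superpixel = superpixel_config(),
                            patch_size = 224, coverage_threshold = 0.5,
                            patch_limit = 10, seed = 1L,
                            classes = default_classes(),
                            rejection_threshold = 0.1,
                            closing_radius = 10, opening_radius = 5,
                            margin_width_um = 500, batch_size = 64) {
  cfg <- list(downsample = downsample, white_threshold = white_threshold,
              stain = stain, superpixel = superpixel,
              patch_size = patch_size,
              coverage_threshold = coverage_threshold,
              patch_limit = patch_limit, seed = as.integer(seed),
              classes = classes,
              rejection_threshold = rejection_threshold,
              closing_radius = closing_radius,
              opening_radius = opening_radius,
              margin_width_um = margin_width_um, batch_size = batch_size)
  if (patch_size %% downsample != 0)
    stop("patch_size must be divisible by downsample")
  structure(cfg, class = "pipeline_config")
}

#' Run the whole-slide cartography pipeline
#'
#' Executes the full chain on one slide: analysis-plane selection,
#' foreground detection and bounding-box crop, colour deconvolution,
#' stain-aware SLIC superpixels with background labelling, native patch
#' grid with coverage-based assignment, seeded random subsampling under
#' the patch budget, patch classification, softmax fusion with
#' vote-difference confidence, rejection and class-map rendering.
#'
#' @param pyramid A `slide_pyramid`.
#' @param classifier Patch classifier function (see [classify_patches()]).
#' @param cfg A [pipeline_config].
#' @return List: `class_map` (rejection applied), `class_map_unrejected`,
#'   `labeling` (pre-rejection confidences retained), `spmap` (cropped to
#'   the tissue bounding box), `bbox` (analysis coordinates), `tissue`
#'   (full-plane foreground mask), `manifest` (counts and seed).
#' @export
run_cartography <- function(pyramid, classifier, cfg = pipeline_config()) {
  plane <- select_plane(pyramid, cfg$downsample)
  fg <- foreground_mask(plane, cfg$white_threshold)
  bbox <- tissue_bounding_box(fg)
  crop_px <- plane$pixels[bbox[1]:bbox[3], bbox[2]:bbox[4], , drop = FALSE]
  fg_crop <- fg[bbox[1]:bbox[3], bbox[2]:bbox[4]]

  od <- rgb_to_od(crop_px)
  channels <- deconvolve(od, cfg$stain)
  k <- compute_k(prod(dim(fg_crop)), cfg$superpixel$avg_size_px)
  spmap <- slic_he(channels, cfg$superpixel, k)
  spmap <- mark_background(spmap, fg_crop)

  ds <- cfg$downsample
  native_bbox <- c((bbox[1] - 1L) * ds + 1L, (bbox[2] - 1L) * ds + 1L,
                   bbox[3] * ds, bbox[4] * ds)
  grid <- build_grid(native_bbox, cfg$patch_size)
  assignment <- assign_patches(grid, spmap, ds, cfg$coverage_threshold)
  sampled <- sample_patches(assignment, cfg$patch_limit, cfg$seed)

  native <- select_plane(pyramid, 1)
  K <- length(cfg$classes)
  probs <- matrix(numeric(0), 0L, K)
  if (nrow(sampled)) {
    batches <- split(seq_len(nrow(sampled)),
                     ceiling(seq_len(nrow(sampled)) / cfg$batch_size))
    probs <- do.call(rbind, lapply(batches, function(ix) {
      patches <- lapply(ix, function(i)
        extract_patch(native$pixels, grid,
                      sampled$patch_row[i], sampled$patch_col[i]))
      classify_patches(classifier, patches, K)
    }))
  }
  labeling <- fuse_superpixels(sampled, probs, spmap, names(cfg$classes))
  rejected <- apply_rejection(labeling, cfg$rejection_threshold)

  embed <- function(lab) {
    cm_crop <- render_class_map(spmap, lab, mpp = plane$mpp)
    full <- matrix(sentinel_codes()[["BACKGROUND"]],
                   nrow(plane$pixels), ncol(plane$pixels))
    full[bbox[1]:bbox[3], bbox[2]:bbox[4]] <- cm_crop$codes
    class_map(full, names(cfg$classes), mpp = plane$mpp)
  }
  manifest <- list(seed = cfg$seed,
                   analysis_dim = dim(plane$pixels)[1:2],
                   bbox = unname(bbox), k = spmap$k,
                   n_superpixels = length(spmap$sizes),
                   n_background = length(spmap$background_ids),
                   n_grid_patches = grid$n_rows * grid$n_cols,
                   n_assigned = sum(!is.na(assignment$superpixel_id)),
                   n_classified = nrow(sampled),
                   patch_limit = cfg$patch_limit,
                   rejection_threshold = cfg$rejection_threshold,
                   n_rejected = sum(rejected$status == "REJECTED"))
  list(class_map = embed(rejected),
       class_map_unrejected = embed(labeling),
       labeling = rejected, spmap = spmap, bbox = bbox, tissue = fg,
       assignment = assignment, manifest = manifest)
}

#' Evaluation and tumour endpoints for a class map
#'
#' Computes (when ground truth is supplied) the pixelwise confusion
#' matrix and metrics, then the tumour-area mask, its overlap against a
#' reference tumour mask, the invasive-margin band and the composition
#' ratios inside the reference tumour region. Without ground truth the
#' evaluation is skipped with a warning and the endpoints are still
#' computed (overlap and composition require a reference mask).
#'
#' @param cmap A `class_map`.
#' @param gt Optional ground-truth class raster.
#' @param tissue Optional tissue mask (default: non-background pixels of
#'   the class map).
#' @param gt_tumor Optional reference tumour mask; default: the
#'   tumour-area rule applied to `gt`.
#' @param cfg A [pipeline_config].
#' @return List: `metrics`, `confusion`, `tumor` (a `tumor_area_result`),
#'   `overlap`, `margin` (logical mask), `composition`.
#' @export
run_endpoints <- function(cmap, gt = NULL, tissue = NULL, gt_tumor = NULL,
                          cfg = pipeline_config()) {
  sent <- sentinel_codes()
  if (is.null(tissue))
    tissue <- cmap$codes != sent[["BACKGROUND"]]
  tum <- tumor_area(cmap, closing_radius = cfg$closing_radius,
                    opening_radius = cfg$opening_radius)
  res <- list(tumor = tum)
  res$margin <- if (any(tum$mask))
    invasive_margin(tum$mask, tissue, cfg$margin_width_um,
                    mpp = if (is.na(cmap$mpp)) 3.54 else cmap$mpp)
  else tum$mask
  if (is.null(gt)) {
    warning("no ground truth supplied: evaluation skipped")
  } else {
    cm <- confusion(gt, cmap, n_classes = length(cmap$legend))
    res$confusion <- cm
    res$metrics <- if (sum(cm) > 0) metrics(cm) else NULL
    if (is.null(gt_tumor))
      gt_tumor <- tumor_area(gt, closing_radius = cfg$closing_radius,
                             opening_radius = cfg$opening_radius,
                             mpp = cmap$mpp)$mask
  }
  if (!is.null(gt_tumor)) {
    res$overlap <- overlap(tum$mask, gt_tumor)
    if (any(gt_tumor)) res$composition <- composition(cmap, gt_tumor)
  }
  res
}
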