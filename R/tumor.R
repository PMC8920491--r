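#' Tumour-area derivation from a class map
#'
#' Implements the morphological tumour-area rule at analysis resolution:
#' (1) binarise the tumour-cell, necrosis and mucus classes; (2) apply a
#' morphological closing (disc, `closing_radius`) to the tumour-cell map;
#' (3) add every necrosis/mucus connected component that touches a closed
#' tumour-cell component (8-connected contact, tested by overlap after a
#' 1-px dilation); (4) close then open the union (disc radii
#' `closing_radius` / `opening_radius`); (5) fill the holes of each
#' component, so the area is that enclosed by the outer contour. The area
#' is converted to mm^2 with the map's microns-per-pixel.
#'
#' @param cmap A `class_map` (or integer raster, then `mpp` must be given).
#' @param tumor_code,necrosis_code,mucus_code Class codes of the three
#'   classes (defaults from [default_classes()]).
#' @param closing_radius Disc radius in px for the closings (default 10,
#'   about 35 um at 3.54 um/px).
#' @param opening_radius Disc radius in px for the opening (default 5).
#' @param mpp Microns per pixel (default: from the class map).
#' @return A `tumor_area_result`: list with `mask` (logical matrix),
#'   `area_mm2` (3 decimals), `components` (count).
#' @export
tumor_area <- function(cmap,
                       tumor_code = default_classes()[["tumor_cells"]],
                       necrosis_code = default_classes()[["necrosis"]],
                       mucus_code = default_classes()[["mucus"]],
                       closing_radius = 10, opening_radius = 5,
                       mpp = NULL) {
  codes <- if (inherits(cmap, "class_map")) cmap$codes else cmap
  if (is.null(mpp)) mpp <- if (inherits(cmap, "class_map")) cmap$mpp else NA_real_
  tum <- codes == tumor_code
  nec <- codes == necrosis_code
  muc <- codes == mucus_code
  if (!any(tum | nec | muc)) {
    return(structure(list(mask = matrix(FALSE, nrow(codes), ncol(codes)),
                          area_mm2 = 0, components = 0L),
                     class = "tumor_area_result"))
  }
  tum_closed <- mclose(tum, closing_radius)
  union <- tum_closed
  nm <- nec | muc
  if (any(nm)) {
    cc <- EBImage::bwlabel(nm)
    touch <- mdilate(tum_closed, 1) # 1-px 8-connected contact zone
    keep <- unique(cc[cc > 0L & touch])
    if (length(keep)) union <- union | matrix(cc %in% keep, nrow(codes))
  }
  final <- mopen(mclose(union, closing_radius), opening_radius)
  final <- EBImage::fillHull(EBImage::bwlabel(final)) > 0
  comps <- max(EBImage::bwlabel(final))
  area <- if (is.na(mpp)) NA_real_ else
    round(sum(final) * (mpp / 1000)^2, 3)
  structure(list(mask = final, area_mm2 = area, components = as.integer(comps)),
            class = "tumor_area_result")
}

# disc-brush morphology wrappers operating on logical matrices
disc_kernel <- function(radius) {
  if (radius < 1) return(matrix(1, 1, 1))
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}
mdilate <- function(m, radius) {
  if (radius < 1) return(m)
  k <- if (radius == 1) matrix(1, 3, 3) else disc_kernel(radius)
  EBImage::dilate(m * 1, k) > 0
}
merode <- function(m, radius) {
  if (radius < 1) return(m)
  EBImage::erode(m * 1, disc_kernel(radius)) > 0
}
mclose <- function(m, radius) {
  if (radius < 1) return(m)
  EBImage::closing(m * 1, disc_kernel(radius)) > 0
}
mopen <- function(m, radius) {
  if (radius < 1) return(m)
  EBImage::opening(m * 1, disc_kernel(radius)) > 0
}

#' Overlap metrics between an estimated and a reference mask
#'
#' `IoU = |E intersect GT| / |E union GT| = TP/(TP+FP+FN)` and
#' `Dice = 2|E intersect GT| / (|E|+|GT|) = 2TP/(2TP+FP+FN)`.
#'
#' @param est,gt Logical masks of equal shape.
#' @return List with `iou`, `dice`, `tp`, `fp`, `fn`. Both metrics are 1
#'   when the masks are identical and both are defined as 0 for two empty
#'   masks.
#' @export
overlap <- function(est, gt) {
  stopifnot_aligned(est, gt, "masks")
  tp <- sum(est & gt); fp <- sum(est & !gt); fn <- sum(!est & gt)
  denom_i <- tp + fp + fn
  list(iou = if (denom_i > 0) tp / denom_i else 0,
       dice = if (denom_i > 0) 2 * tp / (2 * tp + fp + fn) else 0,
       tp = tp, fp = fp, fn = fn)
}

#' Invasive-margin band
#'
#' The tumour mask is extended by the margin width `w` (disc dilation);
#' the intersection of this extension with non-tumour tissue forms the
#' outward basis of the margin. The basis is extended again by `w` so the
#' band reaches into the tumour side, and the result is restricted to the
#' extended tumour region and to tissue — yielding a band of half-width
#' `w` straddling the tumour boundary into both sides.
#'
#' @param tumor Logical tumour mask (analysis resolution).
#' @param tissue Logical tissue mask (TRUE = tissue).
#' @param width_um Margin half-width in microns (default 500).
#' @param mpp Microns per pixel of the masks.
#' @return Logical margin mask (subset of `tissue`).
#' @export
invasive_margin <- function(tumor, tissue, width_um = 500, mpp = 3.54) {
  stopifnot_aligned(tumor, tissue, "masks")
  if (width_um <= 0) stop("margin width must be > 0")
  if (!any(tissue)) return(tissue & FALSE)
  w <- max(1L, as.integer(round(width_um / mpp)))
  if (!any(tumor)) return(tissue & FALSE)
  ext <- mdilate(tumor, w)
  basis <- ext & tissue & !tumor
  if (!any(basis)) return(basis)
  mdilate(basis, w) & ext & tissue
}

#' Tissue composition within a reference region
#'
#' Fractions of tumour-cell, necrosis and mucus pixels within a reference
#' region (for example the annotated tumour area), each divided by the
#' same region pixel count.
#'
#' @param cmap A `class_map` or integer raster.
#' @param region Logical reference-region mask (nonempty).
#' @param tumor_code,necrosis_code,mucus_code Class codes.
#' @return List with `tumor_ratio`, `necrosis_ratio`, `mucus_ratio`,
#'   `region_px`.
#' @export
composition <- function(cmap, region,
                        tumor_code = default_classes()[["tumor_cells"]],
                        necrosis_code = default_classes()[["necrosis"]],
                        mucus_code = default_classes()[["mucus"]]) {
  codes <- if (inherits(cmap, "class_map")) cmap$codes else cmap
  stopifnot_aligned(codes, region, "class map and region")
  n <- sum(region)
  if (n == 0) stop("empty reference region")
  inside <- codes[region]
  list(tumor_ratio = sum(inside == tumor_code) / n,
       necrosis_ratio = sum(inside == necrosis_code) / n,
       mucus_ratio = sum(inside == mucus_code) / n,
       region_px = n)
}
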