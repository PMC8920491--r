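#' Slide planes and pyramids
#'
#' A `slide_plane` is one resolution level of a slide: an RGB raster plus
#' its microns-per-pixel and its downsample factor relative to the native
#' level. A `slide_pyramid` is an ordered list of planes (downsample
#' strictly increasing, level 1 at factor 1) with the native mpp.
#'
#' @param pixels RGB array (rows x cols x 3), intensities 0..255.
#' @param mpp Microns per pixel of this plane.
#' @param downsample Downsample factor relative to native (1 = native).
#' @return A `slide_plane` / `slide_pyramid` object.
#' @export
slide_plane <- function(pixels, mpp, downsample = 1) {
  stopifnot_rgb(pixels, "slide_plane pixels")
  structure(list(pixels = pixels, mpp = mpp, downsample = downsample),
            class = "slide_plane")
}

#' @rdname slide_plane
#' @param planes List of `slide_plane` objects.
#' @param native_mpp Microns per pixel at the native level.
#' @export
slide_pyramid <- function(planes, native_mpp = planes[[1]]$mpp) {
  ds <- vapply(planes, `[[`, numeric(1), "downsample")
  if (is.unsorted(ds, strictly = TRUE)) planes <- planes[order(ds)]
  ds <- sort(ds)
  if (ds[1] != 1) stop("pyramid must contain the native level (downsample 1)")
  for (p in planes) {
    if (abs(p$mpp - native_mpp * p$downsample) > 0.02 * p$mpp)
      stop("plane mpp inconsistent with native_mpp * downsample")
  }
  structure(list(planes = planes, native_mpp = native_mpp),
            class = "slide_pyramid")
}

#' @export
print.slide_pyramid <- function(x, ...) {
  cat("slide_pyramid:", length(x$planes), "level(s), native mpp",
      x$native_mpp, "\n")
  for (p in x$planes)
    cat(sprintf("  x%-3g %5d x %5d px, %.3f um/px\n", p$downsample,
                dim(p$pixels)[1], dim(p$pixels)[2], p$mpp))
  invisible(x)
}

#' Block-mean downsampling of an RGB raster
#'
#' Mean pooling over non-overlapping `factor` x `factor` blocks; trailing
#' rows/columns that do not fill a block are dropped.
#'
#' @param pixels RGB array.
#' @param factor Integer pooling factor (>= 1).
#' @return Pooled RGB array.
#' @export
block_mean_pool <- function(pixels, factor) {
  stopifnot_rgb(pixels)
  factor <- as.integer(factor)
  if (factor < 1L) stop("pooling factor must be >= 1")
  if (factor == 1L) return(pixels)
  d <- dim(pixels)
  nr <- d[1] %/% factor; nc <- d[2] %/% factor
  if (nr < 1L || nc < 1L) stop("raster smaller than one pooling block")
  x <- pixels[seq_len(nr * factor), seq_len(nc * factor), , drop = FALSE]
  out <- array(0, c(nr, nc, 3L))
  for (ch in 1:3) {
    m <- x[, , ch]
    dim(m) <- c(factor, nr, factor * nc)
    m <- colMeans(m)                      # nr x (factor*nc)
    dim(m) <- c(nr, factor, nc)
    out[, , ch] <- colMeans(aperm(m, c(2, 1, 3)))
  }
  out
}

#' Select (or synthesize) a pyramid level
#'
#' Returns the plane at the requested downsample factor. When the pyramid
#' lacks that level it is synthesized from the nearest finer stored level by
#' integer block-mean pooling.
#'
#' @param pyramid A `slide_pyramid`.
#' @param downsample Requested factor (>= 1).
#' @return A `slide_plane` with the requested downsample.
#' @export
select_plane <- function(pyramid, downsample) {
  ds <- vapply(pyramid$planes, `[[`, numeric(1), "downsample")
  if (downsample < 1) stop("requested factor finer than native level")
  hit <- which(ds == downsample)
  if (length(hit)) return(pyramid$planes[[hit[1]]])
  finer <- which(ds < downsample & downsample %% ds == 0)
  if (!length(finer))
    stop("no stored level can synthesize downsample ", downsample)
  src <- pyramid$planes[[max(finer)]]
  f <- as.integer(downsample / src$downsample)
  slide_plane(block_mean_pool(src$pixels, f),
              mpp = pyramid$native_mpp * downsample, downsample = downsample)
}

#' Tissue foreground mask
#'
#' A pixel is white background iff all of its RGB channels are at least
#' `white_threshold`; the mask is `TRUE` on tissue.
#'
#' @param plane A `slide_plane` or RGB array.
#' @param white_threshold Intensity threshold, default 220 (0..255 scale).
#' @return Logical matrix (`TRUE` = tissue) with attribute
#'   `white_threshold`.
#' @export
foreground_mask <- function(plane, white_threshold = 220) {
  px <- if (inherits(plane, "slide_plane")) plane$pixels else plane
  stopifnot_rgb(px, "foreground_mask() input")
  white <- px[, , 1] >= white_threshold &
           px[, , 2] >= white_threshold &
           px[, , 3] >= white_threshold
  structure(!white, white_threshold = white_threshold)
}

#' Tissue bounding box
#'
#' Tightest axis-aligned rectangle containing all tissue pixels,
#' as `c(row0, col0, row1, col1)`, 1-based inclusive.
#'
#' @param mask Logical tissue mask (`TRUE` = tissue).
#' @return Integer vector `c(row0, col0, row1, col1)`.
#' @export
tissue_bounding_box <- function(mask) {
  if (!any(mask)) stop("no tissue pixels in mask")
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  c(row0 = rows[1], col0 = cols[1],
    row1 = rows[length(rows)], col1 = cols[length(cols)])
}

#' Read a slide image from disk
#'
#' Reads an RGB TIFF (all directories of a multi-page/pyramidal file) or a
#' PNG into a `slide_pyramid`. Pages whose dimensions are integer fractions
#' of the largest page are treated as pyramid levels; intensities are
#' rescaled to 0..255.
#'
#' @param path File path (`.tif`, `.tiff` or `.png`).
#' @param native_mpp Microns per pixel of the largest level (default 0.22).
#' @return A `slide_pyramid`.
#' @export
read_slide <- function(path, native_mpp = 0.22) {
  ext <- tolower(tools::file_ext(path))
  pages <- if (ext %in% c("tif", "tiff")) {
    p <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(p)) list(p) else p
  } else if (ext == "png") {
    list(png::readPNG(path))
  } else stop("unsupported slide format: .", ext)
  pages <- lapply(pages, function(x) {
    if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
    if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
    x * 255
  })
  nr0 <- max(vapply(pages, function(x) dim(x)[1], integer(1)))
  planes <- lapply(pages, function(x) {
    f <- nr0 / dim(x)[1]
    slide_plane(x, mpp = native_mpp * f, downsample = f)
  })
  slide_pyramid(planes, native_mpp = native_mpp)
}

#' Write a single-plane RGB TIFF
#' @param pixels RGB array on the 0..255 scale.
#' @param path Output path.
#' @export
write_rgb_tiff <- function(pixels, path) {
  stopifnot_rgb(pixels)
  tiff::writeTIFF(pmin(pmax(pixels / 255, 0), 1), path, bits.per.sample = 8L)
  invisible(path)
}
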