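#' Stain matrices for colour deconvolution
#'
#' A stain matrix holds one unit-norm optical-density vector per row
#' (RGB components in columns). `stain_matrix_he()` returns the standard
#' Ruifrok-Johnston haematoxylin/eosin basis completed with an orthogonal
#' residual vector; `stain_matrix_hdab()` the haematoxylin/DAB basis used for
#' immunohistochemistry. `stain_matrix()` validates a user-supplied 3x3
#' matrix (rows are renormalised to unit length).
#'
#' @param m Numeric 3x3 matrix, rows = stain OD vectors in RGB order.
#' @param names Character vector of three stain names.
#' @return A 3x3 numeric matrix of class `stain_matrix` with unit-norm rows.
#' @export
stain_matrix <- function(m, names = rownames(m)) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L))) stop("stain matrix must be 3x3")
  if (is.null(names)) names <- c("stain1", "stain2", "stain3")
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < 1e-8)) stop("stain matrix has a zero row")
  m <- m / nrm
  if (abs(det(m)) < 1e-8) stop("stain matrix is singular")
  dimnames(m) <- list(names, c("R", "G", "B"))
  class(m) <- c("stain_matrix", "matrix", "array")
  m
}

#' @rdname stain_matrix
#' @export
stain_matrix_he <- function() {
  h <- c(0.65, 0.70, 0.29)
  e <- c(0.07, 0.99, 0.11)
  r <- pracma_cross(h, e)
  stain_matrix(rbind(h, e, r), names = c("H", "E", "residual"))
}

#' @rdname stain_matrix
#' @export
stain_matrix_hdab <- function() {
  h <- c(0.65, 0.70, 0.29)
  d <- c(0.27, 0.57, 0.78)
  r <- pracma_cross(h, d)
  stain_matrix(rbind(h, d, r), names = c("H", "DAB", "residual"))
}

# cross product (avoids a dependency for three lines of algebra)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' RGB to optical density and back
#'
#' Converts transmitted-light intensities to optical densities with the
#' Beer-Lambert relation `OD = -log(I / I0)` (natural log, `I0` the white
#' background intensity). Intensities are floored at `background / 255`
#' before the log so a zero pixel maps to a large finite OD.
#'
#' @param plane RGB array (rows x cols x 3), intensities in
#'   `[0, background]`.
#' @param od OD array as produced by `rgb_to_od()`.
#' @param background Scalar background (white) intensity, default 255.
#' @return `rgb_to_od()`: nonnegative OD array of the same shape.
#'   `od_to_rgb()`: RGB array with intensities in `[0, background]`.
#' @export
rgb_to_od <- function(plane, background = 255) {
  stopifnot_rgb(plane, "rgb_to_od() input")
  floor_i <- background / 255
  -log(pmax(plane, floor_i) / background)
}

#' @rdname rgb_to_od
#' @export
od_to_rgb <- function(od, background = 255) {
  pmin(pmax(background * exp(-od), 0), background)
}

#' Colour deconvolution into stain channels
#'
#' Solves, per pixel, `od = c %*% m` for the stain concentration vector `c`.
#' With a full-rank 3x3 stain matrix this is the exact least-squares
#' solution. Channels are returned in the row order of `m`.
#'
#' @param od OD array (rows x cols x 3).
#' @param m A [stain_matrix].
#' @param clip_negative Cap concentrations at 0 (default `TRUE`); set
#'   `FALSE` for exact algebraic round trips.
#' @return Object of class `stain_channels`: a named list of concentration
#'   matrices (one per stain) with attribute `stain_matrix`.
#' @export
deconvolve <- function(od, m, clip_negative = TRUE) {
  stopifnot_rgb(od, "deconvolve() input")
  if (!inherits(m, "stain_matrix")) m <- stain_matrix(m)
  d <- dim(od)
  px <- matrix(od, ncol = 3L)            # pixels x RGB
  conc <- px %*% solve(m)                # od = c %*% m  =>  c = od %*% m^-1
  if (clip_negative) conc <- pmax(conc, 0)
  ch <- lapply(seq_len(3L), function(j) matrix(conc[, j], d[1], d[2]))
  names(ch) <- rownames(m)
  structure(ch, stain_matrix = m, class = "stain_channels")
}

#' Reconstruct an OD raster from stain channels
#'
#' Inverse of [deconvolve()]: `od = c %*% m` per pixel.
#'
#' @param channels A `stain_channels` object.
#' @param m Stain matrix; defaults to the one stored on `channels`.
#' @return OD array (rows x cols x 3).
#' @export
reconstruct_od <- function(channels, m = attr(channels, "stain_matrix")) {
  d <- dim(channels[[1]])
  conc <- vapply(channels, as.vector, numeric(prod(d)))
  od <- conc %*% m
  array(od, c(d, 3L))
}

#' Per-stain channel perturbation
#'
#' Linearly rescales and shifts individual stain concentration channels
#' (`c' = c * scale + shift`), emulating slide-to-slide variation in
#' staining intensity. Intended as a data-augmentation utility for patch
#' classifiers and for phantom variation.
#'
#' @param channels A `stain_channels` object.
#' @param scale Numeric scalar or per-stain vector of multipliers (> 0).
#' @param shift Numeric scalar or per-stain vector of offsets.
#' @return Perturbed `stain_channels`.
#' @export
hed_perturb <- function(channels, scale = 1, shift = 0) {
  k <- length(channels)
  scale <- rep_len(scale, k); shift <- rep_len(shift, k)
  if (any(scale <= 0)) stop("scales must be > 0")
  out <- channels
  for (i in seq_len(k)) out[[i]] <- channels[[i]] * scale[i] + shift[i]
  out
}
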