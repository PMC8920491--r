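#' Superpixel configuration
#'
#' Parameters of the stain-aware SLIC segmentation at the analysis
#' resolution. Defaults follow the reference pipeline: average superpixel
#' size 3600 px (a square superpixel covers 0.2 x 0.2 mm at 3.54 um/px),
#' Gaussian smoothing sigma 5 px applied to the stain channels, and 10
#' k-means iterations. `compactness` weights the spatial term against the
#' stain term (stain channels are standardised to unit variance per slide
#' before clustering); `background_fraction` is the white-pixel fraction at
#' or above which a superpixel is labelled background.
#'
#' @param avg_size_px Target pixels per superpixel (analysis resolution).
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @param iterations Number of SLIC k-means iterations.
#' @param compactness Spatial-vs-stain weighting (> 0).
#' @param background_fraction White fraction for background labelling.
#' @return A `superpixel_config` list.
#' @export
superpixel_config <- function(avg_size_px = 3600, sigma = 5, iterations = 10,
                              compactness = 0.1, background_fraction = 0.5) {
  stopifnot(avg_size_px >= 1, iterations >= 1, compactness > 0,
            background_fraction >= 0, background_fraction <= 1)
  structure(list(avg_size_px = avg_size_px, sigma = sigma,
                 iterations = as.integer(iterations),
                 compactness = compactness,
                 background_fraction = background_fraction),
            class = "superpixel_config")
}

#' Superpixel count rule
#'
#' The SLIC input parameter k is the foreground bounding-box pixel count
#' divided by the target average superpixel size, rounded, and floored
#' at 1.
#'
#' @param pixel_count Pixel count of the foreground bounding box (>= 1).
#' @param avg_size_px Target average superpixel size in pixels (>= 1).
#' @return Integer k >= 1.
#' @export
compute_k <- function(pixel_count, avg_size_px = 3600) {
  if (pixel_count < 1 || avg_size_px < 1)
    stop("pixel_count and avg_size_px must be >= 1")
  max(1L, as.integer(round(pixel_count / avg_size_px)))
}

#' Stain-aware SLIC superpixel segmentation
#'
#' Localised k-means over per-pixel feature vectors `[H, E, x, y]`: the
#' haematoxylin and eosin concentration channels (smoothed with a Gaussian
#' of `cfg$sigma` and standardised to unit variance) replace the usual
#' Lab colour features. Cluster centres start on a regular grid with
#' spacing `S = sqrt(npix / k)`; each of `cfg$iterations` iterations
#' assigns pixels within a 2S window of each centre to the centre with the
#' smallest distance `d = dH^2 + dE^2 + (compactness/S)^2 * (dx^2 + dy^2)`
#' and then recomputes centres. A connectivity pass relabels disconnected
#' fragments to their dominant neighbouring superpixel, so each label is a
#' single connected component. The procedure is deterministic.
#'
#' @param channels `stain_channels` aligned with the plane (first two
#'   channels are used as H and E).
#' @param cfg A [superpixel_config].
#' @param k Number of superpixels (see [compute_k()]).
#' @return A `superpixel_map`: list with `labels` (integer matrix, labels
#'   1..n), `background_ids` (integer vector, filled by
#'   [mark_background()]), `sizes` (named pixel counts), `k`, `cfg`.
#' @export
slic_he <- function(channels, cfg = superpixel_config(), k) {
  h <- channels[[1]]; e <- channels[[2]]
  stopifnot_aligned(h, e, "stain channels")
  nr <- nrow(h); nc <- ncol(h); npix <- nr * nc
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > npix) stop("k exceeds pixel count")

  if (cfg$sigma > 0) {
    h <- EBImage::gblur(h, sigma = cfg$sigma, boundary = "replicate")
    e <- EBImage::gblur(e, sigma = cfg$sigma, boundary = "replicate")
  }
  sdh <- stats::sd(h); sde <- stats::sd(e)
  if (sdh > 1e-12) h <- h / sdh
  if (sde > 1e-12) e <- e / sde

  S <- sqrt(npix / k)
  # regular grid initialisation: grid_r x grid_c >= k centres, then trim
  grid_r <- max(1L, round(nr / S)); grid_c <- max(1L, ceiling(k / grid_r))
  while (grid_r * grid_c < k) grid_c <- grid_c + 1L
  cy <- (seq_len(grid_r) - 0.5) * nr / grid_r
  cx <- (seq_len(grid_c) - 0.5) * nc / grid_c
  centers <- expand.grid(y = cy, x = cx)[seq_len(k), ]
  cyv <- centers$y; cxv <- centers$x
  chv <- h[cbind(pmin(pmax(round(cyv), 1), nr), pmin(pmax(round(cxv), 1), nc))]
  cev <- e[cbind(pmin(pmax(round(cyv), 1), nr), pmin(pmax(round(cxv), 1), nc))]

  ratio2 <- (cfg$compactness / S)^2
  rowpos <- matrix(seq_len(nr), nr, nc)
  colpos <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  labels <- matrix(0L, nr, nc)
  win <- ceiling(2 * S)

  for (it in seq_len(cfg$iterations)) {
    dist <- matrix(Inf, nr, nc)
    for (j in seq_len(k)) {
      r0 <- max(1L, floor(cyv[j] - win)); r1 <- min(nr, ceiling(cyv[j] + win))
      c0 <- max(1L, floor(cxv[j] - win)); c1 <- min(nc, ceiling(cxv[j] + win))
      rr <- r0:r1; cc <- c0:c1
      d <- (h[rr, cc, drop = FALSE] - chv[j])^2 +
           (e[rr, cc, drop = FALSE] - cev[j])^2 +
           ratio2 * (outer((rr - cyv[j])^2, (cc - cxv[j])^2, `+`))
      upd <- d < dist[rr, cc]
      if (any(upd)) {
        dw <- dist[rr, cc]; lw <- labels[rr, cc]
        dw[upd] <- d[upd]; lw[upd] <- j
        dist[rr, cc] <- dw; labels[rr, cc] <- lw
      }
    }
    # any pixel outside every window (degenerate geometry): nearest centre
    if (any(labels == 0L)) {
      idx <- which(labels == 0L)
      for (p in idx) {
        r <- rowpos[p]; ccol <- colpos[p]
        j <- which.min((h[p] - chv)^2 + (e[p] - cev)^2 +
                       ratio2 * ((r - cyv)^2 + (ccol - cxv)^2))
        labels[p] <- j
      }
    }
    lf <- factor(labels, levels = seq_len(k))
    n <- tabulate(labels, k)
    keep <- n > 0
    safe_mean <- function(v) if (length(v)) mean(v) else NA_real_
    cyv2 <- vapply(split(rowpos, lf), safe_mean, numeric(1))
    cxv2 <- vapply(split(colpos, lf), safe_mean, numeric(1))
    chv2 <- vapply(split(h, lf), safe_mean, numeric(1))
    cev2 <- vapply(split(e, lf), safe_mean, numeric(1))
    cyv[keep] <- cyv2[keep]; cxv[keep] <- cxv2[keep]
    chv[keep] <- chv2[keep]; cev[keep] <- cev2[keep]
  }

  for (pass in 1:5) {
    relab <- enforce_connectivity(labels, k)
    if (identical(relab, labels)) break
    labels <- relab
  }
  labels <- compact_labels(labels)
  sizes <- tabulate(labels)
  names(sizes) <- seq_along(sizes)
  structure(list(labels = labels, background_ids = integer(0),
                 sizes = sizes, k = k, cfg = cfg),
            class = "superpixel_map")
}

# Relabel disconnected fragments of each superpixel to the dominant
# neighbouring superpixel (standard SLIC cleanup). 4-connectivity.
enforce_connectivity <- function(labels, k) {
  nr <- nrow(labels); nc <- ncol(labels)
  for (j in seq_len(k)) {
    m <- labels == j
    if (!any(m)) next
    cc <- EBImage::bwlabel(m)
    ncc <- max(cc)
    if (ncc <= 1) next
    sizes <- tabulate(cc[cc > 0], ncc)
    keep <- which.max(sizes)
    for (frag in setdiff(seq_len(ncc), keep)) {
      idx <- which(cc == frag)
      rows <- ((idx - 1L) %% nr) + 1L
      cols <- ((idx - 1L) %/% nr) + 1L
      nb <- c(labels[cbind(pmax(rows - 1L, 1L), cols)],
              labels[cbind(pmin(rows + 1L, nr), cols)],
              labels[cbind(rows, pmax(cols - 1L, 1L))],
              labels[cbind(rows, pmin(cols + 1L, nc))])
      nb <- nb[nb != j & nb > 0L]
      labels[idx] <- if (length(nb)) as.integer(names(which.max(table(nb))))
                     else j  # isolated: keep (single-component case)
    }
  }
  labels
}

# Renumber labels to 1..n with no gaps, preserving order of first use.
compact_labels <- function(labels) {
  u <- sort(unique(as.vector(labels)))
  u <- u[u > 0L]
  map <- integer(max(u)); map[u] <- seq_along(u)
  out <- labels
  out[labels > 0L] <- map[labels[labels > 0L]]
  out
}

#' Label background superpixels
#'
#' A superpixel is background iff its fraction of white (non-tissue) pixels
#' is at least `fraction`. Background superpixels are excluded from all
#' later classification.
#'
#' @param spmap A `superpixel_map`.
#' @param fg Logical tissue mask aligned with `spmap$labels`.
#' @param fraction White-pixel fraction threshold (default from config).
#' @return The `superpixel_map` with `background_ids` filled in.
#' @export
mark_background <- function(spmap, fg, fraction = spmap$cfg$background_fraction) {
  stopifnot_aligned(spmap$labels, fg, "superpixel map and mask")
  n <- length(spmap$sizes)
  lab <- spmap$labels
  white_per_sp <- tabulate(lab[!fg & lab > 0L], n)
  frac <- white_per_sp / as.numeric(spmap$sizes)
  spmap$background_ids <- which(frac >= fraction)
  spmap
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat("superpixel_map:", length(x$sizes), "superpixels (",
      length(x$background_ids), "background ), plane",
      nrow(x$labels), "x", ncol(x$labels), "\n")
  invisible(x)
}
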