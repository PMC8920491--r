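#' Native-resolution patch grid
#'
#' Non-overlapping square tiling of a native-resolution bounding box,
#' anchored at the box's top-left corner; partial edge tiles are dropped.
#' The default 224 px patch side corresponds to the input size of typical
#' CNN classifiers and, at downsample 16, maps each patch onto an integer
#' 14 x 14 block of the analysis plane.
#'
#' @param bbox Native-resolution box `c(row0, col0, row1, col1)`,
#'   1-based inclusive.
#' @param patch_size Patch side in native pixels (default 224).
#' @return A `patch_grid`: list with `patch_size`, `origin` (row, col of
#'   the first patch), `n_rows`, `n_cols`.
#' @export
build_grid <- function(bbox, patch_size = 224) {
  h <- bbox[3] - bbox[1] + 1L; w <- bbox[4] - bbox[2] + 1L
  if (h < 1 || w < 1) stop("empty bounding box")
  n_rows <- h %/% patch_size; n_cols <- w %/% patch_size
  if (n_rows < 1 || n_cols < 1)
    warning("bounding box smaller than one patch: empty grid")
  structure(list(patch_size = as.integer(patch_size),
                 origin = c(row = as.integer(bbox[1]), col = as.integer(bbox[2])),
                 n_rows = as.integer(max(n_rows, 0)),
                 n_cols = as.integer(max(n_cols, 0))),
            class = "patch_grid")
}

#' Assign patches to superpixels by coverage
#'
#' Each patch corresponds to a block of the analysis-plane superpixel map
#' (block side `patch_size / downsample`). The superpixel occupying the
#' largest share of that block is found; the patch is assigned iff this
#' share is at least `threshold` and the superpixel is not background.
#' Ties at the maximal share go to the lower superpixel id.
#'
#' @param grid A `patch_grid` at native resolution.
#' @param spmap A `superpixel_map` at analysis resolution; its `labels`
#'   raster must cover the grid footprint (same bounding-box crop).
#' @param downsample Native-to-analysis factor (default 16).
#' @param threshold Minimum coverage fraction (default 0.5).
#' @return A `patch_assignment` data.frame with columns `patch_row`,
#'   `patch_col` (grid indices), `superpixel_id` (NA when unassigned),
#'   `coverage`.
#' @export
assign_patches <- function(grid, spmap, downsample = 16, threshold = 0.5) {
  block <- grid$patch_size / downsample
  if (block != round(block))
    stop("patch_size must be divisible by the analysis downsample")
  block <- as.integer(block)
  lab <- spmap$labels
  need_r <- grid$n_rows * block; need_c <- grid$n_cols * block
  if (nrow(lab) < need_r || ncol(lab) < need_c)
    stop("superpixel map does not cover the patch-grid footprint")
  bg <- spmap$background_ids
  n <- grid$n_rows * grid$n_cols
  out <- data.frame(patch_row = integer(n), patch_col = integer(n),
                    superpixel_id = NA_integer_, coverage = NA_real_)
  i <- 0L
  for (pc in seq_len(grid$n_cols)) {
    for (pr in seq_len(grid$n_rows)) {
      i <- i + 1L
      rr <- ((pr - 1L) * block + 1L):(pr * block)
      cc <- ((pc - 1L) * block + 1L):(pc * block)
      tab <- tabulate(lab[rr, cc])
      if (!length(tab)) next
      best <- which.max(tab)               # ties -> lowest id
      share <- tab[best] / (block * block)
      out$patch_row[i] <- pr; out$patch_col[i] <- pc
      out$coverage[i] <- share
      if (share >= threshold && !(best %in% bg))
        out$superpixel_id[i] <- best
    }
  }
  out$patch_row <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  out$patch_col <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  structure(out, grid = grid, threshold = threshold,
            downsample = downsample, class = c("patch_assignment", "data.frame"))
}

#' Random patch subsampling with a per-superpixel budget
#'
#' For every superpixel with more than `limit` assigned patches, a uniform
#' random subset of size `limit` is drawn without replacement; smaller
#' superpixels keep all their patches. Sampling uses a per-superpixel
#' random stream derived from `seed` and the superpixel id, so the result
#' is independent of processing order.
#'
#' @param assignment A `patch_assignment`.
#' @param limit Maximum patches per superpixel (default 10). `Inf`
#'   disables the budget.
#' @param seed Integer RNG seed.
#' @return A `patch_sample` data.frame (subset of assigned rows) with
#'   attributes `limit` and `seed`.
#' @export
sample_patches <- function(assignment, limit = 10, seed = 1L) {
  if (limit < 1) stop("limit must be >= 1")
  asg <- assignment[!is.na(assignment$superpixel_id), , drop = FALSE]
  keep <- logical(nrow(asg))
  for (id in sort(unique(asg$superpixel_id))) {
    idx <- which(asg$superpixel_id == id)
    if (length(idx) <= limit) {
      keep[idx] <- TRUE
    } else {
      old <- .Random.seed.exists()
      set.seed(derive_seed(seed, id))
      keep[sample(idx, limit)] <- TRUE
      .Random.seed.restore(old)
    }
  }
  out <- asg[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, limit = limit, seed = seed,
            class = c("patch_sample", "data.frame"))
}

# save/restore the global RNG state so sampling does not disturb callers
.Random.seed.exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Extract native-resolution pixels of a sampled patch
#'
#' @param native_pixels Native RGB array (full plane, uncropped).
#' @param grid The `patch_grid` the sample was built on.
#' @param patch_row,patch_col Grid indices of the patch.
#' @return RGB array `patch_size x patch_size x 3`.
#' @export
extract_patch <- function(native_pixels, grid, patch_row, patch_col) {
  ps <- grid$patch_size
  r0 <- grid$origin["row"] + (patch_row - 1L) * ps
  c0 <- grid$origin["col"] + (patch_col - 1L) * ps
  native_pixels[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L), , drop = FALSE]
}
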