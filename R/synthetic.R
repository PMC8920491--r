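#' Phantom specification
#'
#' Describes a synthetic multi-class slide phantom: per-class mean
#' haematoxylin/eosin optical densities with a texture-noise standard
#' deviation, a region process (`"voronoi"` seed tessellation or
#' `"halves"`, a vertical split over the first two classes), optional
#' white background frame and fissure lines, image size and seed. The
#' default seven classes mirror a colorectal tissue legend (tumour cells,
#' muscle, connective/adipose, mucosa, necrosis, inflammation, mucus)
#' with distinct H/E density pairs.
#'
#' Defaults emulate the reference imaging setup at desk scale: native
#' 3584 x 3584 px at 0.22 um/px; the 16x analysis plane is 224 x 224 px.
#'
#' @param classes data.frame with columns `name`, `h`, `e`, `noise_sd`
#'   (ODs >= 0); default 7-class legend.
#' @param size_native Native image side in pixels (multiple of
#'   `downsample`).
#' @param downsample Native-to-analysis factor (default 16).
#' @param region_process `"voronoi"` or `"halves"`.
#' @param region_scale Approximate region diameter in analysis pixels
#'   (controls the number of Voronoi seeds); must be smaller than the
#'   analysis side.
#' @param n_region_classes Number of leading classes the region process
#'   draws from (default: all).
#' @param background_frame White frame width in analysis px (0 disables).
#' @param fissures Number of white fissure lines (0 disables).
#' @param native_mpp Microns per pixel at native resolution.
#' @param seed Integer seed; the phantom is deterministic given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(classes = default_phantom_classes(),
                         size_native = 3584, downsample = 16,
                         region_process = c("voronoi", "halves"),
                         region_scale = 112,
                         n_region_classes = nrow(classes),
                         background_frame = 4, fissures = 1,
                         native_mpp = 0.22, seed = 1L) {
  region_process <- match.arg(region_process)
  stopifnot(nrow(classes) >= 2, region_scale > 0,
            all(classes$h >= 0), all(classes$e >= 0),
            size_native %% downsample == 0)
  size_analysis <- size_native %/% downsample
  if (region_scale >= size_analysis)
    stop("region scale must be smaller than the analysis-plane side")
  structure(list(classes = classes, size_native = as.integer(size_native),
                 downsample = as.integer(downsample),
                 size_analysis = as.integer(size_analysis),
                 region_process = region_process,
                 region_scale = region_scale,
                 n_region_classes = min(n_region_classes, nrow(classes)),
                 background_frame = as.integer(background_frame),
                 fissures = as.integer(fissures),
                 native_mpp = native_mpp, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_phantom_classes <- function() {
  data.frame(
    name = names(default_classes()),
    h = c(0.85, 0.35, 0.15, 0.55, 0.10, 1.10, 0.18),
    e = c(0.35, 0.90, 0.45, 0.75, 0.95, 0.25, 0.05),
    noise_sd = 0.04
  )
}

#' Generate a slide phantom with exact ground truth
#'
#' Draws an analysis-resolution class-label map with the configured region
#' process, stamps white background (frame and fissures), upsamples labels
#' to native resolution and renders RGB per pixel by the Beer-Lambert law
#' from the class H/E optical densities plus Gaussian texture noise.
#' White background renders at intensity 255. Deterministic under the
#' spec's seed.
#'
#' @param spec A [phantom_spec].
#' @return List: `pyramid` (a `slide_pyramid` holding the native plane),
#'   `gt` (integer analysis-resolution label raster, 0 = background),
#'   `spec`.
#' @export
make_phantom <- function(spec) {
  old <- .Random.seed.exists()
  on.exit(.Random.seed.restore(old))
  set.seed(spec$seed)
  na <- spec$size_analysis
  K <- spec$n_region_classes

  gt <- if (spec$region_process == "halves") {
    g <- matrix(1L, na, na)
    g[, (na %/% 2 + 1L):na] <- 2L
    g
  } else {
    n_seeds <- max(K, round((na / spec$region_scale)^2))
    sy <- runif(n_seeds, 1, na); sx <- runif(n_seeds, 1, na)
    scls <- c(seq_len(K), sample.int(K, n_seeds - K, replace = TRUE))
    rows <- matrix(seq_len(na), na, na)
    cols <- matrix(seq_len(na), na, na, byrow = TRUE)
    best <- matrix(Inf, na, na); lab <- matrix(1L, na, na)
    for (s in seq_len(n_seeds)) {
      d <- (rows - sy[s])^2 + (cols - sx[s])^2
      upd <- d < best
      best[upd] <- d[upd]; lab[upd] <- scls[s]
    }
    lab
  }

  if (spec$background_frame > 0) {
    f <- spec$background_frame
    gt[c(seq_len(f), (na - f + 1L):na), ] <- 0L
    gt[, c(seq_len(f), (na - f + 1L):na)] <- 0L
  }
  if (spec$fissures > 0) {
    for (i in seq_len(spec$fissures)) {
      at <- round(na * i / (spec$fissures + 1)) + sample(-3:3, 1)
      at <- min(max(at, 1L), na)
      gt[, pmin(pmax(at + (-1:1), 1L), na)] <- 0L
    }
  }

  # render native RGB from upsampled labels
  up <- gt[rep(seq_len(na), each = spec$downsample),
           rep(seq_len(na), each = spec$downsample)]
  nn <- spec$size_native
  hmean <- c(0, spec$classes$h)[up + 1L]   # background -> 0 OD
  emean <- c(0, spec$classes$e)[up + 1L]
  nsd <- c(0, spec$classes$noise_sd)[up + 1L]
  hod <- hmean + rnorm(nn * nn) * nsd
  eod <- emean + rnorm(nn * nn) * nsd
  hod[hod < 0] <- 0
  eod[eod < 0] <- 0
  m <- stain_matrix_he()
  rgb <- 255 * exp(-(cbind(hod, eod) %*% m[1:2, ]))  # OD >= 0 so rgb in (0,255]
  dim(rgb) <- c(nn, nn, 3L)
  plane <- slide_plane(rgb, mpp = spec$native_mpp, downsample = 1)
  list(pyramid = slide_pyramid(list(plane), native_mpp = spec$native_mpp),
       gt = gt, spec = spec)
}

#' Oracle noise specification
#'
#' @param mode `"none"`, `"symmetric"` (with probability `epsilon` the
#'   patch's vector is replaced by a smoothed one-hot on a class drawn
#'   uniformly from all K classes — standard symmetric label noise, so the
#'   per-patch accuracy is `1 - epsilon + epsilon/K`) or `"confusion"`
#'   (the replacement class is drawn from the row of `confusion` for the
#'   true class).
#' @param epsilon Corruption probability in `[0, 1]`.
#' @param confusion K x K row-stochastic matrix (mode `"confusion"`).
#' @param temperature Softmax temperature of the clean classifier.
#' @return An `oracle_noise` list.
#' @export
oracle_noise <- function(mode = c("none", "symmetric", "confusion"),
                         epsilon = 0, confusion = NULL, temperature = 0.025) {
  mode <- match.arg(mode)
  if (mode == "confusion") {
    if (is.null(confusion) || any(abs(rowSums(confusion) - 1) > 1e-6))
      stop("confusion mode needs a row-stochastic matrix")
  }
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  structure(list(mode = mode, epsilon = epsilon, confusion = confusion,
                 temperature = temperature),
            class = "oracle_noise")
}

#' Oracle patch classifier for phantoms
#'
#' Builds a classifier under the patch-probability protocol that knows
#' the phantom's class stain densities: for each patch it computes the
#' mean optical density, deconvolves it into mean H/E concentrations,
#' and emits a temperature-scaled softmax over negative Euclidean
#' distances to the class (H, E) centroids. The configured noise is then
#' applied per patch using a dedicated RNG stream (seeded from `seed`),
#' so the classifier is deterministic for a given construction.
#'
#' @param spec A [phantom_spec] (provides the class centroids).
#' @param noise An [oracle_noise].
#' @param seed Seed of the classifier's private noise stream.
#' @return Function `patches -> probability matrix` usable with
#'   [classify_patches()].
#' @export
oracle_classifier <- function(spec, noise = oracle_noise("none"), seed = 1L) {
  centroids <- as.matrix(spec$classes[, c("h", "e")])
  K <- nrow(centroids)
  m <- stain_matrix_he()
  minv <- solve(m)
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  function(patches) {
    if (!length(patches)) return(matrix(numeric(0), 0L, K))
    probs <- matrix(0, length(patches), K)
    for (i in seq_along(patches)) {
      mu <- apply(patches[[i]], 3L, mean)
      od <- -log(pmax(mu, 1) / 255)
      conc <- pmax(as.vector(od %*% minv), 0)[1:2]
      d <- sqrt(rowSums((centroids - rep(conc, each = K))^2))
      z <- exp(-(d - min(d)) / noise$temperature)
      probs[i, ] <- z / sum(z)
    }
    if (noise$mode != "none" && noise$epsilon > 0) {
      old <- .Random.seed.exists()
      set.seed(derive_seed(seed, counter$n))
      counter$n <- counter$n + length(patches)
      flip <- runif(nrow(probs)) < noise$epsilon
      for (i in which(flip)) {
        repl <- if (noise$mode == "symmetric") {
          sample.int(K, 1L)
        } else {
          true_cls <- which.max(probs[i, ])
          sample.int(K, 1L, prob = noise$confusion[true_cls, ])
        }
        v <- rep(0.02 / (K - 1), K); v[repl] <- 0.98
        probs[i, ] <- v / sum(v)
      }
      .Random.seed.restore(old)
    }
    probs
  }
}
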