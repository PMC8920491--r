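# One-slot phantom cache: full-scale phantoms are expensive to render and a
# native plane is ~300 MB, so only the most recently used phantom is kept —
# experiment loops that run the pipeline twice on the same phantom reuse it,
# while sweeps over seeds release each phantom before the next.
.phantom_slot <- new.env(parent = emptyenv())

cached_phantom <- function(spec) {
  key <- paste(spec$region_process, spec$size_native, spec$region_scale,
               spec$n_region_classes, spec$seed, sep = "_")
  if (!identical(.phantom_slot$key, key)) {
    .phantom_slot$value <- NULL
    .phantom_slot$value <- make_phantom(spec)
    .phantom_slot$key <- key
  }
  .phantom_slot$value
}

# Default-conditions phantom (voronoi, native 3584, 16x analysis 224x224)
default_phantom <- function(seed) cached_phantom(phantom_spec(seed = seed))

# Large-region phantom for end-to-end recovery: region scale 3x the
# superpixel scale (sqrt(3600) = 60 px -> 180 px), three classes.
recovery_phantom <- function(seed) {
  cached_phantom(phantom_spec(region_scale = 180, n_region_classes = 3,
                              seed = seed))
}

# Small flat-colour slide pyramid for plumbing tests
flat_pyramid <- function(nr = 64, nc = 64, rgb = c(180, 120, 160),
                         native_mpp = 0.22) {
  px <- array(rep(rgb, each = nr * nc), c(nr, nc, 3))
  slide_pyramid(list(slide_plane(px, native_mpp, 1)), native_mpp)
}

# Random softmax matrix (n patches x K classes)
random_probs <- function(n, K) {
  p <- matrix(stats::rexp(n * K), n, K)
  p / rowSums(p)
}

# Run the full cartography pipeline on a phantom with its oracle
run_phantom <- function(ph, noise = oracle_noise("none"), seed = ph$spec$seed,
                        patch_limit = 10, rejection_threshold = 0.1) {
  clf <- oracle_classifier(ph$spec, noise, seed = seed)
  cfg <- pipeline_config(seed = seed, patch_limit = patch_limit,
                         rejection_threshold = rejection_threshold)
  run_cartography(ph$pyramid, clf, cfg)
}
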