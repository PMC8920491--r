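small_spec <- function(...) {
  phantom_spec(size_native = 1024, region_scale = 24, background_frame = 2,
               fissures = 1, ...)
}

test_that("phantoms are deterministic and carry exact ground truth", {
  p1 <- make_phantom(small_spec(seed = 3))
  p2 <- make_phantom(small_spec(seed = 3))
  expect_identical(p1$gt, p2$gt)
  expect_identical(p1$pyramid$planes[[1]]$pixels, p2$pyramid$planes[[1]]$pixels)
  p3 <- make_phantom(small_spec(seed = 4))
  expect_false(identical(p1$gt, p3$gt))
  expect_equal(dim(p1$gt), c(64L, 64L))
  expect_true(all(p1$gt >= 0 & p1$gt <= 7))
})

test_that("a halves phantom splits the plane vertically in the ground truth", {
  ph <- make_phantom(phantom_spec(size_native = 640, region_process = "halves",
                                  region_scale = 10, background_frame = 0,
                                  fissures = 0))
  gt <- ph$gt
  expect_true(all(gt[, 1:20] == 1L))
  expect_true(all(gt[, 21:40] == 2L))
})

test_that("background regions render white and are detected as background", {
  ph <- make_phantom(small_spec(seed = 5))
  plane <- select_plane(ph$pyramid, 16)
  fg <- foreground_mask(plane, 220)
  # ground-truth background (frame + fissure) is white after pooling
  expect_true(all(!fg[ph$gt == 0L]))
  # tissue classes render darker than the white threshold
  expect_gt(mean(fg[ph$gt > 0L]), 0.95)
})

test_that("the noise-free oracle is near-certain on pure-class patches", {
  spec <- small_spec(seed = 6)
  clf <- oracle_classifier(spec)
  # render pure patches directly from class densities
  m <- stain_matrix_he()
  patches <- lapply(seq_len(nrow(spec$classes)), function(ci) {
    od <- outer(rep(1, 32 * 32), c(spec$classes$h[ci], spec$classes$e[ci])) %*%
      m[1:2, ]
    array(255 * exp(-od), c(32, 32, 3))
  })
  p <- classify_patches(clf, patches, nrow(spec$classes))
  for (ci in seq_along(patches)) expect_gte(p[ci, ci], 0.99)
})

test_that("symmetric label noise hits the expected long-run accuracy", {
  spec <- small_spec(seed = 7)
  K <- nrow(spec$classes)
  m <- stain_matrix_he()
  pure <- function(ci) {
    od <- outer(rep(1, 16), c(spec$classes$h[ci], spec$classes$e[ci])) %*% m[1:2, ]
    array(255 * exp(-od), c(4, 4, 3))
  }
  n <- 600
  patches <- lapply(rep(1, n), pure)      # all truly class 1
  # epsilon = 1: every patch re-labelled uniformly over K classes
  clf1 <- oracle_classifier(spec, oracle_noise("symmetric", epsilon = 1),
                            seed = 11)
  acc1 <- mean(apply(classify_patches(clf1, patches, K), 1, which.max) == 1)
  se <- sqrt((1 / K) * (1 - 1 / K) / n)
  expect_lt(abs(acc1 - 1 / K), 3 * se)
  # epsilon = 0.2: accuracy 1 - eps + eps/K
  clf2 <- oracle_classifier(spec, oracle_noise("symmetric", epsilon = 0.2),
                            seed = 12)
  acc2 <- mean(apply(classify_patches(clf2, patches, K), 1, which.max) == 1)
  p_exp <- 1 - 0.2 + 0.2 / K
  expect_lt(abs(acc2 - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("fusion lifts superpixel accuracy above patch accuracy under noise", {
  # pure vote-level simulation: 500 superpixels x 10 patches, eps = 0.2
  K <- 7; eps <- 0.2
  gains <- vapply(1:20, function(s) {
    set.seed(derive <- 1000 + s)
    n_sp <- 500; n_patch <- 10
    patch_correct <- 0; sp_correct <- 0
    for (i in seq_len(n_sp)) {
      true_cls <- sample.int(K, 1)
      probs <- matrix(0, n_patch, K)
      for (j in seq_len(n_patch)) {
        cls <- if (runif(1) < eps) sample.int(K, 1) else true_cls
        v <- rep(0.02 / (K - 1), K); v[cls] <- 0.98
        probs[j, ] <- v
      }
      patch_correct <- patch_correct +
        sum(apply(probs, 1, which.max) == true_cls)
      sp_correct <- sp_correct + (fuse(probs)$label == true_cls)
    }
    sp_correct / n_sp - patch_correct / (n_sp * n_patch)
  }, numeric(1))
  expect_gt(mean(gains), 0)
  expect_gt(mean(gains > 0), 0.9)   # gain in nearly every replicate
})

test_that("phantom spec validation rejects degenerate geometry", {
  expect_error(phantom_spec(size_native = 320, region_scale = 40), "smaller")
  expect_error(phantom_spec(size_native = 1000), "downsample")
})
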