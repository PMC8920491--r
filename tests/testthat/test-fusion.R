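test_that("the classifier protocol is validated", {
  ok <- function(patches) random_probs(length(patches), 3)
  patches <- replicate(4, array(runif(12), c(2, 2, 3)), simplify = FALSE)
  set.seed(1)
  p <- classify_patches(ok, patches, 3)
  expect_equal(dim(p), c(4L, 3L))
  expect_equal(classify_patches(ok, list(), 3), matrix(numeric(0), 0, 3))
  bad_sum <- function(patches) matrix(0.5, length(patches), 3)
  expect_error(classify_patches(bad_sum, patches, 3), "sum to 1")
  bad_dim <- function(patches) random_probs(length(patches), 4)
  expect_error(classify_patches(bad_dim, patches, 3), "protocol")
})

test_that("softmax fusion averages patch vectors and takes the argmax", {
  f <- fuse(matrix(c(0.7, 0.2, 0.1), 1))
  expect_equal(f$label, 1L)
  expect_equal(unname(f$mean_vector), c(0.7, 0.2, 0.1))
  f2 <- fuse(rbind(c(0.6, 0.4), c(0.2, 0.8)))
  expect_equal(unname(f2$mean_vector), c(0.4, 0.6))
  expect_equal(f2$label, 2L)
  expect_error(fuse(matrix(numeric(0), 0, 3)), "empty")
})

test_that("fusion matches a brute-force summation oracle and is invariant", {
  set.seed(77)
  p <- random_probs(50, 7)
  f <- fuse(p)
  # independent oracle: explicit elementwise summation loop
  acc <- numeric(7)
  for (i in 1:50) for (j in 1:7) acc[j] <- acc[j] + p[i, j]
  acc <- acc / 50
  expect_equal(unname(f$mean_vector), acc, tolerance = 1e-12)
  expect_equal(f$label, which.max(acc))
  # permutation invariance
  fp <- fuse(p[sample(50), ])
  expect_equal(fp$mean_vector, f$mean_vector, tolerance = 1e-12)
  expect_equal(fp$label, f$label)
  # duplicating every vector changes nothing
  fd <- fuse(rbind(p, p))
  expect_equal(fd$mean_vector, f$mean_vector, tolerance = 1e-12)
})

test_that("vote-difference confidence matches its definition and bounds", {
  onehot <- function(k, K = 3) { v <- rep(0, K); v[k] <- 1; v }
  votes <- function(counts) do.call(rbind, lapply(
    rep(seq_along(counts), counts), onehot))
  expect_equal(vote_confidence(votes(c(7, 2, 1))), 0.5)
  expect_equal(vote_confidence(votes(c(10, 0, 0))), 1)
  expect_equal(vote_confidence(votes(c(5, 5, 0))), 0)
  expect_equal(vote_confidence(votes(c(4, 0, 0))), 1)  # unanimous, v2 = 0
  set.seed(88)
  for (i in 1:20) {
    c_ <- vote_confidence(random_probs(sample(1:30, 1), 5))
    expect_gte(c_, 0); expect_lte(c_, 1)
  }
})

test_that("rejection is strict and monotone in the threshold", {
  lab <- data.frame(id = 1:4, label = c(1L, 2L, 1L, NA),
                    N = c(10L, 10L, 10L, 0L),
                    confidence = c(0.05, 0.1, 0.8, NA),
                    status = c("LABELED", "LABELED", "LABELED", "UNCLASSIFIED"))
  class(lab) <- c("superpixel_labeling", "data.frame")
  r <- apply_rejection(lab, 0.1)
  expect_equal(r$status, c("REJECTED", "LABELED", "LABELED", "UNCLASSIFIED"))
  expect_equal(apply_rejection(lab, 0)$status[1], "LABELED")
  expect_error(apply_rejection(lab, 1.5), "\\[0, 1\\]")
  # monotone growth of the rejected set
  prev <- 0L
  for (thr in c(0, 0.05, 0.2, 0.9)) {
    n <- sum(apply_rejection(lab, thr)$status == "REJECTED")
    expect_gte(n, prev); prev <- n
  }
})

test_that("rendered class maps propagate labels and sentinels exactly", {
  labels <- matrix(rep(1:4, each = 25), 10, 10)
  sizes <- tabulate(labels); names(sizes) <- 1:4
  sp <- structure(list(labels = labels, background_ids = 4L, sizes = sizes,
                       k = 4L, cfg = superpixel_config()),
                  class = "superpixel_map")
  lab <- data.frame(id = 1:4, label = c(3L, 3L, 2L, NA),
                    N = c(5L, 5L, 5L, 0L),
                    confidence = c(0.9, 0.05, 0.9, NA),
                    status = c("LABELED", "REJECTED", "LABELED", "BACKGROUND"))
  attr(lab, "class_names") <- paste0("c", 1:3)
  class(lab) <- c("superpixel_labeling", "data.frame")
  cm <- render_class_map(sp, lab, mpp = 3.54)
  sent <- sentinel_codes()
  expect_equal(sum(cm$codes == 3L), 25)                      # sp 1
  expect_equal(sum(cm$codes == sent[["REJECTED"]]), 25)      # sp 2 exactly
  expect_true(all(cm$codes[labels == 2L] == sent[["REJECTED"]]))
  expect_equal(sum(cm$codes == 2L), 25)                      # sp 3
  expect_equal(sum(cm$codes == sent[["BACKGROUND"]]), 25)    # sp 4
  # pixel-count conservation against the sizes table
  expect_equal(length(cm$codes), sum(sizes))
  expect_error(render_class_map(sp, lab[1:3, ]), "missing")
})
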