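classes <- default_classes()
TUM <- classes[["tumor_cells"]]; NEC <- classes[["necrosis"]]
MUC <- classes[["mucus"]]

test_that("adjacent necrosis merges into the tumour mask, distant necrosis does not", {
  codes <- matrix(0L, 40, 40)
  codes[5:20, 5:20] <- TUM
  codes[5:20, 21:26] <- NEC          # touches the tumour block
  codes[30:34, 30:34] <- NEC         # 10+ px away from any tumour
  res <- tumor_area(codes, closing_radius = 2, opening_radius = 1, mpp = 3.54)
  expected <- matrix(FALSE, 40, 40)
  expected[5:20, 5:26] <- TRUE       # tumour + adjacent necrosis, rectangles
  expect_identical(res$mask, expected)
  expect_equal(res$components, 1L)
  expect_equal(res$area_mm2, round(sum(expected) * (3.54 / 1000)^2, 3))
})

test_that("mucus components follow the same adjacency rule", {
  codes <- matrix(0L, 30, 30)
  codes[10:20, 10:20] <- TUM
  codes[21:25, 10:20] <- MUC         # adjacent below
  res <- tumor_area(codes, closing_radius = 2, opening_radius = 1)
  expect_true(all(res$mask[10:25, 10:20]))
  expect_equal(sum(res$mask), 16 * 11)
})

test_that("holes enclosed by tumour are filled by the outer-contour rule", {
  codes <- matrix(0L, 40, 40)
  codes[5:30, 5:30] <- TUM
  codes[12:20, 12:20] <- 0L          # unclassified hole inside the tumour
  res <- tumor_area(codes, closing_radius = 2, opening_radius = 1)
  expect_true(all(res$mask[5:30, 5:30]))   # hole filled
  # a necrosis island fully inside tumour is inside the mask regardless
  codes[12:20, 12:20] <- NEC
  res2 <- tumor_area(codes, closing_radius = 2, opening_radius = 1)
  expect_true(all(res2$mask[5:30, 5:30]))
})

test_that("empty class maps give an empty mask with zero area", {
  res <- tumor_area(matrix(0L, 20, 20), mpp = 3.54)
  expect_false(any(res$mask))
  expect_equal(res$area_mm2, 0)
  expect_equal(res$components, 0L)
})

test_that("growing the tumour class never shrinks the final mask", {
  codes <- matrix(0L, 40, 40)
  codes[10:22, 10:22] <- TUM
  base <- tumor_area(codes, closing_radius = 2, opening_radius = 1)$mask
  codes[10:30, 10:22] <- TUM
  grown <- tumor_area(codes, closing_radius = 2, opening_radius = 1)$mask
  expect_true(all(grown[base]))
})

test_that("overlap metrics follow the IoU and Dice formulas", {
  a <- matrix(FALSE, 10, 10); a[1:5, ] <- TRUE
  expect_equal(overlap(a, a)$iou, 1)
  expect_equal(overlap(a, a)$dice, 1)
  b <- matrix(FALSE, 10, 10); b[6:10, ] <- TRUE
  expect_equal(overlap(a, b)$iou, 0)
  expect_equal(overlap(a, b)$dice, 0)

  e <- matrix(FALSE, 20, 10); e[1:10, ] <- TRUE          # |E| = 100
  g <- matrix(FALSE, 20, 10); g[6:15, ] <- TRUE          # |GT| = 100, int 50
  o <- overlap(e, g)
  expect_equal(o$iou, 1 / 3)
  expect_equal(o$dice, 0.5)
})

test_that("the Dice-IoU identity holds on random mask pairs", {
  set.seed(16)
  for (i in 1:100) {
    a <- matrix(runif(100) < runif(1), 10, 10)
    b <- matrix(runif(100) < runif(1), 10, 10)
    o <- overlap(a, b)
    expect_equal(o$dice, 2 * o$iou / (1 + o$iou), tolerance = 1e-12)
  }
})

test_that("the invasive margin matches a distance-transform oracle within 1 px", {
  n <- 80
  tumor <- matrix(FALSE, n, n); tumor[30:50, 30:50] <- TRUE
  tissue <- matrix(TRUE, n, n)
  w_um <- 10 * 3.54                                    # w = 10 px
  got <- invasive_margin(tumor, tissue, width_um = w_um, mpp = 3.54)
  w <- 10
  d_out <- EBImage::distmap(1 - tumor)   # distance of outside px to tumour
  d_in <- EBImage::distmap(tumor * 1)    # distance of tumour px to outside
  oracle <- (d_out > 0 & d_out <= w) | (tumor & d_in <= w)
  mismatch <- which(got != oracle)
  # disagreement may only occur on the 1-px shell at distance w
  dists <- pmax(d_out[mismatch], d_in[mismatch])
  expect_true(all(abs(dists - w) <= 1.5))
  expect_gt(sum(got & oracle) / sum(got | oracle), 0.95)
})

test_that("margin limiting cases behave", {
  n <- 30
  tissue <- matrix(TRUE, n, n)
  tumor <- tissue                       # tumour fills all tissue
  expect_false(any(invasive_margin(tumor, tissue, 100, 3.54)))
  # width of one pixel hugs the boundary with thickness <= 2 px per side
  tumor2 <- matrix(FALSE, n, n); tumor2[10:20, 10:20] <- TRUE
  m1 <- invasive_margin(tumor2, tissue, 3.54, 3.54)
  d_out <- EBImage::distmap(1 - tumor2); d_in <- EBImage::distmap(tumor2 * 1)
  expect_true(all(pmax(d_out[m1], d_in[m1]) <= 2))
  # margin never leaves tissue
  tissue3 <- matrix(FALSE, n, n); tissue3[1:15, ] <- TRUE
  m3 <- invasive_margin(tumor2, tissue3, 20, 3.54)
  expect_true(all(tissue3[m3]))
})

test_that("composition ratios equal a per-pixel loop oracle", {
  codes <- matrix(0L, 10, 10)
  region <- matrix(TRUE, 10, 10)
  codes[] <- TUM
  c1 <- composition(codes, region)
  expect_equal(c(c1$tumor_ratio, c1$necrosis_ratio, c1$mucus_ratio),
               c(1, 0, 0))
  codes[] <- 0L
  codes[1:60] <- TUM; codes[61:85] <- NEC; codes[86:95] <- MUC
  codes[96:100] <- classes[["muscle"]]
  c2 <- composition(codes, region)
  expect_equal(c(c2$tumor_ratio, c2$necrosis_ratio, c2$mucus_ratio),
               c(0.60, 0.25, 0.10))
  # loop oracle on a random map and partial region
  set.seed(17)
  codes <- matrix(sample(0:7, 400, replace = TRUE), 20, 20)
  region <- matrix(runif(400) < 0.5, 20, 20)
  if (!any(region)) region[1] <- TRUE
  c3 <- composition(codes, region)
  nt <- nn <- nm <- 0; nr <- 0
  for (p in seq_along(codes)) if (region[p]) {
    nr <- nr + 1
    if (codes[p] == TUM) nt <- nt + 1
    if (codes[p] == NEC) nn <- nn + 1
    if (codes[p] == MUC) nm <- nm + 1
  }
  expect_equal(c3$tumor_ratio, nt / nr)
  expect_equal(c3$necrosis_ratio, nn / nr)
  expect_equal(c3$mucus_ratio, nm / nr)
  expect_error(composition(codes, region & FALSE), "empty")
})
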