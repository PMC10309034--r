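test_that("bilinear sampling is exact at grid nodes and zero far outside", {
  set.seed(21)
  x <- matrix(rnorm(30), 5, 6)
  for (i in 0:4) for (j in 0:5)
    expect_identical(bilinearSample(x, c(i, j)), x[i + 1, j + 1])
  expect_equal(bilinearSample(matrix(0:3, 2, 2, byrow = TRUE), c(0.5, 0.5)),
               1.5)
  expect_identical(bilinearSample(x, c(-10, -10)), 0)
})

test_that("zero offsets reduce deformable to standard convolution", {
  set.seed(22)
  for (trial in 1:10) {
    H <- sample(5:9, 1)
    cin <- sample(1:8, 1)
    cout <- sample(1:8, 1)
    x <- array(rnorm(H * H * cin), c(H, H, cin))
    w <- array(rnorm(9 * cin * cout), c(3, 3, cin, cout))
    off <- array(0, c(H, H, 18))
    got <- deformableConv(x, w, off, stride = 1, padding = 1)
    ref <- groupedConv(x, w, groups = 1, stride = 1, padding = 1)
    expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-5)
  }
})

test_that("an all-ones kernel over an all-ones patch sums the taps", {
  x <- array(1, c(3, 3, 1))
  w <- array(1, c(3, 3, 1, 1))
  off <- array(0, c(3, 3, 18))
  y <- deformableConv(x, w, off, stride = 1, padding = 1)
  expect_equal(y[2, 2, 1], 9)
})

test_that("integer offsets equal standard convolution on the shifted input", {
  set.seed(23)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  w <- array(rnorm(9 * 2 * 3), c(3, 3, 2, 3))
  off <- array(0, c(6, 6, 18)) # valid (unpadded) output grid
  off[, , seq(2, 18, by = 2)] <- 1 # every tap shifted one column right
  got <- deformableConv(x, w, off, stride = 1, padding = 0)
  xs <- array(0, dim(x)) # column-shifted input (zeros fill the last column)
  xs[, 1:7, ] <- x[, 2:8, ]
  ref <- groupedConv(xs, w, groups = 1, stride = 1, padding = 0)
  expect_lt(max(abs(got - ref)), 1e-10)
  expect_error(deformableConv(x, w, off[, , 1:4]), "2 \\* kh \\* kw")
})

test_that("the freshly built shape encoder equals its non-deformable twin", {
  cfg <- stnetTinyConfig(seed = 7)
  m <- stnet(cfg)
  img <- randomImage(64, seed = 9)
  fDef <- shapeEncode(m, img)
  plain <- stripDeform(m@modules$shapeEnc)
  fPlain <- stnet:::nnForward(plain, img)$y
  expect_lt(max(abs(fDef - fPlain)), 1e-10)
  expect_identical(dim(fDef), c(8L, 8L, 64L))
  expect_identical(fDef, shapeEncode(m, img)) # determinism
})

test_that("the decoder recovers input resolution with values in [0, 1]", {
  cfg <- stnetTinyConfig(seed = 8)
  m <- stnet(cfg)
  feat <- shapeEncode(m, randomImage(64, seed = 10))
  msk <- shapeDecode(m, feat)
  expect_identical(dim(msk), c(64L, 64L))
  expect_true(all(msk > 0 & msk < 1))
  expect_identical(msk, shapeDecode(m, feat))
  expect_error(shapeDecode(m, feat[, , 1:3]), "channel count")
})

test_that("a zeroed output head yields the constant 0.5 mask", {
  cfg <- stnetTinyConfig(seed = 8)
  m <- stnet(cfg)
  dec <- m@modules$decoder
  headIdx <- length(dec$layers) - 1L # 1x1 conv before the squashing
  dec$layers[[headIdx]]$params$w[] <- 0
  dec$layers[[headIdx]]$params[["b"]][] <- 0
  m@modules$decoder <- dec
  msk <- shapeDecode(m, shapeEncode(m, randomImage(64, seed = 11)))
  expect_true(all(msk == 0.5))
})

test_that("mask supervision reaches the encoder's first convolution", {
  cfg <- stnetTinyConfig(seed = 12)
  m <- stnet(cfg)
  img <- randomImage(64, seed = 13)
  enc <- m@modules$shapeEnc
  dec <- m@modules$decoder
  fe <- stnet:::nnForward(enc, img)
  fd <- stnet:::nnForward(dec, fe$y)
  # L2 pull of the predicted mask toward zero
  gmask <- 2 * fd$y / length(fd$y)
  rd <- stnet:::nnBackward(dec, fd$cache, gmask)
  re <- stnet:::nnBackward(enc, fe$cache, rd$gx)
  gFirst <- stnet:::flattenGrads(enc, re$grads)[["L1.params.w"]]
  expect_gt(max(abs(gFirst)), 0)
})

test_that("zeroing the deepest feature makes the mask input-independent", {
  cfg <- stnetTinyConfig(seed = 14)
  m <- stnet(cfg)
  fA <- shapeEncode(m, randomImage(64, seed = 15))
  fB <- shapeEncode(m, randomImage(64, seed = 16))
  expect_false(isTRUE(all.equal(shapeDecode(m, fA), shapeDecode(m, fB))))
  expect_identical(shapeDecode(m, fA * 0), shapeDecode(m, fB * 0))
})
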