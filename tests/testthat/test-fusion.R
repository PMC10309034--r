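test_that("dual pooling averages the channel mean and max", {
  Z <- array(2, c(3, 3, 2))
  expect_equal(globalDualPool(Z), c(2, 2))
  Z2 <- array(c(1, 2, 3, 6), c(2, 2, 1))
  expect_equal(globalDualPool(Z2), 4.5)
  Z3 <- array(7, c(1, 1, 3))
  expect_equal(globalDualPool(Z3), c(7, 7, 7))
  expect_error(globalDualPool(array(numeric(0), c(0, 2, 1))), "non-empty")
})

test_that("channel attention is bounded and has the 0.5 fixed point", {
  g <- c(0.3, -1.2, 4)
  w1 <- matrix(0, 3, 2)
  w2 <- matrix(0, 2, 3)
  expect_equal(channelAttention(g, w1, w2), rep(0.5, 3))
  set.seed(31)
  for (i in 1:20) {
    c <- sample(2:12, 1)
    h <- sample(1:4, 1)
    watt <- channelAttention(rnorm(c, sd = 3),
                             matrix(rnorm(c * h), c, h),
                             matrix(rnorm(h * c), h, c))
    expect_true(all(watt > 0 & watt < 1))
  }
  # identity transforms at g = 0: sigma(sigma(0)) elementwise
  expect_equal(channelAttention(c(0, 0), diag(2), diag(2)),
               rep(1 / (1 + exp(-0.5)), 2), tolerance = 1e-12)
  expect_error(channelAttention(g, matrix(0, 2, 2), w2), "row per channel")
})

test_that("attention weighting scales channels element-wise", {
  set.seed(32)
  Z <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  expect_identical(applyAttention(Z, c(1, 1)), Z)
  expect_true(all(applyAttention(Z, c(0, 0)) == 0))
  got <- applyAttention(Z, c(0.5, 0.25))
  expect_equal(got[, , 1], Z[, , 1] * 0.5)
  expect_equal(got[, , 2], Z[, , 2] * 0.25)
  expect_error(applyAttention(Z, c(1, 1, 1)), "channel count")
})

test_that("channel attention contracts feature magnitudes", {
  set.seed(33)
  for (i in 1:10) {
    c <- sample(2:8, 1)
    Z <- array(rnorm(16 * c, sd = 2), c(4, 4, c))
    caff <- stnet:::nnCAFF(c, reduction = 2L)
    Zp <- stnet:::caffForward(caff, Z)$y
    expect_true(all(abs(Zp) <= abs(Z)))
  }
})

test_that("gradient scaling is the identity forward and validates its factor", {
  set.seed(34)
  x <- array(rnorm(12), c(2, 2, 3))
  expect_identical(gradientScale(x, 0.25), x)
  expect_error(gradientScale(x, 0), "positive")
  expect_error(gradientScale(x, -1), "positive")
})

test_that("the backward contract multiplies gradients by the factor", {
  # downstream f(x) = sum(x^2): analytic upstream gradient is factor * 2x
  set.seed(35)
  x <- array(c(1, 2, -0.5, 0.3), c(2, 2, 1))
  for (f in c(0.1, 0.5, 1)) {
    gs <- stnet:::nnGScale(f)
    fw <- stnet:::nnForward(gs, x)
    bw <- stnet:::nnBackward(gs, fw$cache, 2 * fw$y)
    expect_equal(as.numeric(bw$gx), f * 2 * as.numeric(x), tolerance = 1e-12)
  }
  # and against finite differences through an arbitrary downstream network
  down <- stnet:::nnSeq(stnet:::nnConv(2, 3, 3), stnet:::nnReLU(),
                        stnet:::nnConv(3, 1, 3))
  xin <- array(rnorm(2 * 5 * 5), c(5, 5, 2))
  fdown <- function(v) sum(stnet:::nnForward(down, array(v, c(5, 5, 2)))$y)
  base <- numericGrad(fdown, as.numeric(xin))
  for (f in c(0.1, 0.5, 1)) {
    net <- stnet:::nnSeq(stnet:::nnGScale(f), down)
    fw <- stnet:::nnForward(net, xin)
    bw <- stnet:::nnBackward(net, fw$cache, array(1, dim(fw$y)))
    expect_equal(as.numeric(bw$gx), f * base, tolerance = 1e-2)
  }
})

test_that("fusion classifies with logistic output and supports ablation", {
  set.seed(36)
  cT <- 3L; cS <- 2L
  tex <- array(rnorm(16 * cT), c(4, 4, cT))
  shpA <- array(rnorm(16 * cS), c(4, 4, cS))
  shpB <- array(rnorm(16 * cS), c(4, 4, cS))
  prm <- list(w1 = matrix(rnorm((cT + cS) * 2), cT + cS, 2),
              w2 = matrix(rnorm(2 * (cT + cS)), 2, cT + cS),
              fcW = rnorm(cT + cS), fcB = 0.3, gradScale = 0.1)
  p <- fuseAndClassify(tex, shpA, prm)
  expect_true(p > 0 && p < 1)
  # zero classifier -> 0.5 regardless of input
  zp <- prm
  zp$fcW <- numeric(cT + cS); zp$fcB <- 0
  expect_equal(fuseAndClassify(tex, shpA, zp), 0.5)
  # masking out the shape channels makes p invariant to the shape input
  mp <- prm
  mp$attnMask <- c(rep(1, cT), rep(0, cS))
  pA <- fuseAndClassify(tex, shpA, mp)
  pB <- fuseAndClassify(tex, shpB, mp)
  expect_identical(pA, pB)
  expect_false(identical(fuseAndClassify(tex, shpA, prm),
                         fuseAndClassify(tex, shpB, prm)))
  expect_error(fuseAndClassify(tex, array(0, c(3, 3, cS)), prm),
               "spatial geometry")
})
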