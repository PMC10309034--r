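test_that("cross-entropy has its closed form and label symmetry", {
  expect_equal(crossEntropy(1, 0.5), log(2), tolerance = 1e-12)
  expect_lt(crossEntropy(1, 1 - 1e-9), 1e-6)
  p <- seq(0.05, 0.95, by = 0.1)
  expect_equal(crossEntropy(rep(1, length(p)), p, reduce = "none"),
               crossEntropy(rep(0, length(p)), 1 - p, reduce = "none"))
  expect_true(all(is.finite(crossEntropy(c(0, 1), c(0, 1), reduce = "none"))))
})

test_that("probability transfer clamps easy negatives to zero", {
  expect_identical(transferProbability(0.03, 0.05), 0)
  expect_identical(transferProbability(0.4, 0), 0.4)
  expect_equal(transferProbability(0.50, 0.05), 0.45)
})

test_that("the asymmetric loss matches independent per-point evaluation", {
  # independent scalar oracle, written out longhand
  oracle <- function(y, p, gp, gm, phi) {
    if (y == 1) {
      (1 - p)^gp * (-log(p))
    } else {
      pt <- if (p - phi > 0) p - phi else 0
      pt^gm * (-log(1 - p))
    }
  }
  grid <- expand.grid(y = c(0, 1), p = seq(0.02, 0.98, length.out = 10),
                      gp = c(0, 1, 2), gm = c(0, 1, 3, 4),
                      phi = c(0, 0.05, 0.2))
  set.seed(41)
  grid <- grid[sample(nrow(grid), 200), ]
  got <- suppressWarnings(mapply(function(y, p, gp, gm, phi)
    asymmetricLoss(y, p, asymLossParams(gp, gm, phi)),
    grid$y, grid$p, grid$gp, grid$gm, grid$phi))
  want <- mapply(oracle, grid$y, grid$p, grid$gp, grid$gm, grid$phi)
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("gamma = 0 and phi = 0 recover cross-entropy exactly", {
  y <- rep(c(0, 1), each = 25)
  p <- rep(seq(0.01, 0.99, length.out = 25), 2)
  expect_equal(asymmetricLoss(y, p, asymLossParams(0, 0, 0), reduce = "none"),
               crossEntropy(y, p, reduce = "none"), tolerance = 1e-15)
})

test_that("easy negatives below the cutoff contribute exactly zero loss", {
  prm <- asymLossParams(1, 3, 0.05)
  expect_identical(asymmetricLoss(0, 0.03, prm), 0)
  expect_identical(asymmetricLoss(0, 0.05, prm), 0)
  expect_equal(asymmetricLoss(0, 0.5, prm), 0.45^3 * log(2),
               tolerance = 1e-10)
})

test_that("negative-branch damping is monotone in gammaMinus and below CE", {
  for (p in seq(0.2, 0.9, by = 0.1)) {
    losses <- suppressWarnings(vapply(c(0, 1, 2, 3, 4), function(gm)
      asymmetricLoss(0, p, asymLossParams(1, gm, 0.05)), numeric(1)))
    expect_true(all(diff(losses) <= 1e-12))
  }
  grid <- expand.grid(y = c(0, 1), p = seq(0.05, 0.95, by = 0.05))
  a <- mapply(function(y, p) asymmetricLoss(y, p, asymLossParams(1, 3, 0.05)),
              grid$y, grid$p)
  ce <- mapply(crossEntropy, grid$y, grid$p)
  expect_true(all(a <= ce + 1e-12))
})

test_that("asymmetric parameter validation warns on inverted focusing", {
  expect_warning(asymLossParams(2, 1), "gammaPlus")
  expect_error(asymLossParams(-1, 3), "gammaPlus")
  expect_error(asymLossParams(1, 3, phi = 1), "phi")
})

test_that("loss gradients agree with finite differences", {
  set.seed(42)
  prm <- asymLossParams(1, 3, 0.05)
  for (y in c(0, 1)) for (p in c(0.07, 0.3, 0.6, 0.9)) {
    g <- stnet:::asymmetricLossGrad(y, p, prm)
    fd <- numericGrad(function(v) asymmetricLoss(y, v, prm), p, h = 1e-6)
    expect_equal(g, fd, tolerance = 1e-4)
    gce <- stnet:::crossEntropyGrad(y, p)
    fdce <- numericGrad(function(v) crossEntropy(y, v), p, h = 1e-6)
    expect_equal(gce, fdce, tolerance = 1e-4)
  }
})

test_that("the shape loss is a mean squared error with permutation symmetry", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_identical(shapeLoss(m, m), 0)
  expect_equal(shapeLoss(matrix(0.5, 3, 3), matrix(1, 3, 3)), 0.25)
  set.seed(43)
  a <- matrix(runif(36), 6, 6)
  b <- matrix(rbinom(36, 1, 0.5), 6, 6)
  perm <- sample(36)
  expect_equal(shapeLoss(a, b),
               shapeLoss(matrix(a[perm], 6, 6), matrix(b[perm], 6, 6)))
  expect_error(shapeLoss(a, b[1:5, 1:5]), "spatial size")
})

test_that("the joint objective routes losses to the right parameter groups", {
  w <- jointLossWeights(alpha = 0.1, beta = 1)
  j <- jointObjective(2, 3, w, maskAvailable = TRUE)
  expect_equal(j$texturePath, 2)
  expect_equal(j$shapeEncoderPath, 0.1 * 2 + 3)
  expect_equal(j$decoderPath, 3)
  jNo <- jointObjective(2, 3, w, maskAvailable = FALSE)
  expect_identical(jNo$decoderPath, 0)
  expect_equal(jNo$shapeEncoderPath, 0.2)
  jB0 <- jointObjective(2, 3, jointLossWeights(0.1, 0), TRUE)
  expect_identical(jB0$decoderPath, 0)
  expect_error(jointLossWeights(0, 0), "both")
})
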