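test_that("lesion rendering is deterministic and geometrically calibrated", {
  sp <- lesionSpec(5, 0, 64, irregularity = 0, baseRadiusFrac = 0.3)
  a <- generateLesion(sp)
  b <- generateLesion(sp)
  expect_identical(a, b)
  expect_true(all(a$mask %in% c(0, 1)))
  expected <- pi * (0.3 * 64)^2
  expect_lt(abs(sum(a$mask) - expected) / expected, 0.05)
  expect_true(all(a$image >= 0 & a$image <= 1))
})

test_that("boundary irregularity raises the radial variance of the mask", {
  for (seed in c(21, 22, 23)) {
    v0 <- boundaryRadialVariance(
      generateLesion(lesionSpec(seed, 1, 64, irregularity = 0))$mask)
    v4 <- boundaryRadialVariance(
      generateLesion(lesionSpec(seed, 1, 64, irregularity = 0.4))$mask)
    expect_gt(v4, v0)
  }
})

test_that("masks stay in bounds and simply connected up to irregularity 0.5", {
  for (seed in 1:5) {
    les <- generateLesion(lesionSpec(seed, 1, 64, irregularity = 0.5,
                                     baseRadiusFrac = 0.3))
    expect_identical(dim(les$mask), c(64L, 64L))
    expect_true(sum(les$mask) > 0)
    expect_identical(countComponents(les$mask), 1L)
  }
})

test_that("invalid lesion specs are rejected", {
  expect_error(lesionSpec(1, 0, imageSize = 16), "imageSize")
  expect_error(lesionSpec(1, 0, baseRadiusFrac = 0.6), "baseRadiusFrac")
  expect_error(lesionSpec(1, 2), "label")
  expect_error(lesionSpec(1, 0, irregularity = -1), "irregularity")
})

test_that("a radial-variance threshold alone separates the default classes", {
  cp <- stnet:::defaultClassParams()
  set.seed(42)
  n <- 200
  labs <- as.integer(seq_len(n) <= 52) # ~1:2.85 imbalance
  v <- vapply(seq_len(n), function(i) {
    rng <- if (labs[i] == 1) cp$malignantIrregularity else cp$benignIrregularity
    trng <- if (labs[i] == 1) cp$malignantTexture else cp$benignTexture
    les <- generateLesion(lesionSpec(
      3000 + i, labs[i], 64, stats::runif(1, rng[1], rng[2]),
      stats::runif(1, trng[1], trng[2]),
      stats::runif(1, cp$radiusFrac[1], cp$radiusFrac[2])))
    boundaryRadialVariance(les$mask)
  }, numeric(1))
  accs <- vapply(sort(v), function(t) mean((v > t) == labs), numeric(1))
  expect_gt(max(accs), 0.9)
})

test_that("generateDataset writes the requested rows, masks and imbalance", {
  man <- fixtureDataset("full-mask", 10, 28, maskFraction = 1, seed = 3)
  expect_identical(nSamples(man), 38L)
  md <- manifestData(man)
  expect_identical(sum(nzchar(md$mask)), 38L)
  expect_true(all(file.exists(md$.image)))
  expect_true(all(file.exists(md$.mask)))
  msk <- loadMask(md$.mask[1])
  img <- loadImage(md$.image[1])
  expect_identical(dim(msk), dim(img)[1:2])
  expect_true(all(msk %in% c(0, 1)))
  cc <- classCounts(man)
  expect_identical(unname(cc), c(28L, 10L))

  noMask <- fixtureDataset("no-mask", 4, 4, maskFraction = 0, seed = 4,
                           imageSize = 32L)
  expect_identical(sum(nzchar(manifestData(noMask)$mask)), 0L)
})

test_that("the default imbalance reproduces the archival malignant:benign ratio", {
  man <- fixtureDataset("ratio", 452, 1287, maskFraction = 0, seed = 5,
                        imageSize = 32L)
  cc <- classCounts(man)
  expect_equal(unname(cc["malignant"] / cc["benign"]), 0.351, tolerance = 1e-3)
})

test_that("manifests round-trip through CSV", {
  man <- fixtureDataset("no-mask", 4, 4, maskFraction = 0, seed = 4,
                        imageSize = 32L)
  man2 <- readManifest(file.path(man@dir, "manifest.csv"))
  expect_identical(man2@data$image, man@data$image)
  expect_identical(man2@data$label, man@data$label)
  expect_error(readManifest(tempfile()), "cannot open|missing")
})

test_that("split apportionment matches the 6:2:2 contract", {
  man <- fixtureDataset("full-mask", 10, 28, maskFraction = 1, seed = 3)
  ten <- new("LesionManifest", data = man@data[man@data$label == 1L, ],
             dir = man@dir)
  s <- splitManifest(ten, c(6, 2, 2), seed = 1)
  expect_identical(as.integer(table(s@data$split)[c("train", "val", "test")]),
                   c(6L, 2L, 2L))

  allTrain <- splitManifest(man, c(1, 0, 0), seed = 1)
  expect_true(all(allTrain@data$split == "train"))
})

test_that("stratified splits are disjoint, exhaustive and class-balanced", {
  man <- fixtureDataset("full-mask", 10, 28, maskFraction = 1, seed = 3)
  s <- splitManifest(man, c(0.6, 0.2, 0.2), seed = 9, stratify = TRUE)
  d <- s@data
  expect_identical(sort(unname(unlist(split(seq_len(38), d$split)))), 1:38)
  pMal <- 10 / 38
  for (tag in c("train", "val", "test")) {
    sub <- d[d$split == tag, ]
    expect_lte(abs(sum(sub$label == 1L) - pMal * nrow(sub)), 1)
  }
  s2 <- splitManifest(man, c(0.6, 0.2, 0.2), seed = 9, stratify = TRUE)
  expect_identical(s@data$split, s2@data$split)
  expect_error(splitManifest(man, c(0.6, 0.2)), "ratios")
  two <- new("LesionManifest", data = man@data[1:2, ], dir = man@dir)
  expect_error(splitManifest(two, c(1, 1, 1)), "fewer samples")
})
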