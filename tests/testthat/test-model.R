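test_that("the 50-layer streams produce the canonical 7x7x2048 geometry", {
  cfg <- stnetConfig()
  m <- stnet(cfg, seed = 1)
  img <- randomImage(224, seed = 61)
  ft <- textureEncode(m, img)
  expect_identical(dim(ft), c(7L, 7L, 2048L))
  fs <- shapeEncode(m, img)
  expect_identical(dim(fs), c(7L, 7L, 2048L))
  msk <- shapeDecode(m, fs)
  expect_identical(dim(msk), c(224L, 224L))
  expect_true(all(msk >= 0 & msk <= 1))
  p <- predictProb(m, img)
  expect_true(p > 0 && p < 1)
})

test_that("model construction is a pure function of config and seed", {
  cfg <- stnetTinyConfig(seed = 3)
  m1 <- stnet(cfg)
  m2 <- stnet(cfg)
  expect_identical(stnet:::modelParams(m1), stnet:::modelParams(m2))
  img <- randomImage(64, seed = 62)
  expect_identical(predictProb(m1, img), predictProb(m2, img))
})

test_that("configuration validation catches inconsistent settings", {
  expect_error(stnetConfig(train = list(imageSize = 50L)), "divisible")
  expect_error(stnetConfig(loss = list(alpha = 0.2),
                           fusion = list(gradScale = 0.3)), "same quantity")
  cfg <- stnetConfig(loss = list(alpha = 0.25))
  expect_equal(cfg$fusion$gradScale, 0.25)
  cfg2 <- stnetConfig(fusion = list(gradScale = 0.4))
  expect_equal(cfg2$loss$alpha, 0.4)
  expect_error(stnetConfig(loss = list(type = "hinge")), "loss")
})

test_that("YAML configs round-trip through the reader", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("texture:", "  depth: 8", "shape:", "  depth: 8",
               "train:", "  imageSize: 64", "  lr: 0.001",
               "loss:", "  gammaMinus: 2"), path)
  cfg <- readConfigYAML(path)
  expect_identical(cfg$texture$depth, 8L)
  expect_equal(cfg$train$lr, 0.001)
  expect_equal(cfg$loss$gammaMinus, 2)
  expect_equal(cfg$train$batchSize, 64L) # untouched default
})

test_that("model snapshots round-trip through RDS", {
  cfg <- stnetTinyConfig(seed = 21)
  m <- stnet(cfg)
  path <- tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  img <- randomImage(64, seed = 64)
  expect_identical(predictProb(m, img), predictProb(m2, img))
  expect_identical(predictMask(m, img), predictMask(m2, img))
})

test_that("backbone weight loading restores texture-encoder parameters", {
  cfg <- stnetTinyConfig(seed = 4)
  donor <- stnet(cfg)
  recipient <- stnet(stnetTinyConfig(seed = 5))
  img <- randomImage(64, seed = 63)
  expect_false(identical(textureEncode(donor, img),
                         textureEncode(recipient, img)))
  path <- tempfile(fileext = ".rds")
  flat <- stnet:::modelParams(donor)
  saveRDS(flat[startsWith(names(flat), "tex.")], path)
  loadBackboneWeights(recipient, path)
  expect_identical(textureEncode(donor, img), textureEncode(recipient, img))
})
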