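test_that("group schedules interpolate from dense to depth-wise", {
  expect_identical(pgcGroupSchedule(1, 64), 1L)
  expect_identical(pgcGroupSchedule(3, 64), c(1L, 8L, 64L))
  for (C in c(5L, 7L, 16L))
    expect_identical(pgcGroupSchedule(2, C), c(1L, C))
  for (L in 2:6) for (C in c(8L, 16L, 64L)) {
    g <- pgcGroupSchedule(L, C)
    expect_identical(g[1L], 1L)
    expect_identical(g[L], C)
    expect_true(all(C %% g == 0L))
    expect_true(all(diff(g) >= 0L))
  }
  expect_error(pgcGroupSchedule(0, 8))
  expect_error(pgcGroupSchedule(2, 0))
})

test_that("grouped convolution matches the loop-based oracle", {
  set.seed(11)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  for (g in c(1L, 2L, 4L, 8L)) {
    w <- array(rnorm(3 * 3 * (8 %/% g) * 8), c(3, 3, 8 %/% g, 8))
    got <- groupedConv(x, w, groups = g, stride = 1, padding = 1)
    ref <- bruteGroupedConv(x, w, groups = g, stride = 1, pad = 1)
    expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-5)
  }
  # strided case
  w <- array(rnorm(3 * 3 * 4 * 8), c(3, 3, 4, 8))
  got <- groupedConv(x, w, groups = 2, stride = 2, padding = 1)
  ref <- bruteGroupedConv(x, w, groups = 2, stride = 2, pad = 1)
  expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-5)
  expect_error(groupedConv(x, w, groups = 3), "groups")
})

test_that("depth-wise grouping reduces to per-channel convolution", {
  set.seed(12)
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  w <- array(rnorm(3 * 3 * 1 * 4), c(3, 3, 1, 4))
  got <- groupedConv(x, w, groups = 4)
  for (ci in 1:4) {
    ref <- bruteGroupedConv(x[, , ci, drop = FALSE],
                            w[, , , ci, drop = FALSE], groups = 1)
    expect_equal(got[, , ci], ref[, , 1], tolerance = 1e-10)
  }
})

test_that("perturbing one group's input leaves other groups' outputs unchanged", {
  set.seed(13)
  x <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  w <- array(rnorm(3 * 3 * 2 * 8), c(3, 3, 2, 8))
  y0 <- groupedConv(x, w, groups = 4)
  x2 <- x
  x2[, , 1] <- x2[, , 1] + rnorm(36) # group 1 input
  y1 <- groupedConv(x2, w, groups = 4)
  expect_false(isTRUE(all.equal(y0[, , 1:2], y1[, , 1:2])))
  expect_identical(y0[, , 3:8], y1[, , 3:8])
})

test_that("pyramid schedules give non-increasing per-layer parameter counts", {
  for (C in c(16L, 64L)) {
    g <- pgcGroupSchedule(4, C)
    counts <- C * (C / g) * 9
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("zero input with zero biases gives a zero first-stage response", {
  set.seed(14)
  w <- array(rnorm(3 * 3 * 3 * 8), c(3, 3, 3, 8))
  y <- groupedConv(array(0, c(16, 16, 3)), w, groups = 1)
  expect_true(all(y == 0))
})

test_that("the tiny texture encoder is deterministic with correct geometry", {
  cfg <- stnetTinyConfig(seed = 2)
  m <- stnet(cfg)
  img <- randomImage(64, seed = 5)
  f1 <- textureEncode(m, img)
  f2 <- textureEncode(m, img)
  expect_identical(f1, f2)
  expect_identical(dim(f1), c(8L, 8L, 64L))
  expect_error(textureEncode(m, array(0, c(64, 64, 2))), "h x w x 3")
})
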