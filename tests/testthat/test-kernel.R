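test_that("spatial kernel matches the squared-exponential closed form", {
  expect_equal(spatialKernel(c(1, 1), c(1, 1), delta = 3), 1)
  expect_equal(spatialKernel(c(1, 1), c(1, 2), delta = 2), exp(-1 / 4))
  expect_equal(spatialKernel(c(1, 1), c(4, 5), delta = 1e9), 1,
               tolerance = 1e-12)
  # symmetric and strictly decreasing in distance
  expect_equal(spatialKernel(c(0, 0), c(3, 4), 2),
               spatialKernel(c(3, 4), c(0, 0), 2))
  expect_true(spatialKernel(c(0, 0), c(1, 0), 2) >
                spatialKernel(c(0, 0), c(2, 0), 2))
  expect_error(spatialKernel(c(0, 0), c(1, 0), 0), "positive")
})

test_that("kernel matrices have the right entries, jitter and defaults", {
  spec <- kernelSpec(delta = 1, jitter = 0)
  K <- buildKernel(rbind(c(0, 0), c(1, 0)), rbind(c(0, 0), c(1, 0)), spec)
  expect_equal(K[1, 2], exp(-1))
  expect_equal(K, t(K))
  expect_equal(unname(diag(K)), c(1, 1))
  expect_equal(buildKernel(c(2, 2), c(2, 2), spec), matrix(1, 1, 1))
  # square case gets the jitter on the diagonal
  specJ <- kernelSpec(delta = 1, jitter = 1e-4)
  KJ <- buildKernel(rbind(c(0, 0), c(1, 0)), rbind(c(0, 0), c(1, 0)), specJ)
  expect_equal(unname(diag(KJ)), c(1 + 1e-4, 1 + 1e-4))
  # rectangular case does not
  KR <- buildKernel(rbind(c(0, 0)), rbind(c(0, 0), c(1, 0)), specJ)
  expect_equal(KR[1, 1], 1)
  expect_error(buildKernel(matrix(0, 0, 2), c(0, 0), spec), "nonempty")
  # default delta is the maximum pairwise grid distance
  expect_equal(kernelSpec(grid5)@rangeParameter, sqrt(32))
})

test_that("the hyper-prior must be proper for the grid size", {
  pr <- hyperPrior(25)
  expect_equal(pr@precision, 1)
  expect_equal(pr@wishartDof, 27)
  cfg <- simConfig(horizon = 3)
  pan <- quietPanel(cfg, 1)
  expect_error(fitSlice(pan, 1, prior = hyperPrior(25, wishartDof = 10)),
               "proper")
})
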