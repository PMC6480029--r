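test_that("named cluster patterns are centered circles of 5, 9, 13 cells", {
  co <- gridCoords(grid5)
  for (nm in c(small = 1, medium = sqrt(2), large = 2)) NULL
  radii <- c(small = 1, medium = sqrt(2), large = 2)
  for (nm in names(radii)) {
    mask <- clusterPattern(nm, grid5)
    # oracle: enumerate lattice points within the radius of the center (3,3)
    want <- sqrt((co[, 1] - 3)^2 + (co[, 2] - 3)^2) <= radii[[nm]] + 1e-9
    expect_equal(mask, want, info = nm)
  }
  expect_equal(sum(clusterPattern("small", grid5)), 5L)
  expect_equal(sum(clusterPattern("medium", grid5)), 9L)
  expect_equal(sum(clusterPattern("large", grid5)), 13L)
  expect_error(clusterPattern("huge", grid5), "unknown")
  expect_error(clusterPattern("small", grid3), "5 x 5")
})

test_that("in-control field draws recover the generator moments", {
  cfg <- simConfig(horizon = 5000, changePoint = NA, shiftMagnitude = 0)
  f <- simulateField(cfg, seed = 42)
  X <- panelValues(f)
  # per-location mean within 3 / sqrt(T) of zero (marginal sd = 1)
  expect_true(all(abs(colMeans(X)) < 3 / sqrt(5000)))
})

test_that("the mean shift is applied on the cluster from the change point", {
  cfg <- simConfig(grid = grid5, horizon = 200, changePoint = 1,
                   clusterPattern = rep(TRUE, 25), shiftMagnitude = 2)
  X <- panelValues(simulateField(cfg, seed = 7))
  expect_true(abs(mean(X) - 2) < 0.2)
  cfg2 <- simConfig(horizon = 400, changePoint = 201,
                    clusterPattern = "medium", shiftMagnitude = 1.5)
  X2 <- panelValues(simulateField(cfg2, seed = 8))
  mask <- clusterPattern("medium", grid5)
  pre <- colMeans(X2[1:200, mask])
  post <- colMeans(X2[201:400, mask])
  expect_true(abs(mean(post - pre) - 1.5) < 0.3)
})

test_that("simulation is reproducible under a fixed seed", {
  cfg <- simConfig(horizon = 30)
  expect_identical(panelValues(simulateField(cfg, seed = 5)),
                   panelValues(simulateField(cfg, seed = 5)))
  p1 <- quietPanel(cfg, 9)
  p2 <- quietPanel(cfg, 9)
  expect_identical(panelValues(p1), panelValues(p2))
  expect_identical(observedMask(p1), observedMask(p2))
})

test_that("derived processes are the field plus independent noise", {
  cfg <- simConfig(horizon = 5000, changePoint = NA, shiftMagnitude = 0)
  f <- simulateField(cfg, seed = 12)
  pan0 <- deriveProcesses(f, 2, 0, seed = 1)
  for (l in 1:2)
    expect_equal(pan0@values[l, , ], panelValues(f), ignore_attr = TRUE)
  pan <- deriveProcesses(f, 3, 0.1, seed = 2)
  resid <- pan@values[2, , ] - panelValues(f)
  expect_true(abs(mean(apply(resid, 2, var)) - 0.01) < 0.002)
  expect_error(deriveProcesses(f, 3, -0.1), "nonnegative")
})

test_that("missingness masks the exact per-slice count, uniformly at random", {
  expect_equal(missingCount(0, 25), 0L)
  expect_equal(missingCount(0.2, 25), 5L)
  expect_equal(missingCount(0.3, 25), 8L)   # 7.5 rounds half-up
  expect_equal(missingCount(0.5, 25), 13L)  # 12.5 rounds half-up
  expect_error(missingCount(1, 25), "\\[0, 1\\)")

  cfg <- simConfig(horizon = 40, processCount = 3)
  f <- simulateField(cfg, seed = 3)
  pan <- deriveProcesses(f, 3, 0.1, seed = 4)
  m0 <- applyMissingness(pan, 0, seed = 5)
  expect_true(all(observedMask(m0)))
  m <- suppressWarnings(applyMissingness(pan, 0.2, seed = 5))
  perSlice <- apply(!observedMask(m), c(1, 2), sum)
  expect_true(all(perSlice == 5L))
  # marginal uniformity over repeated masking
  freq <- rep(0, 25)
  for (s in 1:50) {
    ms <- suppressWarnings(applyMissingness(pan, 0.2, seed = 100 + s))
    freq <- freq + colSums(!ms@observed[1, , ])
  }
  freq <- freq / (50 * 40)
  expect_true(all(abs(freq - 0.2) < 3 * sqrt(0.2 * 0.8 / (50 * 40))))
})

test_that("noiseless fully observed derivation is lossless", {
  cfg <- simConfig(horizon = 25)
  f <- simulateField(cfg, seed = 21)
  pan <- applyMissingness(deriveProcesses(f, 2, 0, seed = 1), 0, seed = 2)
  for (l in 1:2)
    expect_identical(pan@values[l, , ], unname(panelValues(f)))
})

test_that("a coverage violation is reported as a warning, not an error", {
  vals <- array(1, c(1, 2, 4))
  obs <- array(TRUE, c(1, 2, 4))
  vals[1, 2, 3] <- NA
  obs[1, 2, 3] <- FALSE
  expect_warning(observationPanel(vals, obs, sensorGrid(2, 2)),
                 "coverage violated")
})
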