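test_that("E-step matches the scalar closed forms", {
  # n = 1, kappa_l = [1], sigma2 = 1, C = 1, m = 0, x = 2 -> alpha = 1, Cl = 1/2
  es <- eStep(list(2), list(matrix(1, 1, 1)), scalarState(0, 1, 1))
  expect_equal(es$weightMeans[[1]], 1)
  expect_equal(es$weightCovariances[[1]], matrix(0.5, 1, 1))
  # prior-dominated limit: sigma2 -> Inf gives alpha -> m, Cl -> C
  es2 <- eStep(list(2), list(matrix(1, 1, 1)), scalarState(0.7, 1.3, 1e12))
  expect_equal(es2$weightMeans[[1]], 0.7, tolerance = 1e-9)
  expect_equal(es2$weightCovariances[[1]][1, 1], 1.3, tolerance = 1e-9)
  # equal-weight posterior mean between prior mean and data
  es3 <- eStep(list(0), list(matrix(1, 1, 1)), scalarState(2, 1, 1))
  expect_equal(es3$weightMeans[[1]], 1)
})

test_that("M-step matches the scalar closed forms", {
  pr <- hyperPrior(1, precision = 1, wishartDof = 3)
  # m = sum(alpha) / (pi + L): three processes with alpha = 1 -> 3/4
  ms <- mStep(list(1, 1, 1), rep(list(matrix(1, 1, 1)), 3),
              list(1, 1, 1), rep(list(matrix(0, 1, 1)), 3),
              pr, matrix(1, 1, 1))
  expect_equal(ms$priorMean, 0.75)
  # sigma2: L = 1, x = 1, alpha = 1, Cl = 0.5 -> 0.5
  ms2 <- mStep(list(1), list(matrix(1, 1, 1)), list(1),
               list(matrix(0.5, 1, 1)), pr, matrix(1, 1, 1))
  expect_equal(ms2$noiseVariance, 0.5)
  # C: pi = 1, tau = 3, kappa = 1, L = 1, alpha = 0, Cl = 1 -> (3 + 1)/4 = 1
  ms3 <- mStep(list(0), list(matrix(1, 1, 1)), list(0),
               list(matrix(1, 1, 1)), pr, matrix(1, 1, 1))
  expect_equal(ms3$priorMean, 0)
  expect_equal(ms3$priorCovariance, matrix(1, 1, 1))
})

test_that("EM reconstructs a noiseless fully observed slice", {
  cfg <- simConfig(horizon = 1, changePoint = NA, shiftMagnitude = 0,
                   processCount = 1, noiseSd = 0, missingRatio = 0)
  pan <- simulatePanel(cfg, seed = 31)
  st <- fitSlice(pan, 1)
  gk <- fieldscan:::gridKernel(pan@grid, kernelSpec(pan@grid))
  rec <- as.numeric(gk$kernel %*% st@weightMeans[[1]])
  x <- pan@values[1, 1, ]
  expect_lt(sqrt(sum((rec - x)^2) / sum(x^2)), 1e-3)
})

test_that("identical observations across processes give identical weights", {
  cfg <- simConfig(horizon = 1, processCount = 1, noiseSd = 0.1,
                   missingRatio = 0.2)
  pan1 <- quietPanel(cfg, 17)
  vals <- array(NA_real_, c(3, 1, 25))
  obs <- array(FALSE, c(3, 1, 25))
  for (l in 1:3) {
    vals[l, 1, ] <- pan1@values[1, 1, ]
    obs[l, 1, ] <- pan1@observed[1, 1, ]
  }
  pan3 <- suppressWarnings(observationPanel(vals, obs, pan1@grid))
  st <- fitSlice(pan3, 1)
  expect_equal(st@weightMeans[[1]], st@weightMeans[[2]], tolerance = 1e-8)
  expect_equal(st@weightMeans[[2]], st@weightMeans[[3]], tolerance = 1e-8)
})

test_that("a zero iteration budget returns the initialization state", {
  cfg <- simConfig(horizon = 1)
  pan <- quietPanel(cfg, 23)
  st <- fitSlice(pan, 1, maxIter = 0)
  expect_false(st@converged)
  expect_equal(st@iterations, 0L)
  expect_equal(st@priorMean, rep(0, 25))
  expect_equal(st@noiseVariance, 1)
})

test_that("posterior covariances shrink below the prior (Loewner order)", {
  cfg <- simConfig(horizon = 1, missingRatio = 0.3)
  pan <- quietPanel(cfg, 29)
  st <- fitSlice(pan, 1, maxIter = 5)
  for (l in 1:3) {
    dC <- st@priorCovariance - st@weightCovariances[[l]]
    ev <- eigen((dC + t(dC)) / 2, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-6 * max(abs(dC))))
  }
  expect_gte(st@noiseVariance, 0)
})

test_that("relabeling locations permutes the fitted weights consistently", {
  cfg <- simConfig(grid = grid3, horizon = 1, processCount = 2,
                   missingRatio = 0.2, clusterPattern = 5L)
  pan <- quietPanel(cfg, 37)
  st <- fitSlice(pan, 1)
  gk <- fieldscan:::gridKernel(grid3, kernelSpec(grid3))
  y <- as.numeric(gk$kernel %*% st@weightMeans[[1]])
  # permute locations (rows of the coordinate table) and refit
  perm <- c(4, 7, 1, 9, 2, 6, 3, 8, 5)
  gPerm <- new("SensorGrid", nRows = 3L, nCols = 3L, spacing = 1,
               coords = gridCoords(grid3)[perm, ])
  panPerm <- suppressWarnings(observationPanel(
    pan@values[, , perm, drop = FALSE],
    pan@observed[, , perm, drop = FALSE], gPerm))
  stPerm <- fitSlice(panPerm, 1)
  gkP <- fieldscan:::gridKernel(gPerm, kernelSpec(gPerm))
  yPerm <- as.numeric(gkP$kernel %*% stPerm@weightMeans[[1]])
  expect_equal(yPerm, y[perm], tolerance = 1e-6)
})

test_that("compiled and reference EM fits agree on the same slice", {
  cfg <- simConfig(horizon = 3, missingRatio = 0.3)
  pan <- quietPanel(cfg, 41)
  gk <- fieldscan:::gridKernel(pan@grid, kernelSpec(pan@grid))
  for (t in 1:3) {
    st <- fitSlice(pan, t)
    sdt <- fieldscan:::sliceData(pan, t)
    f <- fieldscan:::cpp_em_fit(sdt$x, sdt$obs, gk$kernel, gk$inverse,
                                1, 27, 1e-5, 100L, 1e-12,
                                numeric(25), gk$kernel, 1, TRUE)
    yR <- as.numeric(gk$kernel %*% st@weightMeans[[1]])
    yC <- as.numeric(gk$kernel %*% f$alpha[[1]])
    expect_equal(yC, yR, tolerance = 1e-4)
    expect_equal(f$s2, st@noiseVariance, tolerance = 1e-4)
  }
})

test_that("completion copies observed values verbatim and fills the rest", {
  cfg <- simConfig(horizon = 2, missingRatio = 0.2)
  pan <- quietPanel(cfg, 43)
  st <- fitSlice(pan, 1)
  cs <- completeSlice(pan, 1, 1L, st)
  obs <- pan@observed[1, 1, ]
  expect_identical(completedValues(cs)[obs], pan@values[1, 1, obs])
  expect_identical(imputedMask(cs), !obs)
  expect_true(all(is.finite(completedValues(cs))))
  # no missing values: identity regardless of the state
  cfg0 <- simConfig(horizon = 1, missingRatio = 0)
  pan0 <- simulatePanel(cfg0, seed = 47)
  st0 <- fitSlice(pan0, 1, maxIter = 0)
  cs0 <- completeSlice(pan0, 1, 1L, st0)
  expect_identical(completedValues(cs0), pan0@values[1, 1, ])
})

test_that("multitask imputation beats in-control-mean substitution", {
  # 50% missing, the monitored process' truth vs both completions
  cfg <- simConfig(horizon = 1, missingRatio = 0.5)
  gk <- fieldscan:::gridKernel(grid5, kernelSpec(grid5))
  seDiff <- numeric(60)
  for (s in seq_along(seDiff)) {
    set.seed(1000 + s)
    sub <- sample.int(1e6, 3)
    f <- simulateField(cfg, seed = sub[1])
    pan <- deriveProcesses(f, 3, 0.1, seed = sub[2])
    pan <- suppressWarnings(applyMissingness(pan, 0.5, seed = sub[3]))
    sdt <- fieldscan:::sliceData(pan, 1)
    fit <- fieldscan:::cpp_em_fit(sdt$x, sdt$obs, gk$kernel, gk$inverse,
                                  1, 27, 1e-5, 100L, 1e-12,
                                  numeric(25), gk$kernel, 1, TRUE)
    yhat <- as.numeric(gk$kernel %*% fit$alpha[[1]])
    miss <- !pan@observed[1, 1, ]
    truth <- panelValues(f)[1, miss]
    seDiff[s] <- sqrt(mean((yhat[miss] - truth)^2)) -
      sqrt(mean((0 - truth)^2))
  }
  expect_lt(mean(seDiff), 0)
  expect_gt(mean(seDiff < 0), 0.9)
})

test_that("EM recovers the noise variance from model-generated slices", {
  # generate from the model itself: alpha ~ N(m*, C*), y = kappa alpha,
  # x = y + noise; fully observed, L = 10
  n <- 25
  gk <- fieldscan:::gridKernel(grid5, kernelSpec(grid5))
  set.seed(61)
  s2true <- 0.25
  mstar <- rnorm(n, 0, 0.05)
  # weight-space prior proportional to the kernel inverse, the model's own
  # inverse-Wishart scale; gives smooth fields with O(0.2) amplitude
  Cstar <- 0.05 * gk$inverse
  ch <- chol((Cstar + t(Cstar)) / 2 + 1e-8 * diag(n))
  s2hat <- numeric(50)
  for (r in 1:50) {
    xl <- vector("list", 10)
    for (l in 1:10) {
      a <- mstar + as.numeric(rnorm(n) %*% ch)
      xl[[l]] <- as.numeric(gk$kernel %*% a) + rnorm(n, 0, sqrt(s2true))
    }
    f <- fieldscan:::cpp_em_fit(xl, rep(list(1:n), 10), gk$kernel,
                                gk$inverse, 1, 27, 1e-5, 100L, 1e-12,
                                numeric(n), gk$kernel, 1, TRUE)
    s2hat[r] <- f$s2
  }
  expect_lt(abs(mean(s2hat) - s2true) / s2true, 0.25)
})

test_that("panel imputation returns diagnostics and respects engines", {
  cfg <- simConfig(horizon = 4, missingRatio = 0.3)
  pan <- quietPanel(cfg, 53)
  impC <- imputePanel(pan, engine = "cpp")
  impR <- imputePanel(pan, engine = "R")
  expect_equal(impC$values, impR$values, tolerance = 1e-4)
  expect_equal(dim(impC$values), c(4L, 25L))
  expect_equal(nrow(impC$diagnostics), 4L)
  expect_true(all(impC$diagnostics$converged))
  obs <- pan@observed[1, 2, ]
  expect_identical(impC$values[2, obs], pan@values[1, 2, obs])
})
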