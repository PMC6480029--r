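test_that("cluster enumeration matches lattice geometry and deduplicates", {
  cs <- enumerateClusters(grid5, 2)
  expect_equal(cs@radii, c(0, 1, sqrt(2), 2), tolerance = 1e-9)
  # radius 0 gives singletons for every center
  singles <- which(cs@radius == 0)
  expect_equal(length(singles), 25L)
  expect_true(all(lengths(cs@members[singles]) == 1L))
  # center (3,3) radius 1 has 5 members (oracle: lattice enumeration)
  co <- gridCoords(grid5)
  ctr <- which(co[, 1] == 3 & co[, 2] == 3)
  j <- which(cs@centers == ctr & abs(cs@radius - 1) < 1e-9)
  expect_equal(sort(cs@members[[j]]),
               which(sqrt((co[, 1] - 3)^2 + (co[, 2] - 3)^2) <= 1 + 1e-9))
  # monotone membership in r for fixed center
  for (c0 in c(1L, ctr)) {
    js <- which(cs@centers == c0)
    ms <- cs@members[js[order(cs@radius[js])]]
    for (i in seq_len(length(ms) - 1))
      expect_true(all(ms[[i]] %in% ms[[i + 1]]))
  }
  # dedup: identical member sets for one center are collapsed
  key <- paste(cs@centers, vapply(cs@members, paste, "", collapse = ","))
  expect_false(any(duplicated(key)))
  expect_error(enumerateClusters(grid5, -1), "nonnegative")
})

test_that("restricted means zero out locations outside the cluster", {
  mu <- rep(1, 25)
  expect_equal(restrictMean(mu, 1:25), mu)
  expect_equal(restrictMean(mu, integer(0)), rep(0, 25))
  r <- restrictMean(mu, c(2, 5, 9, 12, 20))
  expect_equal(sum(r), 5)
  expect_equal(which(r == 1), c(2, 5, 9, 12, 20))
})

test_that("the LR increment matches its closed form", {
  n <- 9
  mu <- rep(0, n); mu[4] <- 1
  expect_equal(lrStatistic(mu / 2, mu, diag(n), jitter = 0), 0)
  x <- rep(0, n); x[4] <- 1.5
  expect_equal(lrStatistic(x, mu, diag(n), jitter = 0), 1)
  expect_equal(lrStatistic(rep(1, n), rep(1, n), diag(n), jitter = 0),
               n / 2)
})

test_that("the CUSUM recursion reflects at zero", {
  expect_equal(updateCusum(0, -1), 0)
  expect_equal(updateCusum(2, 3), 5)
  s <- 0
  out <- c()
  for (inc in c(1, 2)) { s <- updateCusum(s, inc); out <- c(out, s) }
  expect_equal(out, c(1, 3))
  expect_equal(updateCusum(c(0, 2), c(-1, 3)), c(0, 5))
})

test_that("scan steps track the maximum and alarm strictly above h", {
  cs <- enumerateClusters(grid3, 0)   # 9 singleton clusters
  spec <- shiftSpec(rep(2, 9), diag(9))
  chart <- scanChart(spec, cs, jitter = 0)
  st <- newScanState(chart)
  # single cell at its shifted mean: increment 2 * (2 - 1) = 2 each step
  x <- rep(0, 9); x[5] <- 2
  for (expect_val in c(2, 4, 6)) {
    res <- scanStep(st, x, chart, h = 100)
    st <- res$state
    expect_equal(st@globalStat, expect_val)
    expect_false(res$alarm)
  }
  # negative increments from 0 leave the statistic at 0, no alarm for h > 0
  st2 <- newScanState(chart)
  res2 <- scanStep(st2, rep(-5, 9), chart, h = 0.5)
  expect_equal(res2$state@globalStat, 0)
  expect_false(res2$alarm)
  # strictness of the alarm condition
  res3 <- scanStep(newScanState(chart), x, chart, h = 2)
  expect_false(res3$alarm)
  res4 <- scanStep(newScanState(chart), x, chart, h = 2 - 1e-9)
  expect_true(res4$alarm)
})

test_that("the vectorized scan equals brute-force recomputation (3x3, K = 2)", {
  set.seed(71)
  n <- 9
  # a well-conditioned covariance so the 1e-10 absolute agreement between
  # the factorized chart and the naive oracle is meaningful
  Sigma <- makeCovariance(grid3, 2)
  cs <- enumerateClusters(grid3, 2)
  dirs <- rbind(rep(1, n), seq(0.5, 1.5, length.out = n))
  chart <- scanChart(shiftSpec(dirs, Sigma), cs)
  X <- matrix(rnorm(5 * n), 5, n)
  oracle <- bruteForceScan(X, dirs, Sigma, cs)
  st <- newScanState(chart)
  for (t in 1:5) {
    st <- scanStep(st, X[t, ], chart, h = Inf)$state
    # compare every (k, c, r) statistic
    vec <- matrix(st@cusum, nrow = nClusters(cs))  # clusters x directions
    expect_lt(max(abs(t(vec) - oracle$cusum[t, , ])), 1e-10)
    expect_equal(st@globalStat, oracle$global[t], tolerance = 1e-12)
  }
})

test_that("with one direction the unknown-shift chart reduces to known-shift", {
  set.seed(73)
  Sigma <- makeCovariance(grid3, 50)
  cs <- enumerateClusters(grid3, 2)
  mu <- rep(1, 9)
  chartK <- scanChart(shiftSpec(mu, Sigma), cs)
  chartU <- scanChart(shiftSpec(rbind(mu), Sigma), cs)
  X <- matrix(rnorm(4 * 9), 4, 9)
  rK <- runScan(X, chartK, h = Inf)
  rU <- runScan(X, chartU, h = Inf)
  expect_identical(rK@trajectory, rU@trajectory)
})

test_that("adding a direction or radius never decreases the global statistic", {
  set.seed(79)
  Sigma <- makeCovariance(grid3, 50)
  X <- matrix(rnorm(6 * 9), 6, 9)
  mu <- rep(1, 9)
  g1 <- runScan(X, scanChart(shiftSpec(mu, Sigma),
                             enumerateClusters(grid3, 1)), Inf)@trajectory
  g2 <- runScan(X, scanChart(shiftSpec(mu, Sigma),
                             enumerateClusters(grid3, 2)), Inf)@trajectory
  expect_true(all(g2 >= g1 - 1e-12))
  g3 <- runScan(X, scanChart(shiftSpec(rbind(mu, mu * 2), Sigma),
                             enumerateClusters(grid3, 1)), Inf)@trajectory
  expect_true(all(g3 >= g1 - 1e-12))
})

test_that("run-level alarms, censoring and the identified cluster behave", {
  set.seed(83)
  Sigma <- makeCovariance(grid3, 50)
  cs <- enumerateClusters(grid3, 2)
  chart <- scanChart(shiftSpec(rep(1, 9), Sigma), cs)
  X <- matrix(rnorm(10 * 9, 0, 0.1), 10, 9)
  rep0 <- runScan(X, chart, h = Inf)
  expect_true(is.na(alarmTime(rep0)))
  expect_length(rep0@trajectory, 10)
  rep1 <- runScan(X, chart, h = -1)
  expect_equal(alarmTime(rep1), 1L)
  expect_error(runScan(matrix(0, 0, 9), chart, 1), "nonempty")
  expect_error(runScan(matrix(NA_real_, 2, 9), chart, 1), "missing")
})

test_that("under control the expected LR increment is negative everywhere", {
  set.seed(89)
  Sigma <- makeCovariance(grid3, 50)
  cs <- enumerateClusters(grid3, 2)
  chart <- scanChart(shiftSpec(rep(1, 9), Sigma), cs)
  R <- chol(Sigma + fieldJitter() * diag(9))
  X <- matrix(rnorm(4000 * 9), 4000, 9) %*% R
  incs <- X %*% t(chart@solved) -
    matrix(chart@offsets, 4000, length(chart@offsets), byrow = TRUE)
  means <- colMeans(incs)
  # theoretical mean is -mu' Sigma^-1 mu / 2 = -offsets; all must be < 0
  expect_true(all(means < 0))
  expect_equal(means, -chart@offsets, tolerance = 0.2 * max(chart@offsets))
})

test_that("the benchmark step substitutes the in-control mean for NAs", {
  Sigma <- makeCovariance(grid3, 50)
  cs <- enumerateClusters(grid3, 2)
  chart <- scanChart(shiftSpec(rep(1, 9), Sigma), cs)
  x <- rnorm(9)
  a <- scanStep(newScanState(chart), x, chart, 1e9)
  b <- benchmarkStep(newScanState(chart), x, chart, 1e9)
  expect_identical(a$state@cusum, b$state@cusum)
  xm <- x; xm[c(2, 5)] <- NA
  x0 <- x; x0[c(2, 5)] <- 0
  c1 <- benchmarkStep(newScanState(chart), xm, chart, 1e9)
  c2 <- scanStep(newScanState(chart), x0, chart, 1e9)
  expect_identical(c1$state@cusum, c2$state@cusum)
})
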