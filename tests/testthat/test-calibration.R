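# Small study configuration for fast Monte-Carlo checks: full 5x5 geometry
# but a desk-scale ARL0 target.
smallCfg <- function(shift = 1, ratio = 0.2, pattern = "medium",
                     v = 11, horizon = 120) {
  simConfig(shiftMagnitude = shift, missingRatio = ratio,
            clusterPattern = pattern, changePoint = v, horizon = horizon)
}

test_that("run lengths behave at degenerate thresholds and are reproducible", {
  cfg <- smallCfg()
  chart <- chartForConfig(cfg)
  r1 <- runLength(cfg, h = -1, seed = 2, cap = 50, chart = chart)
  expect_equal(r1$runLength, 1L)
  expect_true(r1$alarm)
  r2 <- runLength(cfg, h = Inf, seed = 2, cap = 20, chart = chart)
  expect_equal(r2$runLength, 20L)
  expect_false(r2$alarm)
  r3 <- runLength(cfg, h = 1e5, seed = 7, cap = 60, chart = chart)
  r4 <- runLength(cfg, h = 1e5, seed = 7, cap = 60, chart = chart)
  expect_identical(r3$runLength, r4$runLength)
  expect_identical(r3$trajectory, r4$trajectory)
  expect_error(runLength(cfg, 1, cap = 0), "positive")
})

test_that("pathwise run length is nondecreasing in the threshold", {
  cfg <- smallCfg()
  chart <- chartForConfig(cfg)
  for (s in 1:5) {
    tr <- runLength(cfg, h = Inf, seed = 300 + s, cap = 80,
                    chart = chart)$trajectory
    U <- cummax(tr)
    rl <- function(h) { i <- which(U > h); if (length(i)) i[1] else 80L }
    hs <- sort(stats::runif(4, 0, max(U) * 1.2))
    expect_true(all(diff(vapply(hs, rl, 1L)) >= 0))
  }
})

test_that("the calibrated threshold matches the geometric oracle", {
  # Bernoulli alarm chart: one statistic jumping +2 w.p. p, else -2;
  # any threshold in (0, 2) alarms exactly on a jump, so the run length
  # is geometric with mean 1/p
  p <- 0.02
  oracle <- function(k) matrix(ifelse(stats::runif(k) < p, 2, -2), 1, k)
  cal <- calibrateH(targetArl0 = 1 / p, reps = 2000, cap = 20 / p,
                    seed = 5, incrementFun = oracle)
  expect_gt(cal@threshold, 0)
  expect_lt(cal@threshold, 2)
  expect_lt(abs(cal@achievedArl0 - 1 / p) / (1 / p), 0.05)
  expect_gte(cal@replications, 200L)
})

test_that("a degenerate chart is flagged unattainable, not calibrated", {
  # global statistic identically zero: every h >= 0 censors at the cap,
  # so the target is unattainable and the conservative limit is returned
  deg <- function(k) matrix(-1, 1, k)
  expect_warning(
    cal <- calibrateH(targetArl0 = 20, reps = 10, cap = 80, seed = 1,
                      incrementFun = deg),
    "unattainable")
  expect_equal(cal@threshold, 0)
  expect_false(is.finite(cal@achievedArl0))
})

test_that("calibration is monotone and consistent under fresh seeds", {
  # moderate-tail oracle: run lengths roughly geometric around exp(h)
  mkInc <- function(k) matrix(stats::rnorm(k, -1, 1), 1, k)
  cal <- calibrateH(targetArl0 = 40, reps = 150, cap = 160, seed = 11,
                    incrementFun = mkInc)
  # larger thresholds give larger ARLs on the same stream machinery
  set.seed(31)
  inc <- mkInc(30000)
  a1 <- fieldscan:::segmentStats(inc, cal@threshold * 0.7, 160)$arl
  a2 <- fieldscan:::segmentStats(inc, cal@threshold, 160)$arl
  a3 <- fieldscan:::segmentStats(inc, cal@threshold * 1.3, 160)$arl
  expect_true(a1 <= a2 && a2 <= a3)
  expect_lt(abs(cal@achievedArl0 - 40) / 40, 0.06)
})

test_that("ARL1 is immediate for an overwhelming shift and delays are valid", {
  # a shift-2 outbreak against a modest limit alarms at the change point
  cfg <- smallCfg(shift = 2, ratio = 0.2)
  chart <- chartForConfig(cfg)
  rl <- estimateArl1(cfg, h = 1, reps = 40, seed = 17, chart = chart)
  expect_true(all(rl@runLengths >= 1))
  expect_equal(rl@arl1, 1, tolerance = 0.051)
  expect_lte(rl@discarded, 40L)
})

test_that("standard errors shrink like one over the square root of reps", {
  mkInc <- function(k) matrix(stats::rnorm(k, -1, 1), 1, k)
  cal25 <- calibrateH(targetArl0 = 30, reps = 25, cap = 120, seed = 19,
                      incrementFun = mkInc)
  cal100 <- calibrateH(targetArl0 = 30, reps = 100, cap = 120, seed = 19,
                       incrementFun = mkInc)
  ratio <- cal25@standardError / cal100@standardError
  expect_gt(ratio, 1.1)
})

test_that("the experiment grid crosses scenarios with shared calibrations", {
  cfg <- smallCfg()
  res <- suppressWarnings(
    experimentGrid(cfg, shifts = 0.5, patterns = c("medium", "large"),
                   ratios = 0.2, models = "multitask",
                   targetArl0 = 20, calibReps = 30, evalReps = 20,
                   cap = 80, seed = 23))
  expect_equal(nrow(res), 2L)
  expect_equal(length(unique(res$h)), 1L)  # same chart, same h
  expect_true(all(res$arl1 >= 1))
  res1 <- experimentGrid(cfg, shifts = 0.5, patterns = "medium",
                         ratios = 0.2, models = "meanfill", targetArl0 = 20,
                         calibReps = 30, evalReps = 10, cap = 80, seed = 23)
  expect_equal(nrow(res1), 1L)
  expect_error(experimentGrid(cfg, numeric(0), "medium", 0.2), "nonempty")
})
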