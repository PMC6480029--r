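# Independent sub-seeds spawned from one master seed (kept below 2^31).
subSeeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Known-shift scan chart of a study configuration
#'
#' Builds the chart a configuration implies: the known `Sigma` is the
#' in-control covariance of the monitored sensor values -- the field
#' covariance plus the sensor-noise variance on the diagonal -- the
#' homogeneous shift of the configured magnitude is the single
#' direction, and circular clusters up to `maxRadius` are scanned.
#'
#' @param config a [SimulationConfig-class].
#' @param maxRadius upper scan radius in grid units (default 2 grid
#'   spacings, covering the largest named cluster pattern).
#' @param directions optional `K x n` matrix of directions overriding the
#'   homogeneous default (the unknown-shift chart).
#' @return a [ScanChart-class].
#' @export
chartForConfig <- function(config, maxRadius = NULL, directions = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  grid <- config@grid
  n <- nLocations(grid)
  if (is.null(maxRadius)) maxRadius <- 2 * grid@spacing
  if (is.null(directions)) {
    if (config@shiftMagnitude <= 0)
      stop("a positive shift magnitude is required to build the known-shift chart")
    directions <- matrix(homogeneousDirection(config@shiftMagnitude, n),
                         nrow = 1L)
  }
  sigma <- makeCovariance(grid, config@covarianceScale) +
    config@noiseSd^2 * diag(n)
  spec <- shiftSpec(directions, sigma)
  scanChart(spec, enumerateClusters(grid, maxRadius))
}

# Bundle everything the compiled pipeline kernels need.
pipelinePrep <- function(config, chart, kspec = NULL, prior = NULL,
                         tol = 1e-5, maxIter = 100L) {
  grid <- config@grid
  n <- nLocations(grid)
  if (is.null(kspec)) kspec <- kernelSpec(grid)
  if (is.null(prior)) prior <- hyperPrior(n)
  gk <- gridKernel(grid, kspec)
  S <- makeCovariance(grid, config@covarianceScale)
  cholU <- chol(S + fieldJitter() * diag(n))
  shift <- ifelse(config@clusterMask, config@shiftMagnitude, 0)
  list(cholU = cholU, shift = shift,
       v = if (is.na(config@changePoint)) 0L else config@changePoint,
       L = config@processCount, noiseSd = config@noiseSd,
       nmiss = missingCount(config@missingRatio, n),
       mu0 = chart@spec@inControlMean,
       kj = gk$kernel, kinv = gk$inverse,
       pi0 = prior@precision, tau = prior@wishartDof,
       tol = tol, maxIter = as.integer(maxIter),
       Bt = chart@solved, offs = chart@offsets)
}

modeCode <- function(model) {
  model <- match.arg(model, c("multitask", "meanfill"))
  if (model == "multitask") 0L else 1L
}

#' Run length of one monitored replication
#'
#' Simulates the configured pipeline (field, related noisy processes,
#' MCAR masking, per-slice completion, scan) until the global statistic
#' first strictly exceeds `h`, or until `cap` steps have passed.
#'
#' @param config a [SimulationConfig-class]; its change point and shift
#'   are honoured (use an in-control configuration for false-alarm runs).
#' @param h control limit.
#' @param seed integer seed (`NULL` keeps the current RNG state).
#' @param cap maximum number of steps (>= 1).
#' @param model `"multitask"` (imputation) or `"meanfill"` (benchmark
#'   in-control-mean substitution).
#' @param chart optional precomputed [ScanChart-class].
#' @return list with `runLength` (first exceedance time, or `cap` when
#'   censored), logical `alarm`, and the global-statistic `trajectory`.
#' @export
runLength <- function(config, h, seed = NULL, cap = 1000L,
                      model = c("multitask", "meanfill"), chart = NULL) {
  cap <- as.integer(cap)
  if (is.na(cap) || cap < 1L) stop("cap must be a positive integer")
  if (is.null(chart)) chart <- chartForConfig(config)
  p <- pipelinePrep(config, chart)
  if (!is.null(seed)) set.seed(seed)
  tr <- cpp_run_traj(p$cholU, p$shift, p$v, p$L, p$noiseSd, p$nmiss,
                     p$mu0, p$kj, p$kinv, p$pi0, p$tau, p$tol, p$maxIter,
                     1e-12, p$Bt, p$offs, h, cap, modeCode(model))
  list(runLength = length(tr$U), alarm = tr$alarm, trajectory = tr$U)
}

# Run-length statistics of the reflected CUSUM scan at threshold h over a
# stored increment stream.  The scan restarts from zero after every alarm,
# so the segment lengths between alarms are i.i.d. run lengths; segments
# longer than `cap` are censored at the cap.  The trailing partial segment
# is dropped.
segmentStats <- function(inc, h, cap) {
  sg <- cpp_segment_run_lengths(inc, h)
  lens <- sg$lengths
  if (!length(lens))
    return(list(arl = Inf, se = NA_real_, n = 0L, censored = 0L,
                runLengths = numeric(0)))
  censored <- sum(lens >= cap)
  lens <- pmin(lens, cap)
  list(arl = mean(lens), se = stats::sd(lens) / sqrt(length(lens)),
       n = length(lens), censored = as.integer(censored),
       runLengths = lens)
}

# Bisection of a nondecreasing ARL(h) curve on [0, hMax] for a target.
bisectArl <- function(arlFun, target, hMax, relTol, maxIter = 80L) {
  lo <- 0
  hi <- hMax
  best <- hMax
  bestGap <- Inf
  for (i in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    a <- arlFun(mid)
    gap <- abs(a - target)
    if (is.finite(gap) && gap < bestGap) {
      bestGap <- gap
      best <- mid
    }
    if (is.finite(a) && gap <= relTol * target) return(mid)
    if (is.finite(a) && a < target) lo <- mid else hi <- mid
    if ((hi - lo) <= 1e-12 * max(1, hi)) break
  }
  best
}

#' Calibrate the control limit for a target in-control ARL
#'
#' Monte-Carlo calibration of the control limit `h` against the full
#' monitoring pipeline (simulation, masking, imputation, scan).  The
#' calibration exploits the regenerative structure of the reflected
#' CUSUM: all statistics restart from zero at an alarm, so on one long
#' in-control increment stream the segments between successive alarms at
#' a given threshold are independent run-length replications.  The stream
#' is grown until at least `reps` completed replications exist at the
#' calibrated threshold, and `h` is found by bisection over the stored
#' stream -- every candidate threshold is evaluated on the same
#' increments (exact common random numbers) -- until the achieved ARL is
#' within `relTol` of the target or the bracket collapses.  Replications
#' exceeding `cap` are censored at the cap.
#'
#' @param config a [SimulationConfig-class]; the shift and change point
#'   are ignored (calibration is under control), but the shift magnitude
#'   defines the chart direction.
#' @param targetArl0 target in-control average run length (> 1).
#' @param reps minimum number of run-length replications at the
#'   calibrated threshold (>= 10, default 200).
#' @param cap run-length cap (default `4 * targetArl0`).
#' @param seed master seed.
#' @param model `"multitask"` or `"meanfill"`.
#' @param relTol relative calibration tolerance (default 0.05).
#' @param chart optional precomputed [ScanChart-class].
#' @param incrementFun optional function `f(nSteps)` returning a
#'   `statistics x nSteps` increment matrix, replacing the simulated
#'   pipeline (used to validate the calibration machinery against charts
#'   with known run-length laws).
#' @return a [CalibrationResult-class].
#' @export
calibrateH <- function(config = NULL, targetArl0 = 1000, reps = 200,
                       cap = 4 * targetArl0, seed = 1,
                       model = c("multitask", "meanfill"), relTol = 0.05,
                       chart = NULL, incrementFun = NULL) {
  if (targetArl0 <= 1) stop("targetArl0 must exceed 1")
  reps <- as.integer(reps)
  if (reps < 10L) stop("at least 10 replications are required")
  cap <- as.integer(cap)
  if (cap < 4L * targetArl0 - 1e-9)
    stop("cap must be at least 4 * targetArl0")
  model <- match.arg(model)
  p <- NULL
  if (is.null(incrementFun)) {
    if (is.null(config)) stop("either a config or an incrementFun is required")
    if (is.null(chart)) chart <- chartForConfig(config)
    p <- pipelinePrep(config, chart)
  }
  set.seed(seed)
  drawChunk <- function(k) {
    if (is.null(incrementFun)) {
      cpp_increment_stream(p$cholU, p$L, p$noiseSd, p$nmiss, p$mu0, p$kj,
                           p$kinv, p$pi0, p$tau, p$tol, p$maxIter, 1e-12,
                           p$Bt, p$offs, as.integer(k), modeCode(model))
    } else {
      incrementFun(as.integer(k))
    }
  }
  # Grow the stream in chunks.  A first short chunk settles whether the
  # target is attainable at all: if even the zero threshold (alarm on any
  # positive statistic) yields an ARL conclusively above the target, no
  # h >= 0 can achieve it -- the chart is then run at h = 0, the closest
  # (conservative) attainable limit.
  total <- ceiling(1.05 * reps * targetArl0)
  inc <- drawChunk(ceiling(0.3 * reps * targetArl0))
  maxLen <- max(ceiling(3 * reps * targetArl0), ceiling(100 * targetArl0))
  unattainable <- FALSE
  repeat {
    a0 <- segmentStats(inc, 0, cap)
    conclusiveHigh <- a0$n >= 10L && is.finite(a0$arl) &&
      a0$arl - 2 * a0$se > targetArl0 * (1 + relTol)
    # with few or no excursions, a conservative lower bound on the
    # zero-threshold ARL still settles unattainability
    lowerBound <- ncol(inc) / (a0$n + 1)
    if (conclusiveHigh ||
        (ncol(inc) >= 20 * targetArl0 && lowerBound > 2 * targetArl0)) {
      unattainable <- TRUE
      h <- 0
      st <- if (a0$n > 0L) a0 else
        list(arl = Inf, se = NA_real_, n = 0L, censored = 0L)
      break
    }
    hMax <- max(cpp_global_path(inc))
    st <- NULL
    if (hMax > 0) {
      h <- bisectArl(function(hh) segmentStats(inc, hh, cap)$arl,
                     targetArl0, hMax, relTol)
      st <- segmentStats(inc, h, cap)
      if (st$n >= reps) break
    }
    if (ncol(inc) >= maxLen) {
      if (hMax <= 0)
        stop("the global statistic never left zero; cannot bracket the control limit")
      break
    }
    deficit <- if (is.null(st)) total - ncol(inc) else
      max(total - ncol(inc), (reps - st$n) * targetArl0)
    chunk <- min(max(deficit, 1), ceiling(0.35 * reps * targetArl0),
                 maxLen - ncol(inc))
    inc <- cbind(inc, drawChunk(chunk))
  }
  if (unattainable)
    warning(sprintf(
      "target ARL0 = %g is unattainable: even at h = 0 the achieved ARL0 is %s (the in-control scan statistic rarely leaves zero); returning the conservative limit h = 0",
      targetArl0,
      if (is.finite(st$arl)) sprintf("%.0f", st$arl)
      else "beyond the simulated stream"))
  if (!unattainable && st$n < reps)
    warning(sprintf(
      "only %d run-length replications completed within the stream budget",
      st$n))
  new("CalibrationResult", threshold = h,
      targetArl0 = as.numeric(targetArl0),
      achievedArl0 = st$arl,
      standardError = st$se,
      replications = st$n, cap = cap, censored = st$censored,
      seed = as.integer(seed))
}

#' Fresh-seed re-estimation of the in-control ARL
#'
#' Runs independent in-control replications of the full pipeline at a
#' fixed control limit and averages the run lengths (censored at `cap`).
#'
#' @inheritParams calibrateH
#' @param h control limit.
#' @param reps number of replications.
#' @return list with `arl0`, `standardError`, `runLengths` and `censored`.
#' @export
estimateArl0 <- function(config, h, reps = 200, seed = 1,
                         cap = 4000, model = c("multitask", "meanfill"),
                         chart = NULL) {
  model <- match.arg(model)
  if (is.null(chart)) chart <- chartForConfig(config)
  p <- pipelinePrep(config, chart)
  seeds <- subSeeds(seed, reps)
  rls <- numeric(reps)
  cens <- 0L
  for (i in seq_len(reps)) {
    set.seed(seeds[i])
    tr <- cpp_run_traj(p$cholU, numeric(length(p$shift)), 0L, p$L,
                       p$noiseSd, p$nmiss, p$mu0, p$kj, p$kinv, p$pi0,
                       p$tau, p$tol, p$maxIter, 1e-12, p$Bt, p$offs,
                       h, as.integer(cap), modeCode(model))
    rls[i] <- length(tr$U)
    if (!tr$alarm) cens <- cens + 1L
  }
  list(arl0 = mean(rls), standardError = stats::sd(rls) / sqrt(reps),
       runLengths = rls, censored = cens)
}

#' Estimate the out-of-control ARL of a scenario
#'
#' For each replication the full sequence is simulated with the
#' configured shift from the change point onward, the CUSUM state being
#' carried through the in-control prefix.  The detection delay is
#' `alarm time - changePoint + 1`.  Replications that alarm before the
#' change point are discarded and counted; replications that never alarm
#' within `cap` steps are counted at the censored delay.
#'
#' @param config a [SimulationConfig-class] with a change point set.
#' @param h control limit.
#' @param reps number of replications (default 100).
#' @param seed master seed.
#' @param model `"multitask"` or `"meanfill"`.
#' @param cap maximum simulated steps (default the configured horizon).
#' @param chart optional precomputed [ScanChart-class].
#' @return a [RunLengthSummary-class].
#' @export
estimateArl1 <- function(config, h, reps = 100, seed = 1,
                         model = c("multitask", "meanfill"), cap = NULL,
                         chart = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (is.na(config@changePoint))
    stop("config must set a change point for out-of-control estimation")
  model <- match.arg(model)
  if (is.null(chart)) chart <- chartForConfig(config)
  if (is.null(cap)) cap <- config@horizon
  cap <- as.integer(cap)
  v <- config@changePoint
  if (cap < v) stop("cap must reach the change point")
  p <- pipelinePrep(config, chart)
  seeds <- subSeeds(seed, reps)
  delays <- numeric(0)
  discarded <- 0L
  censored <- 0L
  for (i in seq_len(reps)) {
    set.seed(seeds[i])
    tr <- cpp_run_traj(p$cholU, p$shift, p$v, p$L, p$noiseSd, p$nmiss,
                       p$mu0, p$kj, p$kinv, p$pi0, p$tau, p$tol,
                       p$maxIter, 1e-12, p$Bt, p$offs, h, cap,
                       modeCode(model))
    tAlarm <- length(tr$U)
    if (tr$alarm && tAlarm < v) {
      discarded <- discarded + 1L
      next
    }
    if (!tr$alarm) censored <- censored + 1L
    delays <- c(delays, tAlarm - v + 1)
  }
  if (!length(delays))
    stop("every replication alarmed before the change point; nothing to summarize")
  new("RunLengthSummary", arl1 = mean(delays),
      standardError = stats::sd(delays) / sqrt(length(delays)),
      runLengths = delays, discarded = discarded,
      censored = censored)
}

#' Scenario grid of calibrated out-of-control ARLs
#'
#' Crosses shift magnitudes, cluster patterns, missing ratios and models.
#' Each (model, shift, ratio) combination gets its own calibrated control
#' limit -- the chart direction depends on the shift and the pipeline on
#' the ratio and model -- which is then shared by all cluster patterns of
#' that combination (the chart scans every cluster regardless of the true
#' outbreak geometry).  Evaluation replications use the same master seed
#' across scenarios, so comparisons between models, shifts and patterns
#' are paired.
#'
#' @param config base [SimulationConfig-class].
#' @param shifts numeric vector of shift magnitudes.
#' @param patterns character vector of cluster patterns.
#' @param ratios numeric vector of missing ratios.
#' @param models character subset of `c("multitask", "meanfill")`.
#' @param targetArl0 target in-control ARL for each calibration.
#' @param calibReps calibration replications.
#' @param evalReps evaluation replications.
#' @param cap calibration run-length cap (default `4 * targetArl0`).
#' @param seed master seed.
#' @return long-format data frame with one row per scenario cell:
#'   `model`, `shift`, `pattern`, `ratio`, `h`, `achievedArl0`, `arl1`,
#'   `se`, `nValid`, `discarded`, `censored`.
#' @export
experimentGrid <- function(config, shifts, patterns, ratios,
                           models = c("multitask", "meanfill"),
                           targetArl0 = 1000, calibReps = 200,
                           evalReps = 100, cap = 4 * targetArl0,
                           seed = 1) {
  if (!length(shifts) || !length(patterns) || !length(ratios) ||
      !length(models))
    stop("shifts, patterns, ratios and models must be nonempty")
  seeds <- subSeeds(seed, 2L)
  rows <- list()
  for (model in models) {
    for (shift in shifts) {
      for (ratio in ratios) {
        cfg <- simConfig(grid = config@grid,
                         covarianceScale = config@covarianceScale,
                         horizon = config@horizon,
                         changePoint = config@changePoint,
                         clusterPattern = patterns[1L],
                         shiftMagnitude = shift,
                         processCount = config@processCount,
                         noiseSd = config@noiseSd, missingRatio = ratio)
        chart <- chartForConfig(cfg)
        cal <- calibrateH(cfg, targetArl0 = targetArl0, reps = calibReps,
                          cap = cap, seed = seeds[1L], model = model,
                          chart = chart)
        for (pattern in patterns) {
          cfgP <- simConfig(grid = config@grid,
                            covarianceScale = config@covarianceScale,
                            horizon = config@horizon,
                            changePoint = config@changePoint,
                            clusterPattern = pattern,
                            shiftMagnitude = shift,
                            processCount = config@processCount,
                            noiseSd = config@noiseSd,
                            missingRatio = ratio)
          rl <- estimateArl1(cfgP, cal@threshold, reps = evalReps,
                             seed = seeds[2L], model = model,
                             chart = chart)
          rows[[length(rows) + 1L]] <- data.frame(
            model = model, shift = shift, pattern = pattern,
            ratio = ratio, h = cal@threshold,
            achievedArl0 = cal@achievedArl0, arl1 = rl@arl1,
            se = rl@standardError, nValid = length(rl@runLengths),
            discarded = rl@discarded, censored = rl@censored)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' @rdname threshold
#' @export
setMethod("threshold", "CalibrationResult", function(x) x@threshold)

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult: h = %.6g for target ARL0 = %g\n  achieved ARL0 = %.1f (SE %.1f) from %d replications (cap %d, %d censored)\n",
    object@threshold, object@targetArl0, object@achievedArl0,
    object@standardError, object@replications, object@cap,
    object@censored))
  invisible(object)
})

setMethod("show", "RunLengthSummary", function(object) {
  cat(sprintf(
    "RunLengthSummary: ARL1 = %.2f (SE %.2f) from %d delays (%d discarded, %d censored)\n",
    object@arl1, object@standardError, length(object@runLengths),
    object@discarded, object@censored))
  invisible(object)
})
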