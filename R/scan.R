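#' Enumerate circular scan clusters
#'
#' Builds every candidate cluster `O_{c,r} = {s_i : ||s_i - c|| <= r}`
#' with every grid location as a candidate center and `r` running over
#' the distinct pairwise distances of the grid (including 0) up to
#' `maxRadius`.  For a fixed center, radii that yield an identical member
#' set are collapsed to the smallest such radius, since duplicated
#' clusters cannot change the scan maximum.  Every singleton `{c}` is
#' present through radius 0.
#'
#' @param grid a [SensorGrid-class].
#' @param maxRadius nonnegative upper scan radius `r_u`.
#' @return a [ClusterSet-class], ordered by center index then radius.
#' @examples
#' cs <- enumerateClusters(sensorGrid(5, 5), 2)
#' nClusters(cs)
#' cs@radii   # 0, 1, sqrt(2), 2
#' @export
enumerateClusters <- function(grid, maxRadius) {
  stopifnot(is(grid, "SensorGrid"))
  if (!is.numeric(maxRadius) || length(maxRadius) != 1L || maxRadius < 0)
    stop("maxRadius must be a single nonnegative number")
  D <- gridDistances(grid)
  radii <- sort(unique(round(D[D <= maxRadius + 1e-9], 9)))
  if (!length(radii)) radii <- 0
  n <- nLocations(grid)
  centers <- integer(0)
  radius <- numeric(0)
  members <- list()
  for (c0 in seq_len(n)) {
    prevSize <- -1L
    for (r in radii) {
      mem <- unname(which(D[c0, ] <= r + 1e-9))
      if (length(mem) == prevSize) next
      prevSize <- length(mem)
      centers <- c(centers, c0)
      radius <- c(radius, r)
      members[[length(members) + 1L]] <- mem
    }
  }
  new("ClusterSet", grid = grid, maxRadius = as.numeric(maxRadius),
      radii = radii, centers = centers, radius = radius, members = members)
}

#' @rdname nClusters
#' @export
setMethod("nClusters", "ClusterSet", function(x) length(x@centers))

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf(
    "ClusterSet: %d clusters on a %d x %d grid (radii up to %g: %s)\n",
    nClusters(object), object@grid@nRows, object@grid@nCols,
    object@maxRadius, paste(signif(object@radii, 4), collapse = ", ")))
  invisible(object)
})

#' Restrict a shift direction to a cluster
#'
#' Zeroes out the components of an out-of-control mean direction that fall
#' outside the cluster: `[mu_{c,r}]_j = [mu_1]_j` for `j` in the cluster
#' and 0 otherwise.
#'
#' @param direction length-`n` shift direction `mu_1`.
#' @param cluster integer vector of member location indices.
#' @return length-`n` restricted mean vector.
#' @export
restrictMean <- function(direction, cluster) {
  out <- numeric(length(direction))
  out[cluster] <- direction[cluster]
  out
}

#' Likelihood-ratio increment of one cluster
#'
#' The per-step log-likelihood-ratio score
#' `l = mu_{c,r}' Sigma^{-1} (x - mu_{c,r} / 2)` contrasting the shifted
#' against the in-control mean under the multivariate normal model.  For
#' repeated evaluation over time use [scanChart()], which factorizes
#' `Sigma` once and precomputes `Sigma^{-1} mu` for every cluster.
#'
#' @param xHat completed slice values (length `n`).
#' @param muCr restricted mean vector (length `n`).
#' @param sigma `n x n` covariance matrix.
#' @param jitter diagonal ridge added before factorization (default
#'   [fieldJitter()]).
#' @return the scalar increment.
#' @export
lrStatistic <- function(xHat, muCr, sigma, jitter = fieldJitter()) {
  n <- length(xHat)
  ch <- cholRidge(sigma + jitter * diag(n), "covariance matrix")
  b <- backsolve(ch, forwardsolve(t(ch), muCr))
  sum(b * (xHat - muCr / 2))
}

#' CUSUM recursion
#'
#' `S_t = max(0, S_{t-1} + l_t)`: accumulate evidence, reflecting at zero.
#'
#' @param prev previous CUSUM value(s), nonnegative.
#' @param increment likelihood-ratio increment(s).
#' @return updated value(s).
#' @export
updateCusum <- function(prev, increment) {
  pmax(0, prev + increment)
}

#' Specify the monitored shift alternatives
#'
#' @param directions numeric matrix (`K x n`) of candidate out-of-control
#'   mean directions, or a single length-`n` vector for the known-shift
#'   chart.
#' @param sigma `n x n` in-control covariance matrix.
#' @param inControlMean in-control mean (scalar recycled to length `n`;
#'   default 0, the standardized scale).
#' @return a [ShiftSpec-class].
#' @export
shiftSpec <- function(directions, sigma, inControlMean = 0) {
  if (is.null(dim(directions)))
    directions <- matrix(directions, nrow = 1L)
  n <- ncol(directions)
  mu0 <- rep_len(as.numeric(inControlMean), n)
  new("ShiftSpec", inControlMean = mu0, directions = directions,
      covariance = sigma)
}

#' Homogeneous shift direction
#'
#' The direction used by the known-shift chart of a homogeneous outbreak:
#' a constant shift of the given magnitude at every location (restriction
#' to each scanned cluster happens inside the chart).
#'
#' @param magnitude shift magnitude.
#' @param n number of locations.
#' @return length-`n` direction vector.
#' @export
homogeneousDirection <- function(magnitude, n) {
  rep(as.numeric(magnitude), n)
}

#' Precompute the MCUSUM scan chart
#'
#' For every direction `k` and cluster `(c, r)` the restricted mean is
#' formed, `Sigma^{-1} mu_{c,r}^k` is solved once through a Cholesky
#' factorization of the jittered covariance, and the offset
#' `mu' Sigma^{-1} mu / 2` is stored.  All per-slice statistics then
#' reduce to one matrix-vector product.
#'
#' @param spec a [ShiftSpec-class].
#' @param clusters a [ClusterSet-class].
#' @param jitter diagonal ridge for the covariance factorization
#'   (default [fieldJitter()]).
#' @return a [ScanChart-class].
#' @export
scanChart <- function(spec, clusters, jitter = fieldJitter()) {
  stopifnot(is(spec, "ShiftSpec"), is(clusters, "ClusterSet"))
  n <- length(spec@inControlMean)
  K <- nrow(spec@directions)
  M <- nClusters(clusters)
  ch <- cholRidge(spec@covariance + jitter * diag(n), "covariance matrix")
  solved <- matrix(0, K * M, n)
  offsets <- numeric(K * M)
  dirIdx <- integer(K * M)
  cluIdx <- integer(K * M)
  row <- 0L
  for (k in seq_len(K)) {
    for (j in seq_len(M)) {
      row <- row + 1L
      mu <- restrictMean(spec@directions[k, ], clusters@members[[j]])
      b <- backsolve(ch, forwardsolve(t(ch), mu))
      solved[row, ] <- b
      offsets[row] <- sum(mu * b) / 2
      dirIdx[row] <- k
      cluIdx[row] <- j
    }
  }
  new("ScanChart", spec = spec, clusters = clusters, solved = solved,
      offsets = offsets, directionIndex = dirIdx, clusterIndex = cluIdx)
}

#' @rdname nClusters
#' @export
setMethod("nClusters", "ScanChart", function(x) nClusters(x@clusters))

setMethod("show", "ScanChart", function(object) {
  cat(sprintf(
    "ScanChart: %d direction(s) x %d clusters = %d CUSUM statistics\n",
    nrow(object@spec@directions), nClusters(object@clusters),
    nrow(object@solved)))
  invisible(object)
})

#' Fresh scan state
#'
#' All CUSUM statistics start at zero at time zero.
#'
#' @param chart a [ScanChart-class].
#' @return a [ScanState-class].
#' @export
newScanState <- function(chart) {
  new("ScanState", cusum = numeric(nrow(chart@solved)), time = 0L,
      globalStat = 0, history = numeric(0))
}

#' Advance the scan chart by one slice
#'
#' Updates every (direction, cluster) CUSUM in parallel with the slice's
#' likelihood-ratio increments, takes the global statistic as their
#' maximum and raises an alarm when it strictly exceeds the control
#' limit.  With a single direction the global statistic of the
#' unknown-shift chart coincides with that of the known-shift chart.
#'
#' @param state a [ScanState-class].
#' @param xHat completed slice values (length `n`).
#' @param chart a [ScanChart-class].
#' @param h control limit.
#' @return list with the updated `state` and logical `alarm`.
#' @export
scanStep <- function(state, xHat, chart, h) {
  stopifnot(is(state, "ScanState"), is(chart, "ScanChart"))
  inc <- as.numeric(chart@solved %*% xHat) - chart@offsets
  cus <- updateCusum(state@cusum, inc)
  g <- max(cus)
  st <- new("ScanState", cusum = cus, time = state@time + 1L,
            globalStat = g, history = c(state@history, g))
  list(state = st, alarm = g > h)
}

#' Run the scan chart over a sequence of slices
#'
#' Feeds completed slices to [scanStep()] in time order and stops at the
#' first strict exceedance of the control limit.  Raw slices containing
#' `NA` can be completed on the fly through `imputeHook`.  The scan argmax
#' identifies the outbreak as the (direction, center, radius) of the
#' maximal CUSUM; ties break toward the smallest direction index, then
#' center index, then radius (the chart's row order).
#'
#' @param slices `T x n` matrix of slice values, one row per time step.
#' @param chart a [ScanChart-class].
#' @param h control limit (may be `Inf` or negative).
#' @param imputeHook optional function applied to each raw slice before
#'   scanning (e.g. an imputer closure); receives the row and its index.
#' @param keepHistory retain the global-statistic trajectory (default
#'   `TRUE`).
#' @return an [AlarmReport-class].
#' @export
runScan <- function(slices, chart, h, imputeHook = NULL,
                    keepHistory = TRUE) {
  if (is.null(dim(slices)) || nrow(slices) == 0L)
    stop("slices must be a nonempty time x location matrix")
  state <- newScanState(chart)
  Tn <- nrow(slices)
  for (t in seq_len(Tn)) {
    x <- slices[t, ]
    if (!is.null(imputeHook)) x <- imputeHook(x, t)
    if (anyNA(x))
      stop("slice contains missing values; supply an imputeHook or complete the panel first")
    res <- scanStep(state, x, chart, h)
    state <- res$state
    if (res$alarm) {
      am <- which.max(state@cusum)
      j <- chart@clusterIndex[am]
      return(new("AlarmReport", alarmTime = t,
                 direction = chart@directionIndex[am],
                 center = chart@clusters@centers[j],
                 radius = chart@clusters@radius[j],
                 statistic = state@globalStat, threshold = as.numeric(h),
                 trajectory = if (keepHistory) state@history else numeric(0)))
    }
  }
  am <- which.max(state@cusum)
  j <- chart@clusterIndex[am]
  new("AlarmReport", alarmTime = NA_integer_,
      direction = chart@directionIndex[am],
      center = chart@clusters@centers[j],
      radius = chart@clusters@radius[j],
      statistic = state@globalStat, threshold = as.numeric(h),
      trajectory = if (keepHistory) state@history else numeric(0))
}

#' Benchmark chart step without multitask imputation
#'
#' The comparator chart: identical scan, but every missing entry of the
#' raw slice is replaced by the in-control mean instead of a multitask
#' imputation.
#'
#' @param state a [ScanState-class].
#' @param xRaw raw slice values with `NA` at missing entries.
#' @param chart a [ScanChart-class].
#' @param h control limit.
#' @return list with the updated `state` and logical `alarm`.
#' @export
benchmarkStep <- function(state, xRaw, chart, h) {
  miss <- is.na(xRaw)
  xRaw[miss] <- chart@spec@inControlMean[miss]
  scanStep(state, xRaw, chart, h)
}

#' @rdname threshold
#' @export
setMethod("threshold", "AlarmReport", function(x) x@threshold)

#' @rdname alarmTime
#' @export
setMethod("alarmTime", "AlarmReport", function(x) x@alarmTime)

setMethod("show", "AlarmReport", function(object) {
  if (is.na(object@alarmTime)) {
    cat(sprintf(
      "AlarmReport: no alarm (final statistic %.4g <= h = %.4g)\n",
      object@statistic, object@threshold))
  } else {
    cat(sprintf(
      "AlarmReport: alarm at t = %d (statistic %.4g > h = %.4g); cluster center %d, radius %.3g, direction %d\n",
      object@alarmTime, object@statistic, object@threshold,
      object@center, object@radius, object@direction))
  }
  invisible(object)
})
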