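#' Spatial covariance of the latent field
#'
#' Builds the `n x n` covariance matrix of the latent field from the
#' exponentiated squared-distance covariance function
#' `c(s_i, s_j) = exp(-||s_i - s_j||^2 / d)`.  The matrix has unit
#' diagonal and is positive semidefinite; because large `d` on a small
#' grid makes it nearly rank-deficient, downstream factorizations add a
#' `1e-8` diagonal jitter (see [fieldJitter()]).
#'
#' @param grid a [SensorGrid-class].
#' @param d positive covariance scale.
#' @return symmetric `n x n` covariance matrix with unit diagonal.
#' @examples
#' S <- makeCovariance(sensorGrid(5, 5), 250)
#' S[1, 2]  # adjacent cells: exp(-1/250)
#' @export
makeCovariance <- function(grid, d) {
  stopifnot(is(grid, "SensorGrid"))
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("covariance scale d must be a single positive number")
  D <- gridDistances(grid)
  S <- exp(-D^2 / d)
  (S + t(S)) / 2
}

#' Diagonal jitter used before factorizing field covariances
#'
#' @return the ridge (1e-8) added to the diagonal of the field covariance
#'   before Cholesky factorization or linear solves.
#' @export
fieldJitter <- function() 1e-8

#' Outbreak-cluster geometries
#'
#' Named circular outbreak clusters centered at the grid center:
#' `small` has radius 1 (5 cells on a unit lattice), `medium` radius
#' `sqrt(2)` (a 3 x 3 block, 9 cells) and `large` radius 2 (13 cells).
#' The three patterns are concentric and monotone in size.
#'
#' @param name one of `"small"`, `"medium"`, `"large"`.
#' @param grid a [SensorGrid-class] with at least 5 rows and columns.
#' @return logical membership vector over locations.
#' @examples
#' sum(clusterPattern("medium", sensorGrid(5, 5)))  # 9
#' @export
clusterPattern <- function(name, grid) {
  stopifnot(is(grid, "SensorGrid"))
  radii <- c(small = 1, medium = sqrt(2), large = 2)
  if (!is.character(name) || length(name) != 1L || !name %in% names(radii))
    stop("unknown cluster pattern: ", paste(name, collapse = ", "),
         " (expected small, medium or large)")
  if (grid@nRows < 5L || grid@nCols < 5L)
    stop("named cluster patterns require a grid of at least 5 x 5")
  co <- gridCoords(grid)
  center <- c(p = (grid@nRows + 1) / 2, q = (grid@nCols + 1) / 2) *
    grid@spacing
  dd <- sqrt((co[, 1L] - center[1L])^2 + (co[, 2L] - center[2L])^2)
  dd <= radii[[name]] * grid@spacing + 1e-9
}

#' Configure a synthetic monitoring study
#'
#' The defaults regenerate the reference simulation design: a 5 x 5 unit
#' grid, exponential spatial covariance with scale `d = 250`, a horizon of
#' 300 steps with the outbreak starting at time 51, three related
#' processes sharing the latent field plus `N(0, 0.1^2)` sensor noise, and
#' 20% of each process masked missing per time slice.
#'
#' @param grid a [SensorGrid-class].
#' @param covarianceScale covariance scale `d` (default 250).
#' @param horizon number of time steps (default 300).
#' @param changePoint first out-of-control step or `NA`; the default is
#'   51 when the horizon reaches that far, otherwise `NA` (in control).
#' @param clusterPattern `"small"`, `"medium"`, `"large"`, or a logical /
#'   integer vector giving explicit cluster membership.
#' @param shiftMagnitude homogeneous mean shift on the cluster (default 1).
#' @param processCount number of related processes `L` (default 3).
#' @param noiseSd sensor-noise standard deviation (default 0.1).
#' @param missingRatio per-slice missing fraction in `[0, 1)` (default 0.2).
#' @param seed integer seed recorded with the configuration (default `NA`).
#' @return a [SimulationConfig-class].
#' @examples
#' cfg <- simConfig(missingRatio = 0.5, shiftMagnitude = 2)
#' @export
simConfig <- function(grid = sensorGrid(5, 5), covarianceScale = 250,
                      horizon = 300, changePoint = NULL,
                      clusterPattern = "medium", shiftMagnitude = 1,
                      processCount = 3, noiseSd = 0.1, missingRatio = 0.2,
                      seed = NA) {
  n <- nLocations(grid)
  if (is.null(changePoint))
    changePoint <- if (horizon >= 51) 51 else NA_integer_
  mask <- if (is.character(clusterPattern)) {
    fieldscan::clusterPattern(clusterPattern, grid)
  } else if (is.logical(clusterPattern)) {
    if (length(clusterPattern) != n)
      stop("logical clusterPattern must have one entry per location")
    clusterPattern
  } else {
    m <- rep(FALSE, n)
    m[as.integer(clusterPattern)] <- TRUE
    m
  }
  new("SimulationConfig", grid = grid,
      covarianceScale = as.numeric(covarianceScale),
      horizon = as.integer(horizon), changePoint = as.integer(changePoint),
      clusterMask = mask, shiftMagnitude = as.numeric(shiftMagnitude),
      processCount = as.integer(processCount), noiseSd = as.numeric(noiseSd),
      missingRatio = as.numeric(missingRatio), seed = as.integer(seed))
}

#' Number of entries masked missing per process and time slice
#'
#' The missing count is exact rather than Bernoulli: `ratio * n` rounded
#' half-up, so the configured ratio holds at every slice.
#'
#' @param ratio missing fraction in `[0, 1)`.
#' @param n number of locations.
#' @return integer count of missing entries per (process, time).
#' @examples
#' missingCount(0.2, 25)  # 5
#' missingCount(0.5, 25)  # 13 (round half-up)
#' @export
missingCount <- function(ratio, n) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio < 0 || ratio >= 1)
    stop("missing ratio must lie in [0, 1)")
  as.integer(floor(ratio * n + 0.5))
}

#' Simulate the latent spatiotemporal field
#'
#' Draws `horizon` independent multivariate-normal rows with mean zero and
#' the covariance of [makeCovariance()]; from the change point onward the
#' configured mean shift is added on the cluster locations.  The in-control
#' mean is zero on the standardized scale.
#'
#' @param config a [SimulationConfig-class].
#' @param seed integer seed; when `NULL` the current RNG state is used.
#' @return a [FieldPanel-class].
#' @export
simulateField <- function(config, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  n <- nLocations(config@grid)
  Tn <- config@horizon
  S <- makeCovariance(config@grid, config@covarianceScale)
  R <- chol(S + fieldJitter() * diag(n))
  X <- matrix(stats::rnorm(Tn * n), Tn, n) %*% R
  v <- config@changePoint
  if (!is.na(v) && config@shiftMagnitude > 0 && any(config@clusterMask)) {
    shift <- ifelse(config@clusterMask, config@shiftMagnitude, 0)
    idx <- seq.int(v, Tn)
    X[idx, ] <- X[idx, , drop = FALSE] +
      matrix(shift, length(idx), n, byrow = TRUE)
  }
  new("FieldPanel", values = X, changePoint = config@changePoint,
      clusterMask = config@clusterMask,
      shiftMagnitude = config@shiftMagnitude, grid = config@grid)
}

#' Assemble an observation panel
#'
#' Low-level constructor validating the value/mask arrays and checking the
#' coverage assumption: at every time step the union over processes of
#' observed locations should cover the whole grid.  A violation is reported
#' as a warning, not an error, since imputation remains defined.
#'
#' @param values numeric `L x T x n` array (`NA` at missing entries).
#' @param observed logical array of the same dimension.
#' @param grid the shared [SensorGrid-class].
#' @param checkCoverage warn when some location is unobserved by every
#'   process at some time (default `TRUE`).
#' @return an [ObservationPanel-class].
#' @export
observationPanel <- function(values, observed, grid, checkCoverage = TRUE) {
  pan <- new("ObservationPanel", values = values, observed = observed,
             grid = grid)
  if (checkCoverage) {
    cover <- apply(observed, c(2L, 3L), any)
    bad <- which(!cover, arr.ind = TRUE)
    if (nrow(bad)) {
      warning(sprintf(
        "coverage violated: %d (time, location) cells observed by no process (first at t = %d, location %d)",
        nrow(bad), bad[1L, 1L], bad[1L, 2L]))
    }
  }
  pan
}

#' Derive related noisy processes from a latent field
#'
#' Each of the `L` related processes equals the shared latent field plus
#' independent Gaussian sensor noise; the processes differ only in their
#' noise realizations.  The returned panel is fully observed.
#'
#' @param field a [FieldPanel-class].
#' @param processCount number of processes `L` (>= 1).
#' @param noiseSd nonnegative noise standard deviation.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a fully observed [ObservationPanel-class].
#' @export
deriveProcesses <- function(field, processCount, noiseSd, seed = NULL) {
  stopifnot(is(field, "FieldPanel"))
  L <- as.integer(processCount)
  if (is.na(L) || L < 1L) stop("processCount must be at least 1")
  if (!is.numeric(noiseSd) || length(noiseSd) != 1L || noiseSd < 0)
    stop("noiseSd must be a single nonnegative number")
  if (!is.null(seed)) set.seed(seed)
  Tn <- nrow(field@values)
  n <- ncol(field@values)
  vals <- array(NA_real_, c(L, Tn, n))
  for (l in seq_len(L))
    vals[l, , ] <- field@values +
      matrix(stats::rnorm(Tn * n, 0, noiseSd), Tn, n)
  observationPanel(vals, array(TRUE, c(L, Tn, n)), field@grid,
                   checkCoverage = FALSE)
}

#' Mask entries missing completely at random
#'
#' For every process and time slice exactly [missingCount()] locations are
#' masked missing, drawn uniformly without replacement and independently
#' across processes and times.  Existing missing entries are preserved.
#'
#' @param panel an [ObservationPanel-class].
#' @param ratio missing fraction in `[0, 1)`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an [ObservationPanel-class] with the mask applied.
#' @export
applyMissingness <- function(panel, ratio, seed = NULL) {
  stopifnot(is(panel, "ObservationPanel"))
  if (!is.null(seed)) set.seed(seed)
  d <- dim(panel@values)
  n <- d[3L]
  k <- missingCount(ratio, n)
  vals <- panel@values
  obs <- panel@observed
  if (k > 0L) {
    for (l in seq_len(d[1L])) {
      for (t in seq_len(d[2L])) {
        miss <- sample.int(n, k)
        vals[l, t, miss] <- NA_real_
        obs[l, t, miss] <- FALSE
      }
    }
  }
  observationPanel(vals, obs, panel@grid,
                   checkCoverage = ratio > 0)
}

#' Simulate a complete observation panel
#'
#' Convenience wrapper chaining [simulateField()], [deriveProcesses()] and
#' [applyMissingness()].  The master seed spawns independent sub-seeds for
#' the field, the noise and the masks, so each component is reproducible on
#' its own.
#'
#' @param config a [SimulationConfig-class].
#' @param seed master integer seed; `NULL` uses the current RNG state.
#' @return an [ObservationPanel-class].
#' @export
simulatePanel <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max - 1L, 3L)
  field <- simulateField(config, seed = subSeeds[1L])
  pan <- deriveProcesses(field, config@processCount, config@noiseSd,
                         seed = subSeeds[2L])
  applyMissingness(pan, config@missingRatio, seed = subSeeds[3L])
}
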