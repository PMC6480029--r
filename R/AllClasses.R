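#' @import methods
NULL

setClassUnion("integerOrNA", "integer")

#' Regular rectangular sensor lattice
#'
#' A `SensorGrid` describes the fixed sensor network on which every process
#' is observed: an `nRows` by `nCols` lattice with constant `spacing` between
#' neighbouring sensors.  Locations carry both a vector index `i = 1..n` and
#' 2-D coordinates `(p, q)`; the two labellings are a bijection, with `p`
#' varying fastest (column-major order).
#'
#' @slot nRows number of lattice rows (integer, `N_p`).
#' @slot nCols number of lattice columns (integer, `N_q`).
#' @slot spacing distance between adjacent sensors, in grid units.
#' @slot coords `n x 2` numeric matrix of `(p, q)` coordinates in grid
#'   units times `spacing`, one row per vector index.
#'
#' @seealso [sensorGrid()]
#' @export
setClass("SensorGrid",
  representation(nRows = "integer", nCols = "integer",
                 spacing = "numeric", coords = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@nRows) != 1L || object@nRows < 1L)
      msg <- c(msg, "nRows must be a single positive integer")
    if (length(object@nCols) != 1L || object@nCols < 1L)
      msg <- c(msg, "nCols must be a single positive integer")
    if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
        object@spacing <= 0)
      msg <- c(msg, "spacing must be a single positive number")
    n <- object@nRows * object@nCols
    if (!is.numeric(object@coords) || nrow(object@coords) != n ||
        ncol(object@coords) != 2L)
      msg <- c(msg, "coords must be an (nRows*nCols) x 2 numeric matrix")
    if (length(msg)) msg else TRUE
  })

#' Latent spatiotemporal field with a possible outbreak cluster
#'
#' A `FieldPanel` holds the noiseless latent field of a simulated study:
#' one row per time point, one column per sensor location.  Before the
#' change point every row has in-control mean zero; from the change point
#' onward the locations flagged in `clusterMask` carry an additive mean
#' shift of `shiftMagnitude`.
#'
#' @slot values `T x n` numeric matrix of latent field values.
#' @slot changePoint first out-of-control time step (integer), or
#'   `NA_integer_` when the whole run is in control.
#' @slot clusterMask logical vector over locations marking outbreak-cluster
#'   membership.
#' @slot shiftMagnitude nonnegative mean shift applied on the cluster.
#' @slot grid the [SensorGrid-class] the field lives on.
#'
#' @seealso [simulateField()]
#' @export
setClass("FieldPanel",
  representation(values = "matrix", changePoint = "integer",
                 clusterMask = "logical", shiftMagnitude = "numeric",
                 grid = "SensorGrid"),
  validity = function(object) {
    msg <- character()
    n <- object@grid@nRows * object@grid@nCols
    if (ncol(object@values) != n)
      msg <- c(msg, "values must have one column per grid location")
    if (length(object@clusterMask) != n)
      msg <- c(msg, "clusterMask must have one entry per grid location")
    if (length(object@shiftMagnitude) != 1L || object@shiftMagnitude < 0)
      msg <- c(msg, "shiftMagnitude must be a single nonnegative number")
    v <- object@changePoint
    if (length(v) != 1L)
      msg <- c(msg, "changePoint must be a single integer or NA")
    else if (!is.na(v) && (v < 1L || v > nrow(object@values) + 1L))
      msg <- c(msg, "changePoint must lie within the horizon")
    if (length(msg)) msg else TRUE
  })

#' Multi-process observation panel with explicit missingness
#'
#' An `ObservationPanel` stores the sensor readings of `L` related processes
#' over time on a shared grid, together with the observation mask.  Entry
#' `values[l, t, i]` is the reading of process `l` at time `t` and location
#' `i`, or `NA` when that reading is missing; `observed[l, t, i]` is `TRUE`
#' exactly when the reading is available.
#'
#' @slot values numeric array of dimension `L x T x n` with `NA` at missing
#'   entries.
#' @slot observed logical array of the same dimension; `TRUE` = observed.
#' @slot grid the shared [SensorGrid-class].
#'
#' @seealso [deriveProcesses()], [applyMissingness()], [readPanel()]
#' @export
setClass("ObservationPanel",
  representation(values = "array", observed = "array", grid = "SensorGrid"),
  validity = function(object) {
    msg <- character()
    dv <- dim(object@values)
    if (length(dv) != 3L)
      msg <- c(msg, "values must be a 3-d array (process x time x location)")
    else {
      if (!identical(dv, dim(object@observed)))
        msg <- c(msg, "values and observed must have identical dimensions")
      n <- object@grid@nRows * object@grid@nCols
      if (dv[3L] != n)
        msg <- c(msg, "third dimension must match the number of locations")
      if (!is.logical(object@observed))
        msg <- c(msg, "observed must be a logical array")
      else if (any(is.na(object@values) != !object@observed))
        msg <- c(msg, "values must be NA exactly at unobserved entries")
    }
    if (length(msg)) msg else TRUE
  })

#' Configuration of a synthetic monitoring study
#'
#' Bundles every knob of the synthetic generator: grid geometry, spatial
#' covariance scale, horizon, change point, outbreak-cluster membership,
#' shift magnitude, number of related processes, observation noise and the
#' missing-data ratio.  The defaults of [simConfig()] reproduce the
#' reference simulation design used throughout the package documentation.
#'
#' @slot grid the [SensorGrid-class].
#' @slot covarianceScale scale `d` of the exponential spatial covariance
#'   `exp(-dist^2 / d)` of the latent field.
#' @slot horizon number of simulated time steps `T`.
#' @slot changePoint first out-of-control step, or `NA_integer_`.
#' @slot clusterMask logical outbreak-cluster membership over locations.
#' @slot shiftMagnitude homogeneous mean shift on the cluster.
#' @slot processCount number of related processes `L`.
#' @slot noiseSd standard deviation of the additive sensor noise.
#' @slot missingRatio fraction of locations masked missing per process and
#'   time slice (`0 <= ratio < 1`).
#' @slot seed integer seed recorded with the configuration (may be `NA`).
#'
#' @seealso [simConfig()]
#' @export
setClass("SimulationConfig",
  representation(grid = "SensorGrid", covarianceScale = "numeric",
                 horizon = "integer", changePoint = "integer",
                 clusterMask = "logical", shiftMagnitude = "numeric",
                 processCount = "integer", noiseSd = "numeric",
                 missingRatio = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    n <- object@grid@nRows * object@grid@nCols
    if (object@covarianceScale <= 0)
      msg <- c(msg, "covarianceScale must be positive")
    if (object@horizon < 1L)
      msg <- c(msg, "horizon must be at least 1")
    if (!is.na(object@changePoint) && object@changePoint > object@horizon)
      msg <- c(msg, "changePoint must not exceed the horizon")
    if (length(object@clusterMask) != n)
      msg <- c(msg, "clusterMask must have one entry per location")
    if (object@shiftMagnitude < 0)
      msg <- c(msg, "shiftMagnitude must be nonnegative")
    if (object@processCount < 1L)
      msg <- c(msg, "processCount must be at least 1")
    if (object@noiseSd < 0)
      msg <- c(msg, "noiseSd must be nonnegative")
    if (object@missingRatio < 0 || object@missingRatio >= 1)
      msg <- c(msg, "missingRatio must lie in [0, 1)")
    else if (round(object@missingRatio * n + 1e-9) >= n)
      msg <- c(msg, "missingRatio would mask every location")
    if (length(msg)) msg else TRUE
  })

#' Squared-exponential spatial kernel specification
#'
#' The kernel `k(s_i, s_j) = exp(-||s_i - s_j||^2 / delta^2)` that carries
#' spatial correlation into the multitask Gaussian-process weight prior.
#' The default range parameter `delta` is the maximum pairwise distance of
#' the grid, so that correlation stays substantial across the whole domain.
#'
#' @slot rangeParameter the range parameter `delta` (> 0).
#' @slot jitter nonnegative ridge added to the diagonal of square kernel
#'   matrices before factorization.
#'
#' @seealso [kernelSpec()], [spatialKernel()], [buildKernel()]
#' @export
setClass("KernelSpec",
  representation(rangeParameter = "numeric", jitter = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@rangeParameter) != 1L || object@rangeParameter <= 0)
      msg <- c(msg, "rangeParameter must be a single positive number")
    if (length(object@jitter) != 1L || object@jitter < 0)
      msg <- c(msg, "jitter must be a single nonnegative number")
    if (length(msg)) msg else TRUE
  })

#' Normal-inverse-Wishart hyper-prior on the weight distribution
#'
#' The conjugate hyper-prior on the mean and covariance of the kernel
#' weights: `m | C ~ N(0, C / precision)` and
#' `C ~ IW(wishartDof, kernel^-1)`.  `wishartDof` must exceed `n - 1` for
#' the inverse-Wishart to be proper; [fitSlice()] checks this against the
#' grid size.
#'
#' @slot precision prior precision `pi` (> 0) of the weight mean.
#' @slot wishartDof inverse-Wishart degrees of freedom `tau`.
#'
#' @seealso [hyperPrior()], [fitSlice()]
#' @export
setClass("HyperPrior",
  representation(precision = "numeric", wishartDof = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@precision) != 1L || object@precision <= 0)
      msg <- c(msg, "precision must be a single positive number")
    if (length(object@wishartDof) != 1L || object@wishartDof <= 0)
      msg <- c(msg, "wishartDof must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Fitted multitask EM state for one time slice
#'
#' The converged (or budget-exhausted) EM quantities for a single time
#' slice: per-process posterior weight means and covariances, the shared
#' prior mean and covariance, and the common noise variance.
#'
#' @slot weightMeans list of per-process posterior weight mean vectors.
#' @slot weightCovariances list of per-process posterior weight covariance
#'   matrices.
#' @slot priorMean shared prior weight mean vector.
#' @slot priorCovariance shared prior weight covariance matrix.
#' @slot noiseVariance estimated observation-noise variance.
#' @slot iterations number of EM map evaluations performed.
#' @slot converged `TRUE` if the stopping tolerance was reached.
#'
#' @seealso [fitSlice()], [completeSlice()]
#' @export
setClass("MultitaskState",
  representation(weightMeans = "list", weightCovariances = "list",
                 priorMean = "numeric", priorCovariance = "matrix",
                 noiseVariance = "numeric", iterations = "integer",
                 converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@weightMeans) != length(object@weightCovariances))
      msg <- c(msg, "weightMeans and weightCovariances must have equal length")
    if (object@noiseVariance < 0)
      msg <- c(msg, "noiseVariance must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' Completed slice of the target process
#'
#' One time slice of the target process after imputation: observed entries
#' are copied verbatim from the raw panel, missing entries are filled with
#' the kernel reconstruction of the fitted weights.
#'
#' @slot values length-`n` completed value vector.
#' @slot imputed logical vector; `TRUE` where the entry was imputed.
#'
#' @seealso [completeSlice()]
#' @export
setClass("CompletedSlice",
  representation(values = "numeric", imputed = "logical"),
  validity = function(object) {
    if (length(object@values) != length(object@imputed))
      "values and imputed must have equal length" else TRUE
  })

#' Circular scan clusters of a grid
#'
#' All candidate circular clusters `O_{c,r} = {s_i : ||s_i - c|| <= r}` for
#' every grid location `c` as center and every achievable radius up to
#' `maxRadius`.  Radii are the distinct pairwise distances (including 0)
#' not exceeding `maxRadius`; for a fixed center, radii yielding the same
#' member set are collapsed to the smallest such radius.  Clusters are
#' ordered by center index, then radius.
#'
#' @slot grid the [SensorGrid-class].
#' @slot maxRadius upper scan radius `r_u`.
#' @slot radii sorted distinct candidate radii (including 0).
#' @slot centers integer vector: center location index of each cluster.
#' @slot radius numeric vector: radius of each cluster.
#' @slot members list of integer vectors: member location indices.
#'
#' @seealso [enumerateClusters()]
#' @export
setClass("ClusterSet",
  representation(grid = "SensorGrid", maxRadius = "numeric",
                 radii = "numeric", centers = "integer",
                 radius = "numeric", members = "list"),
  validity = function(object) {
    msg <- character()
    m <- length(object@centers)
    if (length(object@radius) != m || length(object@members) != m)
      msg <- c(msg, "centers, radius and members must have equal length")
    if (length(msg)) msg else TRUE
  })

#' Shift alternatives and covariance of the monitoring chart
#'
#' The in-control mean, the candidate out-of-control mean directions (one
#' row per direction; a single row for the known-shift chart) and the known
#' spatial covariance used by the likelihood-ratio statistics.  Directions
#' must dominate the in-control mean component-wise, reflecting that only
#' upward outbreaks are monitored.
#'
#' @slot inControlMean length-`n` in-control mean vector.
#' @slot directions `K x n` matrix of candidate out-of-control means.
#' @slot covariance `n x n` in-control spatial covariance.
#'
#' @seealso [shiftSpec()], [scanChart()]
#' @export
setClass("ShiftSpec",
  representation(inControlMean = "numeric", directions = "matrix",
                 covariance = "matrix"),
  validity = function(object) {
    msg <- character()
    n <- length(object@inControlMean)
    if (ncol(object@directions) != n)
      msg <- c(msg, "directions must have one column per location")
    if (nrow(object@directions) < 1L)
      msg <- c(msg, "at least one shift direction is required")
    if (!isTRUE(all(t(object@directions) >= object@inControlMean - 1e-12)))
      msg <- c(msg, "every direction must dominate the in-control mean component-wise")
    if (nrow(object@covariance) != n || ncol(object@covariance) != n)
      msg <- c(msg, "covariance must be n x n")
    if (max(abs(object@covariance - t(object@covariance))) > 1e-8)
      msg <- c(msg, "covariance must be symmetric")
    if (length(msg)) msg else TRUE
  })

#' Precomputed MCUSUM scan chart
#'
#' Precomputation of the likelihood-ratio scan: for every direction `k` and
#' cluster `(c, r)` the restricted mean `mu_{c,r}^k`, the solved vector
#' `Sigma^-1 mu_{c,r}^k` and the offset `mu' Sigma^-1 mu / 2`, laid out so
#' that all statistics of one slice are a single matrix-vector product.
#' Rows are ordered by direction, then cluster; ties in the scan argmax are
#' therefore broken toward the smallest direction index, then center, then
#' radius.
#'
#' @slot spec the [ShiftSpec-class].
#' @slot clusters the [ClusterSet-class].
#' @slot solved `(K*M) x n` matrix with rows `(Sigma^-1 mu_{c,r}^k)'`.
#' @slot offsets length `K*M` vector of `mu' Sigma^-1 mu / 2`.
#' @slot directionIndex integer direction index of each row.
#' @slot clusterIndex integer cluster index of each row.
#'
#' @seealso [scanChart()], [scanStep()], [runScan()]
#' @export
setClass("ScanChart",
  representation(spec = "ShiftSpec", clusters = "ClusterSet",
                 solved = "matrix", offsets = "numeric",
                 directionIndex = "integer", clusterIndex = "integer"),
  validity = function(object) {
    msg <- character()
    m <- nrow(object@solved)
    if (length(object@offsets) != m || length(object@directionIndex) != m ||
        length(object@clusterIndex) != m)
      msg <- c(msg, "offsets and index vectors must match the solved rows")
    if (length(msg)) msg else TRUE
  })

#' Running state of the MCUSUM scan
#'
#' The CUSUM statistic of every (direction, cluster) pair, the current
#' time, the global statistic (their maximum) and an optional history of
#' the global statistic.
#'
#' @slot cusum numeric vector of per-(direction, cluster) CUSUM values.
#' @slot time current time step (0 before any update).
#' @slot globalStat current global statistic.
#' @slot history per-time global statistics recorded so far.
#'
#' @seealso [newScanState()], [scanStep()]
#' @export
setClass("ScanState",
  representation(cusum = "numeric", time = "integer",
                 globalStat = "numeric", history = "numeric"),
  validity = function(object) {
    if (any(object@cusum < 0))
      "all CUSUM values must be nonnegative" else TRUE
  })

#' Outcome of a monitored run
#'
#' Alarm time (or `NA` when the run ended without an alarm), the
#' identified direction and cluster at the alarm, the alarm statistic, the
#' control limit and (optionally) the full global-statistic trajectory.
#'
#' @slot alarmTime first time the global statistic strictly exceeded the
#'   control limit, or `NA_integer_`.
#' @slot direction direction index of the scan argmax at the alarm.
#' @slot center center location index of the identified cluster.
#' @slot radius radius of the identified cluster.
#' @slot statistic global statistic at the alarm (or at the final step).
#' @slot threshold the control limit `h` used.
#' @slot trajectory per-time global statistic (empty unless requested).
#'
#' @seealso [runScan()]
#' @export
setClass("AlarmReport",
  representation(alarmTime = "integer", direction = "integer",
                 center = "integer", radius = "numeric",
                 statistic = "numeric", threshold = "numeric",
                 trajectory = "numeric"))

#' Result of a control-limit calibration
#'
#' The calibrated control limit together with the achieved in-control
#' average run length and its Monte-Carlo standard error, estimated from
#' independent replications of the full monitoring pipeline (simulation,
#' masking, imputation, scan).
#'
#' @slot threshold calibrated control limit `h`.
#' @slot targetArl0 requested in-control average run length.
#' @slot achievedArl0 replication estimate of the in-control ARL at `h`.
#' @slot standardError Monte-Carlo standard error of `achievedArl0`.
#' @slot replications number of independent replications.
#' @slot cap run-length cap; censored runs are counted at the cap.
#' @slot censored number of censored replications.
#' @slot seed master seed of the calibration.
#'
#' @seealso [calibrateH()]
#' @export
setClass("CalibrationResult",
  representation(threshold = "numeric", targetArl0 = "numeric",
                 achievedArl0 = "numeric", standardError = "numeric",
                 replications = "integer", cap = "integer",
                 censored = "integer", seed = "integer"))

#' Summary of out-of-control run lengths
#'
#' Detection delays of a monitored out-of-control scenario: the average run
#' length after the change point, its standard error, the individual
#' delays, and the number of replications discarded because they alarmed
#' before the change point.
#'
#' @slot arl1 mean detection delay (alarm time - change point + 1).
#' @slot standardError Monte-Carlo standard error of `arl1`.
#' @slot runLengths per-replication detection delays.
#' @slot discarded replications discarded for alarming before the change
#'   point.
#' @slot censored replications that never alarmed (delay counted at cap).
#'
#' @seealso [estimateArl1()]
#' @export
setClass("RunLengthSummary",
  representation(arl1 = "numeric", standardError = "numeric",
                 runLengths = "numeric", discarded = "integer",
                 censored = "integer"),
  validity = function(object) {
    if (length(object@runLengths) && any(object@runLengths < 1))
      "all detection delays must be at least 1" else TRUE
  })
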