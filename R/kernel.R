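#' Kernel specification with grid-derived default range
#'
#' The default range parameter is the maximum pairwise Euclidean distance
#' of the grid (the "length" of the space domain), so the squared
#' exponential `exp(-dist^2 / delta^2)` keeps appreciable correlation
#' across the whole field.
#'
#' @param grid optional [SensorGrid-class] used to derive the default
#'   `delta`.
#' @param delta positive range parameter; overrides the grid default.
#' @param jitter nonnegative diagonal ridge for square kernel matrices
#'   (default 1e-8).
#' @return a [KernelSpec-class].
#' @examples
#' kernelSpec(sensorGrid(5, 5))   # delta = sqrt(32)
#' @export
kernelSpec <- function(grid = NULL, delta = NULL, jitter = 1e-8) {
  if (is.null(delta)) {
    if (is.null(grid))
      stop("either a grid or an explicit delta is required")
    delta <- max(gridDistances(grid))
  }
  new("KernelSpec", rangeParameter = as.numeric(delta),
      jitter = as.numeric(jitter))
}

#' Normal-inverse-Wishart hyper-prior
#'
#' Weakly informative defaults: precision 1 and `n + 2` inverse-Wishart
#' degrees of freedom, the smallest integer choice keeping the prior
#' proper with a finite mean for any grid size `n`.
#'
#' @param n number of locations (used for the default degrees of freedom).
#' @param precision prior precision `pi` (> 0, default 1).
#' @param wishartDof degrees of freedom `tau` (default `n + 2`).
#' @return a [HyperPrior-class].
#' @export
hyperPrior <- function(n, precision = 1, wishartDof = n + 2) {
  new("HyperPrior", precision = as.numeric(precision),
      wishartDof = as.numeric(wishartDof))
}

#' Squared-exponential spatial kernel
#'
#' `k(s_i, s_j) = exp(-||s_i - s_j||^2 / delta^2)`: symmetric, equal to 1
#' exactly when the locations coincide and strictly decreasing in their
#' distance.
#'
#' @param si,sj numeric length-2 location coordinates.
#' @param delta positive range parameter.
#' @return kernel value in `(0, 1]`.
#' @examples
#' spatialKernel(c(1, 1), c(1, 2), delta = 2)  # exp(-1/4)
#' @export
spatialKernel <- function(si, sj, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a single positive number")
  exp(-sum((si - sj)^2) / delta^2)
}

#' Kernel matrix between two location sets
#'
#' Entry `(i, j)` is [spatialKernel()] evaluated at `rows[i, ]` and
#' `cols[j, ]`.  When the two sets are identical (a square kernel that
#' will be factorized or inverted) the kernel specification's jitter is added to
#' the diagonal.
#'
#' @param rows,cols numeric matrices of location coordinates (one row per
#'   location); vectors are treated as a single location.
#' @param spec a [KernelSpec-class].
#' @return `nrow(rows) x nrow(cols)` kernel matrix.
#' @export
buildKernel <- function(rows, cols, spec) {
  stopifnot(is(spec, "KernelSpec"))
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L)
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = 1L)
  if (nrow(rows) == 0L || nrow(cols) == 0L)
    stop("location sets must be nonempty")
  d2 <- outer(rowSums(rows^2), rowSums(cols^2), `+`) -
    2 * tcrossprod(rows, cols)
  d2[d2 < 0] <- 0
  K <- exp(-d2 / spec@rangeParameter^2)
  if (identical(dim(K)[1L], dim(K)[2L]) && isTRUE(all.equal(rows, cols)))
    K <- K + spec@jitter * diag(nrow(K))
  K
}

# Full jittered grid kernel and its inverse, with escalating jitter on
# factorization failure (x10 up to 1e-4, with a warning).
gridKernel <- function(grid, spec) {
  K0 <- buildKernel(gridCoords(grid), gridCoords(grid), spec)
  jit <- spec@jitter
  repeat {
    ch <- tryCatch(chol(K0), error = function(e) NULL)
    if (!is.null(ch)) {
      Kinv <- chol2inv(ch)
      return(list(kernel = K0, inverse = (Kinv + t(Kinv)) / 2, jitter = jit))
    }
    if (jit >= 1e-4)
      stop("grid kernel not positive definite even after jitter escalation")
    newJit <- max(jit, 1e-8) * 10
    warning(sprintf("kernel factorization failed at jitter %g; escalating to %g",
                    jit, newJit))
    K0 <- K0 + (newJit - jit) * diag(nrow(K0))
    jit <- newJit
  }
}
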