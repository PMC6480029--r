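#' Expectation step of the multitask EM
#'
#' Updates the posterior weight mean and covariance of every process given
#' the current shared state.  The update is the Gaussian posterior
#' \deqn{\alpha_l = (\sigma^{-2}\kappa_l'\kappa_l + C^{-1})^{-1}
#'       (\sigma^{-2}\kappa_l'\tilde x_l + C^{-1}m),\qquad
#'       C_l = (\sigma^{-2}\kappa_l'\kappa_l + C^{-1})^{-1},}
#' computed through the matrix-inversion lemma as
#' `alpha_l = m + C k_l' A^{-1} (x_l - k_l m)` with
#' `A = k_l C k_l' + sigma^2 I`, so that no explicit inverse of the prior
#' covariance is ever formed and the factorized system stays
#' well-conditioned even as the noise variance approaches zero.
#' A process with no observations keeps its prior (`alpha_l = m`,
#' `C_l = C`).
#'
#' @param observations list of per-process observed-value vectors.
#' @param kernels list of per-process `n_tl x n` kernel matrices (rows at
#'   the observed locations of the process, columns the full grid).
#' @param state a [MultitaskState-class] providing the current prior mean,
#'   prior covariance and noise variance.
#' @return list with elements `weightMeans` and `weightCovariances`.
#' @export
eStep <- function(observations, kernels, state) {
  stopifnot(is(state, "MultitaskState"))
  L <- length(observations)
  if (L != length(kernels))
    stop("observations and kernels must have equal length")
  m <- state@priorMean
  C <- state@priorCovariance
  s2 <- state@noiseVariance
  alphas <- covs <- vector("list", L)
  for (l in seq_len(L)) {
    K <- kernels[[l]]
    if (is.null(dim(K))) K <- matrix(K, nrow = length(observations[[l]]))
    if (nrow(K) == 0L) {
      alphas[[l]] <- m
      covs[[l]] <- C
      next
    }
    CKt <- C %*% t(K)
    A <- K %*% CKt
    diag(A) <- diag(A) + s2
    A <- (A + t(A)) / 2
    ch <- cholRidge(A, "E-step posterior system")
    W <- backsolve(ch, forwardsolve(t(ch), t(CKt)))
    covs[[l]] <- C - CKt %*% W
    alphas[[l]] <- as.numeric(
      m + CKt %*% backsolve(ch, forwardsolve(t(ch),
                                             observations[[l]] - K %*% m)))
  }
  list(weightMeans = alphas, weightCovariances = covs)
}

# Cholesky with escalating relative ridge; errors with diagnostics when the
# matrix stays indefinite at a ridge of 1e-4 times its diagonal scale.
cholRidge <- function(A, what) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  scale <- mean(diag(A))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  for (j in 10^(-10:-4)) {
    ch <- tryCatch(chol(A + j * scale * diag(nrow(A))),
                   error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop(sprintf("%s is singular beyond jitter repair (diagonal scale %g)",
               what, scale))
}

#' Maximization step of the multitask EM
#'
#' Re-estimates the shared prior mean, prior covariance and noise variance
#' from the E-step posteriors under the normal-inverse-Wishart hyper-prior:
#' \deqn{m = (\pi + L)^{-1}\sum_l \alpha_l}
#' \deqn{C = (\tau + L)^{-1}\big(\pi m m' + \tau\kappa^{-1} + \sum_l C_l
#'       + \sum_l (\alpha_l - m)(\alpha_l - m)'\big)}
#' \deqn{\sigma^2 = \big(\sum_l n_{tl}\big)^{-1}\sum_l\big(
#'       \|\tilde x_l - \kappa_l\alpha_l\|^2
#'       + \mathrm{tr}(\kappa_l C_l \kappa_l')\big).}
#' The covariance is symmetrized after assembly.  The noise variance is a
#' sum of a squared norm and a trace of a positive-semidefinite congruence
#' and is therefore always nonnegative.
#'
#' @param observations list of per-process observed-value vectors.
#' @param kernels list of per-process kernel matrices (as in [eStep()]).
#' @param weightMeans,weightCovariances E-step posteriors.
#' @param prior a [HyperPrior-class].
#' @param kernelMatrix the square `n x n` kernel matrix `kappa`.
#' @param kernelInverse optional precomputed inverse of `kernelMatrix`.
#' @return list with elements `priorMean`, `priorCovariance` and
#'   `noiseVariance`.
#' @export
mStep <- function(observations, kernels, weightMeans, weightCovariances,
                  prior, kernelMatrix, kernelInverse = NULL) {
  stopifnot(is(prior, "HyperPrior"))
  L <- length(observations)
  if (L < 1L) stop("at least one process is required")
  counts <- vapply(observations, length, 1L)
  if (sum(counts) < 1L)
    stop("no observations available in any process")
  if (is.null(kernelInverse)) {
    ch <- cholRidge(kernelMatrix, "kernel matrix")
    kernelInverse <- chol2inv(ch)
  }
  n <- nrow(kernelMatrix)
  pi0 <- prior@precision
  tau <- prior@wishartDof
  m <- Reduce(`+`, weightMeans) / (pi0 + L)
  C <- pi0 * tcrossprod(m) + tau * kernelInverse
  s2 <- 0
  for (l in seq_len(L)) {
    d <- weightMeans[[l]] - m
    C <- C + weightCovariances[[l]] + tcrossprod(d)
    if (counts[l] > 0L) {
      K <- kernels[[l]]
      if (is.null(dim(K))) K <- matrix(K, nrow = counts[l])
      r <- observations[[l]] - K %*% weightMeans[[l]]
      s2 <- s2 + sum(r^2) +
        sum(crossprod(K) * weightCovariances[[l]])
    }
  }
  C <- (C + t(C)) / (2 * (tau + L))
  list(priorMean = as.numeric(m), priorCovariance = C,
       noiseVariance = s2 / sum(counts))
}

# Extract one time slice of a panel as per-process observation lists.
sliceData <- function(panel, t) {
  L <- processCount(panel)
  obs <- x <- vector("list", L)
  for (l in seq_len(L)) {
    o <- which(panel@observed[l, t, ])
    obs[[l]] <- o
    x[[l]] <- panel@values[l, t, o]
  }
  list(obs = obs, x = x)
}

#' Fit the multitask model to one time slice
#'
#' Alternates [eStep()] and [mStep()] from the deterministic start
#' (`m = 0`, `C = kappa`, `sigma^2 = 1`) until the relative change of
#' `(m, sigma^2)` falls below `tol` or the iteration budget is exhausted.
#' Each slice is fitted independently; `init` allows an optional warm
#' start from a previously fitted state.  The kernel rows of process `l`
#' are the rows of the full jittered grid kernel at that process's
#' observed locations, so the weight vector always lives on the full grid.
#'
#' @param panel an [ObservationPanel-class].
#' @param t time index of the slice to fit.
#' @param spec a [KernelSpec-class]; default derives `delta` from the
#'   panel grid.
#' @param prior a [HyperPrior-class]; default [hyperPrior()] for the grid
#'   size.
#' @param tol relative-change stopping tolerance (default 1e-5).
#' @param maxIter maximum EM iterations (default 100); `maxIter = 0`
#'   returns the initialization state with `converged = FALSE`.
#' @param init optional [MultitaskState-class] used as a warm start.
#' @return a [MultitaskState-class].
#' @export
fitSlice <- function(panel, t, spec = NULL, prior = NULL, tol = 1e-5,
                     maxIter = 100, init = NULL) {
  stopifnot(is(panel, "ObservationPanel"))
  if (is.null(spec)) spec <- kernelSpec(panel@grid)
  n <- nLocations(panel)
  if (is.null(prior)) prior <- hyperPrior(n)
  if (prior@wishartDof <= n - 1)
    stop("wishartDof must exceed n - 1 for a proper inverse-Wishart prior")
  sd <- sliceData(panel, t)
  if (sum(lengths(sd$obs)) == 0L)
    stop(sprintf("no process has any observation at time %d; cannot fit", t))
  gk <- gridKernel(panel@grid, spec)
  kernels <- lapply(sd$obs, function(o) gk$kernel[o, , drop = FALSE])
  if (is.null(init)) {
    state <- new("MultitaskState", weightMeans = list(),
                 weightCovariances = list(), priorMean = numeric(n),
                 priorCovariance = gk$kernel, noiseVariance = 1,
                 iterations = 0L, converged = FALSE)
  } else {
    state <- init
  }
  it <- 0L
  converged <- FALSE
  alphas <- covs <- list()
  while (it < maxIter) {
    it <- it + 1L
    es <- eStep(sd$x, kernels, state)
    alphas <- es$weightMeans
    covs <- es$weightCovariances
    ms <- mStep(sd$x, kernels, alphas, covs, prior, gk$kernel, gk$inverse)
    s2new <- max(ms$noiseVariance, 1e-12)
    dm <- sqrt(sum((ms$priorMean - state@priorMean)^2)) /
      (sqrt(sum(state@priorMean^2)) + 1e-12)
    ds <- abs(s2new - state@noiseVariance) / (state@noiseVariance + 1e-12)
    state@priorMean <- ms$priorMean
    state@priorCovariance <- ms$priorCovariance
    state@noiseVariance <- s2new
    if (max(dm, ds) < tol) {
      converged <- TRUE
      break
    }
  }
  new("MultitaskState", weightMeans = alphas, weightCovariances = covs,
      priorMean = state@priorMean,
      priorCovariance = state@priorCovariance,
      noiseVariance = state@noiseVariance,
      iterations = it, converged = converged)
}

#' Complete one slice of the target process
#'
#' Observed entries of the target process are copied verbatim from the
#' panel; missing entries are filled from the kernel reconstruction
#' `y = kappa alpha` of the target's fitted weights.
#'
#' @param panel an [ObservationPanel-class].
#' @param t time index.
#' @param target target process index (default 1).
#' @param state a fitted [MultitaskState-class] for this slice.
#' @param spec the [KernelSpec-class] used in the fit.
#' @return a [CompletedSlice-class].
#' @export
completeSlice <- function(panel, t, target = 1L, state, spec = NULL) {
  stopifnot(is(panel, "ObservationPanel"), is(state, "MultitaskState"))
  if (is.null(spec)) spec <- kernelSpec(panel@grid)
  n <- nLocations(panel)
  obs <- panel@observed[target, t, ]
  vals <- panel@values[target, t, ]
  if (!all(obs)) {
    if (length(state@weightMeans) < target)
      stop("state carries no fitted weights for the target process")
    gk <- gridKernel(panel@grid, spec)
    yhat <- as.numeric(gk$kernel %*% state@weightMeans[[target]])
    vals[!obs] <- yhat[!obs]
  }
  new("CompletedSlice", values = vals, imputed = !obs)
}

#' @rdname completedValues
#' @export
setMethod("completedValues", "CompletedSlice", function(x) x@values)

#' @rdname imputedMask
#' @export
setMethod("imputedMask", "CompletedSlice", function(x) x@imputed)

setMethod("show", "MultitaskState", function(object) {
  cat(sprintf(
    "MultitaskState: %d process(es), n = %d; sigma^2 = %.6g; %d iteration(s), %s\n",
    length(object@weightMeans), length(object@priorMean),
    object@noiseVariance, object@iterations,
    if (object@converged) "converged" else "not converged"))
  invisible(object)
})

setMethod("show", "CompletedSlice", function(object) {
  cat(sprintf("CompletedSlice: %d locations, %d imputed\n",
              length(object@values), sum(object@imputed)))
  invisible(object)
})

#' Impute every slice of a panel
#'
#' Fits the multitask model independently at each time step and returns
#' the completed target-process matrix together with per-slice EM
#' diagnostics.  The `"cpp"` engine runs the compiled accelerated fitter;
#' `"R"` runs the reference implementation built on [eStep()] and
#' [mStep()].  Both converge to the same fixed point.
#'
#' @param panel an [ObservationPanel-class].
#' @param target target process index (default 1).
#' @param spec a [KernelSpec-class] (default grid-derived).
#' @param prior a [HyperPrior-class] (default [hyperPrior()]).
#' @param tol stopping tolerance (default 1e-5).
#' @param maxIter iteration budget per slice (default 100).
#' @param engine `"cpp"` (default) or `"R"`.
#' @return list with `values` (`T x n` completed matrix), `imputed`
#'   (`T x n` logical) and `diagnostics` (data frame with one row per
#'   slice: `time`, `iterations`, `converged`, `noiseVariance`).
#' @export
imputePanel <- function(panel, target = 1L, spec = NULL, prior = NULL,
                        tol = 1e-5, maxIter = 100,
                        engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  stopifnot(is(panel, "ObservationPanel"))
  if (is.null(spec)) spec <- kernelSpec(panel@grid)
  n <- nLocations(panel)
  if (is.null(prior)) prior <- hyperPrior(n)
  Tn <- horizon(panel)
  out <- matrix(NA_real_, Tn, n)
  imp <- matrix(FALSE, Tn, n)
  diag_it <- integer(Tn)
  diag_cv <- logical(Tn)
  diag_s2 <- numeric(Tn)
  gk <- gridKernel(panel@grid, spec)
  for (t in seq_len(Tn)) {
    obs <- panel@observed[target, t, ]
    if (engine == "cpp") {
      sd <- sliceData(panel, t)
      if (sum(lengths(sd$obs)) == 0L)
        stop(sprintf("no process has any observation at time %d", t))
      f <- cpp_em_fit(sd$x, sd$obs, gk$kernel, gk$inverse,
                      prior@precision, prior@wishartDof, tol,
                      as.integer(maxIter), 1e-12,
                      numeric(n), gk$kernel, 1.0, TRUE)
      vals <- panel@values[target, t, ]
      if (!all(obs)) {
        yhat <- as.numeric(gk$kernel %*% f$alpha[[target]])
        vals[!obs] <- yhat[!obs]
      }
      out[t, ] <- vals
      diag_it[t] <- f$iterations
      diag_cv[t] <- f$converged
      diag_s2[t] <- f$s2
    } else {
      st <- fitSlice(panel, t, spec, prior, tol, maxIter)
      cs <- completeSlice(panel, t, target, st, spec)
      out[t, ] <- cs@values
      diag_it[t] <- st@iterations
      diag_cv[t] <- st@converged
      diag_s2[t] <- st@noiseVariance
    }
    imp[t, ] <- !obs
  }
  list(values = out, imputed = imp,
       diagnostics = data.frame(time = seq_len(Tn), iterations = diag_it,
                                converged = diag_cv,
                                noiseVariance = diag_s2))
}
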