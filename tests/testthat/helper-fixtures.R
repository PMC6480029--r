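# Common small objects used across tests.

grid5 <- sensorGrid(5, 5)
grid3 <- sensorGrid(3, 3)

# simulatePanel with the Assumption-1 coverage warning silenced (expected
# at high missing ratios on small grids)
quietPanel <- function(config, seed) {
  suppressWarnings(simulatePanel(config, seed = seed))
}

# scalar MultitaskState for closed-form EM checks
scalarState <- function(m, C, s2) {
  new("MultitaskState", weightMeans = list(), weightCovariances = list(),
      priorMean = m, priorCovariance = matrix(C, 1, 1),
      noiseVariance = s2, iterations = 0L, converged = FALSE)
}

# independent brute-force recomputation of the scan chart: quadruple loop
# over (t, k, c, r), solving the covariance system afresh each time
bruteForceScan <- function(X, directions, Sigma, clusters) {
  K <- nrow(directions)
  M <- length(clusters@members)
  Tn <- nrow(X)
  n <- ncol(X)
  Sj <- Sigma + fieldJitter() * diag(n)
  S <- array(0, c(Tn + 1, K, M))
  global <- numeric(Tn)
  for (t in seq_len(Tn)) {
    for (k in seq_len(K)) {
      for (j in seq_len(M)) {
        mu <- numeric(n)
        mem <- clusters@members[[j]]
        mu[mem] <- directions[k, mem]
        ell <- drop(t(mu) %*% solve(Sj, X[t, ] - mu / 2))
        S[t + 1, k, j] <- max(0, S[t, k, j] + ell)
      }
    }
    global[t] <- max(S[t + 1, , ])
  }
  list(cusum = S[-1, , , drop = FALSE], global = global)
}
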