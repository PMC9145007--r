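# Independent oracles used to cross-check the implementation paths.

# Stationary law by eigen-decomposition of the transposed generator:
# the (normalized) null vector of t(Q), independent of the dense
# replaced-row solve used in the package.
eigenStationary <- function(Q) {
  e <- eigen(t(Q))
  k <- which.min(abs(e$values))
  v <- Re(e$vectors[, k])
  v / sum(v)
}

# Lyapunov solution via the eigen-decomposition of the drift matrix:
# Sigma = V X V^H with X_ij = -(V^-1 D V^-H)_ij / (lambda_i + lambda_j),
# independent of the Kronecker vectorization used in the package.
eigenLyapunov <- function(A, D) {
  e <- eigen(A)
  V <- e$vectors
  Vi <- solve(V)
  Dt <- Vi %*% D %*% Conj(t(Vi))
  n <- nrow(A)
  X <- matrix(0 + 0i, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    X[i, j] <- -Dt[i, j] / (e$values[i] + Conj(e$values[j]))
  Re(V %*% X %*% Conj(t(V)))
}

# A random stable drift matrix (eigenvalues shifted into the left half
# plane) and a PSD diffusion, for property-style Lyapunov tests.
randomStableSystem <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  A <- A - (max(Re(eigen(A, only.values = TRUE)$values)) + 1) * diag(n)
  B <- matrix(rnorm(n * n), n, n)
  list(A = A, D = B %*% t(B))
}

# Brute-force mutual information from an explicit joint pmf (plain sums,
# no shared code with the package's entropy path).
bruteForceMI <- function(J) {
  px <- rowSums(J)
  py <- colSums(J)
  total <- 0
  for (i in seq_len(nrow(J))) for (j in seq_len(ncol(J))) {
    if (J[i, j] > 0)
      total <- total + J[i, j] * log(J[i, j] / (px[i] * py[j]))
  }
  total
}

unitRates <- function(nDownstream = 0L) {
  if (nDownstream > 0L)
    rateParameters(1, 1, 1, 1, k3Plus = rep(1, nDownstream),
                   k3Minus = rep(1, nDownstream))
  else rateParameters(1, 1, 1, 1)
}

# fast-binding models with binding rates `mult` times the unit catalytic
# rates, upstream and downstream (dissociation constants all 1)
fastBindingModel <- function(topology, mult, nDownstream = 0L, ...) {
  r <- rateParameters(mult, mult, 1, 1,
                      k3Plus = rep(mult, max(nDownstream, 1L)),
                      k3Minus = rep(mult, max(nDownstream, 1L)))
  buildModel(topology, r, nDownstream = nDownstream, ...)
}
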