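#' @include AllClasses.R
NULL

.xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

.toUnits <- function(nats, units) {
  units <- match.arg(units, c("nats", "bits"))
  if (units == "bits") nats / log(2) else nats
}

#' Shannon entropy of a discrete pmf
#'
#' Natural-log entropy with the \code{0 * log(0) := 0} continuity
#' convention.
#'
#' @param p numeric pmf (non-negative, sums to 1 within \code{1e-9}).
#' @param units "nats" (default) or "bits".
#' @return entropy, between 0 and \code{log(length(p))}.
#' @examples
#' shannonEntropy(c(0.5, 0.5))  # log(2)
#' @export
shannonEntropy <- function(p, units = "nats") {
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-9)
    stop("p must be a normalized pmf")
  .toUnits(-sum(.xlogx(p)), units)
}

#' Kullback-Leibler divergence between two discrete pmfs (nats)
#'
#' @param p,q pmfs on the same support; \code{Inf} when p puts mass where q
#'   does not.
#' @return divergence in nats.
#' @export
klDivergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p > 0 & q == 0)) return(Inf)
  sum(ifelse(p > 0, p * (log(p) - log(q)), 0))
}

## joint pmf of the Z-channel: rows input 0/1, columns output 0/1
.zJoint <- function(A, P01) {
  P11 <- 1 - P01
  rbind(c(P01, 0), c(A * P11, (1 - A) * P11))
}

.miFromJoint <- function(J) {
  px <- rowSums(J)
  py <- colSums(J)
  ## I(X;Y) = H(X) + H(Y) - H(X,Y), all in nats
  -sum(.xlogx(px)) - sum(.xlogx(py)) + sum(.xlogx(J))
}

#' Mutual information across a Z-channel
#'
#' Mutual information between the binary input symbol and the steady-state
#' output for a channel in which symbol 0 is noiseless and symbol 1 is
#' received as 0 with probability A. Computed canonically as
#' \eqn{H(X) - H(X|Y)} from the joint pmf
#' \code{rbind(c(P01, 0), c(A*(1-P01), (1-A)*(1-P01)))}.
#'
#' @param A flip probability \eqn{P(Y = 0 \mid X = 1)} in [0, 1]; vectorized.
#' @param P01 prior of input symbol 0; vectorized (recycled against A).
#' @param units "nats" (default) or "bits".
#' @return mutual information, in \code{[0, log(2)]} nats.
#' @examples
#' miZChannel(1, 0.5)    # 0: output independent of input
#' miZChannel(0, 0.5)    # log(2): noiseless binary channel
#' @export
miZChannel <- function(A, P01, units = "nats") {
  if (any(A < -1e-12 | A > 1 + 1e-12) || any(P01 < 0 | P01 > 1))
    stop("A and P01 must lie in [0, 1]")
  n <- max(length(A), length(P01))
  A <- rep_len(pmin(pmax(A, 0), 1), n)
  P01 <- rep_len(P01, n)
  mi <- vapply(seq_len(n), function(i)
    .miFromJoint(.zJoint(A[i], P01[i])), numeric(1))
  .toUnits(pmax(mi, 0), units)
}

#' Mutual information of a channel or joint pmf
#'
#' @param x a [ZChannel-class] or a joint pmf matrix.
#' @param units "nats" or "bits".
#' @return mutual information.
#' @export
mutualInformation <- function(x, units = "nats") {
  J <- if (methods::is(x, "ZChannel")) x@joint else as.matrix(x)
  if (any(J < -1e-12) || abs(sum(J) - 1) > 1e-9)
    stop("joint pmf must be normalized and non-negative")
  .toUnits(max(.miFromJoint(J), 0), units)
}

#' Z-channel capacity (closed form)
#'
#' Capacity of the Z-channel with flip probability A, i.e. the maximum of
#' [miZChannel()] over the input prior:
#' \deqn{C = \log_2\left(1 + (1-A)\,A^{A/(1-A)}\right) \textrm{ bits}.}
#'
#' @param A flip probability in [0, 1]; vectorized.
#' @param units "nats" (default) or "bits".
#' @return capacity; \code{log(2)} nats at A = 0, 0 at A = 1.
#' @examples
#' zChannelCapacity(0.5, units = "bits")  # log2(1.25)
#' @export
zChannelCapacity <- function(A, units = "nats") {
  if (any(A < -1e-12 | A > 1 + 1e-12)) stop("A must lie in [0, 1]")
  A <- pmin(pmax(A, 0), 1)
  cap <- ifelse(A >= 1, 0, log1p((1 - A) * A^(A / (1 - A))))
  .toUnits(cap, units)
}

#' Capacity of a discrete memoryless channel by Blahut-Arimoto iteration
#'
#' Independent capacity oracle: alternating maximization of the mutual
#' information over the input distribution. Iterates are monotone
#' non-decreasing in capacity and the duality gap
#' \eqn{\max_x KL(W_x \| q) - I} bounds the error, which is used as the
#' stopping rule.
#'
#' @param conditional row-stochastic matrix W with W[x, y] = P(y | x).
#' @param tol stopping tolerance on the capacity gap (nats).
#' @param maxIter iteration cap; non-convergence raises an error.
#' @param units "nats" or "bits".
#' @return list with elements \code{capacity}, \code{inputDistribution},
#'   \code{iterations}.
#' @export
blahutArimoto <- function(conditional, tol = 1e-12, maxIter = 10000L,
                          units = "nats") {
  W <- as.matrix(conditional)
  if (any(W < -1e-12) || max(abs(rowSums(W) - 1)) > 1e-9)
    stop("conditional must be row-stochastic")
  W <- pmax(W, 0)
  m <- nrow(W)
  p <- rep(1 / m, m)
  for (it in seq_len(maxIter)) {
    q <- drop(p %*% W)
    d <- apply(W, 1L, klDivergence, q = q) # KL(W_x || q)
    d[!is.finite(d)] <- max(d[is.finite(d)], 0) + 50 # unreachable outputs
    lower <- sum(p * d)
    upper <- max(d)
    if (upper - lower < tol) {
      return(list(capacity = .toUnits(lower, units),
                  inputDistribution = p, iterations = it))
    }
    p <- p * exp(d - max(d))
    p <- p / sum(p)
  }
  stop("Blahut-Arimoto did not converge in ", maxIter, " iterations")
}

#' Dual (KL-divergence) upper bound on channel capacity
#'
#' For any output distribution q, \eqn{C \le \max_x KL(W_x \| q)}; the bound
#' is tight when q is the capacity-achieving output distribution. Applied
#' here to the Z-channel with flip probability A.
#'
#' @param A flip probability of the Z-channel.
#' @param q candidate binary output pmf (length 2).
#' @param units "nats" or "bits".
#' @return the upper bound (possibly \code{Inf} for unsupported q).
#' @export
capacityUpperBound <- function(A, q, units = "nats") {
  if (length(q) != 2L || any(q < 0) || abs(sum(q) - 1) > 1e-9)
    stop("q must be a binary pmf")
  W <- rbind(c(1, 0), c(A, 1 - A))
  .toUnits(max(apply(W, 1L, klDivergence, q = q)), units)
}

#' Lower/upper capacity-bound surface over (A, P01)
#'
#' For each grid value of A: the mutual information at each input prior (a
#' lower bound on capacity), the closed-form Z-channel capacity, and the
#' dual KL upper bound minimized over a grid of output distributions. At
#' every A the maximum of the lower bound, the capacity, and the minimum of
#' the upper bound coincide up to grid resolution.
#'
#' @param aGrid grid of flip probabilities in [0, 1].
#' @param p01Grid grid of input priors in [0, 1].
#' @param qGrid grid of output-0 probabilities for the upper bound (defaults
#'   to \code{p01Grid}).
#' @param units "nats" or "bits".
#' @return data.frame with columns A, P01, lower, capacity, upper (capacity
#'   and upper repeated within each A block).
#' @export
boundSurface <- function(aGrid, p01Grid, qGrid = p01Grid, units = "nats") {
  stopifnot(all(aGrid >= 0 & aGrid <= 1), all(p01Grid >= 0 & p01Grid <= 1))
  rows <- lapply(aGrid, function(A) {
    ub <- min(vapply(qGrid, function(q0)
      capacityUpperBound(A, c(q0, 1 - q0), units = units), numeric(1)))
    data.frame(A = A, P01 = p01Grid,
               lower = miZChannel(A, p01Grid, units = units),
               capacity = zChannelCapacity(A, units = units),
               upper = ub)
  })
  do.call(rbind, rows)
}

#' Capacity curve over a grid of A values
#'
#' Closed-form Z-channel capacity with the numerically optimizing input
#' prior at each A (found by one-dimensional maximization of
#' [miZChannel()]).
#'
#' @param aGrid grid of flip probabilities.
#' @param units "nats" or "bits".
#' @return data.frame with columns A, capacity, optimalP01.
#' @export
capacityCurve <- function(aGrid, units = "nats") {
  opt <- vapply(aGrid, function(A) {
    if (A >= 1) return(NA_real_)
    stats::optimize(function(p) miZChannel(A, p), c(0, 1),
                    maximum = TRUE, tol = 1e-10)$maximum
  }, numeric(1))
  data.frame(A = aGrid,
             capacity = zChannelCapacity(aGrid, units = units),
             optimalP01 = opt)
}
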