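#' @include AllClasses.R
NULL

#' Steady-state mean of the reduced isolated SISO circuit
#'
#' The high-count analysis reduces the single upstream system to a one-step
#' cyclic reaction \eqn{I_1 + E \to E + Z_1, Z_1 \to I_1} with the enzyme at
#' a fixed concentration. Setting the rate equation
#' \eqn{dZ_1/dt = c_1 E (I_{tot1} - Z_1) - c_2 Z_1} to zero gives
#' \deqn{\mu_0 = \frac{c_1 E\, I_{tot1}}{c_2 + c_1 E}.}
#'
#' @param c1 catalytic rate; \code{E} enzyme concentration.
#' @param E enzyme concentration.
#' @param Itot1 total input concentration.
#' @param c2 recycling rate.
#' @return the mean output concentration, in \code{[0, Itot1]}.
#' @examples
#' sisoReducedMean(1, 1, 10, 1)  # 5
#' @export
sisoReducedMean <- function(c1, E, Itot1, c2) {
  stopifnot(c1 >= 0, E >= 0, Itot1 >= 0, c2 >= 0)
  if (c2 + c1 * E == 0) stop("c2 and c1*E cannot both be zero")
  c1 * E * Itot1 / (c2 + c1 * E)
}

#' Stationary variance of the reduced isolated SISO circuit
#'
#' One-dimensional Lyapunov solution around \eqn{\mu_0}:
#' \deqn{\sigma_0^2 = \frac{c_1 E\, I_{tot1}\, c_2}{\Omega\,(c_1 E + c_2)^2},}
#' which scales as \eqn{1/\Omega} and vanishes at \eqn{c_2 = 0}
#' (deterministic full conversion).
#'
#' @inheritParams sisoReducedMean
#' @param omega reaction volume.
#' @return the stationary variance of the output concentration.
#' @examples
#' sisoReducedVariance(1, 1, 10, 1, omega = 1)  # 2.5
#' @export
sisoReducedVariance <- function(c1, E, Itot1, c2, omega = 1) {
  stopifnot(omega > 0)
  if (c2 + c1 * E == 0) stop("c2 and c1*E cannot both be zero")
  c1 * E * Itot1 * c2 / (omega * (c1 * E + c2)^2)
}

#' Steady-state downstream complex concentration
#'
#' Setting the binding site's rate equation to zero and using the site
#' conservation law gives the hyperbolic (saturating) occupancy
#' \deqn{C_j = \frac{Z_1 D_{tot}}{k_3 + Z_1}.}
#'
#' @param Z1 free output concentration (>= 0).
#' @param Dtot total site concentration.
#' @param k3 downstream dissociation constant (> 0).
#' @return complex concentration in \code{[0, Dtot]}.
#' @export
downstreamComplexSteady <- function(Z1, Dtot, k3) {
  stopifnot(k3 > 0, all(Z1 >= 0), Dtot >= 0)
  Z1 * Dtot / (k3 + Z1)
}

#' Steady-state output mean of the loaded SISO circuit
#'
#' Solves the reduced rate equation of the SISO circuit connected to N
#' identical downstream sites, with the site occupancies at their
#' quasi-steady-state value [downstreamComplexSteady()]. At the fixed point
#' the binding and unbinding fluxes cancel identically (the net flux into
#' each complex is zero), so the equation collapses to the isolated one and
#' the mean is untouched by the load: \eqn{\mu_N = \mu_0}. This is the
#' high-count counterpart of the classic retroactivity result that load
#' reshapes dynamics and fluctuations, not the steady-state mean.
#'
#' @inheritParams sisoReducedVariance
#' @param k3 downstream dissociation constant (common to all sites).
#' @param Dtot per-site total concentration.
#' @param N number of downstream sites.
#' @return list with elements \code{mean} (the root), \code{complexes}
#'   (per-site occupancy at the root) and \code{residual}.
#' @export
sisoDownstreamMean <- function(c1, E, Itot1, c2, k3 = 1, Dtot = 1, N = 0L) {
  stopifnot(c1 >= 0, E >= 0, Itot1 > 0, c2 >= 0, k3 > 0, Dtot >= 0, N >= 0)
  if (c2 + c1 * E == 0) stop("c2 and c1*E cannot both be zero")
  f <- function(Z) {
    C <- downstreamComplexSteady(Z, Dtot, k3)
    ## binding/unbinding written out; they cancel for any association rate
    ## once C sits at its steady state (shown here with unit association)
    c1 * E * (Itot1 - Z) - c2 * Z + (k3 * C - Z * (Dtot - C)) * N
  }
  lo <- 0
  hi <- Itot1
  if (f(lo) < 0 || f(hi) > 0) {
    if (abs(f(lo)) < 1e-12) return(list(mean = 0, complexes = 0, residual = f(lo)))
    stop("no root bracketed in [0, Itot1]; inconsistent parameters")
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  ## polish: the substituted equation is linear in Z
  root <- c1 * E * Itot1 / (c2 + c1 * E)
  list(mean = root,
       complexes = downstreamComplexSteady(root, Dtot, k3),
       residual = f(root))
}

#' Steady-state means of the isolated MIMO circuit
#'
#' Solves the four coupled rate equations of the two-step MIMO model (two
#' substrate/enzyme branches sharing one enzyme) for the fixed point, with
#' the conservation substitutions \eqn{I_i = I_{tot,i} - M_i - Z_i} and
#' \eqn{E = E_{tot} - M_1 - M_2}. A damped Newton iteration from the
#' interior of the conservation polytope; residuals of all four equations
#' are checked against \code{tol}.
#'
#' @param rates a [RateParameters-class] (second branch is a replica).
#' @param Etot,Itot1,Itot2 total concentrations.
#' @param tol residual tolerance.
#' @param maxIter Newton iteration cap.
#' @return an [LNASteadyState-class] with means (Z1, M1, Z2, M2).
#' @export
mimoSteadyState <- function(rates, Etot = 1, Itot1 = 1, Itot2 = 1,
                            tol = 1e-10, maxIter = 200L) {
  stopifnot(methods::is(rates, "RateParameters"),
            Etot > 0, Itot1 >= 0, Itot2 >= 0)
  kp <- rates@k0Plus
  km <- rates@k0Minus
  c1 <- rates@c1
  c2 <- rates@c2
  f <- function(x) {
    Z1 <- x[1]; M1 <- x[2]; Z2 <- x[3]; M2 <- x[4]
    E <- Etot - M1 - M2
    c(c1 * M1 - c2 * Z1,
      kp * E * (Itot1 - M1 - Z1) - (km + c1) * M1,
      c1 * M2 - c2 * Z2,
      kp * E * (Itot2 - M2 - Z2) - (km + c1) * M2)
  }
  x <- c(Itot1 / 4, min(Etot, Itot1) / 4, Itot2 / 4, min(Etot, Itot2) / 4)
  sol <- .newtonSolve(f, x, tol = tol, maxIter = maxIter)
  means <- stats::setNames(sol$x, c("Z1", "M1", "Z2", "M2"))
  methods::new("LNASteadyState", means = means,
               covariance = matrix(numeric(0), 0, 0), omega = rates@omega,
               residual = c(rate = max(abs(sol$f))))
}

#' Steady-state means of the MIMO circuit with N downstream sites
#'
#' As [mimoSteadyState()] but with N identical downstream sites bound to the
#' first output; the site occupancy enters through its quasi-steady state
#' [downstreamComplexSteady()], which cancels the binding fluxes in the Z1
#' equation and sequesters part of the first input pool in the M1 equation
#' (\eqn{I_1 = I_{tot1} - M_1 - Z_1 - \sum_j C_j}).
#'
#' @inheritParams mimoSteadyState
#' @param N number of downstream sites.
#' @param k3 downstream dissociation constant.
#' @param Dtot per-site total concentration.
#' @return an [LNASteadyState-class] with means (Z1, M1, Z2, M2, Ctot).
#' @export
mimoDownstreamSteadyState <- function(rates, Etot = 1, Itot1 = 1, Itot2 = 1,
                                      N = 0L, k3 = 1, Dtot = 1,
                                      tol = 1e-10, maxIter = 200L) {
  stopifnot(N >= 0, k3 > 0, Dtot >= 0)
  kp <- rates@k0Plus
  km <- rates@k0Minus
  c1 <- rates@c1
  c2 <- rates@c2
  f <- function(x) {
    Z1 <- x[1]; M1 <- x[2]; Z2 <- x[3]; M2 <- x[4]
    E <- Etot - M1 - M2
    C <- downstreamComplexSteady(max(Z1, 0), Dtot, k3)
    c(c1 * M1 - c2 * Z1 + N * (k3 * C - Z1 * (Dtot - C)),
      kp * E * (Itot1 - M1 - Z1 - N * C) - (km + c1) * M1,
      c1 * M2 - c2 * Z2,
      kp * E * (Itot2 - M2 - Z2) - (km + c1) * M2)
  }
  x <- c(Itot1 / 4, min(Etot, Itot1) / 4, Itot2 / 4, min(Etot, Itot2) / 4)
  sol <- .newtonSolve(f, x, tol = tol, maxIter = maxIter)
  Z1 <- sol$x[1]
  means <- stats::setNames(c(sol$x, N * downstreamComplexSteady(max(Z1, 0), Dtot, k3)),
                           c("Z1", "M1", "Z2", "M2", "Ctot"))
  methods::new("LNASteadyState", means = means,
               covariance = matrix(numeric(0), 0, 0), omega = rates@omega,
               residual = c(rate = max(abs(sol$f))))
}

## damped Newton with numerical Jacobian
.newtonSolve <- function(f, x0, tol = 1e-10, maxIter = 200L) {
  x <- x0
  fx <- f(x)
  for (it in seq_len(maxIter)) {
    if (max(abs(fx)) < tol) break
    n <- length(x)
    J <- matrix(0, n, n)
    h <- pmax(abs(x), 1) * 1e-7
    for (k in seq_len(n)) {
      xp <- x; xp[k] <- xp[k] + h[k]
      J[, k] <- (f(xp) - fx) / h[k]
    }
    step <- tryCatch(solve(J, -fx), error = function(e)
      stop("singular Jacobian in Newton solve (residual ",
           format(max(abs(fx))), ")"))
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      fn <- f(xn)
      if (max(abs(fn)) < max(abs(fx)) || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    x <- xn
    fx <- fn
  }
  if (max(abs(fx)) >= tol)
    stop("Newton iteration did not converge; residuals: ",
         paste(format(fx, digits = 4), collapse = ", "))
  list(x = x, f = fx, iterations = it)
}

#' Stationary covariance from the Lyapunov equation
#'
#' Solves \eqn{A \Sigma + \Sigma A^T + BB^T = 0} for the stationary
#' covariance of the linear noise approximation, by dense Kronecker
#' vectorization (\eqn{(I \otimes A + A \otimes I)\,vec(\Sigma) =
#' -vec(BB^T)}). The drift Jacobian must be Hurwitz (stable steady state).
#'
#' @param jacobian drift Jacobian A of the linearized rate equations.
#' @param diffusion diffusion matrix \eqn{BB^T} (symmetric PSD; the sum of
#'   \eqn{\delta \delta^T \times} flux over reactions, divided by the
#'   volume).
#' @param tol residual tolerance.
#' @return symmetric covariance matrix.
#' @examples
#' lyapunovCovariance(matrix(-2), matrix(4))  # 1 (= d / (2 a))
#' @export
lyapunovCovariance <- function(jacobian, diffusion, tol = 1e-10) {
  A <- as.matrix(jacobian)
  D <- as.matrix(diffusion)
  n <- nrow(A)
  stopifnot(ncol(A) == n, all(dim(D) == n))
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("jacobian is not Hurwitz (eigenvalue with non-negative real part); ",
         "the steady state is not stable")
  M <- kronecker(diag(n), A) + kronecker(A, diag(n))
  S <- matrix(solve(M, -as.vector(D)), n, n)
  S <- (S + t(S)) / 2
  res <- max(abs(A %*% S + S %*% t(A) + D))
  if (res > tol * max(1, max(abs(D))))
    stop("Lyapunov residual ", format(res), " exceeds tolerance")
  S
}

#' Full LNA of the loaded SISO circuit (means and covariance)
#'
#' Two-dimensional linear noise approximation of the reduced SISO circuit
#' with N identical downstream sites, tracking the free output Z1 and the
#' pooled complex concentration. Means come from the rate equations
#' (\eqn{\mu_N = \mu_0}); the covariance solves the Lyapunov equation with
#' the diffusion assembled from the steady-state reaction fluxes scaled by
#' \eqn{1/\Omega}. Exposes the output variance under load, for which no
#' closed form is carried: compare with [sisoReducedVariance()] to study how
#' load reshapes the fluctuations.
#'
#' @inheritParams sisoDownstreamMean
#' @param k3Plus downstream association rate (with \code{k3} fixing
#'   \code{k3Minus = k3 * k3Plus}).
#' @param omega reaction volume.
#' @return an [LNASteadyState-class] over (Z1, Ctot).
#' @export
lnaSisoDownstream <- function(c1, E, Itot1, c2, k3 = 1, Dtot = 1, N = 0L,
                              k3Plus = 1, omega = 1) {
  mu <- sisoReducedMean(c1, E, Itot1, c2)
  k3Minus <- k3 * k3Plus
  Cst <- downstreamComplexSteady(mu, Dtot, k3)
  Ctot <- N * Cst
  DtotAll <- N * Dtot
  ## drift of (Z, Ctot): dZ = c1 E (Itot - Z) - c2 Z - k3p Z (DtotAll - Ctot)
  ##                        + k3m Ctot ; dCtot = -(those binding terms)
  A <- rbind(
    c(-(c1 * E + c2) - k3Plus * (DtotAll - Ctot), k3Plus * mu + k3Minus),
    c(k3Plus * (DtotAll - Ctot), -(k3Plus * mu + k3Minus)))
  prodFlux <- c1 * E * (Itot1 - mu)
  recFlux <- c2 * mu
  bindFlux <- k3Plus * mu * (DtotAll - Ctot)
  unbindFlux <- k3Minus * Ctot
  D <- rbind(
    c(prodFlux + recFlux + bindFlux + unbindFlux, -(bindFlux + unbindFlux)),
    c(-(bindFlux + unbindFlux), bindFlux + unbindFlux)) / omega
  if (N == 0L) {
    A <- A[1, 1, drop = FALSE]
    D <- D[1, 1, drop = FALSE]
  }
  S <- lyapunovCovariance(A, D)
  means <- c(Z1 = mu, Ctot = Ctot)
  if (N == 0L) means <- means[1]
  cov <- S
  dimnames(cov) <- list(names(means), names(means))
  methods::new("LNASteadyState", means = means, covariance = cov,
               omega = omega,
               residual = c(lyapunov = max(abs(A %*% S + S %*% t(A) + D))))
}

#' Capacity of the additive white Gaussian noise channel
#'
#' \deqn{C = \tfrac{1}{2}\log(1 + S/N_v)} nats, the Shannon capacity with
#' signal power S and noise power \code{noiseVariance} (the LNA channel
#' model takes unit noise variance).
#'
#' @param signalVariance signal power (here: the stationary output variance
#'   from the LNA).
#' @param noiseVariance noise power (default 1).
#' @param units "nats" or "bits".
#' @return capacity (0 when the signal power is 0).
#' @examples
#' awgnCapacity(2.5)  # 0.5 * log(3.5)
#' @export
awgnCapacity <- function(signalVariance, noiseVariance = 1, units = "nats") {
  if (any(signalVariance < 0) || any(noiseVariance <= 0))
    stop("variances must be non-negative (noise strictly positive)")
  .toUnits(0.5 * log1p(signalVariance / noiseVariance), units)
}
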