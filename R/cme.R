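#' @include AllClasses.R reaction-networks.R
NULL

## conserved totals under one input-symbol condition: the input totals are
## fixed by the symbols (one molecule of I present or absent at t0), the
## enzyme and site totals come from the model
.conditionTotals <- function(model, i1, i2 = 0L) {
  stopifnot(i1 %in% c(0L, 1L) || i1 >= 0, i2 %in% c(0L, 1L) || i2 >= 0)
  tot <- model@totals
  tot["Itot1"] <- i1
  if ("Itot2" %in% names(tot)) tot["Itot2"] <- i2
  tot
}

## the all-free state for a condition: I1 = i1, I2 = i2, enzymes and sites
## unbound (no complexes or output present before t0)
.initialState <- function(model, i1, i2 = 0L) {
  x <- stats::setNames(integer(length(model@species)), model@species)
  tot <- .conditionTotals(model, i1, i2)
  x["I1"] <- as.integer(tot[["Itot1"]])
  if ("I2" %in% model@species) x["I2"] <- as.integer(tot[["Itot2"]])
  x["E"] <- as.integer(tot[["Etot"]])
  if ("E2" %in% model@species) x["E2"] <- as.integer(tot[["Etot2"]])
  for (j in seq_len(model@nDownstream))
    x[paste0("D", j)] <- as.integer(tot[[paste0("Dtot", j)]])
  x
}

#' Enumerate the microstates of a circuit under one input condition
#'
#' Returns every assignment of non-negative integer counts to the model's
#' species that satisfies all conservation laws, with the input totals fixed
#' by the binary symbols \code{i1}, \code{i2} (the on-off keying alphabet:
#' symbol 1 means one input molecule present at t0). States are returned in
#' a canonical order: lexicographic on the count vectors with species sorted
#' alphabetically.
#'
#' @param model a [ModelSpec-class].
#' @param i1,i2 input symbols (non-negative integers; 0/1 in the on-off
#'   keying alphabet). \code{i2} is ignored for single-input topologies.
#' @param maxStates guard on the enumeration size.
#' @return integer matrix, one microstate per row, columns named by species.
#' @examples
#' m <- buildModel("ISOLATED_SISO", rateParameters())
#' nrow(enumerateStates(m, i1 = 1))  # 3 microstates
#' @export
enumerateStates <- function(model, i1, i2 = 0L, maxStates = 1e5) {
  stopifnot(methods::is(model, "ModelSpec"))
  laws <- conservationLaws(model)
  tot <- .conditionTotals(model, i1, i2)
  b <- vapply(names(laws), function(nm) as.numeric(tot[[nm]]), numeric(1))
  L <- do.call(rbind, laws) # nlaws x nspecies, 0/1 coefficients
  sp <- model@species
  n <- length(sp)
  states <- vector("list", 256L)
  count <- 0L
  x <- integer(n)
  rem <- b # remaining capacity per law

  recurse <- function(idx) {
    if (idx > n) {
      if (all(rem == 0)) {
        count <<- count + 1L
        if (count > maxStates)
          stop("state space exceeds maxStates = ", maxStates)
        if (count > length(states)) length(states) <<- 2L * count
        states[[count]] <<- x
      }
      return(invisible())
    }
    inLaws <- which(L[, idx] > 0)
    cap <- if (length(inLaws)) floor(min(rem[inLaws] / L[inLaws, idx])) else 0
    for (v in 0:cap) {
      x[idx] <<- v
      rem[inLaws] <<- rem[inLaws] - v * L[inLaws, idx]
      recurse(idx + 1L)
      rem[inLaws] <<- rem[inLaws] + v * L[inLaws, idx]
    }
    x[idx] <<- 0L
  }
  recurse(1L)
  S <- do.call(rbind, states[seq_len(count)])
  colnames(S) <- sp
  ## canonical order: lexicographic on counts, species alphabetical
  ord <- do.call(order, as.data.frame(S[, order(sp), drop = FALSE]))
  S[ord, , drop = FALSE]
}

.stateKeys <- function(S) apply(S, 1L, paste, collapse = ",")

#' Build the CTMC generator on an enumerated state set
#'
#' Off-diagonal entry (i, j) is the total propensity of the reactions
#' carrying microstate i to microstate j; diagonal entries make rows sum to
#' zero. Errors if any reaction with positive propensity leaves the supplied
#' state set (which would signal an enumeration bug).
#'
#' @param model a [ModelSpec-class].
#' @param states integer matrix of microstates from [enumerateStates()].
#' @return dense square generator matrix.
#' @export
buildGenerator <- function(model, states) {
  stopifnot(methods::is(model, "ModelSpec"), is.matrix(states))
  n <- nrow(states)
  keys <- .stateKeys(states)
  idx <- stats::setNames(seq_len(n), keys)
  Q <- matrix(0, n, n)
  omega <- model@rates@omega
  sp <- model@species
  deltas <- lapply(model@reactions, reactionDelta, species = sp)
  for (r in seq_along(model@reactions)) {
    rx <- model@reactions[[r]]
    d <- deltas[[r]]
    for (i in seq_len(n)) {
      a <- reactionPropensity(rx, states[i, ], omega)
      if (a <= 0) next
      target <- states[i, ] + d
      j <- idx[paste(target, collapse = ",")]
      if (is.na(j))
        stop("reaction '", rx$rateName, "' leaves the enumerated state set")
      Q[i, j] <- Q[i, j] + a
      Q[i, i] <- Q[i, i] - a
    }
  }
  Q
}

#' Stationary distribution of a CTMC generator
#'
#' Solves \eqn{\pi^T Q = 0, \sum \pi = 1} restricted to the closed
#' communicating class reachable from \code{initialIndex}: strongly
#' connected components with no outgoing transitions are identified on the
#' reachable subgraph; exactly one such recurrent class must be reachable
#' (otherwise the stationary law is ambiguous and an error is raised).
#' Transient states receive probability zero. The solve is a dense linear
#' system with one equation replaced by the normalization constraint.
#'
#' @param generator square CTMC generator (rows sum to 0).
#' @param states optional microstate matrix carried through to the result.
#' @param initialIndex row index of the initial state (default 1).
#' @param condition integer input-symbol pair recorded in the result.
#' @param tol residual tolerance on \eqn{\|\pi^T Q\|_\infty}.
#' @return a [StationaryDistribution-class].
#' @export
stationaryDistribution <- function(generator, states = NULL,
                                   initialIndex = 1L,
                                   condition = c(1L, 0L), tol = 1e-10) {
  n <- nrow(generator)
  stopifnot(n == ncol(generator))
  if (is.null(states)) {
    states <- matrix(seq_len(n), ncol = 1, dimnames = list(NULL, "state"))
  }
  if (max(abs(rowSums(generator))) > 1e-9)
    stop("generator rows must sum to 0")

  ## reachable set from the initial state
  adj <- generator > 0
  diag(adj) <- FALSE
  reach <- rep(FALSE, n)
  frontier <- initialIndex
  reach[frontier] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0)
    frontier <- nxt[!reach[nxt]]
    reach[frontier] <- TRUE
  }
  ridx <- which(reach)
  subAdj <- adj[ridx, ridx, drop = FALSE]

  ## recurrent classes = terminal strongly connected components
  g <- igraph::graph_from_adjacency_matrix(subAdj, mode = "directed")
  comp <- igraph::components(g, mode = "strong")$membership
  terminal <- logical(max(comp))
  for (k in seq_len(max(comp))) {
    inside <- comp == k
    terminal[k] <- !any(subAdj[inside, !inside, drop = FALSE])
  }
  if (sum(terminal) > 1L)
    stop("multiple recurrent classes reachable from the initial state; ",
         "the stationary distribution is ambiguous")
  cc <- ridx[comp == which(terminal)]

  probs <- numeric(n)
  if (length(cc) == 1L) {
    probs[cc] <- 1
  } else {
    Qcc <- generator[cc, cc, drop = FALSE]
    A <- t(Qcc)
    A[length(cc), ] <- 1
    rhs <- c(rep(0, length(cc) - 1L), 1)
    pi_cc <- solve(A, rhs)
    pi_cc[pi_cc < 0 & pi_cc > -1e-12] <- 0
    probs[cc] <- pi_cc / sum(pi_cc)
  }
  res <- max(abs(drop(probs %*% generator)))
  if (res > tol)
    stop("stationary solve residual ", format(res), " exceeds tol ", tol)
  methods::new("StationaryDistribution", states = states, probs = probs,
               condition = as.integer(condition), residual = res)
}

#' Solve the stationary CME of a circuit for one input condition
#'
#' Convenience wrapper: enumerates the microstates, builds the generator,
#' and solves for the stationary law starting from the all-free initial
#' state of the condition.
#'
#' @inheritParams enumerateStates
#' @param tol residual tolerance passed to [stationaryDistribution()].
#' @return a [StationaryDistribution-class].
#' @export
cmeStationary <- function(model, i1, i2 = 0L, maxStates = 1e5, tol = 1e-10) {
  S <- enumerateStates(model, i1, i2, maxStates = maxStates)
  Q <- buildGenerator(model, S)
  init <- .initialState(model, i1, i2)
  i0 <- match(paste(init[colnames(S)], collapse = ","), .stateKeys(S))
  if (is.na(i0)) stop("initial state not found in the enumerated set")
  stationaryDistribution(Q, states = S, initialIndex = i0,
                         condition = c(i1, i2), tol = tol)
}

## P(Z1 free = 0) under a stationary distribution
.probZ1Zero <- function(sd) {
  z <- sd@states[, "Z1"]
  sum(sd@probs[z == 0])
}

#' Extract the Z-channel of a circuit from the exact CME solution
#'
#' Solves the stationary CME for input symbol 1 and reads off
#' \eqn{\hat A = P(Z_1(t_s) = 0 \mid I_1(t_0) = 1)}. For two-input
#' topologies the conditional is computed per second-input symbol and
#' marginalized with the priors \code{(P02, P12)}; the per-branch
#' conditionals are kept in the returned object (they are the numeric
#' mixture components of the MIMO retroactivity constants). The
#' \code{i1 = 0} condition needs no solve: conservation forces
#' \eqn{Z_1 = 0} exactly, which is what makes every topology a Z-channel.
#'
#' @param model a [ModelSpec-class].
#' @param P01 prior of the first input's symbol 0.
#' @param secondInputPriors numeric \code{c(P02, P12)}, priors of the second
#'   input's symbols (two-input topologies only).
#' @param tol stationary-solve tolerance.
#' @return a [ZChannel-class].
#' @examples
#' ch <- channelFromCME(buildModel("ISOLATED_SISO", rateParameters()))
#' aValue(ch)  # 3/4 at unit rates
#' @export
channelFromCME <- function(model, P01 = 0.5,
                           secondInputPriors = c(0.5, 0.5), tol = 1e-10) {
  stopifnot(methods::is(model, "ModelSpec"),
            P01 >= 0, P01 <= 1)
  twoInput <- model@topology %in% c("ISOLATED_MIMO", "MIMO_N_DOWNSTREAM",
                                    "TWO_SISO_MAC")
  if (twoInput) {
    pr <- secondInputPriors
    if (length(pr) != 2L || any(pr < 0) || abs(sum(pr) - 1) > 1e-9)
      stop("secondInputPriors must be a probability pair (P02, P12)")
    cond <- vapply(c(0L, 1L), function(i2)
      .probZ1Zero(cmeStationary(model, 1L, i2, tol = tol)), numeric(1))
    names(cond) <- c("i2=0", "i2=1")
    A <- sum(pr * cond)
  } else {
    cond <- numeric(0)
    A <- .probZ1Zero(cmeStationary(model, 1L, tol = tol))
  }
  zChannel(A, P01, branchConditionals = cond)
}

#' Construct a Z-channel from A and the input prior
#'
#' @param A probability of output 0 given input 1.
#' @param P01 prior of input symbol 0.
#' @param branchConditionals optional named conditionals to carry along.
#' @return a [ZChannel-class] with the 2x2 joint pmf
#'   \code{rbind(c(P01, 0), c(A*P11, (1-A)*P11))}.
#' @export
zChannel <- function(A, P01 = 0.5, branchConditionals = numeric(0)) {
  A <- min(max(A, 0), 1)
  P11 <- 1 - P01
  joint <- rbind(c(P01, 0), c(A * P11, (1 - A) * P11))
  methods::new("ZChannel", A = A, P01 = P01, joint = joint,
               branchConditionals = branchConditionals)
}

#' Mutual information of a circuit from the exact CME solution
#'
#' Mutual information in nats between the input symbol at t0 and the
#' steady-state output occupancy, computed from the Z-channel joint pmf of
#' the exact stationary solution.
#'
#' @inheritParams channelFromCME
#' @param priors numeric \code{c(P01, P11, P02, P12)}; the trailing pair is
#'   ignored for single-input topologies.
#' @return mutual information in nats (in \code{[0, log(2)]}).
#' @export
miFromCME <- function(model, priors = c(0.5, 0.5, 0.5, 0.5), tol = 1e-10) {
  stopifnot(length(priors) >= 2,
            abs(priors[1] + priors[2] - 1) < 1e-9)
  if (length(priors) < 4) priors <- c(priors[1:2], 0.5, 0.5)
  ch <- channelFromCME(model, P01 = priors[1],
                       secondInputPriors = priors[3:4], tol = tol)
  miZChannel(ch@A, ch@P01)
}

#' Export a stationary distribution as a data.frame / CSV
#'
#' @param sd a [StationaryDistribution-class].
#' @param file optional CSV path.
#' @return data.frame of state label columns plus a probability column.
#' @export
stationaryTable <- function(sd, file = NULL) {
  df <- as.data.frame(sd@states)
  df$probability <- sd@probs
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
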