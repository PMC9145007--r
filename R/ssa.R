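#' @include AllClasses.R reaction-networks.R cme.R
NULL

#' Exact stochastic simulation of a circuit model (Gillespie)
#'
#' Direct-method simulation of the continuous-time Markov chain defined by a
#' model's mass-action propensities. Random numbers are consumed in a fixed
#' order per event — exponential waiting time first, then reaction selection
#' — so trajectories are bit-reproducible given the seed. If the total
#' propensity vanishes before \code{tEnd} (an absorbing state, e.g. the
#' non-cyclic circuit), the path legitimately ends there.
#'
#' @param model a [ModelSpec-class].
#' @param initial named integer vector of initial counts, or \code{NULL} for
#'   the all-free state of condition \code{(i1, i2)}.
#' @param tEnd simulation horizon (> 0).
#' @param seed RNG seed.
#' @param i1,i2 input symbols used when \code{initial} is \code{NULL}.
#' @param maxEvents guard on the number of jumps.
#' @return list with \code{times} (jump times, starting at 0),
#'   \code{states} (integer matrix, one row per epoch), \code{tEnd},
#'   \code{seed}, and \code{absorbed} (logical).
#' @export
gillespie <- function(model, initial = NULL, tEnd = 1000, seed = 1L,
                      i1 = 1L, i2 = 0L, maxEvents = 1e6) {
  stopifnot(methods::is(model, "ModelSpec"), tEnd > 0)
  sp <- model@species
  if (is.null(initial)) initial <- .initialState(model, i1, i2)
  x <- stats::setNames(as.integer(initial[sp]), sp)
  stopifnot(all(x >= 0))
  omega <- model@rates@omega
  rx <- model@reactions
  deltas <- lapply(rx, function(r) as.integer(reactionDelta(r, sp)))
  set.seed(as.integer(seed))
  times <- numeric(1024L)
  states <- matrix(0L, 1024L, length(sp))
  n <- 1L
  times[1L] <- 0
  states[1L, ] <- x
  t <- 0
  absorbed <- FALSE
  repeat {
    a <- vapply(rx, reactionPropensity, numeric(1), state = x, omega = omega)
    a0 <- sum(a)
    if (a0 <= 0) { absorbed <- TRUE; break }
    t <- t + stats::rexp(1L, a0)
    if (t >= tEnd) break
    r <- findInterval(stats::runif(1L) * a0, cumsum(a), left.open = TRUE) + 1L
    x <- x + deltas[[r]]
    n <- n + 1L
    if (n > maxEvents) stop("maxEvents exceeded")
    if (n > nrow(states)) {
      length(times) <- 2L * nrow(states)
      states <- rbind(states, matrix(0L, nrow(states), ncol(states)))
    }
    times[n] <- t
    states[n, ] <- x
  }
  colnames(states) <- sp
  list(times = times[seq_len(n)], states = states[seq_len(n), , drop = FALSE],
       tEnd = tEnd, seed = as.integer(seed), absorbed = absorbed)
}

#' Time-averaged occupancy of a trajectory
#'
#' Time-weighted occupancy pmf over the visited microstates after a burn-in
#' window, with per-batch occupancies for batch-means standard errors. A
#' single long trajectory estimates the stationary law of the chain's
#' closed class (the chain is ergodic there), which is cheaper than many
#' endpoint samples and estimates the same distribution.
#'
#' @param path result of [gillespie()].
#' @param burnIn time discarded from the start (default 10% of the horizon).
#' @param nBatches number of equal-time batches for the standard error.
#' @return a [TrajectorySummary-class].
#' @export
occupancyPmf <- function(path, burnIn = 0.1 * path$tEnd, nBatches = 20L) {
  tEnd <- path$tEnd
  stopifnot(burnIn >= 0, burnIn < tEnd)
  times <- path$times
  states <- path$states
  starts <- pmax(times, burnIn)
  ends <- pmax(c(times[-1L], tEnd), burnIn)
  keep <- ends > starts
  starts <- starts[keep]
  ends <- ends[keep]
  states <- states[keep, , drop = FALSE]
  keys <- .stateKeys(states)
  uk <- !duplicated(keys)
  uniqStates <- states[uk, , drop = FALSE]
  idx <- match(keys, keys[uk])

  dur <- ends - starts
  fidx <- factor(idx, levels = seq_len(nrow(uniqStates)))
  w <- vapply(split(dur, fidx), sum, numeric(1))
  probs <- as.numeric(w / sum(w))

  ## equal-time batches over [burnIn, tEnd]; intervals split across edges
  edges <- seq(burnIn, tEnd, length.out = nBatches + 1L)
  B <- matrix(0, nBatches, nrow(uniqStates))
  for (b in seq_len(nBatches)) {
    lo <- edges[b]; hi <- edges[b + 1L]
    d <- pmax(pmin(ends, hi) - pmax(starts, lo), 0)
    if (sum(d) > 0)
      B[b, ] <- vapply(split(d, fidx), sum, numeric(1)) / sum(d)
  }
  methods::new("TrajectorySummary", states = uniqStates, probs = probs,
               batchProbs = B, totalTime = tEnd, burnIn = burnIn,
               seed = path$seed)
}

#' Total variation distance between two pmfs over microstates
#'
#' Aligns the two supports by state key and returns
#' \eqn{\tfrac12 \sum |p - q|}.
#'
#' @param x,y [TrajectorySummary-class], [StationaryDistribution-class], or
#'   lists with \code{states}/\code{probs}.
#' @return total variation distance in [0, 1].
#' @export
tvDistance <- function(x, y) {
  get <- function(o) {
    if (methods::is(o, "TrajectorySummary") ||
        methods::is(o, "StationaryDistribution"))
      list(states = o@states, probs = o@probs)
    else o
  }
  x <- get(x); y <- get(y)
  kx <- .stateKeys(x$states)
  ky <- .stateKeys(y$states)
  keys <- union(kx, ky)
  p <- stats::setNames(numeric(length(keys)), keys)
  q <- p
  p[kx] <- x$probs
  q[ky] <- y$probs
  sum(abs(p - q)) / 2
}

#' Batch-means standard error of the total variation distance
#'
#' The yardstick for agreement between simulated occupancy and the exact
#' stationary law. The total variation distance is half a sum of absolute
#' per-state deviations, so its Monte-Carlo standard error is bounded via
#' the triangle inequality by half the sum of the per-state batch-means
#' standard errors; that conservative bound is reported as \code{se}.
#'
#' @param summary a [TrajectorySummary-class].
#' @param reference a [StationaryDistribution-class].
#' @return list with \code{tv} (overall distance), \code{se} (conservative
#'   batch-means standard error of \code{tv}), \code{batchTv} (per-batch
#'   distances to the reference).
#' @export
tvBatchError <- function(summary, reference) {
  stopifnot(methods::is(summary, "TrajectorySummary"),
            methods::is(reference, "StationaryDistribution"))
  tv <- tvDistance(summary, reference)
  nb <- nrow(summary@batchProbs)
  perStateSd <- apply(summary@batchProbs, 2L, stats::sd)
  batchTv <- vapply(seq_len(nb), function(b)
    tvDistance(list(states = summary@states,
                    probs = summary@batchProbs[b, ]), reference), numeric(1))
  list(tv = tv, se = 0.5 * sum(perStateSd) / sqrt(nb), batchTv = batchTv)
}

#' Export a trajectory as a CSV event list
#'
#' @param path result of [gillespie()].
#' @param file CSV path.
#' @return the written data.frame (time column plus one column per species),
#'   invisibly.
#' @export
writeTrajectory <- function(path, file) {
  df <- data.frame(time = path$times, path$states, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
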