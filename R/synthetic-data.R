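#' @include AllClasses.R reaction-networks.R
NULL

#' Sample rate-parameter sets in a stated regime
#'
#' Log-uniform draws of the circuit rate constants, constrained to one of
#' the regimes the analysis distinguishes. Log-uniform sampling is used
#' because the claims of interest span rate ratios over orders of magnitude
#' (the recycling rate runs from 0 to effectively infinite).
#'
#' Regimes: \describe{
#'   \item{generic}{all rates log-uniform on \code{catalyticRange} /
#'     \code{bindingRange}.}
#'   \item{fast_binding}{binding rates are the catalytic scale times a
#'     log-uniform multiplier in \code{[100, 1e4]}, so that
#'     \code{min(k0Plus, k0Minus) >= 100 * max(c1, c2)} always holds.}
#'   \item{noncyclic}{as generic, with \code{c2 = 0}.}
#'   \item{large_c2}{as generic, with \code{c2 >= 1e6 * c1} (the
#'     instant-recycling limit).}
#' }
#'
#' @param regime one of "generic", "fast_binding", "noncyclic", "large_c2".
#' @param nDraws number of parameter sets (>= 1).
#' @param seed RNG seed; identical seeds reproduce identical draws.
#' @param nDownstream how many downstream rate pairs to draw per set.
#' @param catalyticRange log-uniform range for c1, c2.
#' @param bindingRange log-uniform range for generic binding rates.
#' @param k3Range log-uniform range for downstream dissociation constants.
#' @param omega reaction volume stored in each draw.
#' @return list of [RateParameters-class] objects, each with attributes
#'   \code{regime} and \code{seed}.
#' @examples
#' draws <- sampleRates("fast_binding", nDraws = 3, seed = 1)
#' @export
sampleRates <- function(regime = c("generic", "fast_binding", "noncyclic",
                                   "large_c2"),
                        nDraws = 1L, seed = 1L, nDownstream = 2L,
                        catalyticRange = c(1e-2, 1e2),
                        bindingRange = c(1e-2, 1e2),
                        k3Range = c(1e-1, 1e1), omega = 1) {
  regime <- match.arg(regime)
  stopifnot(nDraws >= 1)
  set.seed(as.integer(seed))
  runifLog <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))
  draws <- vector("list", nDraws)
  for (i in seq_len(nDraws)) {
    c1 <- runifLog(1, catalyticRange)
    c2 <- switch(regime,
                 noncyclic = 0,
                 large_c2 = c1 * 1e6 * runifLog(1, c(1, 1e2)),
                 runifLog(1, catalyticRange))
    cmax <- max(c1, if (regime == "large_c2") c1 else c2)
    if (regime == "fast_binding") {
      k0Plus <- cmax * runifLog(1, c(1e2, 1e4))
      k0Minus <- cmax * runifLog(1, c(1e2, 1e4))
    } else {
      k0Plus <- runifLog(1, bindingRange)
      k0Minus <- runifLog(1, bindingRange)
    }
    k3 <- runifLog(nDownstream, k3Range)
    k3Plus <- if (regime == "fast_binding") rep(100 * cmax, nDownstream)
              else rep(1, nDownstream)
    r <- rateParameters(k0Plus = k0Plus, k0Minus = k0Minus, c1 = c1, c2 = c2,
                        k3Plus = k3Plus, k3Minus = k3 * k3Plus / omega,
                        omega = omega)
    if (regime == "fast_binding" &&
        min(r@k0Plus, r@k0Minus) < 100 * max(r@c1, r@c2))
      stop("internal error: fast-binding constraint violated")
    attr(r, "regime") <- regime
    attr(r, "seed") <- as.integer(seed)
    draws[[i]] <- r
  }
  draws
}

#' Input-symbol prior record for on-off keying
#'
#' Completes and validates the prior record of the two binary inputs of the
#' concentration on-off keying alphabet (symbol 1 = one input molecule
#' present at t0, symbol 0 = none).
#'
#' @param P01 prior of the first input's symbol 0.
#' @param P02 prior of the second input's symbol 0.
#' @return named numeric vector (P01, P11, P02, P12) with an attribute
#'   \code{degenerate} flagging a deterministic first input (MI is 0 there).
#' @export
symbolEnsemble <- function(P01 = 0.5, P02 = 0.5) {
  if (P01 < 0 || P01 > 1 || P02 < 0 || P02 > 1)
    stop("priors must lie in [0, 1]")
  out <- c(P01 = P01, P11 = 1 - P01, P02 = P02, P12 = 1 - P02)
  attr(out, "degenerate") <- P01 %in% c(0, 1)
  out
}

#' Grid of input priors for capacity searches
#'
#' @param n number of grid points (default 101).
#' @return equally spaced priors covering [0, 1].
#' @export
priorGrid <- function(n = 101L) seq(0, 1, length.out = n)

#' Canonical hand-checkable fixtures
#'
#' The small named fixtures the validation suite is built on, each carrying
#' its expected values: \describe{
#'   \item{siso_unit_rates}{the 3-state isolated SISO chain at unit rates,
#'     with its hand-solved stationary law (1/2, 1/4, 1/4) (balance
#'     equations: \eqn{\pi_2 = \pi_1 k_0^+/(k_0^- + c_1)},
#'     \eqn{\pi_3 = \pi_2 c_1/c_2}) and A = 3/4.}
#'   \item{mimo_statespace}{the isolated MIMO circuit at unit rates with
#'     both inputs on: 8 microstates (3 x 3 minus the double-complex state
#'     excluded by the single shared enzyme).}
#'   \item{fastbinding_ladder}{isolated SISO models with binding rates 10,
#'     100 and 1000 times the unit catalytic rates; the gap between the
#'     exact A and the closed form shrinks along the ladder.}
#' }
#'
#' @return named list of fixtures; each has a \code{model} (or
#'   \code{models}) plus \code{expected} values.
#' @export
fixtureSuite <- function() {
  unit <- rateParameters(1, 1, 1, 1)
  ladder <- lapply(c(10, 100, 1000), function(k)
    buildModel("ISOLATED_SISO", rateParameters(k, k, 1, 1)))
  list(
    siso_unit_rates = list(
      model = buildModel("ISOLATED_SISO", unit),
      expected = list(nStates = 3L, pi = c(1 / 2, 1 / 4, 1 / 4), A = 3 / 4,
                      stateOrder = c("I1+E", "M1", "E+Z1"))),
    mimo_statespace = list(
      model = buildModel("ISOLATED_MIMO", unit),
      expected = list(nStates = 8L)),
    fastbinding_ladder = list(
      models = ladder,
      multipliers = c(10, 100, 1000),
      expected = list(a0 = 2 / 3, gapDecreasing = TRUE, topGap = 1e-3)))
}

#' Write a synthetic experiment directory
#'
#' Serializes a set of parameter draws and the symbol priors to JSON so a
#' full synthetic experiment can be archived and re-run.
#'
#' @param dir output directory (created if missing).
#' @param regime,nDraws,seed passed to [sampleRates()].
#' @param P01,P02 symbol priors.
#' @return the directory path, invisibly.
#' @export
writeSyntheticExperiment <- function(dir, regime = "fast_binding",
                                     nDraws = 10L, seed = 1L,
                                     P01 = 0.5, P02 = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  draws <- sampleRates(regime, nDraws = nDraws, seed = seed)
  ser <- lapply(draws, function(r)
    list(k0Plus = r@k0Plus, k0Minus = r@k0Minus, c1 = r@c1, c2 = r@c2,
         k3Plus = r@k3Plus, k3Minus = r@k3Minus, omega = r@omega))
  jsonlite::write_json(
    list(regime = regime, seed = seed, draws = ser,
         priors = as.list(symbolEnsemble(P01, P02))),
    file.path(dir, "experiment.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
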