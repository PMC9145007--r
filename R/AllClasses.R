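#' Supported circuit topologies
#'
#' The five signaling circuit layouts handled by the package: an isolated
#' single-input single-output (SISO) enzymatic cycle, the same cycle loaded
#' by N downstream binding sites (a broadcast-like layout), an isolated
#' two-input circuit sharing one enzyme (MIMO), the MIMO circuit with N
#' downstream sites on the first output, and two independent SISO circuits
#' competing for a shared pool of N sites (a multiple-access layout).
#'
#' @export
TOPOLOGIES <- c("ISOLATED_SISO", "SISO_N_DOWNSTREAM", "ISOLATED_MIMO",
                "MIMO_N_DOWNSTREAM", "TWO_SISO_MAC")

#' Rate parameters of a signaling circuit
#'
#' Mass-action rate constants for the two-step enzymatic upstream cycle
#' \eqn{I + E \rightleftharpoons M \to E + Z \to I} and the reversible
#' downstream binding reactions \eqn{Z + D_j \rightleftharpoons C_j}.
#' Bimolecular propensities are scaled by \code{1/omega} in count units, so
#' the dissociation constants are \code{k0 = k0Minus * omega / k0Plus} and
#' \code{k3_j = k3Minus_j * omega / k3Plus_j}.
#'
#' @slot k0Plus association rate of the input/enzyme binding (per molecule
#'   pair per time; divided by the volume in propensities).
#' @slot k0Minus dissociation rate of the enzyme/substrate complex (per time).
#' @slot c1 catalytic rate of the production step \eqn{M \to E + Z}.
#' @slot c2 recycling rate of the cycle-closing step \eqn{Z \to I}.
#' @slot k3Plus,k3Minus per-site downstream association/dissociation rates
#'   (numeric vectors of equal length, one entry per downstream site).
#' @slot omega reaction volume (dimensionless scale for bimolecular rates).
#'
#' @seealso [rateParameters()]
#' @export
setClass("RateParameters",
  representation(k0Plus = "numeric", k0Minus = "numeric",
                 c1 = "numeric", c2 = "numeric",
                 k3Plus = "numeric", k3Minus = "numeric",
                 omega = "numeric"),
  prototype(k0Plus = 1, k0Minus = 1, c1 = 1, c2 = 1,
            k3Plus = numeric(0), k3Minus = numeric(0), omega = 1))

setValidity("RateParameters", function(object) {
  msgs <- character(0)
  sc <- c(k0Plus = object@k0Plus, k0Minus = object@k0Minus,
          c1 = object@c1, c2 = object@c2, omega = object@omega)
  if (any(lengths(list(object@k0Plus, object@k0Minus, object@c1,
                       object@c2, object@omega)) != 1L))
    msgs <- c(msgs, "scalar rate slots must have length 1")
  if (any(!is.finite(sc)) || any(sc < 0))
    msgs <- c(msgs, "rates must be finite and non-negative")
  if (length(object@omega) == 1L && object@omega <= 0)
    msgs <- c(msgs, "omega must be > 0")
  if (length(object@k3Plus) != length(object@k3Minus))
    msgs <- c(msgs, "k3Plus and k3Minus must have the same length")
  if (any(object@k3Plus < 0) || any(object@k3Minus < 0))
    msgs <- c(msgs, "downstream rates must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' A signaling circuit model
#'
#' One of the five supported topologies, fully instantiated: species list,
#' mass-action reaction list, conserved totals, and rate constants. Built by
#' [buildModel()]; the reaction list is what the CME, LNA and SSA engines
#' consume.
#'
#' @slot topology one of [TOPOLOGIES].
#' @slot nDownstream number of downstream binding sites N (0 for isolated
#'   topologies).
#' @slot qConnected number of sites Q reachable by the first upstream output
#'   (multiple-access topology only; equals N otherwise).
#' @slot totals named numeric vector of conserved totals (Etot, Itot1, ...,
#'   Dtot1..DtotN).
#' @slot rates a [RateParameters-class] object.
#' @slot species character vector of species names, in canonical model order.
#' @slot reactions list of reactions; each is a list with elements
#'   \code{reactants}, \code{products} (named stoichiometry vectors),
#'   \code{rate}, \code{rateName} and \code{bimolecular}.
#'
#' @export
setClass("ModelSpec",
  representation(topology = "character", nDownstream = "integer",
                 qConnected = "integer", totals = "numeric",
                 rates = "RateParameters", species = "character",
                 reactions = "list"))

setValidity("ModelSpec", function(object) {
  msgs <- character(0)
  if (!object@topology %in% TOPOLOGIES)
    msgs <- c(msgs, paste("unknown topology:", object@topology))
  if (object@nDownstream < 0L)
    msgs <- c(msgs, "nDownstream must be >= 0")
  if (object@qConnected < 0L || object@qConnected > object@nDownstream)
    msgs <- c(msgs, "qConnected must satisfy 0 <= Q <= N")
  if (any(object@totals < 0))
    msgs <- c(msgs, "totals must be non-negative")
  for (r in object@reactions) {
    if (!all(c(names(r$reactants), names(r$products)) %in% object@species))
      msgs <- c(msgs, "reaction references unknown species")
  }
  if (length(msgs)) msgs else TRUE
})

#' Stationary distribution of a circuit's chemical master equation
#'
#' The stationary probability mass function over the enumerated microstates
#' of a [ModelSpec-class] for one input-symbol condition. Probabilities are
#' supported on the single closed communicating class reachable from the
#' initial state; transient states carry probability zero.
#'
#' @slot states integer matrix, one row per microstate, columns named by
#'   species.
#' @slot probs numeric vector of stationary probabilities (sums to 1).
#' @slot condition integer vector \code{c(i1, i2)} of the input symbols that
#'   fixed the conserved totals.
#' @slot residual infinity norm of \eqn{\pi^T Q} from the solve.
#'
#' @export
setClass("StationaryDistribution",
  representation(states = "matrix", probs = "numeric",
                 condition = "integer", residual = "numeric"))

setValidity("StationaryDistribution", function(object) {
  msgs <- character(0)
  if (nrow(object@states) != length(object@probs))
    msgs <- c(msgs, "states and probs length mismatch")
  if (any(object@probs < -1e-12))
    msgs <- c(msgs, "negative probabilities")
  if (abs(sum(object@probs) - 1) > 1e-10)
    msgs <- c(msgs, "probabilities must sum to 1 within 1e-10")
  if (length(msgs)) msgs else TRUE
})

#' Z-channel between the input symbol and the steady-state output
#'
#' The binary input/output channel induced by a circuit at steady state:
#' input symbol 0 (no input molecule) deterministically yields output 0,
#' while input symbol 1 yields output 0 with probability A. The joint pmf is
#' \deqn{P(I(t_0), Z(t_s)) = \begin{pmatrix} P_{01} & 0 \\ A P_{11} & (1-A) P_{11} \end{pmatrix}.}
#'
#' @slot A probability that the output is 0 given input symbol 1.
#' @slot P01 prior probability of input symbol 0.
#' @slot joint the 2x2 joint pmf (rows: input 0/1; columns: output 0/1).
#' @slot branchConditionals named numeric vector of per-condition
#'   conditionals P(Z1=0 | i1=1, i2) for two-input topologies (empty
#'   otherwise); used to extract the mixture components of the MIMO
#'   retroactivity constants.
#'
#' @export
setClass("ZChannel",
  representation(A = "numeric", P01 = "numeric", joint = "matrix",
                 branchConditionals = "numeric"),
  prototype(branchConditionals = numeric(0)))

setValidity("ZChannel", function(object) {
  msgs <- character(0)
  if (object@A < -1e-12 || object@A > 1 + 1e-12)
    msgs <- c(msgs, "A must lie in [0, 1]")
  if (object@P01 < 0 || object@P01 > 1)
    msgs <- c(msgs, "P01 must lie in [0, 1]")
  J <- object@joint
  if (!all(dim(J) == c(2L, 2L)))
    msgs <- c(msgs, "joint must be 2x2")
  else {
    if (J[1, 2] != 0)
      msgs <- c(msgs, "joint[1,2] must be exactly 0 (Z-channel structure)")
    if (any(J < -1e-12) || abs(sum(J) - 1) > 1e-10)
      msgs <- c(msgs, "joint must be a pmf")
    if (abs(J[1, 1] - object@P01) > 1e-10)
      msgs <- c(msgs, "first row must sum to P01")
  }
  if (length(msgs)) msgs else TRUE
})

#' A retroactivity constant with its validity regime
#'
#' The probability \eqn{A = P(Z_1(t_s) = 0 \mid I_1(t_0) = 1)} for a given
#' circuit model, either from a closed form (valid asymptotically in the
#' fast-binding regime where binding/unbinding rates dominate the catalytic
#' rates) or extracted numerically from the exact stationary solver.
#'
#' @slot value the constant, in [0, 1].
#' @slot model short tag of the circuit/constant family (e.g. "A0", "AN",
#'   "B", "G", "A0_MIMO", "AN_MIMO", "AQ_MAC").
#' @slot regime "generic" for exact/numeric values, "fast_binding_asymptotic"
#'   for closed forms that hold in the fast-binding limit.
#' @slot inputs named list of the parameter values used.
#'
#' @export
setClass("AConstant",
  representation(value = "numeric", model = "character",
                 regime = "character", inputs = "list"),
  prototype(regime = "generic", inputs = list()))

setValidity("AConstant", function(object) {
  if (length(object@value) != 1L || !is.finite(object@value))
    return("value must be a finite scalar")
  if (object@value < -1e-12 || object@value > 1 + 1e-12)
    return("value must lie in [0, 1]")
  TRUE
})

#' Linear noise approximation steady state
#'
#' Deterministic steady-state means (concentrations, counts per volume) and
#' the stationary covariance of the Gaussian fluctuations around them,
#' obtained from the Lyapunov equation of the linearized dynamics.
#'
#' @slot means named numeric vector of steady-state concentrations.
#' @slot covariance symmetric covariance matrix over the tracked species
#'   (may be 0x0 when only means were requested).
#' @slot omega reaction volume.
#' @slot residual named numeric vector of solver residuals (rate-equation
#'   residual, Lyapunov residual).
#'
#' @export
setClass("LNASteadyState",
  representation(means = "numeric", covariance = "matrix",
                 omega = "numeric", residual = "numeric"),
  prototype(covariance = matrix(numeric(0), 0, 0), residual = numeric(0)))

setValidity("LNASteadyState", function(object) {
  msgs <- character(0)
  if (object@omega <= 0) msgs <- c(msgs, "omega must be > 0")
  S <- object@covariance
  if (length(S) && max(abs(S - t(S))) > 1e-8)
    msgs <- c(msgs, "covariance must be symmetric")
  if (length(msgs)) msgs else TRUE
})

#' Time-averaged occupancy of a stochastic simulation
#'
#' Empirical occupancy pmf over microstates estimated from one Gillespie
#' trajectory after a burn-in window, together with batch-means summaries for
#' Monte-Carlo error estimation.
#'
#' @slot states integer matrix of visited microstates (rows).
#' @slot probs time-weighted occupancy probabilities (sum to 1).
#' @slot batchProbs matrix of per-batch occupancy pmfs (batches in rows),
#'   used for batch-means standard errors.
#' @slot totalTime total simulated time.
#' @slot burnIn burn-in time discarded before averaging.
#' @slot seed RNG seed of the trajectory.
#'
#' @export
setClass("TrajectorySummary",
  representation(states = "matrix", probs = "numeric", batchProbs = "matrix",
                 totalTime = "numeric", burnIn = "numeric", seed = "integer"))

setValidity("TrajectorySummary", function(object) {
  msgs <- character(0)
  if (abs(sum(object@probs) - 1) > 1e-8)
    msgs <- c(msgs, "occupancy pmf must sum to 1")
  if (object@burnIn >= object@totalTime)
    msgs <- c(msgs, "burn-in must be shorter than the total simulated time")
  if (length(msgs)) msgs else TRUE
})
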