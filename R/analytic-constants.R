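#' @include AllClasses.R cme.R
NULL

.aConstant <- function(value, model, regime, inputs) {
  methods::new("AConstant", value = min(max(value, 0), 1), model = model,
               regime = regime, inputs = inputs)
}

.checkPriors2 <- function(P02, P12) {
  if (P02 < 0 || P12 < 0 || abs(P02 + P12 - 1) > 1e-9)
    stop("P02 and P12 must be non-negative and sum to 1")
}

#' Retroactivity constant of the isolated SISO circuit
#'
#' Closed form \deqn{A_0 = \frac{(1 + k_0)\,c_2}{c_1 + (1 + k_0)\,c_2},}
#' the steady-state probability that no free output molecule is present
#' given input symbol 1, in the fast-binding regime where the
#' binding/unbinding rates dominate the catalytic rates. The recycling
#' reaction is what keeps \eqn{A_0 > 0}: at \eqn{c_2 = 0} the input is fully
#' converted and \eqn{A_0 = 0}; as \eqn{c_2 \to \infty} the output is
#' recycled instantly and \eqn{A_0 \to 1}.
#'
#' @param k0 volume-scaled dissociation constant \code{k0Minus*omega/k0Plus}.
#' @param c1 catalytic (production) rate.
#' @param c2 recycling rate.
#' @return an [AConstant-class] (tag "A0").
#' @examples
#' aValue(a0Const(k0 = 1, c1 = 1, c2 = 1))  # 2/3
#' @export
a0Const <- function(k0, c1, c2) {
  stopifnot(k0 >= 0, c1 >= 0, c2 >= 0)
  if (c1 == 0 && c2 == 0)
    stop("A0 is undefined when both catalytic rates are zero")
  .aConstant((1 + k0) * c2 / (c1 + (1 + k0) * c2), "A0",
             "fast_binding_asymptotic", list(k0 = k0, c1 = c1, c2 = c2))
}

#' Retroactivity constant of the SISO circuit with N downstream sites
#'
#' Closed form \deqn{A_N = 1 - \frac{c_1}{(1 + k_0) c_2 +
#' \left(1 + \sum_j 1/k_{3j}\right) c_1}.} The downstream load enters only
#' through \eqn{\sum_j 1/k_{3j}}: removing it (\code{k3} empty) recovers
#' \eqn{A_0}, and \eqn{A_N \to 1} as the number of identical sites grows,
#' which drives the mutual information to zero.
#'
#' @inheritParams a0Const
#' @param k3 numeric vector of volume-scaled downstream dissociation
#'   constants, one per site (all > 0; empty for no load).
#' @return an [AConstant-class] (tag "AN").
#' @examples
#' aValue(aNConst(1, 1, 1, k3 = 1))  # 3/4
#' aValue(aNConst(1, 1, 1, k3 = numeric(0)))  # equals a0Const(1, 1, 1)
#' @export
aNConst <- function(k0, c1, c2, k3 = numeric(0)) {
  stopifnot(k0 >= 0, c1 >= 0, c2 >= 0)
  if (length(k3) && any(k3 <= 0))
    stop("k3 must be strictly positive (k3 = 0 is an infinite-affinity site)")
  if (c1 == 0 && c2 == 0)
    stop("AN is undefined when both catalytic rates are zero")
  S <- sum(1 / k3)
  .aConstant(1 - c1 / ((1 + k0) * c2 + (1 + S) * c1), "AN",
             "fast_binding_asymptotic",
             list(k0 = k0, c1 = c1, c2 = c2, k3 = k3))
}

#' Non-cyclic (c2 = 0) variant of the loaded SISO constant
#'
#' With the recycling reaction removed the upstream cycle opens and
#' \eqn{A_N = \sum_j (1/k_{3j}) / (1 + \sum_j 1/k_{3j})}: the load alone
#' keeps output molecules sequestered. No downstream sites gives 0.
#'
#' @param c1 catalytic rate (> 0).
#' @param k3 downstream dissociation constants (> 0).
#' @return an [AConstant-class] (tag "AN_noncyclic").
#' @export
aNConstNoncyclic <- function(c1, k3 = numeric(0)) {
  stopifnot(c1 > 0)
  if (length(k3) && any(k3 <= 0)) stop("k3 must be strictly positive")
  S <- sum(1 / k3)
  .aConstant(1 - c1 / ((1 + S) * c1), "AN_noncyclic",
             "fast_binding_asymptotic", list(c1 = c1, k3 = k3))
}

#' Mixture component B of the isolated MIMO constant
#'
#' Closed form for the conditional \eqn{P(Z_1 = 0 \mid i_1 = 1, i_2 = 1)} in
#' the isolated MIMO circuit, derived under equal catalytic rates
#' \code{c1 = c2 = c} and fast binding (\code{k0Plus, k0Minus >> c}):
#' \deqn{B = \frac{3\kappa_+^2 + \kappa_-^2 + 4\kappa_-\kappa_+ +
#' 3\kappa_- c + 6\kappa_+ c}{5\kappa_+^2 + \kappa_-^2 + 5\kappa_-\kappa_+ +
#' 3\kappa_- c + 8\kappa_+ c},} with \eqn{\kappa_+ = k_0^+/\Omega},
#' \eqn{\kappa_- = k_0^-}. A warning (not an error) is emitted outside the
#' fast-binding regime.
#'
#' @param k0Plus,k0Minus association/dissociation rates.
#' @param c common catalytic rate (c1 = c2 = c).
#' @param omega reaction volume.
#' @param regimeFactor fast-binding threshold: warn unless
#'   \code{min(k0Plus/omega, k0Minus) >= regimeFactor * c}.
#' @return an [AConstant-class] (tag "B").
#' @export
bConst <- function(k0Plus, k0Minus, c, omega = 1, regimeFactor = 100) {
  stopifnot(k0Plus > 0, k0Minus >= 0, c >= 0, omega > 0)
  kp <- k0Plus / omega
  km <- k0Minus
  if (c > 0 && min(kp, km) < regimeFactor * c)
    warning(sprintf(
      "fast-binding regime violated: min(k0+/omega, k0-)/c = %.3g < %g",
      min(kp, km) / c, regimeFactor))
  num <- 3 * kp^2 + km^2 + 4 * km * kp + 3 * km * c + 6 * kp * c
  den <- 5 * kp^2 + km^2 + 5 * km * kp + 3 * km * c + 8 * kp * c
  .aConstant(num / den, "B", "fast_binding_asymptotic",
             list(k0Plus = k0Plus, k0Minus = k0Minus, c = c, omega = omega))
}

#' Isolated-MIMO retroactivity constant
#'
#' Mixture \eqn{A_{0,MIMO} = A_0 P_{02} + B P_{12}} over the second input's
#' symbol priors. With \eqn{P_{12} = 0} the second branch is silent and the
#' isolated SISO constant is recovered; since \eqn{B \ge A_0}, the mixture
#' never improves on the isolated circuit.
#'
#' @param a0 an [AConstant-class] or numeric value of A0.
#' @param B an [AConstant-class] or numeric value of B.
#' @param P02,P12 priors of the second input's symbols (sum to 1).
#' @return an [AConstant-class] (tag "A0_MIMO").
#' @export
a0MimoConst <- function(a0, B, P02 = 0.5, P12 = 0.5) {
  .checkPriors2(P02, P12)
  a0v <- if (methods::is(a0, "AConstant")) a0@value else a0
  Bv <- if (methods::is(B, "AConstant")) B@value else B
  .aConstant(a0v * P02 + Bv * P12, "A0_MIMO", "fast_binding_asymptotic",
             list(A0 = a0v, B = Bv, P02 = P02, P12 = P12))
}

#' Mixture component G of the loaded MIMO constant (numeric)
#'
#' The conditional \eqn{G = P(Z_1 = 0 \mid i_1 = 1, i_2 = 1)} of the MIMO
#' circuit with N downstream sites has no tractable closed form (it depends
#' on the downstream binding rates as well as the upstream ones), so it is
#' extracted from the exact stationary CME solution. Values are cached per
#' parameter set within a session.
#'
#' @param rates a [RateParameters-class] carrying the downstream rates.
#' @param nDownstream number of downstream sites N.
#' @return an [AConstant-class] (tag "G", regime "generic").
#' @export
gConstNumeric <- local({
  cache <- new.env(parent = emptyenv())
  function(rates, nDownstream) {
    stopifnot(methods::is(rates, "RateParameters"))
    key <- paste(format(c(rates@k0Plus, rates@k0Minus, rates@c1, rates@c2,
                          rates@k3Plus, rates@k3Minus, rates@omega,
                          nDownstream), digits = 17), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    topo <- if (nDownstream > 0L) "MIMO_N_DOWNSTREAM" else "ISOLATED_MIMO"
    model <- buildModel(topo, rates, nDownstream = nDownstream)
    G <- .probZ1Zero(cmeStationary(model, 1L, 1L))
    out <- .aConstant(G, "G", "generic",
                      list(rates = rates, nDownstream = nDownstream))
    cache[[key]] <- out
    out
  }
})

#' Loaded-MIMO retroactivity constant
#'
#' Mixture \eqn{A_{N,MIMO} = A_N P_{02} + G P_{12}}. With \eqn{P_{12} = 0}
#' the loaded SISO constant is recovered. Whether the MIMO layout mitigates
#' retroactivity relative to the loaded SISO circuit reduces to the sign of
#' \eqn{G - A_N}: the mixture exceeds \eqn{A_N} iff \eqn{G \ge A_N}.
#'
#' @param aN an [AConstant-class] or numeric value of AN.
#' @param G an [AConstant-class] or numeric value of G.
#' @inheritParams a0MimoConst
#' @return an [AConstant-class] (tag "AN_MIMO").
#' @export
aNMimoConst <- function(aN, G, P02 = 0.5, P12 = 0.5) {
  .checkPriors2(P02, P12)
  aNv <- if (methods::is(aN, "AConstant")) aN@value else aN
  Gv <- if (methods::is(G, "AConstant")) G@value else G
  .aConstant(aNv * P02 + Gv * P12, "AN_MIMO", "mixed",
             list(AN = aNv, G = Gv, P02 = P02, P12 = P12))
}

#' Multiple-access retroactivity constant
#'
#' Two independent SISO circuits sharing N downstream sites: the first
#' output reaches only \code{Q <= N} of them, so its constant is the loaded
#' SISO form truncated to the first Q load terms,
#' \deqn{A_{Q,MAC} = 1 - \frac{c_1}{(1 + k_0) c_2 +
#' \left(1 + \sum_{j \le Q} 1/k_{3j}\right) c_1}.}
#' Q = 0 recovers the isolated constant, Q = N the fully loaded one; the
#' shared pool therefore always improves on the broadcast layout.
#'
#' @inheritParams aNConst
#' @param Q number of sites claimed by the first output (0..length(k3)).
#' @return an [AConstant-class] (tag "AQ_MAC").
#' @examples
#' aValue(aQMacConst(1, 1, 1, k3 = c(1, 1), Q = 1))  # 3/4
#' @export
aQMacConst <- function(k0, c1, c2, k3, Q) {
  if (Q < 0 || Q > length(k3)) stop("Q must satisfy 0 <= Q <= N")
  out <- aNConst(k0, c1, c2, k3 = k3[seq_len(Q)])
  out@model <- "AQ_MAC"
  out@inputs$Q <- Q
  out
}

#' Tabulate retroactivity constants over parameter draws
#'
#' @param draws list of [RateParameters-class] objects (e.g. from
#'   [sampleRates()]).
#' @param nDownstream number of downstream sites for the loaded constants.
#' @param P02,P12 second-input priors for the MIMO mixtures.
#' @param withG also extract the CME-based G (slower).
#' @param file optional CSV path.
#' @return data.frame of constants, one row per draw.
#' @export
aConstantTable <- function(draws, nDownstream = 1L, P02 = 0.5, P12 = 0.5,
                           withG = FALSE, file = NULL) {
  rows <- lapply(draws, function(r) {
    dc <- dissociationConstants(r)
    k3 <- dc$k3[seq_len(min(nDownstream, length(dc$k3)))]
    a0 <- aValue(a0Const(dc$k0, r@c1, r@c2))
    aN <- aValue(aNConst(dc$k0, r@c1, r@c2, k3))
    B <- aValue(suppressWarnings(
      bConst(r@k0Plus, r@k0Minus, (r@c1 + r@c2) / 2, r@omega)))
    out <- data.frame(k0 = dc$k0, c1 = r@c1, c2 = r@c2,
                      A0 = a0, AN = aN, B = B,
                      A0_MIMO = a0 * P02 + B * P12)
    if (withG) {
      G <- aValue(gConstNumeric(r, nDownstream))
      out$G <- G
      out$AN_MIMO <- aN * P02 + G * P12
    }
    out
  })
  df <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
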