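#' @include AllClasses.R
NULL

#' Construct a rate-parameter set
#'
#' @param k0Plus,k0Minus association/dissociation rates of the input/enzyme
#'   binding step.
#' @param c1 catalytic rate of the production step.
#' @param c2 recycling rate closing the enzymatic cycle (0 gives a
#'   non-cyclic upstream system).
#' @param k3Plus,k3Minus per-site downstream association/dissociation rates
#'   (recycled to a common length; empty for isolated topologies).
#' @param omega reaction volume; bimolecular propensities scale as
#'   \code{1/omega}.
#' @return a [RateParameters-class] object.
#' @examples
#' rateParameters(k0Plus = 1, k0Minus = 1, c1 = 1, c2 = 1)
#' @export
rateParameters <- function(k0Plus = 1, k0Minus = 1, c1 = 1, c2 = 1,
                           k3Plus = numeric(0), k3Minus = numeric(0),
                           omega = 1) {
  n <- max(length(k3Plus), length(k3Minus))
  if (n > 0) {
    k3Plus <- rep_len(as.numeric(k3Plus), n)
    k3Minus <- rep_len(as.numeric(k3Minus), n)
  }
  methods::new("RateParameters", k0Plus = as.numeric(k0Plus),
               k0Minus = as.numeric(k0Minus), c1 = as.numeric(c1),
               c2 = as.numeric(c2), k3Plus = as.numeric(k3Plus),
               k3Minus = as.numeric(k3Minus), omega = as.numeric(omega))
}

#' Volume-scaled dissociation constants
#'
#' \code{k0 = k0Minus * omega / k0Plus} and, per downstream site,
#' \code{k3_j = k3Minus_j * omega / k3Plus_j}.
#'
#' @param rates a [RateParameters-class] object.
#' @return list with elements \code{k0} and \code{k3} (numeric vector).
#' @export
dissociationConstants <- function(rates) {
  stopifnot(methods::is(rates, "RateParameters"))
  list(k0 = rates@k0Minus * rates@omega / rates@k0Plus,
       k3 = if (length(rates@k3Plus)) rates@k3Minus * rates@omega / rates@k3Plus
            else numeric(0))
}

## one mass-action reaction; stoichiometries are named integer vectors
.reaction <- function(reactants, products, rate, rateName) {
  list(reactants = reactants, products = products,
       rate = as.numeric(rate), rateName = rateName,
       bimolecular = sum(reactants) >= 2L)
}

## the four reactions of one two-step enzymatic cycle
.upstreamBranch <- function(input, enzyme, complex, output, rates) {
  list(
    .reaction(c(1L, 1L) |> stats::setNames(c(input, enzyme)),
              stats::setNames(1L, complex), rates@k0Plus, "k0Plus"),
    .reaction(stats::setNames(1L, complex),
              c(1L, 1L) |> stats::setNames(c(input, enzyme)),
              rates@k0Minus, "k0Minus"),
    .reaction(stats::setNames(1L, complex),
              c(1L, 1L) |> stats::setNames(c(enzyme, output)),
              rates@c1, "c1"),
    .reaction(stats::setNames(1L, output), stats::setNames(1L, input),
              rates@c2, "c2"))
}

## reversible binding of an output to downstream site j
.downstreamPair <- function(output, site, complex, j, rates) {
  list(
    .reaction(c(1L, 1L) |> stats::setNames(c(output, site)),
              stats::setNames(1L, complex),
              rates@k3Plus[j], sprintf("k3Plus[%d]", j)),
    .reaction(stats::setNames(1L, complex),
              c(1L, 1L) |> stats::setNames(c(output, site)),
              rates@k3Minus[j], sprintf("k3Minus[%d]", j)))
}

#' Build one of the five signaling circuit models
#'
#' Instantiates the mass-action reaction network of the requested topology.
#' The upstream system is the two-step enzymatic cycle
#' \eqn{I_1 + E \rightleftharpoons M_1 \to E + Z_1 \to I_1}; each downstream
#' site is the reversible binding \eqn{Z_1 + D_j \rightleftharpoons C_j}.
#' Two-input topologies add a second branch, by default a replica of the
#' first (same rate constants), sharing the enzyme (MIMO) or with its own
#' enzyme (multiple-access). In the multiple-access topology the first
#' upstream output can reach sites \code{1..Q} and the second output the
#' complementary sites \code{Q+1..N}; each site obeys the shared
#' conservation law \eqn{Dtot_j = D_j + C_{j1} + C_{j2}}.
#'
#' @param topology one of [TOPOLOGIES].
#' @param rates a [RateParameters-class]; must carry at least
#'   \code{nDownstream} downstream rate pairs for loaded topologies.
#' @param nDownstream number of downstream sites N (must be 0 for isolated
#'   topologies).
#' @param qConnected number of sites reachable by the first output
#'   (multiple-access only; defaults to N otherwise and to
#'   \code{floor(N/2)} for the multiple-access topology, the average split
#'   when both outputs are emitted at the same rate).
#' @param totals named numeric vector overriding the default conserved
#'   totals (defaults: Etot = Etot2 = Itot1 = Itot2 = 1, Dtot_j = 1).
#' @param rates2 optional [RateParameters-class] for the second upstream
#'   branch; defaults to a replica of \code{rates}.
#' @return a [ModelSpec-class] object.
#' @examples
#' m <- buildModel("ISOLATED_SISO", rateParameters())
#' length(reactions(m))  # 4: bind, unbind, catalyze, recycle
#' @export
buildModel <- function(topology, rates = rateParameters(), nDownstream = 0L,
                       qConnected = NULL, totals = NULL, rates2 = NULL) {
  topology <- match.arg(topology, TOPOLOGIES)
  stopifnot(methods::is(rates, "RateParameters"))
  N <- as.integer(nDownstream)
  if (N < 0L) stop("nDownstream must be >= 0")
  isolated <- topology %in% c("ISOLATED_SISO", "ISOLATED_MIMO")
  if (isolated && N != 0L)
    stop("isolated topologies must have nDownstream = 0")
  if (is.null(qConnected))
    qConnected <- if (topology == "TWO_SISO_MAC") N %/% 2L else N
  Q <- as.integer(qConnected)
  if (Q < 0L || Q > N) stop("qConnected must satisfy 0 <= Q <= N")
  if (topology != "TWO_SISO_MAC" && Q != N)
    stop("qConnected is a free parameter only for TWO_SISO_MAC")
  if (N > 0L && length(rates@k3Plus) < N)
    stop("rates must provide k3Plus/k3Minus for each of the ", N,
         " downstream sites")
  if (is.null(rates2)) rates2 <- rates else
    stopifnot(methods::is(rates2, "RateParameters"))

  Dn <- if (N > 0L) paste0("D", seq_len(N)) else character(0)
  tot <- c(Etot = 1, Itot1 = 1)
  rx <- list()

  if (topology %in% c("ISOLATED_SISO", "SISO_N_DOWNSTREAM")) {
    species <- c("I1", "E", "M1", "Z1", Dn,
                 if (N > 0L) paste0("C", seq_len(N)) else character(0))
    rx <- .upstreamBranch("I1", "E", "M1", "Z1", rates)
    for (j in seq_len(N))
      rx <- c(rx, .downstreamPair("Z1", paste0("D", j), paste0("C", j), j, rates))
  } else if (topology %in% c("ISOLATED_MIMO", "MIMO_N_DOWNSTREAM")) {
    species <- c("I1", "I2", "E", "M1", "M2", "Z1", "Z2", Dn,
                 if (N > 0L) paste0("C", seq_len(N)) else character(0))
    rx <- c(.upstreamBranch("I1", "E", "M1", "Z1", rates),
            .upstreamBranch("I2", "E", "M2", "Z2", rates2))
    for (j in seq_len(N))
      rx <- c(rx, .downstreamPair("Z1", paste0("D", j), paste0("C", j), j, rates))
    tot <- c(tot, Itot2 = 1)
  } else { # TWO_SISO_MAC
    species <- c("I1", "E", "M1", "Z1", "I2", "E2", "M2", "Z2", Dn,
                 if (N > 0L) c(paste0("C", seq_len(N), "_1"),
                               paste0("C", seq_len(N), "_2")) else character(0))
    rx <- c(.upstreamBranch("I1", "E", "M1", "Z1", rates),
            .upstreamBranch("I2", "E2", "M2", "Z2", rates2))
    for (j in seq_len(N)) {
      if (j <= Q)
        rx <- c(rx, .downstreamPair("Z1", paste0("D", j),
                                    paste0("C", j, "_1"), j, rates))
      else
        rx <- c(rx, .downstreamPair("Z2", paste0("D", j),
                                    paste0("C", j, "_2"), j, rates2))
    }
    tot <- c(Etot = 1, Etot2 = 1, Itot1 = 1, Itot2 = 1)
  }
  if (N > 0L) tot <- c(tot, stats::setNames(rep(1, N), paste0("Dtot", seq_len(N))))
  if (!is.null(totals)) {
    unknown <- setdiff(names(totals), names(tot))
    if (length(unknown)) stop("unknown totals: ", paste(unknown, collapse = ", "))
    tot[names(totals)] <- totals
  }
  if (any(tot < 0)) stop("totals must be non-negative")

  methods::new("ModelSpec", topology = topology, nDownstream = N,
               qConnected = Q, totals = tot, rates = rates,
               species = species, reactions = rx)
}

#' Conservation laws of a circuit model
#'
#' Linear integer invariants of the reaction network: each returned
#' coefficient vector \code{v} (over \code{speciesNames(model)}) satisfies
#' \code{sum(v * delta) == 0} for the net stoichiometry \code{delta} of every
#' reaction. The totals they equal are fixed by the model's \code{totals}
#' (for enzymes and sites) and by the input symbols (for Itot1/Itot2).
#'
#' @param model a [ModelSpec-class].
#' @return named list of integer coefficient vectors, one per law
#'   ("Etot", "Itot1", ..., "Dtot1", ...).
#' @examples
#' laws <- conservationLaws(buildModel("ISOLATED_SISO", rateParameters()))
#' names(laws)  # "Etot", "Itot1"
#' @export
conservationLaws <- function(model) {
  stopifnot(methods::is(model, "ModelSpec"))
  sp <- model@species
  N <- model@nDownstream
  law <- function(members) {
    v <- stats::setNames(integer(length(sp)), sp)
    v[members] <- 1L
    v
  }
  Cs <- function(suffix = "") if (N > 0L) paste0("C", seq_len(N), suffix) else character(0)
  laws <- switch(model@topology,
    ISOLATED_SISO = list(Etot = law(c("E", "M1")),
                         Itot1 = law(c("I1", "M1", "Z1"))),
    SISO_N_DOWNSTREAM = list(Etot = law(c("E", "M1")),
                             Itot1 = law(c("I1", "M1", "Z1", Cs()))),
    ISOLATED_MIMO = list(Etot = law(c("E", "M1", "M2")),
                         Itot1 = law(c("I1", "M1", "Z1")),
                         Itot2 = law(c("I2", "M2", "Z2"))),
    MIMO_N_DOWNSTREAM = list(Etot = law(c("E", "M1", "M2")),
                             Itot1 = law(c("I1", "M1", "Z1", Cs())),
                             Itot2 = law(c("I2", "M2", "Z2"))),
    TWO_SISO_MAC = list(
      Etot = law(c("E", "M1")),
      Etot2 = law(c("E2", "M2")),
      Itot1 = law(c("I1", "M1", "Z1", Cs("_1"))),
      Itot2 = law(c("I2", "M2", "Z2", Cs("_2")))))
  for (j in seq_len(N)) {
    members <- if (model@topology == "TWO_SISO_MAC")
      c(paste0("D", j), paste0("C", j, "_1"), paste0("C", j, "_2"))
    else c(paste0("D", j), paste0("C", j))
    laws[[paste0("Dtot", j)]] <- law(members)
  }
  laws
}

#' Net stoichiometry vector of one reaction
#' @param reaction one element of \code{reactions(model)}.
#' @param species species ordering to expand into.
#' @return named integer vector (products minus reactants).
#' @export
reactionDelta <- function(reaction, species) {
  v <- stats::setNames(integer(length(species)), species)
  v[names(reaction$reactants)] <- v[names(reaction$reactants)] -
    as.integer(reaction$reactants)
  v[names(reaction$products)] <- v[names(reaction$products)] +
    as.integer(reaction$products)
  v
}

#' Mass-action propensity of one reaction at a state
#'
#' Counts convention: a unimolecular reaction fires at \code{rate * x},
#' a bimolecular one at \code{rate * x_a * x_b / omega} (or
#' \code{rate * x * (x - 1) / omega} for a homodimerization).
#'
#' @param reaction one element of \code{reactions(model)}.
#' @param state named integer vector of molecule counts.
#' @param omega reaction volume.
#' @return non-negative propensity.
#' @export
reactionPropensity <- function(reaction, state, omega = 1) {
  a <- reaction$rate
  for (sp in names(reaction$reactants)) {
    k <- reaction$reactants[[sp]]
    x <- state[[sp]]
    a <- a * prod(pmax(x - seq_len(k) + 1, 0))
  }
  order <- sum(reaction$reactants)
  if (order > 1L) a <- a / omega^(order - 1L)
  a
}

#' Human-readable reaction table
#'
#' @param model a [ModelSpec-class].
#' @param file optional path; when given, the table is written as TSV.
#' @return data.frame with columns reaction, rateName, rate, bimolecular.
#' @export
reactionTable <- function(model, file = NULL) {
  stopifnot(methods::is(model, "ModelSpec"))
  side <- function(s) {
    if (!length(s)) return("0")
    paste(ifelse(s > 1L, paste0(s, " "), ""), names(s),
          sep = "", collapse = " + ")
  }
  df <- data.frame(
    reaction = vapply(model@reactions, function(r)
      paste(side(r$reactants), "->", side(r$products)), character(1)),
    rateName = vapply(model@reactions, `[[`, character(1), "rateName"),
    rate = vapply(model@reactions, `[[`, numeric(1), "rate"),
    bimolecular = vapply(model@reactions, `[[`, logical(1), "bimolecular"),
    stringsAsFactors = FALSE)
  if (!is.null(file))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

#' Randomized site allocation for the multiple-access topology
#'
#' Draws the number of sites Q claimed by the first upstream output from a
#' symmetric binomial over N, the ensemble whose mean is the average split
#' Q = N/2 when both outputs are emitted at the same rate.
#'
#' @param nDownstream total number of sites N.
#' @param nDraws how many allocations to draw.
#' @param seed RNG seed.
#' @return integer vector of Q values in \code{0..N}.
#' @export
macAllocateQ <- function(nDownstream, nDraws = 1L, seed = 1L) {
  stopifnot(nDownstream >= 0)
  set.seed(as.integer(seed))
  stats::rbinom(nDraws, size = as.integer(nDownstream), prob = 0.5)
}

#' Serialize / deserialize a model to a plain-text config
#'
#' Round-trippable key-value representation (JSON) of a [ModelSpec-class]:
#' topology, counts, totals and rates.
#'
#' @param model a [ModelSpec-class].
#' @param file path to write to / read from.
#' @return \code{writeModelConfig} returns \code{file} invisibly;
#'   \code{readModelConfig} returns the rebuilt [ModelSpec-class].
#' @export
writeModelConfig <- function(model, file) {
  stopifnot(methods::is(model, "ModelSpec"))
  r <- model@rates
  cfg <- list(topology = model@topology, nDownstream = model@nDownstream,
              qConnected = model@qConnected, totals = as.list(model@totals),
              rates = list(k0Plus = r@k0Plus, k0Minus = r@k0Minus,
                           c1 = r@c1, c2 = r@c2, k3Plus = r@k3Plus,
                           k3Minus = r@k3Minus, omega = r@omega))
  jsonlite::write_json(cfg, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname writeModelConfig
#' @export
readModelConfig <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  rates <- rateParameters(k0Plus = cfg$rates$k0Plus, k0Minus = cfg$rates$k0Minus,
                          c1 = cfg$rates$c1, c2 = cfg$rates$c2,
                          k3Plus = cfg$rates$k3Plus %||% numeric(0),
                          k3Minus = cfg$rates$k3Minus %||% numeric(0),
                          omega = cfg$rates$omega)
  buildModel(cfg$topology, rates, nDownstream = cfg$nDownstream,
             qConnected = cfg$qConnected, totals = unlist(cfg$totals))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
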