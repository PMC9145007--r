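#' @include AllClasses.R cme.R analytic-constants.R lna.R
NULL

#' Experiment configuration
#'
#' A fully serializable record of everything an experiment run depends on,
#' so re-running with the same configuration reproduces all outputs (the
#' stochastic stages are keyed by the seed).
#'
#' @param rates a [RateParameters-class] used for the deterministic sweeps.
#' @param nMax largest number of downstream sites in load sweeps.
#' @param P01,P02 input symbol priors.
#' @param seed RNG seed for the stochastic stages.
#' @param units "nats" or "bits" for information quantities.
#' @param gridPoints grid resolution for capacity/bound studies.
#' @param omegaGrid volumes for the high-count suite.
#' @param nDraws number of parameter draws for ensemble studies.
#' @return a list of class "experimentConfig".
#' @export
experimentConfig <- function(rates = rateParameters(1, 1, 1, 1,
                                                    k3Plus = rep(1, 10),
                                                    k3Minus = rep(1, 10)),
                             nMax = 5L, P01 = 0.5, P02 = 0.5, seed = 1L,
                             units = "nats", gridPoints = 101L,
                             omegaGrid = c(1, 10, 100), nDraws = 20L) {
  structure(list(rates = rates, nMax = as.integer(nMax), P01 = P01,
                 P02 = P02, seed = as.integer(seed), units = units,
                 gridPoints = as.integer(gridPoints), omegaGrid = omegaGrid,
                 nDraws = as.integer(nDraws)),
            class = "experimentConfig")
}

.writeManifest <- function(config, outDir, name) {
  if (is.null(outDir)) return(invisible(NULL))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  r <- config$rates
  manifest <- list(
    experiment = name,
    package = "retromi",
    version = as.character(utils::packageVersion("retromi")),
    seed = config$seed, units = config$units,
    rates = list(k0Plus = r@k0Plus, k0Minus = r@k0Minus, c1 = r@c1,
                 c2 = r@c2, k3Plus = r@k3Plus, k3Minus = r@k3Minus,
                 omega = r@omega),
    nMax = config$nMax, P01 = config$P01, P02 = config$P02,
    gridPoints = config$gridPoints, omegaGrid = config$omegaGrid,
    nDraws = config$nDraws)
  jsonlite::write_json(manifest, file.path(outDir, paste0(name, "-manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

.regimeTolerance <- function(rates) {
  ## empirical fast-binding ladder: the gap between the exact conditional
  ## and the closed forms decays like ~0.1 * c / min(k0+, k0-); allow 5x
  rho <- min(rates@k0Plus, rates@k0Minus) / max(rates@c1, rates@c2, 1e-300)
  min(1, 5 / rho)
}

#' Mutual information versus downstream load
#'
#' Sweeps the number of downstream sites N for the loaded SISO circuit and,
#' for the multiple-access layout, the number of sites Q claimed by the
#' first output at fixed N. Each row carries the closed-form constant, the
#' exact CME value, their gap against the regime tolerance, and the
#' resulting mutual information and capacity. The run fails loudly if the
#' cross-engine gap exceeds the tolerance.
#'
#' @param config an [experimentConfig()].
#' @param outDir optional directory for CSV + manifest output.
#' @return data.frame with columns model, N, Q, A_analytic, A_cme, MI,
#'   capacity.
#' @export
runMiVsLoad <- function(config = experimentConfig(), outDir = NULL) {
  r <- config$rates
  dc <- dissociationConstants(r)
  tol <- .regimeTolerance(r)
  rows <- list()
  for (N in 0:config$nMax) {
    model <- if (N == 0L) buildModel("ISOLATED_SISO", r)
             else buildModel("SISO_N_DOWNSTREAM", r, nDownstream = N)
    aAn <- aValue(aNConst(dc$k0, r@c1, r@c2, dc$k3[seq_len(N)]))
    aCme <- aValue(channelFromCME(model, P01 = config$P01))
    if (abs(aCme - aAn) > tol)
      stop(sprintf("cross-engine gap %.3g exceeds regime tolerance %.3g (N=%d)",
                   abs(aCme - aAn), tol, N))
    rows[[length(rows) + 1L]] <- data.frame(
      model = "SISO_N_DOWNSTREAM", N = N, Q = N, A_analytic = aAn,
      A_cme = aCme, MI = miZChannel(aCme, config$P01, units = config$units),
      capacity = zChannelCapacity(aCme, units = config$units))
  }
  N <- config$nMax
  for (Q in 0:N) {
    model <- buildModel("TWO_SISO_MAC", r, nDownstream = N, qConnected = Q)
    aAn <- aValue(aQMacConst(dc$k0, r@c1, r@c2, dc$k3[seq_len(N)], Q))
    aCme <- aValue(channelFromCME(model, P01 = config$P01,
                                  secondInputPriors = c(1 - config$P02, config$P02)))
    if (abs(aCme - aAn) > tol)
      stop(sprintf("cross-engine gap %.3g exceeds regime tolerance %.3g (Q=%d)",
                   abs(aCme - aAn), tol, Q))
    rows[[length(rows) + 1L]] <- data.frame(
      model = "TWO_SISO_MAC", N = N, Q = Q, A_analytic = aAn, A_cme = aCme,
      MI = miZChannel(aCme, config$P01, units = config$units),
      capacity = zChannelCapacity(aCme, units = config$units))
  }
  df <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    .writeManifest(config, outDir, "mi-vs-load")
    utils::write.csv(df, file.path(outDir, "mi-vs-load.csv"), row.names = FALSE)
  }
  df
}

#' Does a second upstream system mitigate retroactivity?
#'
#' For an ensemble of fast-binding parameter draws, compares the loaded-SISO
#' constant with the numerically extracted MIMO mixture component G. The
#' loaded MIMO mixture exceeds the loaded SISO constant exactly when
#' \eqn{G \ge A_N}, so each draw is classified by the sign of that gap and
#' annotated with the mutual information of both layouts.
#'
#' @param config an [experimentConfig()]; \code{nDraws} draws are taken in
#'   the fast-binding regime with \code{nDownstream = 1}.
#' @param outDir optional directory for CSV + manifest output.
#' @return data.frame with one row per draw: AN, G, mitigates (G < AN),
#'   MI_siso_loaded, MI_mimo_loaded.
#' @export
runMimoMitigation <- function(config = experimentConfig(), outDir = NULL) {
  draws <- sampleRates("fast_binding", nDraws = config$nDraws,
                       seed = config$seed, nDownstream = 1L)
  P12 <- 1 - config$P02
  rows <- lapply(draws, function(r) {
    dc <- dissociationConstants(r)
    aN <- aValue(aNConst(dc$k0, r@c1, r@c2, dc$k3))
    G <- aValue(gConstNumeric(r, 1L))
    aNM <- aValue(aNMimoConst(aN, G, config$P02, P12))
    data.frame(k0 = dc$k0, c1 = r@c1, c2 = r@c2, k3 = dc$k3[1],
               AN = aN, G = G, AN_MIMO = aNM, mitigates = G < aN,
               MI_siso_loaded = miZChannel(aN, config$P01, units = config$units),
               MI_mimo_loaded = miZChannel(aNM, config$P01, units = config$units))
  })
  df <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    .writeManifest(config, outDir, "mimo-mitigation")
    utils::write.csv(df, file.path(outDir, "mimo-mitigation.csv"),
                     row.names = FALSE)
  }
  df
}

#' Capacity bounds over the (A, P01) plane
#'
#' The capacity-bound study: at each flip probability A, the mutual
#' information as a lower bound over the prior grid, the closed-form
#' Z-channel capacity, and the dual KL upper bound minimized over a grid of
#' output distributions. The three coincide (up to grid resolution) along
#' the capacity line, and the capacity is non-increasing in A.
#'
#' @param config an [experimentConfig()].
#' @param outDir optional directory for CSV + manifest output.
#' @param plot when TRUE and \code{outDir} is given, also renders the
#'   capacity curve to a PNG.
#' @return list with \code{surface} (from [boundSurface()]) and
#'   \code{curve} (from [capacityCurve()]).
#' @export
runCapacityBounds <- function(config = experimentConfig(), outDir = NULL,
                              plot = FALSE) {
  grid <- priorGrid(config$gridPoints)
  surface <- boundSurface(grid, grid, units = config$units)
  curve <- capacityCurve(grid, units = config$units)
  if (!is.null(outDir)) {
    .writeManifest(config, outDir, "capacity-bounds")
    utils::write.csv(surface, file.path(outDir, "bound-surface.csv"),
                     row.names = FALSE)
    utils::write.csv(curve, file.path(outDir, "capacity-curve.csv"),
                     row.names = FALSE)
    if (plot && capabilities("png")) {
      grDevices::png(file.path(outDir, "capacity-curve.png"), 640, 480)
      graphics::plot(curve$A, curve$capacity, type = "l",
                     xlab = "A", ylab = paste0("capacity (", config$units, ")"),
                     main = "Z-channel capacity vs flip probability")
      grDevices::dev.off()
    }
  }
  list(surface = surface, curve = curve)
}

#' High-count suite: means, variances and Gaussian capacities
#'
#' Tabulates, across volumes, the reduced isolated-SISO mean and variance
#' (closed forms, cross-checked against the generic Lyapunov solver), the
#' loaded-circuit mean (identical to the isolated one), the loaded output
#' variance from the two-dimensional Lyapunov solve, the resulting Gaussian
#' channel capacities, and the sign of the variance change under load (an
#' exploratory record, not an asserted fact).
#'
#' @param config an [experimentConfig()]; the LNA concentrations use
#'   \code{Itot1 = 10}, \code{E = 1}, \code{Dtot = 1} per site.
#' @param outDir optional directory for CSV + manifest output.
#' @param Itot1,E,Dtot concentration scales of the high-count regime.
#' @return data.frame with one row per (omega, N).
#' @export
runLnaSuite <- function(config = experimentConfig(), outDir = NULL,
                        Itot1 = 10, E = 1, Dtot = 1) {
  r <- config$rates
  dc <- dissociationConstants(r)
  k3 <- if (length(dc$k3)) dc$k3[1] else 1
  rows <- list()
  for (omega in config$omegaGrid) {
    for (N in c(0L, config$nMax)) {
      mu0 <- sisoReducedMean(r@c1, E, Itot1, r@c2)
      s20 <- sisoReducedVariance(r@c1, E, Itot1, r@c2, omega)
      muN <- sisoDownstreamMean(r@c1, E, Itot1, r@c2, k3, Dtot, N)$mean
      lna <- lnaSisoDownstream(r@c1, E, Itot1, r@c2, k3, Dtot, N,
                               omega = omega)
      s2N <- lnaCovariance(lna)["Z1", "Z1"]
      rows[[length(rows) + 1L]] <- data.frame(
        omega = omega, N = N, mu0 = mu0, muN = muN,
        sigma2_isolated = s20, sigma2_loaded = s2N,
        capacity_isolated = awgnCapacity(s20, units = config$units),
        capacity_loaded = awgnCapacity(s2N, units = config$units),
        load_reduces_variance = s2N < s20)
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    .writeManifest(config, outDir, "lna-suite")
    utils::write.csv(df, file.path(outDir, "lna-suite.csv"), row.names = FALSE)
  }
  df
}

#' Consistency battery across engines
#'
#' Runs the validation checks connecting the exact stationary solver, the
#' closed forms, the information metrics and the stochastic simulation on
#' the canonical fixtures; errors on the first violation.
#'
#' @param seed RNG seed for the simulation stage.
#' @param tEnd simulation horizon for the occupancy check.
#' @return TRUE invisibly on success.
#' @export
validateEngines <- function(seed = 1L, tEnd = 2000) {
  fx <- fixtureSuite()
  ## exact solver vs hand-solved chain
  sd <- cmeStationary(fx$siso_unit_rates$model, 1L)
  stopifnot(max(abs(sort(sd@probs, decreasing = TRUE) -
                    sort(fx$siso_unit_rates$expected$pi, decreasing = TRUE))) < 1e-10)
  ## channel A
  A <- aValue(channelFromCME(fx$siso_unit_rates$model))
  stopifnot(abs(A - fx$siso_unit_rates$expected$A) < 1e-10)
  ## capacity: closed form vs Blahut-Arimoto
  for (a in c(0.1, 0.5, 0.9)) {
    ba <- blahutArimoto(rbind(c(1, 0), c(a, 1 - a)))$capacity
    stopifnot(abs(ba - zChannelCapacity(a)) < 1e-8)
  }
  ## SSA occupancy vs stationary law
  path <- gillespie(fx$siso_unit_rates$model, tEnd = tEnd, seed = seed)
  err <- tvBatchError(occupancyPmf(path), sd)
  stopifnot(err$tv < 3 * err$se + 1e-3)
  invisible(TRUE)
}
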