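test_that("microstate enumeration matches exhaustive counting", {
  iso <- buildModel("ISOLATED_SISO", unitRates())
  S1 <- enumerateStates(iso, i1 = 1)
  expect_identical(nrow(S1), 3L)
  keys <- apply(S1, 1, function(s)
    paste(names(s)[s > 0], collapse = "+"))
  expect_setequal(keys, c("I1+E", "M1", "E+Z1"))

  # empty input class: only the free-enzyme state
  S0 <- enumerateStates(iso, i1 = 0)
  expect_identical(nrow(S0), 1L)
  expect_identical(S0[1, "E"], c(E = 1L))
  expect_true(all(S0[1, c("I1", "M1", "Z1")] == 0L))

  # both MIMO inputs on: 3 x 3 minus the state needing two enzymes
  mimo <- buildModel("ISOLATED_MIMO", unitRates())
  expect_identical(nrow(enumerateStates(mimo, 1, 1)), 8L)
  expect_identical(nrow(enumerateStates(mimo, 1, 0)), 3L)
})

test_that("enumerated states satisfy every conservation law", {
  for (topo in c("SISO_N_DOWNSTREAM", "MIMO_N_DOWNSTREAM", "TWO_SISO_MAC")) {
    m <- buildModel(topo, unitRates(2L), nDownstream = 2L)
    S <- enumerateStates(m, 1, 1)
    laws <- conservationLaws(m)
    tot <- modelTotals(m)
    tot["Itot1"] <- 1
    if ("Itot2" %in% names(tot)) tot["Itot2"] <- 1
    for (nm in names(laws))
      expect_true(all(S %*% laws[[nm]] == tot[[nm]]), label = paste(topo, nm))
  }
})

test_that("enumeration order is canonical and reproducible", {
  m <- buildModel("SISO_N_DOWNSTREAM", unitRates(2L), nDownstream = 2L)
  expect_identical(enumerateStates(m, 1), enumerateStates(m, 1))
  expect_error(enumerateStates(m, 1, maxStates = 2), "maxStates")
})

test_that("the generator has the hand-derived transition structure", {
  m <- buildModel("ISOLATED_SISO", unitRates())
  S <- enumerateStates(m, 1)
  Q <- buildGenerator(m, S)
  expect_equal(rowSums(Q), rep(0, 3))
  expect_true(all(Q - diag(diag(Q)) >= 0))
  # locate states by content
  i_IE <- which(S[, "I1"] == 1)
  i_M <- which(S[, "M1"] == 1)
  i_EZ <- which(S[, "Z1"] == 1)
  expect_equal(Q[i_IE, i_M], 1)  # binding at k0+
  expect_equal(Q[i_M, i_IE], 1)  # unbinding at k0-
  expect_equal(Q[i_M, i_EZ], 1)  # catalysis at c1
  expect_equal(Q[i_EZ, i_IE], 1) # recycling at c2
  # empty-input class: no reaction can fire
  S0 <- enumerateStates(m, 0)
  expect_equal(buildGenerator(m, S0), matrix(0, 1, 1))
})

test_that("stationary solver reproduces the hand-solved chain", {
  m <- buildModel("ISOLATED_SISO", unitRates())
  sd <- cmeStationary(m, 1)
  S <- microstates(sd)
  # balance equations: pi(M) = pi(IE) k0+/(k0- + c1), pi(EZ) = pi(M) c1/c2
  expect_equal(stationaryProbs(sd)[S[, "I1"] == 1], 1 / 2)
  expect_equal(stationaryProbs(sd)[S[, "M1"] == 1], 1 / 4)
  expect_equal(stationaryProbs(sd)[S[, "Z1"] == 1], 1 / 4)
  expect_lt(sd@residual, 1e-10)
})

test_that("stationary solves agree with the eigen-decomposition oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 5L
    Q <- matrix(rexp(n * n), n, n)
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
    pi1 <- stationaryProbs(stationaryDistribution(Q))
    pi2 <- eigenStationary(Q)
    expect_equal(pi1, pi2, tolerance = 1e-9)
    expect_lt(max(abs(pi1 %*% Q)), 1e-10)
  }
})

test_that("the chain restricted to the reachable closed class is handled", {
  # non-cyclic circuit: the output state absorbs, A = 0
  m0 <- buildModel("ISOLATED_SISO", rateParameters(1, 1, 1, 0))
  sd <- cmeStationary(m0, 1)
  expect_equal(aValue(channelFromCME(m0)), 0)
  expect_equal(sum(stationaryProbs(sd)[microstates(sd)[, "Z1"] == 1]), 1)
  # one-state class
  expect_equal(stationaryProbs(cmeStationary(m0, 0)), 1)
})

test_that("every topology yields an exact Z-channel", {
  for (topo in TOPOLOGIES) {
    N <- if (grepl("ISOLATED", topo)) 0L else 2L
    m <- buildModel(topo, unitRates(max(N, 1L)), nDownstream = N)
    ch <- channelFromCME(m, P01 = 0.4)
    J <- jointPmf(ch)
    expect_identical(J[1, 2], 0)          # input 0 cannot produce output
    expect_equal(sum(J), 1)
    expect_equal(rowSums(J), c(0.4, 0.6))
    expect_true(aValue(ch) >= 0 && aValue(ch) <= 1)
  }
})

test_that("channel A at unit rates is 3/4 and MI follows from the joint", {
  m <- buildModel("ISOLATED_SISO", unitRates())
  ch <- channelFromCME(m, P01 = 0.5)
  expect_equal(aValue(ch), 3 / 4)
  expect_equal(miFromCME(m), miZChannel(3 / 4, 0.5))
  expect_equal(miFromCME(m), bruteForceMI(jointPmf(ch)))
})

test_that("degenerate priors and huge recycling kill the information", {
  m <- buildModel("ISOLATED_SISO", unitRates())
  expect_equal(miFromCME(m, priors = c(1, 0)), 0)
  mBig <- buildModel("ISOLATED_SISO", rateParameters(1, 1, 1, 1e6))
  expect_lt(miFromCME(mBig), 1e-4)
})

test_that("A is non-decreasing and MI non-increasing in the load N", {
  aPrev <- -Inf
  miPrev <- Inf
  for (N in 0:3) {
    m <- if (N == 0) buildModel("ISOLATED_SISO", unitRates())
         else buildModel("SISO_N_DOWNSTREAM", unitRates(N), nDownstream = N)
    a <- aValue(channelFromCME(m))
    mi <- miFromCME(m)
    expect_gte(a, aPrev)
    expect_lte(mi, miPrev)
    aPrev <- a
    miPrev <- mi
  }
})

test_that("the shared-pool layout interpolates between isolated and loaded", {
  aIso <- aValue(channelFromCME(buildModel("ISOLATED_SISO", unitRates())))
  aLoad <- aValue(channelFromCME(
    buildModel("SISO_N_DOWNSTREAM", unitRates(2L), nDownstream = 2L)))
  aQ <- vapply(0:2, function(Q) aValue(channelFromCME(
    buildModel("TWO_SISO_MAC", unitRates(2L), nDownstream = 2L,
               qConnected = Q))), numeric(1))
  expect_equal(aQ[1], aIso)
  expect_equal(aQ[3], aLoad)
  expect_true(all(diff(aQ) >= 0))
  expect_true(aQ[2] >= aIso && aQ[2] <= aLoad)
})

test_that("stationary distributions export as tables", {
  sd <- cmeStationary(buildModel("ISOLATED_SISO", unitRates()), 1)
  df <- stationaryTable(sd)
  expect_named(df, c("I1", "E", "M1", "Z1", "probability"))
  expect_equal(sum(df$probability), 1)
})
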