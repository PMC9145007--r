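test_that("reduced SISO mean and variance match their closed forms", {
  expect_equal(sisoReducedMean(1, 1, 10, 1), 5)
  expect_equal(sisoReducedMean(1, 1, 10, 0), 10)   # no recycling: all converted
  expect_equal(sisoReducedMean(0, 1, 10, 1), 0)    # no production
  expect_equal(sisoReducedVariance(1, 1, 10, 1, omega = 1), 2.5)
  expect_equal(sisoReducedVariance(1, 1, 10, 0), 0)
  expect_error(sisoReducedMean(0, 0, 10, 0), "zero")
  # bounds: 0 <= mu <= Itot
  set.seed(3)
  for (rep in 1:25) {
    p <- stats::rexp(4)
    mu <- sisoReducedMean(p[1], p[2], p[3], p[4])
    expect_gte(mu, 0)
    expect_lte(mu, p[3])
  }
})

test_that("variance scales exactly as 1/omega", {
  base <- sisoReducedVariance(2, 1.5, 7, 0.5, omega = 1)
  for (omega in c(1, 10, 100))
    expect_equal(sisoReducedVariance(2, 1.5, 7, 0.5, omega), base / omega)
})

test_that("downstream complex occupancy saturates hyperbolically", {
  expect_equal(downstreamComplexSteady(0, 1, 1), 0)
  expect_equal(downstreamComplexSteady(1, 1, 1), 0.5)   # half saturation
  expect_equal(downstreamComplexSteady(2, 5, 2), 2.5)
  expect_equal(downstreamComplexSteady(1e12, 1, 1), 1, tolerance = 1e-9)
  z <- seq(0, 10, by = 0.5)
  occ <- downstreamComplexSteady(z, 1, 1)
  expect_true(all(diff(occ) > 0) && all(occ <= 1))
})

test_that("the loaded steady-state mean equals the isolated one", {
  # binding and unbinding fluxes cancel at the fixed point, so the load
  # leaves the mean untouched for any parameter draw
  set.seed(17)
  for (rep in 1:100) {
    p <- stats::rexp(6) + 0.01
    N <- sample(0:10, 1)
    out <- sisoDownstreamMean(p[1], p[2], Itot1 = p[3] + 1, c2 = p[4],
                              k3 = p[5], Dtot = p[6], N = N)
    mu0 <- sisoReducedMean(p[1], p[2], p[3] + 1, p[4])
    expect_equal(out$mean, mu0, tolerance = 1e-9)
    expect_lt(abs(out$residual), 1e-10)
    expect_equal(out$complexes,
                 downstreamComplexSteady(mu0, p[6], p[5]))
  }
})

test_that("MIMO steady state solves the rate equations within tolerance", {
  r <- rateParameters(1, 1, 1, 1)
  ss <- mimoSteadyState(r, Etot = 1, Itot1 = 1, Itot2 = 1)
  m <- lnaMeans(ss)
  expect_lt(ss@residual[["rate"]], 1e-10)
  # exchange symmetry of the two branches
  expect_equal(m[["Z1"]], m[["Z2"]], tolerance = 1e-9)
  expect_equal(m[["M1"]], m[["M2"]], tolerance = 1e-9)
  # conservation bounds
  expect_true(all(m >= 0))
  expect_lte(m[["M1"]] + m[["M2"]], 1 + 1e-9)
  expect_lte(m[["M1"]] + m[["Z1"]], 1 + 1e-9)
  # silent second input reduces to the two-step single branch
  ss0 <- mimoSteadyState(r, Etot = 1, Itot1 = 1, Itot2 = 0)
  expect_equal(lnaMeans(ss0)[["Z2"]], 0, tolerance = 1e-12)
  expect_equal(lnaMeans(ss0)[["M2"]], 0, tolerance = 1e-12)
  # strong recycling drains the outputs
  ssBig <- mimoSteadyState(rateParameters(1, 1, 1, 1e4))
  expect_lt(lnaMeans(ssBig)[["Z1"]], 1e-3)
})

test_that("loaded MIMO steady state sequesters output as load grows", {
  r <- rateParameters(1, 1, 1, 1)
  z <- vapply(c(0L, 2L, 5L, 10L), function(N)
    lnaMeans(mimoDownstreamSteadyState(r, N = N))[["Z1"]], numeric(1))
  expect_true(all(diff(z) <= 1e-12))
  # N = 0 coincides with the isolated MIMO solve
  expect_equal(lnaMeans(mimoDownstreamSteadyState(r, N = 0L))[["Z1"]],
               lnaMeans(mimoSteadyState(r))[["Z1"]], tolerance = 1e-9)
  ss <- mimoDownstreamSteadyState(r, N = 3L)
  expect_lt(ss@residual[["rate"]], 1e-10)
})

test_that("Lyapunov solver matches scalar and eigen-decomposition oracles", {
  expect_equal(lyapunovCovariance(matrix(-2), matrix(4)), matrix(1))
  # reduced SISO instance reproduces the closed-form variance
  c1 <- 1; E <- 1; Itot <- 10; c2 <- 1; omega <- 1
  mu0 <- sisoReducedMean(c1, E, Itot, c2)
  A <- matrix(-(c1 * E + c2))
  D <- matrix((c1 * E * (Itot - mu0) + c2 * mu0) / omega)
  expect_equal(lyapunovCovariance(A, D)[1, 1],
               sisoReducedVariance(c1, E, Itot, c2, omega), tolerance = 1e-12)
  # random stable systems vs independent oracle
  for (seed in 1:5) {
    sys <- randomStableSystem(3L, seed)
    S <- lyapunovCovariance(sys$A, sys$D)
    expect_equal(S, eigenLyapunov(sys$A, sys$D), tolerance = 1e-8)
    expect_lt(max(abs(sys$A %*% S + S %*% t(sys$A) + sys$D)), 1e-9)
    expect_true(min(eigen(S, only.values = TRUE)$values) > -1e-9)
  }
  expect_error(lyapunovCovariance(matrix(1), matrix(1)), "Hurwitz")
})

test_that("the loaded-circuit LNA reproduces the isolated limit at N = 0", {
  lna0 <- lnaSisoDownstream(1, 1, 10, 1, N = 0L)
  expect_equal(lnaMeans(lna0)[["Z1"]], 5)
  expect_equal(lnaCovariance(lna0)[1, 1], 2.5, tolerance = 1e-12)
  lnaN <- lnaSisoDownstream(1, 1, 10, 1, k3 = 1, Dtot = 1, N = 5L)
  expect_equal(lnaMeans(lnaN)[["Z1"]], 5) # mean untouched by load
  expect_lt(lnaN@residual[["lyapunov"]], 1e-9)
  # 1/omega scaling of the loaded covariance too
  lna10 <- lnaSisoDownstream(1, 1, 10, 1, k3 = 1, Dtot = 1, N = 5L,
                             omega = 10)
  expect_equal(lnaCovariance(lna10), lnaCovariance(lnaN) / 10,
               tolerance = 1e-10)
})

test_that("Gaussian channel capacity follows the half-log law", {
  expect_equal(awgnCapacity(0), 0)
  expect_equal(awgnCapacity(1), 0.5 * log(2))
  expect_equal(awgnCapacity(2.5), 0.5 * log(3.5))
  expect_equal(awgnCapacity(3, noiseVariance = 3), 0.5 * log(2))
  expect_equal(awgnCapacity(1, units = "bits"), 0.5)
  expect_error(awgnCapacity(-1), "non-negative")
})
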