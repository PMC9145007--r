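test_that("closed-form constants evaluate to the pinned substitutions", {
  expect_equal(aValue(a0Const(1, 1, 1)), 2 / 3)
  expect_equal(aValue(aNConst(1, 1, 1, k3 = 1)), 3 / 4)
  expect_equal(aValue(aQMacConst(1, 1, 1, k3 = c(1, 1), Q = 1)), 3 / 4)
  expect_equal(aValue(aNConstNoncyclic(1, k3 = 1)), 1 / 2)
  # B at k0+ = k0- = 1, c = 0.01
  expect_equal(aValue(suppressWarnings(bConst(1, 1, 0.01))),
               (8 + 9 * 0.01) / (11 + 11 * 0.01))
  # B in the c -> 0 limit
  kp <- 2; km <- 3
  expect_equal(aValue(suppressWarnings(bConst(kp, km, 0))),
               (3 * kp^2 + km^2 + 4 * km * kp) / (5 * kp^2 + km^2 + 5 * km * kp))
})

test_that("the limit battery holds exactly", {
  expect_equal(aValue(a0Const(1, 1, 0)), 0)            # non-cyclic: A0 = 0
  expect_equal(aValue(a0Const(1, 1, 1e9)), 1, tolerance = 1e-6)
  expect_equal(aValue(aNConst(1, 1, 1e9, k3 = rep(1, 3))), 1, tolerance = 1e-6)
  # unloaded reduction
  expect_equal(aValue(aNConst(2, 3, 5)), aValue(a0Const(2, 3, 5)))
  # infinite load
  expect_equal(aValue(aNConst(1, 1, 1, k3 = rep(1, 1e6))), 1, tolerance = 1e-5)
  expect_equal(aValue(aNConstNoncyclic(1, numeric(0))), 0)
  expect_equal(aValue(aNConstNoncyclic(1, k3 = 1e9)), 0, tolerance = 1e-8)
  # MAC endpoints
  k3 <- c(0.5, 2, 1)
  expect_equal(aValue(aQMacConst(1, 2, 3, k3, Q = 0)), aValue(a0Const(1, 2, 3)))
  expect_equal(aValue(aQMacConst(1, 2, 3, k3, Q = 3)),
               aValue(aNConst(1, 2, 3, k3)))
  # mixture endpoints
  expect_equal(aValue(a0MimoConst(a0Const(1, 1, 1), 0.9, P02 = 1, P12 = 0)), 2 / 3)
  expect_equal(aValue(a0MimoConst(a0Const(1, 1, 1), 0.9, P02 = 0, P12 = 1)), 0.9)
  expect_equal(aValue(aNMimoConst(aNConst(1, 1, 1, 1), 0.9, P02 = 1, P12 = 0)), 3 / 4)
})

test_that("invalid constant inputs error or warn as designed", {
  expect_error(a0Const(1, 0, 0), "undefined")
  expect_error(aNConst(1, 1, 1, k3 = 0), "strictly positive")
  expect_error(aQMacConst(1, 1, 1, k3 = c(1, 1), Q = 3), "Q")
  expect_error(a0MimoConst(0.5, 0.6, P02 = 0.7, P12 = 0.7), "sum to 1")
  expect_warning(bConst(1, 1, 1), "fast-binding")
})

test_that("closed forms converge to the exact solver along the fast-binding ladder", {
  gapsA0 <- vapply(c(10, 100, 1000), function(k) {
    m <- fastBindingModel("ISOLATED_SISO", k)
    abs(aValue(channelFromCME(m)) - aValue(a0Const(1, 1, 1)))
  }, numeric(1))
  expect_true(all(diff(gapsA0) < 0))
  expect_lt(gapsA0[3], 1e-3)

  gapsB <- vapply(c(10, 100, 1000), function(k) {
    m <- fastBindingModel("ISOLATED_MIMO", k)
    ch <- channelFromCME(m)
    abs(ch@branchConditionals[["i2=1"]] -
          aValue(suppressWarnings(bConst(k, k, 1))))
  }, numeric(1))
  expect_true(all(diff(gapsB) < 0))
  expect_lt(gapsB[3], 1e-3)

  gapsAN <- vapply(c(10, 100, 1000), function(k) {
    m <- fastBindingModel("SISO_N_DOWNSTREAM", k, nDownstream = 2L)
    abs(aValue(channelFromCME(m)) - aValue(aNConst(1, 1, 1, c(1, 1))))
  }, numeric(1))
  expect_true(all(diff(gapsAN) < 0))
  expect_lt(gapsAN[3], 1e-3)
})

test_that("the MIMO branch conditional for a silent second input recovers A0", {
  m <- fastBindingModel("ISOLATED_MIMO", 1000)
  ch <- channelFromCME(m)
  expect_lt(abs(ch@branchConditionals[["i2=0"]] - aValue(a0Const(1, 1, 1))),
            1e-3)
  # mixture identity: A_hat = P02 * A(i2=0) + P12 * A(i2=1)
  ch37 <- channelFromCME(m, secondInputPriors = c(0.3, 0.7))
  expect_equal(aValue(ch37),
               0.3 * ch37@branchConditionals[["i2=0"]] +
                 0.7 * ch37@branchConditionals[["i2=1"]])
})

test_that("G exceeds B under load in the fast-binding regime", {
  r <- rateParameters(1000, 1000, 1, 1, k3Plus = 1000, k3Minus = 1000)
  G <- aValue(gConstNumeric(r, 1L))
  B <- aValue(suppressWarnings(bConst(1000, 1000, 1)))
  expect_gt(G, B)
  # G with no downstream collapses to the exact-B conditional
  r0 <- rateParameters(1000, 1000, 1, 1)
  expect_lt(abs(aValue(gConstNumeric(r0, 0L)) - B), 1e-3)
})

test_that("ordering battery holds over seeded fast-binding draws", {
  draws <- sampleRates("fast_binding", nDraws = 100L, seed = 11L,
                       nDownstream = 2L)
  for (r in draws) {
    dc <- dissociationConstants(r)
    a0 <- aValue(a0Const(dc$k0, r@c1, r@c2))
    aN <- aValue(aNConst(dc$k0, r@c1, r@c2, dc$k3))
    # the B closed form assumes equal catalytic rates; compare against the
    # matching equal-rate a0
    c <- r@c1
    a0c <- aValue(a0Const(dc$k0, c, c))
    B <- aValue(bConst(r@k0Plus, r@k0Minus, c, r@omega))
    a0m <- aValue(a0MimoConst(a0c, B, 0.5, 0.5))
    aQ <- vapply(0:2, function(Q)
      aValue(aQMacConst(dc$k0, r@c1, r@c2, dc$k3, Q)), numeric(1))
    expect_gte(B, a0c)
    expect_gte(a0m, a0c)
    expect_gte(aN, a0)
    expect_true(all(diff(aQ) >= 0))
    expect_equal(aQ[1], a0)
    expect_equal(aQ[3], aN)
    # MI strictly decreasing along any strict A increase
    if (aN > a0)
      expect_lt(miZChannel(aN, 0.5), miZChannel(a0, 0.5))
  }
})

test_that("constant tables collect the ensemble", {
  draws <- sampleRates("fast_binding", nDraws = 3L, seed = 5L,
                       nDownstream = 1L)
  df <- aConstantTable(draws, nDownstream = 1L, withG = TRUE)
  expect_identical(nrow(df), 3L)
  expect_true(all(df$AN >= df$A0))
  expect_true(all(df$G >= 0 & df$G <= 1))
  expect_true(all(df$AN_MIMO >= pmin(df$AN, df$G) - 1e-12))
})
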