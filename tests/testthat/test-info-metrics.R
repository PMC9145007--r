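test_that("entropy matches direct evaluation and respects its bounds", {
  expect_equal(shannonEntropy(c(0.5, 0.5)), log(2))
  expect_equal(shannonEntropy(c(1, 0)), 0)
  expect_equal(shannonEntropy(c(2 / 3, 1 / 3)), log(3) - (2 / 3) * log(2))
  expect_equal(shannonEntropy(c(0.5, 0.5), units = "bits"), 1)
  expect_error(shannonEntropy(c(0.5, 0.4)), "normalized")
  set.seed(1)
  for (rep in 1:20) {
    p <- stats::runif(4)
    p <- p / sum(p)
    expect_gte(shannonEntropy(p), 0)
    expect_lte(shannonEntropy(p), log(4) + 1e-12)
  }
})

test_that("Z-channel MI matches entropy decomposition on a dense grid", {
  grid <- priorGrid(101L)
  for (A in c(0, 0.25, 0.5, 0.75, 1)) {
    mi <- miZChannel(A, grid)
    direct <- vapply(grid, function(p01) {
      J <- rbind(c(p01, 0), c(A * (1 - p01), (1 - A) * (1 - p01)))
      bruteForceMI(J)
    }, numeric(1))
    expect_equal(mi, pmax(direct, 0), tolerance = 1e-12)
  }
})

test_that("Z-channel MI limit cases and monotonicity", {
  expect_equal(miZChannel(1, 0.5), 0)
  expect_equal(miZChannel(0, 0.5), log(2))
  expect_equal(miZChannel(0.5, 0.5), 0.2157616, tolerance = 1e-6)
  expect_equal(miZChannel(0.3, 1), 0)
  expect_equal(miZChannel(0.3, 0), 0)
  # strictly decreasing in A for interior priors
  a <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(miZChannel(a, 0.5)) < 0))
  expect_error(miZChannel(1.5, 0.5), "0, 1")
})

test_that("closed-form capacity agrees with Blahut-Arimoto and grid search", {
  aGrid <- priorGrid(101L)
  for (A in aGrid) {
    cap <- zChannelCapacity(A)
    W <- rbind(c(1, 0), c(A, 1 - A))
    expect_lt(abs(cap - blahutArimoto(W, tol = 1e-13)$capacity), 1e-8)
  }
  # capacity dominates MI, attained at the optimizing prior
  for (A in c(0.1, 0.5, 0.9)) {
    cap <- zChannelCapacity(A)
    best <- stats::optimize(function(p) miZChannel(A, p), c(0, 1),
                            maximum = TRUE, tol = 1e-12)
    expect_true(all(miZChannel(A, priorGrid(101L)) <= cap + 1e-12))
    expect_lt(abs(best$objective - cap), 1e-8)
  }
  expect_equal(zChannelCapacity(0), log(2))
  expect_equal(zChannelCapacity(0, units = "bits"), 1)
  expect_equal(zChannelCapacity(1), 0)
  expect_equal(zChannelCapacity(0.5, units = "bits"), log2(1.25))
  # non-increasing in A
  expect_true(all(diff(zChannelCapacity(aGrid)) <= 1e-12))
})

test_that("Blahut-Arimoto handles degenerate channels", {
  expect_equal(blahutArimoto(diag(2))$capacity, log(2), tolerance = 1e-10)
  expect_equal(blahutArimoto(rbind(c(0.3, 0.7), c(0.3, 0.7)))$capacity, 0,
               tolerance = 1e-10)
  expect_error(blahutArimoto(rbind(c(0.5, 0.4), c(0.3, 0.7))),
               "row-stochastic")
})

test_that("the dual KL bound dominates capacity and is tight at the optimum", {
  qGrid <- seq(0.01, 0.99, by = 0.01)
  for (A in c(0, 0.25, 0.5, 0.75, 1)) {
    cap <- zChannelCapacity(A)
    ub <- vapply(qGrid, function(q0)
      capacityUpperBound(A, c(q0, 1 - q0)), numeric(1))
    expect_true(all(ub >= cap - 1e-12))
    expect_lt(min(ub) - cap, 1.5e-2) # within the 0.01 grid resolution
  }
  # the duality gap closes as the q grid refines
  fine <- seq(0.001, 0.999, by = 0.001)
  for (A in c(0.5, 0.75)) {
    gapCoarse <- min(vapply(qGrid, function(q0)
      capacityUpperBound(A, c(q0, 1 - q0)), numeric(1))) - zChannelCapacity(A)
    gapFine <- min(vapply(fine, function(q0)
      capacityUpperBound(A, c(q0, 1 - q0)), numeric(1))) - zChannelCapacity(A)
    expect_lte(gapFine, gapCoarse)
    expect_lt(gapFine, 2e-3) # kinked max: the gap shrinks linearly in the step
  }
  # exactly tight at the capacity-achieving output distribution
  A <- 0.5
  ba <- blahutArimoto(rbind(c(1, 0), c(A, 1 - A)), tol = 1e-14)
  qStar <- drop(ba$inputDistribution %*% rbind(c(1, 0), c(A, 1 - A)))
  expect_lt(abs(capacityUpperBound(A, qStar) - zChannelCapacity(A)), 1e-6)
  expect_equal(capacityUpperBound(1, c(1, 0)), 0)
  expect_equal(capacityUpperBound(0, c(0.5, 0.5)), log(2))
})

test_that("the bound surface shows the coincidence property at each A", {
  grid <- priorGrid(101L)
  surf <- boundSurface(c(0, 0.25, 0.5, 0.75, 1), grid)
  for (A in unique(surf$A)) {
    block <- surf[surf$A == A, ]
    cap <- block$capacity[1]
    expect_true(all(block$lower <= cap + 1e-12))
    expect_true(all(block$upper >= cap - 1e-12))
    expect_lt(cap - max(block$lower), 1e-3)
    expect_lt(min(block$upper) - cap, 1.5e-2)
  }
  # capacity column non-increasing in A
  caps <- tapply(surf$capacity, surf$A, unique)
  expect_true(all(diff(caps) <= 1e-12))
})

test_that("capacity curve records the optimizing prior", {
  cc <- capacityCurve(c(0, 0.5, 0.9))
  expect_equal(cc$capacity, zChannelCapacity(c(0, 0.5, 0.9)))
  for (i in 1:3)
    expect_lt(abs(miZChannel(cc$A[i], cc$optimalP01[i]) - cc$capacity[i]),
              1e-7)
})
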