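# Tau-leap engine: analytic oracles on toy systems, conservation laws,
# reproducibility and error handling.

decayNet <- function() {
  toyNetwork("A -> B\t1", c("A\t0\tM:1", "B\t0\tM:1"))
}

test_that("pure decay matches the analytic mean within 3 SE", {
  net <- decayNet()
  mesh <- chainMesh(1)
  n0 <- 1000
  nTrials <- 150
  finals <- numeric(nTrials)
  for (i in seq_len(nTrials)) {
    init <- initFromCounts(mesh, net, list(A = n0))
    tr <- simulateStochastic(mesh, net, init, T = 1, recordInterval = 1,
                             seed = 4000 + i)
    finals[i] <- tr@counts[2, 1, 1]
  }
  expected <- n0 * exp(-1)
  se <- stats::sd(finals) / sqrt(nTrials)
  expect_lt(abs(mean(finals) - expected), 3 * se)
  # analytic variance of a pure death process: n0 e^-kt (1 - e^-kt)
  expect_equal(stats::var(finals), n0 * exp(-1) * (1 - exp(-1)),
               tolerance = 0.35)
})

test_that("symmetric reversible pair equilibrates to equal means", {
  net <- toyNetwork("A <-> B\t1\t1", c("A\t0\tM:1", "B\t0\tM:1"))
  mesh <- chainMesh(1)
  diffs <- numeric(60)
  for (i in seq_along(diffs)) {
    init <- initFromCounts(mesh, net, list(A = 400))
    tr <- simulateStochastic(mesh, net, init, T = 6, recordInterval = 6,
                             seed = 100 + i)
    diffs[i] <- tr@counts[2, 1, 1] - tr@counts[2, 1, 2]
  }
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("diffusion equilibrates two equal boxes to a 50/50 split", {
  net <- toyNetwork(character(0), c("A\t10\tM:1"))
  mesh <- chainMesh(2, volume = 1, area = 1, dist = 1)
  finals <- numeric(50)
  for (i in seq_along(finals)) {
    init <- initFromCounts(mesh, net, list(A = c(1000, 0)))
    tr <- simulateStochastic(mesh, net, init, T = 2, recordInterval = 2,
                             groups = "axial", seed = 200 + i)
    finals[i] <- tr@counts[2, 1, 1]
  }
  # stationary distribution is Binomial(1000, 1/2)
  expect_lt(abs(mean(finals) - 500), 3 * sqrt(250 / length(finals)))
  expect_true(all(finals >= 0 & finals <= 1000))
})

test_that("three-box relaxation follows the analytic rate matrix", {
  D <- 2; n0 <- 3000
  net <- toyNetwork(character(0), c("A\t2\tM:1"))
  mesh <- chainMesh(3, volume = 1, area = 1, dist = 1)
  # oracle: matrix exponential of the hop-rate generator
  k <- D * 1 / (1 * 1)
  Q <- matrix(c(-k, k, 0, k, -2 * k, k, 0, k, -k), 3, 3)
  tEnd <- 0.25
  ev <- eigen(Q)
  expectedFrac <- Re(ev$vectors %*% diag(exp(ev$values * tEnd)) %*%
                       solve(ev$vectors) %*% c(1, 0, 0))
  nTrials <- 60
  box1 <- numeric(nTrials)
  for (i in seq_len(nTrials)) {
    init <- initFromCounts(mesh, net, list(A = c(n0, 0, 0)))
    tr <- simulateStochastic(mesh, net, init, T = tEnd,
                             recordInterval = tEnd, groups = "axial",
                             seed = 300 + i)
    box1[i] <- tr@counts[2, 1, 1]
  }
  se <- stats::sd(box1) / sqrt(nTrials)
  expect_lt(abs(mean(box1) - n0 * expectedFrac[1]), 3 * se + 1e-9)
})

test_that("anchored species never move and totals are conserved", {
  net <- toyNetwork(character(0), c("A\t0\tM:1", "B\t5\tM:1"))
  mesh <- chainMesh(4)
  init <- initFromCounts(mesh, net, list(A = c(100, 0, 0, 0),
                                         B = c(100, 0, 0, 0)))
  tr <- simulateStochastic(mesh, net, init, T = 3, recordInterval = 3,
                           groups = "axial", seed = 7)
  final <- tr@counts[2, , ]
  expect_equal(final[, 1], c(100, 0, 0, 0))     # anchored A untouched
  expect_equal(sum(final[, 2]), 100)            # diffusing B conserved
  expect_gt(max(final[2:4, 2]), 0)              # ...but it did move
})

test_that("moieties are exactly conserved in a full-network spatial run", {
  net <- fullNet()
  mesh <- coarsenMesh(buildShortDendrite(), 31)
  init <- initialState(mesh, net, seed = 11)
  eng <- engineConfig(substepLimit = 16L)
  tr <- simulateStochastic(mesh, net, init, T = 0.5, recordInterval = 0.5,
                           engine = eng, seed = 11)
  before <- moietyTotals(net, init@counts)
  after <- moietyTotals(net, tr@meta$finalCounts)
  expect_identical(unname(before), unname(after))
  # non-negativity of the committed state
  expect_true(all(tr@meta$finalCounts >= 0))
})

test_that("fixed seed reproduces the trajectory bit-exactly; T = 0 returns
          only the initial record", {
  net <- fullNet()
  mesh <- coarsenMesh(buildShortDendrite(), 31)
  init <- initialState(mesh, net, seed = 5)
  eng <- engineConfig(substepLimit = 16L)
  t1 <- simulateStochastic(mesh, net, init, T = 0.2, recordInterval = 0.05,
                           engine = eng, seed = 42)
  t2 <- simulateStochastic(mesh, net, init, T = 0.2, recordInterval = 0.05,
                           engine = eng, seed = 42)
  expect_identical(t1@counts, t2@counts)
  t3 <- simulateStochastic(mesh, net, init, T = 0.2, recordInterval = 0.05,
                           engine = eng, seed = 43)
  expect_false(identical(t1@counts, t2@counts) &&
                 identical(t1@counts, t3@counts))
  t0 <- simulateStochastic(mesh, net, init, T = 0, recordInterval = 1,
                           seed = 1)
  expect_equal(length(t0@time), 1)
  expect_equal(sum(t0@counts[1, , ]), sum(init@counts))
})

test_that("a zero-amplitude train leaves a seed-matched run unchanged", {
  net <- fullNet()
  mesh <- coarsenMesh(buildShortDendrite(), 31)
  init <- initialState(mesh, net, seed = 9)
  eng <- engineConfig(substepLimit = 16L)
  zero <- calciumTetanus(mesh, onset = 0.01, rate = 0)
  tA <- simulateStochastic(mesh, net, init, list(zero), T = 0.2,
                           recordInterval = 0.1, engine = eng, seed = 31)
  tB <- simulateStochastic(mesh, net, init, list(), T = 0.2,
                           recordInterval = 0.1, engine = eng, seed = 31)
  expect_identical(tA@counts, tB@counts)
})

test_that("over-large fixed steps are rejected naming the fast species", {
  net <- toyNetwork(character(0), c("A\t100\tM:1"))
  mesh <- chainMesh(2, volume = 0.01, area = 1, dist = 0.1)
  init <- initFromCounts(mesh, net, list(A = c(10, 0)))
  eng <- engineConfig(dtMode = "fixed", dt = 1e-3)
  expect_error(
    simulateStochastic(mesh, net, init, T = 0.1, engine = eng, seed = 1),
    "hop probability")
})

test_that("negativity policy prevents negative counts at aggressive steps", {
  # strong drain A -> B with few molecules and a large fixed step
  net <- toyNetwork("A -> B\t50", c("A\t0\tM:1", "B\t0\tM:1"))
  mesh <- chainMesh(1)
  init <- initFromCounts(mesh, net, list(A = 5))
  tr <- simulateStochastic(mesh, net, init, T = 0.5, recordInterval = 0.05,
                           engine = engineConfig(dtMode = "fixed", dt = 0.05),
                           seed = 3)
  expect_true(all(tr@counts >= 0))
  expect_equal(tr@counts[11, 1, 1] + tr@counts[11, 1, 2], 5)
})
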