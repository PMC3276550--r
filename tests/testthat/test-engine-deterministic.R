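# Deterministic mass-action engine: closed forms, diffusion oracle,
# conservation and solver-tolerance robustness.

test_that("symmetric isomerization follows its closed form", {
  # A <-> B with kf = kb = 1: A(t) = 1 + e^(-2t) for A0 = 2, B0 = 0
  net <- toyNetwork("A <-> B\t1\t1", c("A\t0\tM:1", "B\t0\tM:1"))
  mesh <- chainMesh(1, volume = 1)
  NAv <- 0.602214076
  init <- new("InitialState",
              counts = matrix(c(2, 0) * NAv, 1, 2,
                              dimnames = list(NULL, c("A", "B"))),
              stochastic = FALSE)
  tr <- runDeterministic(mesh, net, init, T = 3, recordInterval = 0.25,
                         groups = "total", rtol = 1e-9, atol = 1e-10)
  a <- groupConcentration(tr, "A")
  expect_equal(a, 1 + exp(-2 * tr@time), tolerance = 1e-6)
})

test_that("enzyme triple approaches its Michaelis-Menten reduction", {
  # E + S <-> ES -> E + P with S >> E: dP/dt ~ kcat E0 S / (Km + S)
  net <- toyNetwork("E + S <-> ES -> E + P\t0.01\t1\t1",
                    c("E\t0\tE:1", "S\t0\tS:1", "ES\t0\tE:1;S:1",
                      "P\t0\tS:1"))
  mesh <- chainMesh(1, volume = 1)
  NAv <- 0.602214076
  E0 <- 1; S0 <- 2000
  init <- new("InitialState",
              counts = matrix(c(E0, S0, 0, 0) * NAv, 1, 4,
                              dimnames = list(NULL, c("E", "S", "ES", "P"))),
              stochastic = FALSE)
  tr <- runDeterministic(mesh, net, init, T = 20, recordInterval = 1,
                         groups = "total", rtol = 1e-9, atol = 1e-10)
  P <- groupConcentration(tr, "P")
  Km <- (1 + 1) / 0.01
  # QSSA over the sampled interval (S barely depleted)
  rateQSSA <- 1 * E0 * S0 / (Km + S0)
  rateSim <- (P[21] - P[6]) / (tr@time[21] - tr@time[6])
  expect_equal(rateSim, rateQSSA, tolerance = 0.05)
})

test_that("uniform initial state stays spatially uniform", {
  net <- fullNet()
  mesh <- coarsenMesh(buildShortDendrite(), 8)
  cfg <- spatialConfig(ACLocation = "spine", PKALocation = "uniform",
                       PDE10Distribution = "uniform")
  init <- initialState(mesh, net, cfg, stochastic = FALSE)
  tr <- runDeterministic(mesh, net, init, T = 5, recordInterval = 5,
                         groups = "axial")
  # a uniformly initialized diffusible species keeps equal density
  sv <- subvolumes(mesh)
  dendG <- grep("^x", tr@groups$name)
  d32 <- tr@counts[2, dendG, match("DARPP32", tr@species)] /
    (tr@groups$volume[dendG] * 0.602214076)
  # uniform up to the solver's relative error budget
  expect_lt(diff(range(d32)) / mean(d32), 1e-4)
})

test_that("diffusion from a point matches the matrix-exponential oracle", {
  n <- 8; D <- 3
  net <- toyNetwork(character(0), c("A\t3\tM:1"))
  mesh <- chainMesh(n, volume = 0.5, area = 0.25, dist = 0.5)
  k <- D * 0.25 / (0.5 * 0.5)
  Q <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    Q[i, i + 1] <- k; Q[i + 1, i] <- k
  }
  diag(Q) <- -rowSums(Q)
  tEnd <- 0.4
  ev <- eigen(t(Q))
  p <- Re(ev$vectors %*% diag(exp(ev$values * tEnd)) %*%
            solve(ev$vectors) %*% c(1, rep(0, n - 1)))
  NAv <- 0.602214076
  cnt <- matrix(0, n, 1, dimnames = list(NULL, "A"))
  cnt[1, 1] <- 1000
  init <- new("InitialState", counts = cnt, stochastic = FALSE)
  tr <- runDeterministic(mesh, net, init, T = tEnd, recordInterval = tEnd,
                         groups = "axial", rtol = 1e-10, atol = 1e-12)
  got <- tr@counts[2, , 1] / 1000
  expect_equal(unname(got), as.vector(p), tolerance = 1e-6)
})

test_that("moieties are conserved to relative 1e-6 and totals react to
          tolerance refinement by < 0.1%", {
  net <- fullNet()
  mesh <- buildWellMixed()
  init <- initialState(mesh, net, stochastic = FALSE)
  run <- function(rtol) runWellMixed(net, init = init, T = 100,
                                     recordInterval = 10, rtol = rtol,
                                     atol = 1e-3 * rtol / 1e-6)
  tr <- run(1e-6)
  before <- moietyTotals(net, init@counts)
  after <- moietyTotals(net, tr@meta$finalCounts)
  expect_equal(after, before, tolerance = 1e-6)
  # refining tolerances 10x changes the window average by < 0.1 %
  tr2 <- run(1e-7)
  g <- speciesGroups(net)
  w1 <- windowAverage(tr, g$pThr34, 0, 100)
  w2 <- windowAverage(tr2, g$pThr34, 0, 100)
  expect_lt(abs(w1 - w2) / w1, 1e-3)
})

test_that("stochastic means agree with the ODE on a well-mixed toy system", {
  # two-step cascade keeps this cheap but exercises both engines end-to-end
  net <- toyNetwork(c("A -> B\t0.8", "B + B <-> C\t0.01\t2"),
                    c("A\t0\tM:1", "B\t0\tM:1", "C\t0\tM:2"))
  mesh <- chainMesh(1, volume = 1)
  init <- initFromCounts(mesh, net, list(A = 500))
  nTrials <- 80
  finals <- matrix(0, nTrials, 3)
  for (i in seq_len(nTrials)) {
    tr <- simulateStochastic(mesh, net, init, T = 2, recordInterval = 2,
                             seed = 900 + i)
    finals[i, ] <- tr@counts[2, 1, ]
  }
  det <- runDeterministic(mesh, net,
                          new("InitialState", counts = init@counts,
                              stochastic = FALSE),
                          T = 2, recordInterval = 2, groups = "total",
                          rtol = 1e-9, atol = 1e-10)
  for (s in 1:3) {
    se <- stats::sd(finals[, s]) / sqrt(nTrials)
    expect_lt(abs(mean(finals[, s]) - det@counts[2, 1, s]), 3 * se + 0.5)
  }
})
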