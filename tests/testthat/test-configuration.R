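# Initial placement (anchoring, count parity, stochastic rounding) and
# stimulation protocols.

test_that("whole-morphology totals match the tabulated concentrations", {
  net <- fullNet()
  mesh <- buildShortDendrite()
  E <- expectedCounts(mesh, net)
  Vtot <- sum(subvolumes(mesh)$volume)
  conc <- colSums(E) / (Vtot * 0.602214076)
  expect_equal(unname(conc["DARPP32"]), 36400, tolerance = 1e-6)
  expect_equal(unname(conc["PP1"]), 3750, tolerance = 1e-6)
  expect_equal(unname(conc["cAMP"]), 35.6, tolerance = 1e-6)
})

test_that("spine-anchored PKA holoenzyme counts match c*V*N_A", {
  net <- fullNet()
  mesh <- buildShortDendrite()
  sv <- subvolumes(mesh)
  E <- expectedCounts(mesh, net, spatialConfig())
  # head slices only (before the PSD inclusion): ~240 molecules per spine
  headOnly <- sum(E[sv$spine %in% 1 & sv$region == "head", "PKA"])
  expect_equal(headOnly, 7050 * (2 * pi * 0.3^2 * 0.1) * 0.602214076,
               tolerance = 1e-6)
  expect_equal(round(headOnly), 240)
  # PKA species also occupy the PSD slice; the AC complex does not
  expect_gt(sum(E[sv$region == "psd", "PKA"]), 0)
  expect_equal(sum(E[sv$region == "psd", "AC"]), 0)
})

test_that("anchored totals are identical across the four configurations", {
  net <- fullNet()
  mesh <- buildShortDendrite()
  configs <- list(spatialConfig("spine", "spine"),
                  spatialConfig("spine", "focal"),
                  spatialConfig("focal", "spine"),
                  spatialConfig("focal", "focal"))
  anch <- c("R", "Gabg", "GabgR", "AC", "ACCa", "PKA", "PKAcAMP2",
            "PKAcAMP4", "PKAr")
  tot <- vapply(configs, function(cf)
    colSums(expectedCounts(mesh, net, cf))[anch], numeric(length(anch)))
  for (j in 2:4) expect_equal(tot[, j], tot[, 1], tolerance = 1e-12)
})

test_that("focal anchoring reproduces the spine-local concentrations", {
  net <- fullNet()
  mesh <- buildShortDendrite()
  sv <- subvolumes(mesh)
  E <- expectedCounts(mesh, net, spatialConfig("focal", "focal"))
  focal <- sv$region == "dend.sub.focal"
  acDens <- sum(E[focal, "AC"]) / sum(sv$volume[focal])
  expect_equal(acDens, 7428 * 0.602214076, tolerance = 0.02)
})

test_that("anchored species are zero outside their configured region", {
  net <- fullNet()
  mesh <- buildShortDendrite()
  sv <- subvolumes(mesh)
  E <- expectedCounts(mesh, net, spatialConfig("spine", "focal"))
  # AC in spine heads only
  expect_true(all(E[sv$region != "head", "AC"] == 0))
  # PKA in the focal submembrane block only
  expect_true(all(E[sv$region != "dend.sub.focal", "PKA"] == 0))
  # PDE10 restricted to membrane+spine by default
  expect_true(all(E[sv$region == "dend.cyt", "PDE10"] == 0))
  E2 <- expectedCounts(mesh, net,
                       spatialConfig(PDE10Distribution = "uniform"))
  expect_true(all(E2[, "PDE10"] > 0))
  # uniform PKA spreads over every subvolume with equal density
  E3 <- expectedCounts(mesh, net, spatialConfig(PKALocation = "uniform"))
  dens <- E3[, "PKA"] / sv$volume
  expect_lt(diff(range(dens)) / mean(dens), 1e-9)
})

test_that("stochastic rounding preserves expectations over seeds", {
  net <- fullNet()
  mesh <- coarsenMesh(buildShortDendrite(), 8)
  E <- expectedCounts(mesh, net)
  species <- c("PP2BCamCa4", "PKAcAMP4", "DARPP32", "CaPP2A")
  tot <- matrix(0, 100, length(species))
  for (i in 1:100) {
    st <- initialState(mesh, net, seed = i)
    expect_true(all(st@counts >= 0))
    expect_true(all(st@counts == floor(st@counts)))
    tot[i, ] <- colSums(st@counts[, species, drop = FALSE])
  }
  mu <- colMeans(tot)
  se <- apply(tot, 2, stats::sd) / sqrt(nrow(tot))
  target <- colSums(E[, species, drop = FALSE])
  for (j in seq_along(species)) {
    expect_lt(abs(mu[j] - target[j]), 3 * max(se[j], 1e-9) + 1e-9)
  }
})

test_that("phasic dopamine protocol has the reward-transient structure", {
  mesh <- buildShortDendrite()
  st <- dopaminePhasic(mesh, spatialConfig())
  expect_equal(length(st@onsets), 5)
  expect_equal(unique(diff(st@onsets)), 21)   # 1 s pulse + 20 s gap
  expect_equal(st@level, 1000)
  expect_equal(st@mode, "clamp")
  # zero pulses: empty train
  st0 <- dopaminePhasic(mesh, spatialConfig(), nPulses = 0)
  expect_equal(length(st0@onsets), 0)
  # gradient mode is a calibrated injection near spine 1
  stg <- dopaminePhasic(mesh, spatialConfig(dopamineD = 50))
  expect_equal(stg@mode, "injection")
  expect_gt(length(stg@targets), 0)
  expect_gt(stg@level, 0)
})

test_that("gradient-mode release calibration hits the target peak", {
  mesh <- coarsenMesh(buildLongDendrite(), 3)
  cfg <- spatialConfig(dopamineD = 50)
  stg <- dopaminePhasic(mesh, cfg)
  # steady state of the calibrated release must reach 1 uM at the site:
  # verified through the independent route of actually running the ODE
  net <- applyConfig(fullNet(), cfg)
  init <- initialState(mesh, net, cfg, stochastic = FALSE)
  sus <- new("StimulusTrain", species = "Da", mode = "injection",
             targets = stg@targets, onsets = 0, duration = 10,
             level = stg@level)
  tr <- runDeterministic(mesh, net, init, list(sus), T = 8,
                         recordInterval = 1, groups = "axial")
  rel <- which.min(abs(tr@groups$x -
                         subvolumes(mesh)$x[match(stg@targets[1],
                                                  subvolumes(mesh)$id)]))
  daAtSite <- groupConcentration(tr, "Da", tr@groups$name[rel])
  expect_equal(max(daAtSite), 1000, tolerance = 0.05)
})

test_that("calcium tetanus delivers 37500 molecules per stimulated spine", {
  mesh <- buildShortDendrite()
  st <- calciumTetanus(mesh)
  expect_equal(length(st@onsets), 100)
  expect_equal(length(st@targets), 2)           # one PSD per spine
  # total molecules per spine: pulses x duration x rate
  expect_equal(length(st@onsets) * st@duration * 1000 * st@level, 37500)
  # train spans ~1.29 s (100 Hz, ~1 s protocol)
  expect_equal(max(st@onsets) + st@duration - min(st@onsets), 1.29,
               tolerance = 1e-9)
  expect_error(calciumTetanus(mesh, spineIds = c(2, 9)), "absent")
})

test_that("a clamp at the basal level leaves the system unchanged", {
  net <- fullNet()
  # basal dopamine is pinned by the exchange reaction at exactly 10 nM
  trC <- runWellMixed(net, stimuli = list(bathClamp("Da", 10, onset = 0,
                                                    duration = 30)),
                      T = 30, recordInterval = 5)
  trF <- runWellMixed(net, T = 30, recordInterval = 5)
  g <- speciesGroups(net)
  expect_equal(groupConcentration(trC, g$pThr34),
               groupConcentration(trF, g$pThr34), tolerance = 1e-4)
  expect_equal(groupConcentration(trC, "cAMP"),
               groupConcentration(trF, "cAMP"), tolerance = 1e-3)
})
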