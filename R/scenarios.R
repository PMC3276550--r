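# Scenario registry: every simulated experiment, runnable at a
# full-fidelity preset (full mesh, stochastic tau-leap, repeated seeds) or
# a desk-scale preset (coarse-mesh deterministic substitutes for the long
# window-averaged comparisons; reduced stochastic runs where stochasticity
# is the point).  Desk presets keep each scenario within minutes on one
# CPU; the preset substitutions are part of the scenario definitions and
# documented in the methods vignette.

.pkgEnv <- new.env(parent = emptyenv())

.fullNetwork <- function() {
  if (is.null(.pkgEnv$net)) .pkgEnv$net <- loadNetwork()
  .pkgEnv$net
}

# equilibrated well-mixed basal state (model's own fixed point)
.steadyBasal <- function(network, T = 3000) {
  key <- paste0("basal.", digest_rows(network))
  if (is.null(.pkgEnv[[key]])) {
    tr <- runWellMixed(network, T = T, recordInterval = T / 4)
    .pkgEnv[[key]] <- tr@meta$finalCounts
  }
  .pkgEnv[[key]]
}

# cheap structural hash of a network's reaction list (cache key)
digest_rows <- function(network) {
  v <- c(nrow(network@reactions), sum(network@reactions$rate),
         sum(network@species$D), nrow(network@species))
  paste(signif(v, 12), collapse = "_")
}

#' List the registered scenarios
#'
#' @return data.frame with scenario names, the figure-level question each
#'   addresses, the engine used by the desk preset, and default trial
#'   counts (short-dendrite scenarios default to 4 seeds, long-dendrite
#'   scenarios to 6, matching the repeated-trial structure of the study).
#' @export
listScenarios <- function() {
  reg <- list(
    c("validation_da_bath", "bath 10 uM dopamine: pThr34/pThr75/pS845 response", "deterministic.wellmixed", 1),
    c("validation_ca_bath", "bath 600 nM calcium: dephosphorylation response", "deterministic.wellmixed", 1),
    c("validation_da_ca", "paired dopamine + calcium bath", "deterministic.wellmixed", 1),
    c("coloc_2x2.spine_spine", "AC spine / PKA spine (colocalized)", "deterministic.spatial", 4),
    c("coloc_2x2.spine_focal", "AC spine / PKA dendrite (apart)", "deterministic.spatial", 4),
    c("coloc_2x2.focal_spine", "AC dendrite / PKA spine (apart)", "deterministic.spatial", 4),
    c("coloc_2x2.focal_focal", "AC dendrite / PKA dendrite (colocalized)", "deterministic.spatial", 4),
    c("ht31_uniform", "uniform vs spine-anchored PKA (Ht31 mimic), AC in spine", "deterministic.spatial", 4),
    c("neck_series", "spine neck length 0 / 0.3 / 1.0 um", "deterministic.spatial", 4),
    c("sens_diffusion", "doubled diffusion constants", "deterministic.spatial", 4),
    c("sens_glua1_dephos", "scaled GluA1 dephosphorylation rate", "deterministic.spatial", 4),
    c("sens_pde10_uniform", "uniform PDE10 distribution", "deterministic.spatial", 4),
    c("da_ca_paired", "phasic dopamine with/without calcium tetanus", "deterministic.spatial", 4),
    c("ca_spine_peak", "peak spine calcium during the tetanus", "stochastic", 4),
    c("da_gradient_short", "slowed dopamine diffusion, receptors 3 um away", "deterministic.spatial", 4),
    c("gradient_long", "cAMP gradient along the 23 um dendrite", "deterministic.spatial", 6),
    c("gradient_long_d32_frozen", "pThr34 gradient, all DARPP-32 frozen", "deterministic.spatial", 6),
    c("gradient_long_pkabound_frozen", "pThr34 gradient, PKA-bound DARPP-32 frozen", "deterministic.spatial", 6),
    c("gradient_long_pt75block", "frozen DARPP-32 + pThr75/PKA block", "deterministic.spatial", 6),
    c("coloc_regression", "cAMP vs colocalization regression (4 configs x trials)", "stochastic.coarse", 16))
  out <- as.data.frame(do.call(rbind, reg), stringsAsFactors = FALSE)
  names(out) <- c("name", "question", "desk.engine", "seeds")
  out$seeds <- as.integer(out$seeds)
  out
}

# ---- shared pieces ----

.deskShortMesh <- function(neckLength = 0.3) {
  key <- paste0("meshS.", neckLength)
  if (is.null(.pkgEnv[[key]]))
    .pkgEnv[[key]] <- coarsenMesh(buildShortDendrite(neckLength), 2)
  .pkgEnv[[key]]
}

.deskLongMesh <- function() {
  if (is.null(.pkgEnv$meshL))
    .pkgEnv$meshL <- coarsenMesh(buildLongDendrite(), 3)
  .pkgEnv$meshL
}

# spatial deterministic run from the tabulated basal state
.deskSpatialRun <- function(mesh, network, config, stimuli, T,
                            recordInterval = 2, groups = "region") {
  init <- initialState(mesh, network, config, stochastic = FALSE)
  runDeterministic(mesh, network, init, stimuli, T = T,
                   recordInterval = recordInterval, groups = groups)
}

# window metrics shared by the anchoring comparisons
.windowMetrics <- function(tr, network) {
  g <- speciesGroups(network)
  psdGroups <- grep("\\.psd$", tr@groups$name, value = TRUE)
  ps845 <- percentPhosphoGluA1(tr, network,
                               regions = if (length(psdGroups)) psdGroups)
  tt <- tr@time
  sel <- tt >= 50 & tt <= 300
  list(
    PKAcSum = windowAverage(tr, g$PKAc, 50, 350, mode = "sum"),
    pThr34Avg = windowAverage(tr, g$pThr34, 50, 350),
    pS845Avg = mean(ps845[sel]))
}

# local cAMP at the PKA anchoring site, averaged 50-350 s
.localCAMP <- function(tr, pkaLocation) {
  regions <- if (pkaLocation == "spine")
    grep("\\.head$", tr@groups$name, value = TRUE)
  else if (pkaLocation == "focal") "dend.sub.focal"
  else NULL
  windowAverage(tr, "cAMP", 50, 350, regions = regions)
}

.validationRun <- function(network, stimuli, T = 650) {
  basal <- .steadyBasal(network)
  mesh <- buildWellMixed()
  init <- new("InitialState", counts = basal, stochastic = FALSE)
  runDeterministic(mesh, network, init, stimuli, T = T,
                   recordInterval = 2, groups = "total")
}

.validationMetrics <- function(tr, network) {
  g <- speciesGroups(network)
  tt <- tr@time
  p34 <- groupConcentration(tr, g$pThr34)
  p75 <- groupConcentration(tr, g$pThr75)
  ps845 <- percentPhosphoGluA1(tr, network)
  i0 <- which.min(abs(tt - 50))
  list(
    pThr34FoldPeak2min = max(p34[tt >= 50 & tt <= 170]) / p34[i0],
    pThr75MinPct = 100 * min(p75[tt >= 50]) / p75[i0],
    pS845Fold5to10min = mean(ps845[tt >= 350 & tt <= 650]) / ps845[i0],
    basal = list(pThr34 = p34[i0], pThr75 = p75[i0], pS845pct = ps845[i0]))
}

# network edits for the sensitivity scenarios
.scaleDiffusion <- function(network, factor) {
  network@species$D <- network@species$D * factor
  network
}

.scaleGluA1Dephos <- function(network, factor) {
  rows <- grep("^pS8.*GluA1 \\+ PP", network@rows$equation)
  sel <- network@reactions$row %in% rows
  network@reactions$rate[sel] <- network@reactions$rate[sel] * factor
  network
}

# ---- scenario implementations ----

.runColocCase <- function(case, preset, seed) {
  net0 <- .fullNetwork()
  loc <- strsplit(case, "_", fixed = TRUE)[[1]]
  cfg <- spatialConfig(ACLocation = ifelse(loc[1] == "spine", "spine", "focal"),
                       PKALocation = ifelse(loc[2] == "spine", "spine", "focal"))
  net <- applyConfig(net0, cfg)
  mesh <- if (preset == "desk") .deskShortMesh() else buildShortDendrite()
  stim <- dopaminePhasic(mesh, cfg)
  if (preset == "desk") {
    tr <- .deskSpatialRun(mesh, net, cfg, list(stim), T = 350)
  } else {
    init <- initialState(mesh, net, cfg, seed = seed)
    tr <- simulateStochastic(mesh, net, init, list(stim), T = 350,
                             recordInterval = 1, seed = seed)
  }
  m <- .windowMetrics(tr, net)
  m$localCAMP <- .localCAMP(tr, cfg@PKALocation)
  m$colocalized <- as.integer(loc[1] == loc[2])
  m
}

.scenarioImpl <- list(

  validation_da_bath = function(preset, seed, ov) {
    net <- .fullNetwork()
    tr <- .validationRun(net, list(bathClamp("Da", 10000)))
    .validationMetrics(tr, net)
  },

  validation_ca_bath = function(preset, seed, ov) {
    net <- .fullNetwork()
    tr <- .validationRun(net, list(bathClamp("Ca", 600)))
    g <- speciesGroups(net)
    tt <- tr@time
    p34 <- groupConcentration(tr, g$pThr34)
    p75 <- groupConcentration(tr, g$pThr75)
    ps <- percentPhosphoGluA1(tr, net)
    i0 <- which.min(abs(tt - 50))
    list(pThr34PlateauPct = 100 * mean(p34[tt >= 350]) / p34[i0],
         pThr75PlateauPct = 100 * mean(p75[tt >= 350]) / p75[i0],
         pS845PlateauPct = 100 * mean(ps[tt >= 350]) / ps[i0])
  },

  validation_da_ca = function(preset, seed, ov) {
    net <- .fullNetwork()
    tr <- .validationRun(net, list(bathClamp("Da", 10000),
                                   bathClamp("Ca", 600)))
    .validationMetrics(tr, net)
  },

  ht31_uniform = function(preset, seed, ov) {
    net0 <- .fullNetwork()
    mesh <- .deskShortMesh()
    run1 <- function(pka) {
      cfg <- spatialConfig(ACLocation = "spine", PKALocation = pka)
      net <- applyConfig(net0, cfg)
      tr <- .deskSpatialRun(mesh, net, cfg,
                            list(dopaminePhasic(mesh, cfg)), T = 350)
      .windowMetrics(tr, net)
    }
    anch <- run1("spine")
    unif <- run1("uniform")
    list(anchored = anch, uniform = unif,
         pThr34ReductionPct = 100 * (1 - unif$pThr34Avg / anch$pThr34Avg),
         pS845ReductionPct = 100 * (1 - unif$pS845Avg / anch$pS845Avg))
  },

  da_ca_paired = function(preset, seed, ov) {
    net0 <- .fullNetwork()
    cfg <- spatialConfig(ACLocation = "spine", PKALocation = "spine")
    net <- applyConfig(net0, cfg)
    mesh <- .deskShortMesh()
    da <- dopaminePhasic(mesh, cfg)
    # one tetanus accompanies each dopamine transient (paired trials)
    ca <- calciumTetanus(mesh, trains = 5)
    trDa <- .deskSpatialRun(mesh, net, cfg, list(da), T = 350)
    trBoth <- .deskSpatialRun(mesh, net, cfg, list(da, ca), T = 350)
    mDa <- .windowMetrics(trDa, net)
    mB <- .windowMetrics(trBoth, net)
    g <- speciesGroups(net)
    red <- function(f) 100 * (1 - mB[[f]] / mDa[[f]])
    list(dopamine = mDa, paired = mB,
         phosphoCaMKIIPairedSum = windowAverage(trBoth, g$phosphoCaMKII,
                                                50, 350, mode = "sum"),
         PKAReductionPct = red("PKAcSum"),
         pThr34ReductionPct = red("pThr34Avg"),
         pS845ReductionPct = red("pS845Avg"),
         meanReductionPct = mean(c(red("PKAcSum"), red("pThr34Avg"),
                                   red("pS845Avg"))))
  },

  ca_spine_peak = function(preset, seed, ov) {
    net0 <- .fullNetwork()
    cfg <- spatialConfig(ACLocation = "spine", PKALocation = "spine")
    net <- applyConfig(net0, cfg)
    mesh <- buildShortDendrite()
    preT <- if (!is.null(ov$preT)) ov$preT else 0.3
    T <- if (!is.null(ov$T)) ov$T else 2.0
    ca <- calciumTetanus(mesh, onset = preT)
    init <- initialState(mesh, net, cfg, seed = seed)
    tr <- simulateStochastic(mesh, net, init, list(ca), T = T,
                             recordInterval = 0.005, seed = seed)
    heads <- function(s) paste0("spine", s, ".head")
    peakStim <- max(vapply(c(2, 3), function(s)
      max(groupConcentration(tr, "Ca", heads(s))), 0))
    peakOther <- max(vapply(c(1, 4), function(s)
      max(groupConcentration(tr, "Ca", heads(s))), 0))
    dendPeak <- max(groupConcentration(tr, "Ca",
                                       grep("^dend", tr@groups$name,
                                            value = TRUE)))
    list(peakStimulatedSpine_nM = peakStim,
         peakNonStimulatedSpine_nM = peakOther,
         peakDendrite_nM = dendPeak)
  },

  da_gradient_short = function(preset, seed, ov) {
    net0 <- .fullNetwork()
    mesh <- .deskShortMesh()
    run1 <- function(daD) {
      cfg <- spatialConfig(ACLocation = "focal", PKALocation = "focal",
                          dopamineD = daD)
      net <- applyConfig(net0, cfg)
      tr <- .deskSpatialRun(mesh, net, cfg,
                            list(dopaminePhasic(mesh, cfg)), T = 350)
      g <- speciesGroups(net)
      tt <- tr@time
      camp <- groupConcentration(tr, "cAMP")
      p34 <- groupConcentration(tr, g$pThr34)
      list(cAMPAvg = windowAverage(tr, "cAMP", 50, 200),
           pThr34Avg = windowAverage(tr, g$pThr34, 50, 350),
           cAMPPeakTime = tt[which.max(camp)],
           pThr34PeakTime = tt[which.max(p34)])
    }
    vol <- run1(150)
    grad <- run1(50)
    list(volumeTransmission = vol, gradient = grad,
         cAMPRatio = grad$cAMPAvg / vol$cAMPAvg,
         pThr34Ratio = grad$pThr34Avg / vol$pThr34Avg)
  },

  neck_series = function(preset, seed, ov) {
    net0 <- .fullNetwork()
    out <- list()
    for (neck in c(0, 0.3, 1.0)) {
      mesh <- .deskShortMesh(neck)
      run1 <- function(pka) {
        cfg <- spatialConfig(ACLocation = "spine", PKALocation = pka,
                            neckLength = neck)
        net <- applyConfig(net0, cfg)
        tr <- .deskSpatialRun(mesh, net, cfg,
                              list(dopaminePhasic(mesh, cfg)), T = 350)
        .windowMetrics(tr, net)
      }
      co <- run1("spine"); apart <- run1("focal")
      out[[paste0("neck", neck)]] <- list(
        colocalized = co, apart = apart,
        pThr34Diff = co$pThr34Avg - apart$pThr34Avg,
        pS845Diff = co$pS845Avg - apart$pS845Avg)
    }
    out
  },

  sens_diffusion = function(preset, seed, ov) {
    net0 <- .scaleDiffusion(.fullNetwork(),
                            if (!is.null(ov$factor)) ov$factor else 2)
    mesh <- .deskShortMesh()
    run1 <- function(pka) {
      cfg <- spatialConfig(ACLocation = "spine", PKALocation = pka)
      net <- applyConfig(net0, cfg)
      tr <- .deskSpatialRun(mesh, net, cfg,
                            list(dopaminePhasic(mesh, cfg)), T = 350)
      .windowMetrics(tr, net)
    }
    co <- run1("spine"); apart <- run1("focal")
    list(colocalized = co, apart = apart,
         PKAcRatio = co$PKAcSum / apart$PKAcSum)
  },

  sens_glua1_dephos = function(preset, seed, ov) {
    net0 <- .scaleGluA1Dephos(.fullNetwork(),
                              if (!is.null(ov$factor)) ov$factor else 2)
    mesh <- .deskShortMesh()
    run1 <- function(pka) {
      cfg <- spatialConfig(ACLocation = "spine", PKALocation = pka)
      net <- applyConfig(net0, cfg)
      tr <- .deskSpatialRun(mesh, net, cfg,
                            list(dopaminePhasic(mesh, cfg)), T = 350)
      .windowMetrics(tr, net)
    }
    co <- run1("spine"); apart <- run1("focal")
    list(colocalized = co, apart = apart,
         pS845Diff = co$pS845Avg - apart$pS845Avg)
  },

  sens_pde10_uniform = function(preset, seed, ov) {
    net0 <- .fullNetwork()
    mesh <- .deskShortMesh()
    run1 <- function(pka) {
      cfg <- spatialConfig(ACLocation = "spine", PKALocation = pka,
                          PDE10Distribution = "uniform")
      net <- applyConfig(net0, cfg)
      tr <- .deskSpatialRun(mesh, net, cfg,
                            list(dopaminePhasic(mesh, cfg)), T = 350)
      m <- .windowMetrics(tr, net)
      m$localCAMP <- .localCAMP(tr, pka)
      m
    }
    co <- run1("spine"); apart <- run1("focal")
    list(colocalized = co, apart = apart,
         PKAcRatio = co$PKAcSum / apart$PKAcSum)
  },

  gradient_long = function(preset, seed, ov) {
    .gradientLong(spatialConfig(dopamineD = 50, PDE10Distribution = "uniform"),
                  species = "cAMP", window = c(50, 150), fixBaseline = TRUE)
  },

  gradient_long_d32_frozen = function(preset, seed, ov) {
    .gradientLong(spatialConfig(dopamineD = 50, PDE10Distribution = "uniform",
                               d32DiffusionMode = "frozen"),
                  species = "pThr34", window = c(100, 250))
  },

  gradient_long_pkabound_frozen = function(preset, seed, ov) {
    .gradientLong(spatialConfig(dopamineD = 50, PDE10Distribution = "uniform",
                               d32DiffusionMode = "pka.bound.frozen"),
                  species = "pThr34", window = c(100, 250))
  },

  gradient_long_pt75block = function(preset, seed, ov) {
    .gradientLong(spatialConfig(dopamineD = 50, PDE10Distribution = "uniform",
                               d32DiffusionMode = "frozen",
                               pT75PKABlock = TRUE),
                  species = "pThr34", window = c(100, 250))
  },

  coloc_regression = function(preset, seed, ov) {
    nTrials <- if (!is.null(ov$trials)) ov$trials else 4
    .colocRegression(nTrials, seed, ov)
  }
)

# long-dendrite gradient scenario core.  The mesh is first equilibrated
# without stimulation until the slow basal pools (phospho-PDE10,
# phospho-PP2A, basal phosphoThr34) reach the model's own fixed point, so
# the baseline is stationary during the fitting window.  The primary decay
# length fixes the fit baseline at that stationary basal (a spatial
# profile cannot decay below its own basal); the free-baseline variant is
# also reported.
.gradientLong <- function(cfg, species, window, fixBaseline = TRUE,
                          eqT = 1500) {
  net <- applyConfig(.fullNetwork(), cfg)
  mesh <- .deskLongMesh()
  key <- paste0("eqLong.", digest_rows(net))
  if (is.null(.pkgEnv[[key]])) {
    init0 <- initialState(mesh, net, cfg, stochastic = FALSE)
    eq <- runDeterministic(mesh, net, init0, list(), T = eqT,
                           recordInterval = eqT / 2, groups = "total")
    .pkgEnv[[key]] <- eq@meta$finalCounts
  }
  init <- new("InitialState", counts = .pkgEnv[[key]], stochastic = FALSE)
  stim <- dopaminePhasic(mesh, cfg)
  tr <- runDeterministic(mesh, net, init, list(stim), T = window[2] + 10,
                         recordInterval = 2, groups = "axial")
  g <- speciesGroups(net)
  w <- if (species == "cAMP") g$cAMP else g[[species]]
  relX <- tr@groups$x[which(startsWith(tr@groups$name, "x"))]
  prof <- axialProfile(tr, w, window[1], window[2], releaseX = min(relX))
  i0 <- which.min(abs(tr@time - 45))
  basal <- groupConcentration(tr, w)[i0]
  fit <- fitExponentialGradient(prof$x, prof$value,
                                baseline = if (fixBaseline) basal else NULL)
  fitFree <- fitExponentialGradient(prof$x, prof$value, baseline = NULL)
  list(lambda = fit$lambda, se = fit$se, C0 = fit$C0, b = fit$b,
       basal = basal, lambdaFreeBaseline = fitFree$lambda,
       identifiable = fit$identifiable, profile = prof,
       peakValue = max(prof$value))
}

# reduced stochastic 2x2 design for the activity regression: the coarsest
# mesh (whole-spine compartments, PSD merged into the head) with a
# shortened phasic protocol keeps 16 tau-leap trials within minutes
.colocRegression <- function(nTrials, seed, ov = list()) {
  net0 <- .fullNetwork()
  meshC <- coarsenMesh(buildShortDendrite(), 31, mergePSD = TRUE)
  cases <- list(c("spine", "spine"), c("spine", "focal"),
                c("focal", "spine"), c("focal", "focal"))
  nP <- if (!is.null(ov$nPulses)) ov$nPulses else 2
  Tend <- if (!is.null(ov$T)) ov$T else 60
  onset <- 15
  rows <- list()
  for (ci in seq_along(cases)) {
    cfg <- spatialConfig(ACLocation = cases[[ci]][1],
                        PKALocation = cases[[ci]][2])
    net <- applyConfig(net0, cfg)
    stim <- dopaminePhasic(meshC, cfg, onset = onset, nPulses = nP)
    for (tr_i in seq_len(nTrials)) {
      s <- seed * 1000 + ci * 100 + tr_i
      init <- initialState(meshC, net, cfg, seed = s)
      eng <- engineConfig(substepLimit = 16L)
      tr <- simulateStochastic(meshC, net, init, list(stim), T = Tend,
                               recordInterval = 0.5, engine = eng, seed = s)
      g <- speciesGroups(net)
      act <- windowAverage(tr, g$PKAc, onset, Tend, mode = "sum")
      lc <- if (cfg@PKALocation == "spine")
        windowAverage(tr, "cAMP", onset, Tend,
                      grep("\\.head$", tr@groups$name, value = TRUE))
      else windowAverage(tr, "cAMP", onset, Tend, "dend.sub.focal")
      rows[[length(rows) + 1]] <- data.frame(
        config = paste(cases[[ci]], collapse = "_"),
        coloc = as.integer(cases[[ci]][1] == cases[[ci]][2]),
        cAMP = lc, activity = act, seed = s)
    }
  }
  runs <- do.call(rbind, rows)
  reg <- activityRegression(runs)
  list(runs = runs, r.squared = reg$r.squared,
       p.cAMP = unname(reg$p["cAMP"]), p.coloc = unname(reg$p["coloc"]))
}

#' Run a registered scenario
#'
#' Executes the scenario at the requested preset and returns (and
#' optionally writes) its machine-readable summary.  "desk" substitutes
#' documented coarse-mesh deterministic runs (or reduced stochastic runs)
#' for the multi-day full-fidelity stochastic computations; "full" runs
#' the full stochastic protocol on the printed mesh.
#'
#' @param name scenario name from \code{\link{listScenarios}};
#'   \code{coloc_2x2} runs all four anchoring cases
#' @param preset "desk" or "full"
#' @param seed integer seed controlling every random draw of the scenario
#' @param outDir optional output directory: writes \code{summary.json}
#'   (and is created if missing)
#' @param overrides named list of scenario-specific overrides
#' @return the scenario summary (list), invisibly when writing
#' @export
runScenario <- function(name, preset = c("desk", "full"), seed = 1,
                        outDir = NULL, overrides = list()) {
  preset <- match.arg(preset)
  if (name == "coloc_2x2") {
    cases <- c("spine_spine", "spine_focal", "focal_spine", "focal_focal")
    res <- lapply(cases, .runColocCase, preset = preset, seed = seed)
    names(res) <- cases
    res$ordering <- c(
      colocMin = min(res$spine_spine$PKAcSum, res$focal_focal$PKAcSum),
      apartMax = max(res$spine_focal$PKAcSum, res$focal_spine$PKAcSum))
  } else if (startsWith(name, "coloc_2x2.")) {
    res <- .runColocCase(sub("^coloc_2x2\\.", "", name), preset, seed)
  } else {
    impl <- .scenarioImpl[[name]]
    if (is.null(impl)) stop("unknown scenario: ", name)
    set.seed(seed)
    res <- impl(preset, seed, overrides)
  }
  res <- c(list(scenario = name, preset = preset, seed = seed), res)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(res, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    return(invisible(res))
  }
  res
}
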