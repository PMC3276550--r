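# Initial molecule placement and stimulation protocols.
#
# Non-anchored pools are specified as whole-morphology average
# concentrations and populate every subvolume in proportion to volume.
# Anchored pools (D1R/G-protein/adenylate-cyclase complex, PKA, PDE10,
# pumps, GluA1) are restricted to their configured regions.  Anchored-pool
# molecule totals are derived once from the spine-head concentrations, so
# that every anchoring configuration carries exactly the same global and
# local amounts (count parity across the 2x2 colocalization design).

#' Construct a spatial configuration
#'
#' @param ACLocation "spine" or "focal" placement of the
#'   D1R/G-protein/adenylate-cyclase complex
#' @param PKALocation "spine", "focal", or "uniform" (Ht31-style disruption)
#' @param PDE10Distribution "membrane" (submembrane + spine) or "uniform"
#' @param dopamineD 150 (volume transmission) or 50 um^2/s (gradient mode)
#' @param neckLength spine neck length (um)
#' @param d32DiffusionMode "diffuse", "frozen", or "pka.bound.frozen"
#' @param pT75PKABlock block the phosphoThr75-DARPP-32/PKAc interaction
#' @return a \linkS4class{SpatialConfig}
#' @export
spatialConfig <- function(ACLocation = "spine", PKALocation = "spine",
                          PDE10Distribution = "membrane", dopamineD = 150,
                          neckLength = 0.3, d32DiffusionMode = "diffuse",
                          pT75PKABlock = FALSE) {
  new("SpatialConfig", ACLocation = ACLocation, PKALocation = PKALocation,
      PDE10Distribution = PDE10Distribution, dopamineD = dopamineD,
      neckLength = neckLength, d32DiffusionMode = d32DiffusionMode,
      pT75PKABlock = pT75PKABlock)
}

.initEnv <- new.env(parent = emptyenv())

.initTables <- function() {
  if (is.null(.initEnv$nonanchored)) {
    .initEnv$nonanchored <- utils::read.delim(
      system.file("extdata", "initial_nonanchored.tsv", package = "spineRD"),
      comment.char = "#", stringsAsFactors = FALSE)
    .initEnv$anchored <- utils::read.delim(
      system.file("extdata", "initial_anchored.tsv", package = "spineRD"),
      comment.char = "#", stringsAsFactors = FALSE)
  }
  list(nonanchored = .initEnv$nonanchored, anchored = .initEnv$anchored)
}

# canonical per-spine anchored volumes (2 head slices; PSD extra for PKA)
.V_HEADCYT <- 2 * pi * 0.3^2 * 0.1
.V_PSD <- pi * 0.3^2 * 0.1

# membrane region (pumps, PDE10 "membrane" distribution)
.membraneSet <- function(sv) {
  memb <- sv$region %in% c("dend.sub", "dend.sub.focal", "neck", "head", "psd")
  if (!any(sv$region %in% c("dend.sub", "dend.sub.focal"))) return(NULL)
  memb
}

#' Expected per-subvolume molecule counts for a configuration
#'
#' Returns the expectation matrix (subvolume x species) before stochastic
#' rounding; \code{\link{initialState}} rounds it.
#'
#' @param mesh a \linkS4class{Mesh}
#' @param network a \linkS4class{ReactionNetwork}
#' @param config a \linkS4class{SpatialConfig}
#' @return numeric matrix of expected molecule counts
#' @export
expectedCounts <- function(mesh, network,
                           config = spatialConfig()) {
  tabs <- .initTables()
  sv <- mesh@subvolumes
  nsub <- nrow(sv)
  spn <- network@species$name
  E <- matrix(0, nsub, length(spn), dimnames = list(NULL, spn))
  Vtot <- sum(sv$volume)
  wellmixed <- mesh@meta$type == "wellmixed"
  nSpines <- if (wellmixed) 4L else length(mesh@spines)

  vshare <- function(set) {        # volume-proportional weights on a set
    w <- numeric(nsub); w[set] <- sv$volume[set] / sum(sv$volume[set]); w
  }
  memb <- .membraneSet(sv)

  # --- non-anchored (and membrane-distributed) pools ---
  na <- tabs$nonanchored
  for (i in seq_len(nrow(na))) {
    s <- na$species[i]
    if (!s %in% spn) stop("initial concentration for unknown species ", s)
    total <- na$conc_nM[i] * Vtot * .NAV
    plc <- na$placement[i]
    if (plc == "pde10" && config@PDE10Distribution == "membrane" &&
        !is.null(memb) && !wellmixed) {
      E[, s] <- E[, s] + total * vshare(which(memb))
    } else if (plc == "membrane" && !is.null(memb) && !wellmixed) {
      E[, s] <- E[, s] + total * vshare(which(memb))
    } else {
      E[, s] <- E[, s] + na$conc_nM[i] * sv$volume * .NAV
    }
  }

  # --- anchored families ---
  an <- tabs$anchored
  headSet <- which(sv$region == "head")
  psdSet <- which(sv$region == "psd")
  focalSet <- which(sv$region == "dend.sub.focal")
  for (i in seq_len(nrow(an))) {
    s <- an$species[i]
    fam <- an$family[i]
    if (fam == "psd_count") {
      nPer <- an$spine_nM[i]   # molecules per PSD
      if (wellmixed) {
        E[, s] <- E[, s] + nPer * nSpines
      } else {
        for (ids in mesh@spines) {
          p <- match(intersect(ids, sv$id[psdSet]), sv$id)
          if (!length(p))  # PSD merged into the head on coarse meshes
            p <- match(intersect(ids, sv$id[headSet]), sv$id)
          if (length(p))
            E[p, s] <- E[p, s] + nPer * sv$volume[p] / sum(sv$volume[p])
        }
      }
      next
    }
    conc <- an$spine_nM[i]
    perSpineV <- if (fam == "pka") .V_HEADCYT + .V_PSD else .V_HEADCYT
    total <- conc * perSpineV * nSpines * .NAV
    loc <- if (fam == "pka") config@PKALocation else config@ACLocation
    if (wellmixed) {
      E[, s] <- E[, s] + total
    } else if (loc == "uniform") {
      E[, s] <- E[, s] + total * vshare(seq_len(nsub))
    } else if (loc == "spine") {
      set <- if (fam == "pka") c(headSet, psdSet) else headSet
      E[set, s] <- E[set, s] + conc * sv$volume[set] * .NAV
    } else { # focal
      if (!length(focalSet))
        stop("mesh has no focal submembrane region for focal anchoring")
      E[, s] <- E[, s] + total * vshare(focalSet)
    }
  }
  E
}

#' Initialize per-subvolume molecule counts
#'
#' Draws integer counts by expectation-preserving stochastic rounding
#' (floor(x) + Bernoulli(frac(x)) per subvolume), so species whose expected
#' count per subvolume is below one molecule are represented correctly on
#' average.
#'
#' @param mesh a \linkS4class{Mesh}
#' @param network a \linkS4class{ReactionNetwork}
#' @param config a \linkS4class{SpatialConfig}
#' @param seed optional RNG seed
#' @param stochastic if FALSE, return the (fractional) expectations
#' @return an \linkS4class{InitialState}
#' @export
initialState <- function(mesh, network, config = spatialConfig(),
                         seed = NULL, stochastic = TRUE) {
  E <- expectedCounts(mesh, network, config)
  if (stochastic) {
    if (!is.null(seed)) set.seed(seed)
    fl <- floor(E)
    frac <- E - fl
    draw <- matrix(stats::rbinom(length(E), 1L, as.vector(frac)),
                   nrow(E), ncol(E))
    E <- fl + draw
  }
  new("InitialState", counts = E, stochastic = stochastic)
}

# ---- stimulation protocols ----

#' Phasic dopamine transients
#'
#' Five 1-second, 1 uM dopamine elevations, 20 s apart, mimicking reward
#' dopamine transients.  Under volume transmission (dopamine D = 150
#' um^2/s) the elevation is applied uniformly as a clamp; in gradient mode
#' (D = 50) dopamine is injected into the dendritic subvolumes overlying
#' the first spine, with the release rate auto-calibrated so that the
#' steady release-site concentration during a pulse equals the target.
#'
#' @param mesh a \linkS4class{Mesh}
#' @param config a \linkS4class{SpatialConfig} (its \code{dopamineD}
#'   selects the delivery mode)
#' @param onset time of the first pulse (s)
#' @param nPulses number of pulses
#' @param interval gap between pulses (s)
#' @param duration pulse duration (s)
#' @param level peak dopamine concentration (nM)
#' @return a \linkS4class{StimulusTrain}
#' @export
dopaminePhasic <- function(mesh, config = spatialConfig(), onset = 50,
                           nPulses = 5, interval = 20, duration = 1,
                           level = 1000) {
  onsets <- if (nPulses > 0) onset + (0:(nPulses - 1)) * (duration + interval)
  else numeric(0)
  if (config@dopamineD == 150 || mesh@meta$type == "wellmixed") {
    new("StimulusTrain", species = "Da", mode = "clamp",
        targets = integer(0), onsets = onsets, duration = duration,
        level = level)
  } else {
    sv <- mesh@subvolumes
    if (!length(mesh@spines)) stop("gradient-mode release needs spines")
    ax1 <- sv$x[match(mesh@spines[[1]][1], sv$id)]
    # dendritic subvolumes in the axial slice of spine 1
    dend <- which(is.na(sv$spine))
    d <- abs(sv$x[dend] - sv$x[dend][which.min(abs(sv$x[dend] - ax1))])
    targets <- sv$id[dend[d < 1e-9]]
    rate <- .calibrateRelease(mesh, config@dopamineD, targets,
                              target_nM = level - 10)
    new("StimulusTrain", species = "Da", mode = "injection",
        targets = as.integer(targets), onsets = onsets, duration = duration,
        level = rate)
  }
}

# steady-state calibration of the release rate (molecules/ms per target
# subvolume) so that the release-site concentration reaches target_nM above
# basal: solves (removal + diffusion) n = source on the dendrite graph.
.calibrateRelease <- function(mesh, D, targets, target_nM, removal = 2) {
  sv <- mesh@subvolumes
  n <- nrow(sv)
  A <- matrix(0, n, n)
  diag(A) <- removal
  cp <- mesh@couplings
  ia <- match(cp$a, sv$id); ib <- match(cp$b, sv$id)
  kab <- hopRate(D, cp$area, cp$dist, sv$volume[ia])
  kba <- hopRate(D, cp$area, cp$dist, sv$volume[ib])
  for (m in seq_len(nrow(cp))) {
    A[ia[m], ia[m]] <- A[ia[m], ia[m]] + kab[m]
    A[ib[m], ib[m]] <- A[ib[m], ib[m]] + kba[m]
    A[ia[m], ib[m]] <- A[ia[m], ib[m]] - kba[m]
    A[ib[m], ia[m]] <- A[ib[m], ia[m]] - kab[m]
  }
  s <- numeric(n)
  s[match(targets, sv$id)] <- 1
  nss <- solve(A, s)
  peak <- max(nss / (sv$volume * .NAV))
  unit <- target_nM / peak          # molecules/s per target subvolume
  unit / 1000                       # molecules/ms
}

#' Tetanic calcium influx into spine PSDs
#'
#' 100 calcium pulses (3 ms on, 10 ms gap, 125 molecules/ms) into the PSD
#' subvolume of the target spines, approximating NMDA-receptor influx
#' during a 100 Hz, 1 s tetanus.  Total influx per stimulated spine is
#' 100 x 3 x 125 = 37500 molecules.
#'
#' @param mesh a \linkS4class{Mesh}
#' @param spineIds spine numbers to stimulate (default the two central
#'   spines of the four-spine mesh)
#' @param onset first-pulse time (s)
#' @param nPulses,duration,gap,rate train parameters (defaults as above;
#'   duration and gap in s, rate in molecules/ms)
#' @param trains number of tetanus trains; when paired with the phasic
#'   dopamine protocol one train accompanies each dopamine transient
#' @param trainInterval time between train onsets (s), matching the
#'   dopamine inter-transient interval
#' @return a \linkS4class{StimulusTrain}
#' @export
calciumTetanus <- function(mesh, spineIds = c(2, 3), onset = 50,
                           nPulses = 100, duration = 0.003, gap = 0.010,
                           rate = 125, trains = 1, trainInterval = 21) {
  if (!all(spineIds %in% seq_along(mesh@spines)))
    stop("spine ids absent from mesh: ",
         paste(setdiff(spineIds, seq_along(mesh@spines)), collapse = ", "))
  sv <- mesh@subvolumes
  targets <- unlist(lapply(mesh@spines[spineIds], function(ids) {
    ids[sv$region[match(ids, sv$id)] == "psd"]
  }), use.names = FALSE)
  one <- if (nPulses > 0) (0:(nPulses - 1)) * (duration + gap)
  else numeric(0)
  onsets <- as.vector(outer(one, onset + (0:(trains - 1)) * trainInterval,
                            "+"))
  new("StimulusTrain", species = "Ca", mode = "injection",
      targets = as.integer(targets), onsets = sort(onsets),
      duration = duration, level = rate)
}

#' Bath application: clamp a species' free concentration
#'
#' Holds the species at the given concentration uniformly over the mesh
#' for the duration (validation mode); releasing the clamp restores normal
#' kinetics.
#'
#' @param species species name
#' @param level clamp concentration (nM)
#' @param onset clamp onset (s)
#' @param duration clamp duration (s); use a value beyond the run length
#'   for a sustained application
#' @return a \linkS4class{StimulusTrain}
#' @export
bathClamp <- function(species, level, onset = 50, duration = 1e6) {
  if (level < 0) stop("level must be >= 0")
  new("StimulusTrain", species = species, mode = "clamp",
      targets = integer(0), onsets = onset, duration = duration,
      level = level)
}
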