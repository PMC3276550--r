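#' @import methods
NULL

# molecules per (nM * um^3)
.NAV <- 0.602214076

#' Reaction network of elementary mass-action reactions
#'
#' Container for the signaling network: species (with diffusion constants and
#' subunit composition), the parsed reaction-table rows, the expanded list of
#' irreversible elementary reactions, and the stoichiometric matrix.
#' Reversible rows are stored as two elementary reactions and enzyme rows
#' (E + S <-> ES -> E + P) as three, so a single propensity machinery covers
#' the whole network.
#'
#' @slot species data.frame with columns \code{name}, \code{D} (diffusion
#'   constant, um^2/s, 0 = anchored) and \code{composition} (raw string).
#' @slot composition integer matrix (species x moiety) of subunit
#'   multiplicities; moieties are conserved totals such as DARPP32, PP1 or
#'   CaMKII subunits.
#' @slot reactions data.frame of elementary reactions: reactant indices
#'   \code{r1}, \code{r2} (NA = none), \code{order} (1 or 2),
#'   \code{selfPair} (TRUE for A + A), \code{rate} (nM^-1 s^-1 if
#'   bimolecular, s^-1 otherwise), \code{row} (source row index), and
#'   \code{step} ("fwd", "back" or "cat").
#' @slot stoich integer matrix (species x elementary reaction) of net
#'   molecule changes.
#' @slot rows data.frame of parsed table rows incl. raw strings (used for
#'   bit-exact serialization).
#' @export
setClass("ReactionNetwork", representation(
  species = "data.frame",
  composition = "matrix",
  reactions = "data.frame",
  stoich = "matrix",
  rows = "data.frame"
))

setValidity("ReactionNetwork", function(object) {
  msg <- character()
  if (anyDuplicated(object@species$name))
    msg <- c(msg, "species names must be unique")
  if (any(object@species$D < 0))
    msg <- c(msg, "diffusion constants must be >= 0")
  if (nrow(object@reactions)) {
    if (any(object@reactions$rate < 0))
      msg <- c(msg, "rates must be >= 0")
    if (!all(object@reactions$order %in% 1:2))
      msg <- c(msg, "only first and second order reactions are supported")
    bad <- stats::na.omit(c(object@reactions$r1, object@reactions$r2))
    if (length(bad) && (min(bad) < 1 || max(bad) > nrow(object@species)))
      msg <- c(msg, "reactant index out of range")
  }
  if (length(msg)) msg else TRUE
})

#' Subvolume mesh with diffusion couplings
#'
#' A morphology discretized into well-stirred subvolumes: cuboids in the
#' dendrite (2-D diffusion in the length x width plane) and cylindrical
#' slices in the spines (1-D diffusion along the spine axis).
#'
#' @slot subvolumes data.frame: \code{id}, \code{region} (one of
#'   "dend.cyt", "dend.sub", "dend.sub.focal", "neck", "head", "psd"),
#'   \code{x} axial position (um, from the stimulated end), \code{volume}
#'   (um^3), \code{spine} (spine number or NA).
#' @slot couplings data.frame: subvolume ids \code{a}, \code{b}, contact
#'   \code{area} (um^2) and center-to-center \code{dist} (um).  Couplings are
#'   stored once per unordered pair and treated symmetrically.
#' @slot spines list mapping spine number to the ordered neck/head/PSD
#'   subvolume ids.
#' @slot meta list: mesh type, neck length, grid dimensions.
#' @export
setClass("Mesh", representation(
  subvolumes = "data.frame",
  couplings = "data.frame",
  spines = "list",
  meta = "list"
))

setValidity("Mesh", function(object) {
  sv <- object@subvolumes
  cp <- object@couplings
  msg <- character()
  if (any(sv$volume <= 0)) msg <- c(msg, "subvolume volumes must be > 0")
  if (nrow(cp)) {
    if (any(cp$area <= 0) || any(cp$dist <= 0))
      msg <- c(msg, "coupling areas and distances must be > 0")
    if (any(!cp$a %in% sv$id) || any(!cp$b %in% sv$id))
      msg <- c(msg, "coupling references unknown subvolume")
    if (any(cp$a == cp$b)) msg <- c(msg, "self-coupling not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Spatial anchoring / kinetic-variant configuration
#'
#' Where the anchored pools sit and which kinetic variants are active.
#'
#' @slot ACLocation "spine" or "focal": placement of the D1R/G-protein/
#'   adenylate cyclase complex.
#' @slot PKALocation "spine", "focal" or "uniform" (uniform mimics Ht31
#'   disruption of anchoring).
#' @slot PDE10Distribution "membrane" (dendritic submembrane + spine) or
#'   "uniform".
#' @slot dopamineD dopamine diffusion constant (um^2/s); 150 for volume
#'   transmission, 50 for the gradient-producing slowed diffusion.
#' @slot neckLength spine neck length (um): 0, 0.3 or 1.0.
#' @slot d32DiffusionMode "diffuse" (all mobile DARPP-32 forms diffuse),
#'   "frozen" (all DARPP-32 forms immobile) or "pka.bound.frozen" (only the
#'   PKA-bound forms immobile).
#' @slot pT75PKABlock TRUE removes the phosphoThr75-DARPP-32/PKAc
#'   inhibitory binding.
#' @export
setClass("SpatialConfig", representation(
  ACLocation = "character",
  PKALocation = "character",
  PDE10Distribution = "character",
  dopamineD = "numeric",
  neckLength = "numeric",
  d32DiffusionMode = "character",
  pT75PKABlock = "logical"
))

setValidity("SpatialConfig", function(object) {
  msg <- character()
  if (!object@ACLocation %in% c("spine", "focal"))
    msg <- c(msg, "ACLocation must be 'spine' or 'focal'")
  if (!object@PKALocation %in% c("spine", "focal", "uniform"))
    msg <- c(msg, "PKALocation must be 'spine', 'focal' or 'uniform'")
  if (!object@PDE10Distribution %in% c("membrane", "uniform"))
    msg <- c(msg, "PDE10Distribution must be 'membrane' or 'uniform'")
  if (!object@d32DiffusionMode %in% c("diffuse", "frozen", "pka.bound.frozen"))
    msg <- c(msg, "unknown d32DiffusionMode")
  if (!object@neckLength %in% c(0, 0.3, 1.0))
    msg <- c(msg, "neckLength must be 0, 0.3 or 1.0 um")
  if (!object@dopamineD %in% c(150, 50))
    msg <- c(msg, "dopamineD must be 150 or 50 um^2/s")
  if (length(msg)) msg else TRUE
})

#' Per-subvolume initial molecule counts
#'
#' @slot counts numeric matrix (subvolume x species) of molecule counts;
#'   integers for stochastic initializations, expectations for
#'   deterministic ones.
#' @slot stochastic logical; whether counts were stochastically rounded.
#' @export
setClass("InitialState", representation(
  counts = "matrix",
  stochastic = "logical"
))

#' Timed stimulus: species injection or concentration clamp
#'
#' @slot species species name.
#' @slot mode "injection" (molecules/ms into each target subvolume) or
#'   "clamp" (free concentration held at a level, nM).
#' @slot targets integer ids of target subvolumes (empty = whole mesh).
#' @slot onsets pulse onset times (s).
#' @slot duration single pulse duration (s).
#' @slot level clamp level (nM) or injection rate (molecules/ms per
#'   target subvolume).
#' @export
setClass("StimulusTrain", representation(
  species = "character",
  mode = "character",
  targets = "integer",
  onsets = "numeric",
  duration = "numeric",
  level = "numeric"
))

setValidity("StimulusTrain", function(object) {
  msg <- character()
  if (!object@mode %in% c("injection", "clamp"))
    msg <- c(msg, "mode must be 'injection' or 'clamp'")
  if (length(object@onsets) > 1) {
    gaps <- diff(sort(object@onsets))
    if (any(gaps < object@duration - 1e-12))
      msg <- c(msg, "pulses must not overlap")
  }
  if (object@level < 0) msg <- c(msg, "level must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Recorded simulation trajectory
#'
#' Time series of molecule counts aggregated over recording groups
#' (regions, spines or axial bins).  Concentrations are derived by dividing
#' by group volume.
#'
#' @slot time recorded times (s).
#' @slot counts numeric array (time x group x species).
#' @slot groups data.frame: \code{name}, \code{volume} (um^3), \code{x}
#'   (representative axial position, um, NA for non-axial groups).
#' @slot species species names (3rd array dimension).
#' @slot engine "stochastic" or "deterministic".
#' @slot meta list (seed, dt, scenario info).
#' @export
setClass("Trajectory", representation(
  time = "numeric",
  counts = "array",
  groups = "data.frame",
  species = "character",
  engine = "character",
  meta = "list"
))

setMethod("show", "ReactionNetwork", function(object) {
  cat("ReactionNetwork:", nrow(object@species), "species,",
      nrow(object@rows), "table rows,",
      nrow(object@reactions), "elementary reactions\n")
  nd <- sum(object@species$D > 0)
  cat("  diffusible species:", nd, "| moieties:",
      ncol(object@composition), "\n")
})

setMethod("show", "Mesh", function(object) {
  cat("Mesh (", object@meta$type, "): ", nrow(object@subvolumes),
      " subvolumes, ", nrow(object@couplings), " couplings, ",
      length(object@spines), " spines\n", sep = "")
  cat("  total volume:", signif(sum(object@subvolumes$volume), 5), "um^3\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory [", object@engine, "]: ", length(object@time),
      " records x ", nrow(object@groups), " groups x ",
      length(object@species), " species; t = ",
      min(object@time), "..", max(object@time), " s\n", sep = "")
})

setMethod("show", "StimulusTrain", function(object) {
  cat("StimulusTrain:", object@species, object@mode,
      length(object@onsets), "pulse(s), level", object@level,
      if (object@mode == "clamp") "nM" else "molecules/ms", "\n")
})

setMethod("show", "SpatialConfig", function(object) {
  cat("SpatialConfig: AC =", object@ACLocation,
      "| PKA =", object@PKALocation,
      "| PDE10 =", object@PDE10Distribution,
      "| D(Da) =", object@dopamineD,
      "| neck =", object@neckLength, "um\n")
})

# ---- accessors ----

#' Species table of a network
#' @param network a \linkS4class{ReactionNetwork}
#' @return data.frame of species with diffusion constants
#' @export
speciesTable <- function(network) network@species

#' Elementary reactions of a network
#' @param network a \linkS4class{ReactionNetwork}
#' @return data.frame of elementary reactions
#' @export
elementaryReactions <- function(network) network@reactions

#' Stoichiometric matrix (species x elementary reactions)
#' @param network a \linkS4class{ReactionNetwork}
#' @return integer matrix of net molecule changes
#' @export
stoichiometricMatrix <- function(network) network@stoich

#' Subvolume table of a mesh
#' @param mesh a \linkS4class{Mesh}
#' @return data.frame of subvolumes
#' @export
subvolumes <- function(mesh) mesh@subvolumes

#' Diffusion couplings of a mesh
#' @param mesh a \linkS4class{Mesh}
#' @return data.frame of couplings (a, b, area, dist)
#' @export
couplings <- function(mesh) mesh@couplings

#' Recorded times of a trajectory
#' @param trajectory a \linkS4class{Trajectory}
#' @return numeric vector of times (s)
#' @export
recordTimes <- function(trajectory) trajectory@time
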