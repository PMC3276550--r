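# Mesoscopic tau-leap reaction-diffusion engine (R interface).
#
# Each time step applies, per subvolume, Poisson-distributed reaction event
# counts (tau-leaping), then binomial/multinomial diffusion transfers
# between coupled subvolumes.  If a leap would drive a count negative the
# step is locally halved and redrawn (up to 5 times, then an exact SSA
# handles that subvolume-step).  Per-species totals are conserved exactly
# by diffusion; conserved moieties are invariant under reaction updates.

#' Engine configuration for the stochastic simulator
#'
#' @param dtMode "auto" (diffusion-capped fixed step on meshes, adaptive on
#'   well-mixed systems), "fixed", or "adaptive"
#' @param dt fixed time step (s); also the starting step in adaptive mode
#' @param eps adaptive-leap tolerance: bound on the expected relative
#'   propensity change per step (0 < eps <= 0.1)
#' @param dtMin,dtMax adaptive step bounds (s)
#' @param maxHopP maximum per-coupling hop probability per (sub)step
#' @param substepLimit maximum diffusion substeps for fast species in auto
#'   mode (lets slow reactions use a larger outer step than the calcium
#'   diffusion cap alone would allow)
#' @return list of engine settings
#' @export
engineConfig <- function(dtMode = c("auto", "fixed", "adaptive"),
                         dt = 5e-6, eps = 0.03, dtMin = 1e-6, dtMax = 1e-3,
                         maxHopP = 0.095, substepLimit = 4L) {
  dtMode <- match.arg(dtMode)
  stopifnot(dt > 0, eps > 0, eps <= 0.1)
  list(dtMode = dtMode, dt = dt, eps = eps, dtMin = dtMin, dtMax = dtMax,
       maxHopP = maxHopP, substepLimit = as.integer(substepLimit))
}

# directed hop-rate geometry factors g = A/(V_src * d) as CSR over subvolumes
.diffGeometry <- function(mesh) {
  sv <- mesh@subvolumes
  cp <- mesh@couplings
  n <- nrow(sv)
  if (!nrow(cp)) {
    return(list(ptr = integer(n + 1), idx = integer(0), g = numeric(0)))
  }
  ia <- match(cp$a, sv$id); ib <- match(cp$b, sv$id)
  src <- c(ia, ib); dst <- c(ib, ia)
  g <- c(cp$area / (sv$volume[ia] * cp$dist),
         cp$area / (sv$volume[ib] * cp$dist))
  o <- order(src)
  src <- src[o]; dst <- dst[o]; g <- g[o]
  ptr <- c(0L, cumsum(tabulate(src, n)))
  list(ptr = as.integer(ptr), idx = as.integer(dst - 1L), g = g)
}

.recordGroups <- function(mesh, groups = "region") {
  sv <- mesh@subvolumes
  if (is.list(groups)) {
    gnames <- names(groups)
    groupOf <- rep(NA_integer_, nrow(sv))
    for (i in seq_along(groups))
      groupOf[match(groups[[i]], sv$id)] <- i
    if (anyNA(groupOf)) stop("custom groups must cover every subvolume")
  } else if (groups == "region") {
    key <- ifelse(is.na(sv$spine), sv$region,
                  paste0("spine", sv$spine, ".", sv$region))
    gnames <- unique(key)
    groupOf <- match(key, gnames)
  } else if (groups == "axial") {
    key <- ifelse(is.na(sv$spine), paste0("x", format(sv$x)),
                  paste0("spine", sv$spine, ".", sv$region))
    gnames <- unique(key)
    groupOf <- match(key, gnames)
  } else if (groups == "total") {
    gnames <- "total"
    groupOf <- rep(1L, nrow(sv))
  } else stop("unknown grouping: ", groups)
  vol <- as.vector(tapply(sv$volume, groupOf, sum))
  x <- as.vector(tapply(sv$x * sv$volume, groupOf, sum)) / vol
  gdf <- data.frame(name = gnames, volume = vol, x = x,
                    stringsAsFactors = FALSE)
  list(groupOf = as.integer(groupOf - 1L), groups = gdf)
}

.prepReactions <- function(network, mesh) {
  re <- network@reactions
  S <- network@stoich
  nreact <- nrow(re)
  sv <- mesh@subvolumes
  # CSC stoichiometry
  nz <- lapply(seq_len(nreact), function(r) which(S[, r] != 0L))
  sPtr <- c(0L, cumsum(vapply(nz, length, 1L)))
  sIdx <- unlist(nz, use.names = FALSE) - 1L
  sVal <- unlist(lapply(seq_len(nreact), function(r) S[nz[[r]], r]),
                 use.names = FALSE)
  r1 <- re$r1 - 1L
  r2 <- ifelse(is.na(re$r2), -1L, re$r2 - 1L)
  need <- function(ri, r) {
    if (is.na(ri)) return(0L)
    max(1L, -S[ri, r])
  }
  need1 <- vapply(seq_len(nreact), function(r) need(re$r1[r], r), 1L)
  need2 <- vapply(seq_len(nreact), function(r) need(re$r2[r], r), 1L)
  # per-subvolume propensity constants
  cmat <- matrix(0, nrow(sv), nreact)
  for (r in seq_len(nreact)) {
    if (re$order[r] == 1L) {
      cmat[, r] <- re$rate[r]
    } else if (re$selfPair[r]) {
      cmat[, r] <- 2 * re$rate[r] / (.NAV * sv$volume)
    } else {
      cmat[, r] <- re$rate[r] / (.NAV * sv$volume)
    }
  }
  list(r1 = as.integer(r1), r2 = as.integer(r2),
       need1 = as.integer(need1), need2 = as.integer(need2),
       selfPair = re$selfPair, sPtr = as.integer(sPtr),
       sIdx = as.integer(sIdx), sVal = as.numeric(sVal), cmat = cmat)
}

.prepStimuli <- function(stimuli, mesh, network, forCounts = TRUE) {
  sv <- mesh@subvolumes
  spn <- network@species$name
  inj <- list(spec = integer(0), ptr = 0L, sub = integer(0),
              rate = numeric(0), on = numeric(0), off = numeric(0),
              pulsePtr = 0L)
  cl <- list(spec = integer(0), ptr = 0L, sub = integer(0),
             count = numeric(0), on = numeric(0), off = numeric(0),
             pulsePtr = 0L)
  for (st in stimuli) {
    si <- match(st@species, spn)
    if (is.na(si)) stop("stimulus references unknown species ", st@species)
    if (!length(st@onsets)) next
    tg <- if (length(st@targets)) match(st@targets, sv$id)
    else seq_len(nrow(sv))
    if (anyNA(tg)) stop("stimulus targets missing from mesh")
    if (st@mode == "injection") {
      inj$spec <- c(inj$spec, si - 1L)
      inj$ptr <- c(inj$ptr, inj$ptr[length(inj$ptr)] + length(tg))
      inj$sub <- c(inj$sub, tg - 1L)
      inj$rate <- c(inj$rate, rep(st@level * 1000, length(tg)))
      inj$on <- c(inj$on, st@onsets)
      inj$off <- c(inj$off, st@onsets + st@duration)
      inj$pulsePtr <- c(inj$pulsePtr,
                        inj$pulsePtr[length(inj$pulsePtr)] + length(st@onsets))
    } else {
      cnt <- st@level * sv$volume[tg] * .NAV
      if (forCounts) cnt <- round(cnt)
      cl$spec <- c(cl$spec, si - 1L)
      cl$ptr <- c(cl$ptr, cl$ptr[length(cl$ptr)] + length(tg))
      cl$sub <- c(cl$sub, tg - 1L)
      cl$count <- c(cl$count, cnt)
      cl$on <- c(cl$on, st@onsets)
      cl$off <- c(cl$off, st@onsets + st@duration)
      cl$pulsePtr <- c(cl$pulsePtr,
                       cl$pulsePtr[length(cl$pulsePtr)] + length(st@onsets))
    }
  }
  list(inj = inj, cl = cl)
}

# per-subvolume active reactions: support closure over species that can
# ever be present (initially present, diffusible, clamped or injected
# there, or producible from supported reactants)
.activeReactions <- function(network, init, stimuli, mesh) {
  sv <- mesh@subvolumes
  spn <- network@species$name
  re <- network@reactions
  S <- network@stoich
  sup <- init@counts > 0
  sup[, network@species$D > 0] <- TRUE
  for (st in stimuli) {
    si <- match(st@species, spn)
    tg <- if (length(st@targets)) match(st@targets, sv$id)
    else seq_len(nrow(sv))
    sup[tg, si] <- TRUE
  }
  sigs <- apply(sup, 1, paste, collapse = "")
  uniq <- !duplicated(sigs)
  lists <- list()
  for (u in which(uniq)) {
    s <- sup[u, ]
    repeat {
      ok <- s[re$r1] & (is.na(re$r2) | s[ifelse(is.na(re$r2), 1L, re$r2)])
      prod <- rowSums(S[, ok, drop = FALSE] > 0) > 0
      if (!any(prod & !s)) break
      s <- s | prod
    }
    ok <- s[re$r1] & (is.na(re$r2) | s[ifelse(is.na(re$r2), 1L, re$r2)])
    lists[[sigs[u]]] <- which(ok) - 1L
  }
  act <- lists[sigs]
  list(ptr = as.integer(c(0L, cumsum(lengths(act)))),
       idx = as.integer(unlist(act, use.names = FALSE)))
}

#' Run the stochastic tau-leap reaction-diffusion engine
#'
#' Alternates a reaction leap and a diffusion leap each time step, applies
#' stimuli (injections add molecules; clamps reset counts each step), and
#' records group-aggregated counts at the recording interval.  Runs are
#' bit-reproducible for a fixed seed.
#'
#' @param mesh a \linkS4class{Mesh}
#' @param network a \linkS4class{ReactionNetwork} (after
#'   \code{\link{applyConfig}} if a configuration applies)
#' @param init an \linkS4class{InitialState} (integer counts)
#' @param stimuli list of \linkS4class{StimulusTrain} objects
#' @param T run length (s)
#' @param engine settings from \code{\link{engineConfig}}
#' @param recordInterval recording interval (s)
#' @param groups recording aggregation: "region", "axial", "total", or a
#'   named list of subvolume-id vectors
#' @param seed RNG seed (set before the run for reproducibility)
#' @return a \linkS4class{Trajectory} (counts per group and species)
#' @export
simulateStochastic <- function(mesh, network, init, stimuli = list(),
                               T = 1, engine = engineConfig(),
                               recordInterval = 0.1, groups = "region",
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sv <- mesh@subvolumes
  spn <- network@species$name
  stopifnot(ncol(init@counts) == length(spn), nrow(init@counts) == nrow(sv))

  rp <- .prepReactions(network, mesh)
  geo <- .diffGeometry(mesh)
  dOn <- which(network@species$D > 0)
  dSpec <- dOn - 1L
  dRate <- network@species$D[dOn]

  # diffusion cap: per-species max hop rate
  kmax <- vapply(dRate, function(D) {
    if (!length(geo$g)) 0 else max(D * geo$g)
  }, 0)
  dt <- engine$dt
  adaptive <- FALSE
  substeps <- rep(1L, length(dSpec))
  if (engine$dtMode == "fixed") {
    if (any(kmax * dt >= 0.1)) {
      bad <- which.max(kmax)
      stop("diffusion hop probability >= 0.1 at dt = ", dt, " for species ",
           spn[dOn[bad]], " (max hop rate ", signif(kmax[bad], 4),
           " /s); reduce dt")
    }
  } else if (any(kmax > 0)) {
    # auto/adaptive on a mesh: fixed dt from the cap, substepping the
    # fastest species
    dt <- min(engine$maxHopP * engine$substepLimit / kmax[kmax > 0])
    dt <- min(dt, engine$dtMax)
    substeps <- pmax(1L, ceiling(kmax * dt / engine$maxHopP))
    adaptive <- FALSE
  } else {
    adaptive <- engine$dtMode %in% c("auto", "adaptive")
  }

  recTimes <- seq(0, T, by = recordInterval)
  rg <- .recordGroups(mesh, groups)
  stim <- .prepStimuli(stimuli, mesh, network)

  act <- .activeReactions(network, init, stimuli, mesh)

  out <- cpp_tauleap(t(init@counts),
                     rp$r1, rp$r2, rp$need1, rp$need2, rp$selfPair,
                     rp$sPtr, rp$sIdx, rp$sVal, rp$cmat,
                     act$ptr, act$idx,
                     geo$ptr, geo$idx, geo$g,
                     as.integer(dSpec), dRate, as.integer(substeps),
                     as.integer(stim$inj$spec), as.integer(stim$inj$ptr),
                     as.integer(stim$inj$sub), stim$inj$rate,
                     stim$inj$on, stim$inj$off, as.integer(stim$inj$pulsePtr),
                     as.integer(stim$cl$spec), as.integer(stim$cl$ptr),
                     as.integer(stim$cl$sub), stim$cl$count,
                     stim$cl$on, stim$cl$off, as.integer(stim$cl$pulsePtr),
                     dt, T, recTimes, rg$groupOf, nrow(rg$groups),
                     adaptive, engine$eps, engine$dtMin, engine$dtMax)

  counts <- array(out$rec, dim = c(length(recTimes), nrow(rg$groups),
                                   length(spn)))
  new("Trajectory", time = recTimes, counts = counts, groups = rg$groups,
      species = spn, engine = "stochastic",
      meta = list(seed = seed, dt = dt, steps = out$steps,
                  substeps = substeps,
                  finalCounts = t(out$counts)))
}
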