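# Deterministic mass-action engine: the ODE oracle for the stochastic
# simulator and the desk-scale substitute for long spatial runs.
#
# Concentrations (nM) per compartment evolve under mass action over the
# elementary reactions plus inter-compartment fluxes k_hop * c (the
# continuum analog of the diffusion leap).  A stiff solver (lsodes, with
# internally estimated Jacobian sparsity) integrates piecewise between
# stimulus event times; clamps reset the state at segment starts and zero
# the clamped derivatives, injections enter as square-wave source terms.

# segment table from stimuli; rapid pulse trains (gap < smoothGap) are
# merged into an equivalent continuous influx for the ODE engine
.stimulusSegments <- function(stimuli, T, smoothGap = 0.05) {
  ev <- c(0, T)
  acts <- list()
  for (k in seq_along(stimuli)) {
    st <- stimuli[[k]]
    if (!length(st@onsets)) next
    on <- sort(st@onsets)
    off <- on + st@duration
    scale <- rep(1, length(on))
    if (st@mode == "injection" && length(on) > 1) {
      # merge each rapid-pulse cluster into a single pulse at the original
      # rate lasting the cluster's total on-time: total influx and the
      # influx rate (hence the concentration scale seen by cooperative
      # calcium chemistry) are both preserved; only the envelope shortens
      cl <- cumsum(c(1, diff(on) - st@duration >= smoothGap))
      onM <- offM <- numeric(max(cl))
      for (g in seq_len(max(cl))) {
        sel <- cl == g
        onM[g] <- min(on[sel])
        offM[g] <- onM[g] + sum(off[sel] - on[sel])
      }
      on <- onM; off <- offM; scale <- rep(1, max(cl))
    }
    for (p in seq_along(on)) {
      acts[[length(acts) + 1]] <- list(stim = k, on = on[p], off = off[p],
                                       scale = scale[p])
      ev <- c(ev, on[p], off[p])
    }
  }
  ev <- sort(unique(pmin(pmax(ev, 0), T)))
  list(events = ev, acts = acts)
}

#' Run the deterministic (mass-action ODE) engine on a mesh
#'
#' @param mesh a \linkS4class{Mesh} (possibly coarsened, or a single
#'   well-mixed compartment from \code{\link{buildWellMixed}})
#' @param network a \linkS4class{ReactionNetwork}
#' @param init an \linkS4class{InitialState} (expectations; integer counts
#'   also accepted) or a counts matrix
#' @param stimuli list of \linkS4class{StimulusTrain} objects
#' @param T run length (s)
#' @param recordInterval recording interval (s)
#' @param groups recording aggregation (see
#'   \code{\link{simulateStochastic}})
#' @param rtol,atol solver tolerances (relative; absolute in nM)
#' @return a \linkS4class{Trajectory} (group-aggregated counts, engine
#'   "deterministic")
#' @export
runDeterministic <- function(mesh, network, init, stimuli = list(),
                             T = 1, recordInterval = 0.5,
                             groups = "region",
                             rtol = 1e-6, atol = 1e-3) {
  sv <- mesh@subvolumes
  spn <- network@species$name
  ncomp <- nrow(sv)
  nspec <- length(spn)
  counts <- if (is(init, "InitialState")) init@counts else init
  stopifnot(nrow(counts) == ncomp, ncol(counts) == nspec)
  conc <- counts / (sv$volume * .NAV)

  re <- network@reactions
  S <- network@stoich
  nreact <- nrow(re)
  nz <- lapply(seq_len(nreact), function(r) which(S[, r] != 0L))
  sPtr <- as.integer(c(0L, cumsum(vapply(nz, length, 1L))))
  sIdx <- as.integer(unlist(nz, use.names = FALSE) - 1L)
  sVal <- as.numeric(unlist(lapply(seq_len(nreact),
                                   function(r) S[nz[[r]], r]),
                            use.names = FALSE))
  r1 <- as.integer(re$r1 - 1L)
  r2 <- as.integer(ifelse(is.na(re$r2), -1L, re$r2 - 1L))
  kvec <- re$rate

  cp <- mesh@couplings
  if (nrow(cp)) {
    ia <- match(cp$a, sv$id) - 1L
    ib <- match(cp$b, sv$id) - 1L
    g <- cp$area / cp$dist
    gOverVa <- g / sv$volume[ia + 1L]
    gOverVb <- g / sv$volume[ib + 1L]
  } else {
    ia <- ib <- integer(0); gOverVa <- gOverVb <- numeric(0)
  }
  dOn <- which(network@species$D > 0)
  dSpec <- as.integer(dOn - 1L)
  dRate <- network@species$D[dOn]

  seg <- .stimulusSegments(stimuli, T)
  recTimes <- seq(0, T, by = recordInterval)

  # exact Jacobian sparsity: species pairs coupled by a reaction within a
  # compartment, same-species pairs across couplings, and the diagonal
  inz <- local({
    pr <- list()
    for (r in seq_len(nreact)) {
      rows <- nz[[r]]
      cols <- unique(c(re$r1[r], re$r2[r]))
      cols <- cols[!is.na(cols)]
      pr[[r]] <- expand.grid(i = rows, j = cols)
    }
    pr <- if (length(pr)) unique(do.call(rbind, pr))
    else data.frame(i = integer(0), j = integer(0))
    n <- ncomp * nspec
    # per-compartment reaction coupling
    i1 <- as.vector(outer(seq_len(ncomp), (pr$i - 1L) * ncomp, "+"))
    j1 <- as.vector(outer(seq_len(ncomp), (pr$j - 1L) * ncomp, "+"))
    # diffusion coupling (off-diagonal, both directions)
    if (length(ia) && length(dSpec)) {
      sOff <- dSpec * ncomp
      i2 <- as.vector(outer(ia + 1L, sOff, "+"))
      j2 <- as.vector(outer(ib + 1L, sOff, "+"))
    } else i2 <- j2 <- integer(0)
    m <- unique(cbind(c(i1, i2, j2, seq_len(n)),
                      c(j1, j2, i2, seq_len(n))))
    m[order(m[, 2], m[, 1]), , drop = FALSE]
  })

  y <- as.vector(conc)
  recorded <- matrix(NA_real_, length(recTimes), length(y))
  if (recTimes[1] == 0) recorded[1, ] <- y

  emptySrc <- numeric(0)
  for (si in seq_len(length(seg$events) - 1)) {
    t0 <- seg$events[si]; t1 <- seg$events[si + 1]
    if (t1 - t0 <= 1e-12) next
    # active stimuli in (t0, t1)
    src <- NULL
    clampIdx <- integer(0)
    for (a in seg$acts) {
      if (a$on >= t1 - 1e-12 || a$off <= t0 + 1e-12) next
      st <- stimuli[[a$stim]]
      sidx <- match(st@species, spn)
      tg <- if (length(st@targets)) match(st@targets, sv$id)
      else seq_len(ncomp)
      if (st@mode == "injection") {
        if (is.null(src)) src <- numeric(length(y))
        molPerS <- st@level * 1000 * a$scale
        src[(sidx - 1L) * ncomp + tg] <-
          src[(sidx - 1L) * ncomp + tg] + molPerS / (sv$volume[tg] * .NAV)
      } else {
        idx <- (sidx - 1L) * ncomp + tg
        y[idx] <- st@level
        clampIdx <- c(clampIdx, idx - 1L)
      }
    }
    tt <- sort(unique(c(t0, recTimes[recTimes > t0 + 1e-12 &
                                       recTimes < t1 - 1e-12], t1)))
    sol <- deSolve::lsodes(
      y = y, times = tt,
      func = function(t, y, p) {
        list(cpp_rhs(y, ncomp, nspec, r1, r2, sPtr, sIdx, sVal, kvec,
                     ia, ib, gOverVa, gOverVb, dSpec, dRate,
                     if (is.null(src)) emptySrc else src,
                     as.integer(clampIdx)))
      },
      parms = NULL, rtol = rtol, atol = atol,
      sparsetype = "sparseusr", inz = inz,
      lrw = max(20L * nrow(inz), 100000L))
    if (attr(sol, "istate")[1] < 0)
      stop("ODE solver failure in segment [", t0, ", ", t1, "] (istate ",
           attr(sol, "istate")[1], ")")
    hit <- match(round(tt, 9), round(recTimes, 9))
    ok <- !is.na(hit)
    recorded[hit[ok], ] <- sol[ok, -1, drop = FALSE]
    y <- as.numeric(sol[nrow(sol), -1])
  }

  # aggregate to groups (counts, to match the stochastic trajectory)
  rg <- .recordGroups(mesh, groups)
  ngroup <- nrow(rg$groups)
  agg <- matrix(0, ncomp, ngroup)
  agg[cbind(seq_len(ncomp), rg$groupOf + 1L)] <- sv$volume * .NAV
  outCounts <- array(0, dim = c(length(recTimes), ngroup, nspec))
  for (s in seq_len(nspec)) {
    concTS <- recorded[, (s - 1L) * ncomp + seq_len(ncomp), drop = FALSE]
    outCounts[, , s] <- concTS %*% agg
  }
  new("Trajectory", time = recTimes, counts = outCounts,
      groups = rg$groups, species = spn, engine = "deterministic",
      meta = list(rtol = rtol, atol = atol,
                  finalCounts = matrix(y, ncomp, nspec,
                                       dimnames = list(NULL, spn)) *
                    sv$volume * .NAV))
}

#' Run the well-mixed deterministic engine
#'
#' Pools the initial state over the whole morphology and integrates the
#' full network as a single stiff ODE system.
#'
#' @param network a \linkS4class{ReactionNetwork}
#' @param init an \linkS4class{InitialState} on the well-mixed mesh, or
#'   NULL to build the default basal state
#' @param stimuli,T,recordInterval,rtol,atol see
#'   \code{\link{runDeterministic}}
#' @param volume total volume (um^3) when \code{init} is NULL
#' @return a \linkS4class{Trajectory}
#' @export
runWellMixed <- function(network, init = NULL, stimuli = list(), T = 1,
                         recordInterval = 0.5, rtol = 1e-6, atol = 1e-3,
                         volume = NULL) {
  mesh <- if (is.null(volume)) buildWellMixed() else buildWellMixed(volume)
  if (is.null(init))
    init <- initialState(mesh, network, stochastic = FALSE)
  runDeterministic(mesh, network, init, stimuli, T, recordInterval,
                   groups = "total", rtol = rtol, atol = atol)
}
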