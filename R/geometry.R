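# Subvolume meshes.
#
# The short morphology is a 7.75 um dendrite (0.6 um wide x 0.4 um deep)
# discretized into 62 axial x 5 lateral cuboids of 0.12 x 0.125 x 0.4 um^3
# (310 subvolumes); the lateral edge rows are the submembrane region, which
# reproduces the submembrane:cytosol volume ratio of a cylinder with a 70 nm
# shell.  Four spines (neck 0.2 um dia., head 0.6 um dia., 0.1 um slices)
# attach to the top submembrane row.  Diffusion is 2-D in the dendrite plane
# and 1-D along the spine axis.  The long morphology is a 22.8 um dendrite
# of 114 x 3 cuboids (0.2 x 0.2 x 0.4 um^3, 342 subvolumes) with 12 evenly
# spaced spines and no submembrane region.

.spineSlices <- function(neckLength) {
  nNeck <- round(neckLength / 0.1)
  vNeck <- pi * 0.1^2 * 0.1
  vHead <- pi * 0.3^2 * 0.1
  data.frame(
    slot = c(if (nNeck) paste0("neck", seq_len(nNeck)), "head1", "head2", "psd"),
    region = c(rep("neck", nNeck), "head", "head", "psd"),
    volume = c(rep(vNeck, nNeck), vHead, vHead, vHead),
    area = c(rep(pi * 0.1^2, nNeck), rep(pi * 0.3^2, 3))[seq_len(nNeck + 3)],
    stringsAsFactors = FALSE)
}

.buildDendriteMesh <- function(nAxial, nLateral, dx, dy, dz, spineAxial,
                               spineLateral, neckLength, submembrane,
                               focalSpine = 2, focalN = NULL,
                               type = "short") {
  # the focal submembrane block mirrors the total spine-head cytosol
  # volume, so focal anchoring reproduces both the global and the local
  # concentrations of the spine-anchored pools
  if (is.null(focalN))
    focalN <- round(length(spineAxial) * 2 * pi * 0.3^2 * 0.1 /
                      (dx * dy * dz))
  nD <- nAxial * nLateral
  i <- rep(seq_len(nAxial), nLateral)        # axial index
  j <- rep(seq_len(nLateral), each = nAxial) # lateral index
  sv <- data.frame(
    id = seq_len(nD) - 1L,
    region = ifelse(submembrane & (j == 1 | j == nLateral),
                    "dend.sub", "dend.cyt"),
    x = (i - 0.5) * dx, y = (j - 0.5) * dy, z = 0,
    volume = dx * dy * dz,
    spine = NA_integer_,
    stringsAsFactors = FALSE)

  idx <- function(ii, jj) (jj - 1L) * nAxial + ii  # 1-based row index
  cp <- list()
  # axial neighbors
  a <- which(i < nAxial)
  cp[[1]] <- data.frame(a = sv$id[a], b = sv$id[a + 1L],
                        area = dy * dz, dist = dx)
  # lateral neighbors
  a <- which(j < nLateral)
  cp[[2]] <- data.frame(a = sv$id[a], b = sv$id[a + nAxial],
                        area = dx * dz, dist = dy)

  # focal submembrane block beneath the focal spine (bottom row)
  if (submembrane && length(spineAxial) >= focalSpine) {
    ctr <- spineAxial[focalSpine]
    span <- (ctr - (focalN - 1) %/% 2):(ctr + focalN %/% 2)
    sv$region[idx(span, 1L)] <- "dend.sub.focal"
  }

  spines <- list()
  nextId <- nD
  for (s in seq_along(spineAxial)) {
    sl <- .spineSlices(neckLength)
    ids <- nextId + seq_len(nrow(sl)) - 1L
    attach1 <- idx(spineAxial[s], spineLateral)   # 1-based
    zTop <- dz / 2
    zc <- zTop + 0.05 + 0.1 * (seq_len(nrow(sl)) - 1)
    svS <- data.frame(
      id = ids, region = sl$region,
      x = sv$x[attach1], y = sv$y[attach1], z = zc,
      volume = sl$volume, spine = s, stringsAsFactors = FALSE)
    sv <- rbind(sv, svS)
    # dendrite -> first spine subvolume
    cp[[length(cp) + 1]] <- data.frame(
      a = sv$id[attach1], b = ids[1], area = sl$area[1], dist = zTop + 0.05)
    if (nrow(sl) > 1) {
      # along the spine: contact area is the smaller cross-section
      aUp <- pmin(sl$area[-nrow(sl)], sl$area[-1])
      cp[[length(cp) + 1]] <- data.frame(
        a = ids[-length(ids)], b = ids[-1], area = aUp, dist = 0.1)
    }
    spines[[s]] <- ids
    nextId <- nextId + nrow(sl)
  }
  names(spines) <- paste0("spine", seq_along(spineAxial))

  cp <- do.call(rbind, cp)
  new("Mesh", subvolumes = sv, couplings = cp, spines = spines,
      meta = list(type = type, neckLength = neckLength,
                  nAxial = nAxial, nLateral = nLateral,
                  dx = dx, spineAxial = spineAxial, coarse = FALSE))
}

#' Build the short (7.75 um, four-spine) dendrite mesh
#'
#' @param neckLength spine neck length in um: 0, 0.3 (default) or 1.0
#' @return a \linkS4class{Mesh} with 310 dendritic cuboids plus, per spine,
#'   neck slices (3 at the default neck), 2 head slices and 1 PSD slice.
#' @examples
#' mesh <- buildShortDendrite()
#' mesh
#' @export
buildShortDendrite <- function(neckLength = 0.3) {
  if (!neckLength %in% c(0, 0.3, 1.0))
    stop("unsupported neck length: ", neckLength)
  # spines evenly spaced at 1/5..4/5 of the 62-subvolume length, top row
  spineAxial <- round(62 * (1:4) / 5)
  .buildDendriteMesh(62, 5, dx = 0.125, dy = 0.12, dz = 0.4,
                     spineAxial = spineAxial, spineLateral = 5,
                     neckLength = neckLength, submembrane = TRUE,
                     type = "short")
}

#' Build the long (22.8 um, twelve-spine) dendrite mesh
#'
#' Used for the spatial-gradient scenarios; nothing is anchored in the
#' dendrite, so there is no submembrane region and the subvolumes are the
#' coarser 0.2 x 0.2 x 0.4 um^3 cuboids.
#'
#' @return a \linkS4class{Mesh} with 342 dendritic cuboids and 12 spines
#' @export
buildLongDendrite <- function() {
  spineAxial <- round((1:12 - 0.5) * 114 / 12 + 0.5)
  .buildDendriteMesh(114, 3, dx = 0.2, dy = 0.2, dz = 0.4,
                     spineAxial = spineAxial, spineLateral = 3,
                     neckLength = 0.3, submembrane = FALSE,
                     type = "long")
}

#' Per-molecule diffusion hop rate between coupled subvolumes
#'
#' Finite-volume coupling: a molecule with diffusion constant D hops from a
#' subvolume of volume V across a contact of area A at distance d with rate
#' k = D * A / (V * d).  Anchored species (D = 0) never hop.  The formula
#' satisfies detailed balance: k_ab * V_a = k_ba * V_b.
#'
#' @param D diffusion constant (um^2/s)
#' @param area contact area (um^2)
#' @param dist center-to-center distance (um)
#' @param sourceVolume volume of the source subvolume (um^3)
#' @return hop rate (s^-1 per molecule)
#' @export
hopRate <- function(D, area, dist, sourceVolume) {
  if (any(D < 0)) stop("D must be >= 0")
  if (any(area <= 0) || any(dist <= 0) || any(sourceVolume <= 0))
    stop("area, dist and sourceVolume must be > 0")
  D * area / (sourceVolume * dist)
}

#' Total volume per region
#' @param mesh a \linkS4class{Mesh}
#' @return named numeric vector of summed volumes (um^3)
#' @export
regionVolumes <- function(mesh) {
  tapply(mesh@subvolumes$volume, mesh@subvolumes$region, sum)
}

#' Serialize a mesh to structured text (JSON)
#'
#' @param mesh a \linkS4class{Mesh}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeMesh <- function(mesh, path) {
  obj <- list(subvolumes = mesh@subvolumes, couplings = mesh@couplings,
              spines = mesh@spines, meta = mesh@meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a mesh serialized by \code{writeMesh}
#' @param path file written by \code{\link{writeMesh}}
#' @return a \linkS4class{Mesh}
#' @export
readMesh <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv <- as.data.frame(obj$subvolumes)
  sv$spine <- as.integer(sv$spine)
  sv$id <- as.integer(sv$id)
  spines <- lapply(obj$spines, as.integer)
  meta <- obj$meta
  meta$spineAxial <- as.integer(meta$spineAxial)
  new("Mesh", subvolumes = sv, couplings = as.data.frame(obj$couplings),
      spines = spines, meta = meta)
}

#' Coarsen a mesh by merging subvolumes
#'
#' Merges axial blocks of dendritic subvolumes (separately within each
#' region tag) and, optionally, the slices within each spine compartment
#' type.  Volumes add; merged couplings use the summed crossing areas and
#' the distance between volume-weighted centers.  Used by the desk-scale
#' deterministic presets; the coarse mesh is flagged in \code{meta}.
#'
#' @param mesh a \linkS4class{Mesh}
#' @param axialFactor number of axial slices merged into one block
#' @param mergeLateral merge lateral rows within a region tag (default TRUE)
#' @param mergeSpine merge neck slices and head slices (PSD kept separate)
#' @param mergePSD also merge the PSD slice into the head (coarsest
#'   presets only; PSD-resident species then occupy the merged head)
#' @return a coarser \linkS4class{Mesh}; \code{meta$parent} maps each
#'   original subvolume id to its merged group id.
#' @export
coarsenMesh <- function(mesh, axialFactor = 2, mergeLateral = TRUE,
                        mergeSpine = TRUE, mergePSD = FALSE) {
  sv <- mesh@subvolumes
  if (mergePSD) sv$region[sv$region == "psd"] <- "head"
  dx <- mesh@meta$dx
  blk <- ceiling(pmax(1, ceiling(sv$x / dx)) / axialFactor)
  # lateral merge keeps the two submembrane sides apart (they are not
  # adjacent); only contiguous same-region rows merge
  dend <- is.na(sv$spine)
  midY <- if (any(dend)) mean(range(sv$y[dend])) else 0
  side <- ifelse(sv$region == "dend.cyt", "c",
                 ifelse(sv$y <= midY, "lo", "hi"))
  lat <- if (mergeLateral) paste(sv$region, side) else
    paste(sv$region, sv$y)
  key <- ifelse(is.na(sv$spine),
                paste0("d.", lat, ".", blk),
                paste0("s", sv$spine, ".",
                       if (mergeSpine) sv$region else paste0(sv$region, sv$z)))
  grp <- match(key, unique(key))

  vol <- as.vector(tapply(sv$volume, grp, sum))
  wmean <- function(v) as.vector(tapply(v * sv$volume, grp, sum)) / vol
  x <- wmean(sv$x); y <- wmean(sv$y); z <- wmean(sv$z)
  region <- as.vector(tapply(sv$region, grp, `[`, 1))
  spine <- as.vector(tapply(sv$spine, grp, `[`, 1))

  nsv <- data.frame(id = seq_along(vol) - 1L, region = region,
                    x = x, y = y, z = z, volume = vol,
                    spine = as.integer(spine), stringsAsFactors = FALSE)

  cp <- mesh@couplings
  ga <- grp[match(cp$a, sv$id)]
  gb <- grp[match(cp$b, sv$id)]
  cross <- ga != gb
  lo <- pmin(ga, gb)[cross]; hi <- pmax(ga, gb)[cross]
  keyC <- paste(lo, hi)
  keyF <- factor(keyC, levels = unique(keyC))
  areaSum <- as.vector(tapply(cp$area[cross], keyF, sum))
  u <- !duplicated(keyC)
  la <- lo[u]; lb <- hi[u]
  d <- sqrt((x[la] - x[lb])^2 + (y[la] - y[lb])^2 + (z[la] - z[lb])^2)
  ncp <- data.frame(a = la - 1L, b = lb - 1L, area = areaSum, dist = d)

  spines <- lapply(mesh@spines, function(ids) {
    unique(grp[match(ids, sv$id)]) - 1L
  })
  meta <- mesh@meta
  meta$coarse <- TRUE
  meta$axialFactor <- axialFactor
  meta$dx <- dx * axialFactor
  meta$parent <- grp - 1L
  new("Mesh", subvolumes = nsv, couplings = ncp, spines = spines,
      meta = meta)
}

#' Build a single well-mixed compartment mesh
#'
#' One subvolume holding a given total volume; used for pooled (well-mixed)
#' runs such as the bath-application validations.
#'
#' @param volume total volume (um^3); defaults to the short-dendrite
#'   morphology volume.
#' @return a \linkS4class{Mesh} with one subvolume and no couplings
#' @export
buildWellMixed <- function(volume = sum(buildShortDendrite()@subvolumes$volume)) {
  sv <- data.frame(id = 0L, region = "dend.cyt", x = 0, y = 0, z = 0,
                   volume = volume, spine = NA_integer_)
  new("Mesh", subvolumes = sv,
      couplings = data.frame(a = integer(0), b = integer(0),
                             area = numeric(0), dist = numeric(0)),
      spines = list(),
      meta = list(type = "wellmixed", neckLength = NA, coarse = FALSE,
                  dx = 1, spineAxial = integer(0)))
}
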