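# Reaction-table parsing and network assembly.
#
# The table dialect mirrors a printed rate table: one row per entry with
# an equation string and up to three rate constants.  Reversible rows expand
# to two elementary reactions, enzyme rows (E + S <-> ES -> E + P) to three
# (bind, unbind, catalyze).  "2*X" marks a lumped pair: the propensity is
# first order in X but two molecules are consumed or released (used for the
# paired calcium sites of calmodulin and the cAMP pairs binding PKA).
# "A + A" is a true self pair with propensity proportional to n(n-1)/2.

.parseSide <- function(txt, rowLab) {
  toks <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("empty reaction side in row '", rowLab, "'")
  stoich <- rep(1L, length(toks))
  lumped <- grepl("^2\\*", toks)
  stoich[lumped] <- 2L
  toks[lumped] <- sub("^2\\*", "", toks[lumped])
  data.frame(species = toks, stoich = stoich, stringsAsFactors = FALSE)
}

.aggSide <- function(side) {
  # merge duplicate species; remember whether a true self pair was written
  agg <- tapply(side$stoich, side$species, sum)
  selfPair <- anyDuplicated(side$species) > 0
  list(species = names(agg), stoich = as.integer(agg), selfPair = selfPair,
       nterms = nrow(side))
}

.parseEquation <- function(eq, rowLab) {
  # returns list(type, lhs, mid, rhs) of parsed sides
  revSplit <- strsplit(eq, "<->", fixed = TRUE)[[1]]
  if (length(revSplit) == 2) {
    rest <- strsplit(revSplit[2], "->", fixed = TRUE)[[1]]
    if (length(rest) == 2) {
      list(type = "enzyme",
           lhs = .parseSide(revSplit[1], rowLab),
           mid = .parseSide(rest[1], rowLab),
           rhs = .parseSide(rest[2], rowLab))
    } else if (length(rest) == 1) {
      list(type = "reversible",
           lhs = .parseSide(revSplit[1], rowLab),
           mid = NULL,
           rhs = .parseSide(rest[1], rowLab))
    } else stop("cannot parse equation in row '", rowLab, "'")
  } else if (length(revSplit) == 1) {
    irr <- strsplit(eq, "->", fixed = TRUE)[[1]]
    if (length(irr) != 2) stop("cannot parse equation in row '", rowLab, "'")
    list(type = "irreversible",
         lhs = .parseSide(irr[1], rowLab),
         mid = NULL,
         rhs = .parseSide(irr[2], rowLab))
  } else stop("cannot parse equation in row '", rowLab, "'")
}

.numOrNA <- function(x) {
  x <- trimws(x)
  if (!length(x) || !nzchar(x)) return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("malformed rate constant '", x, "'")
  v
}

# one elementary reaction from aggregated reactant/product sides
.elementary <- function(reac, prod, rate, rowIdx, step, specIdx, rowLab) {
  # nterms counts propensity order: "2*X" is one term, "A + A" is two
  if (reac$nterms > 2)
    stop("row '", rowLab, "': reactions above second order are not supported")
  ri <- specIdx[reac$species]
  if (anyNA(ri)) stop("row '", rowLab, "': unknown species token '",
                      reac$species[is.na(ri)][1], "'")
  pi <- specIdx[prod$species]
  if (anyNA(pi)) stop("row '", rowLab, "': unknown species token '",
                      prod$species[is.na(pi)][1], "'")
  selfPair <- reac$selfPair
  if (length(ri) == 2) {
    r1 <- ri[1]; r2 <- ri[2]; ord <- 2L
  } else if (selfPair) {
    r1 <- ri[1]; r2 <- ri[1]; ord <- 2L
  } else {
    r1 <- ri[1]; r2 <- NA_integer_; ord <- 1L
  }
  if (rate < 0) stop("row '", rowLab, "': negative rate")
  d <- structure(numeric(length(specIdx)), names = names(specIdx))
  d[reac$species] <- d[reac$species] - reac$stoich
  d[prod$species] <- d[prod$species] + prod$stoich
  list(r1 = r1, r2 = r2, order = ord, selfPair = selfPair && length(ri) == 1,
       rate = rate, row = rowIdx, step = step, delta = d)
}

#' Load the reaction network from its definition files
#'
#' Reads the reaction-table and species-table text files, expands every row
#' into irreversible elementary mass-action reactions, and assembles the
#' stoichiometric matrix and subunit-composition matrix.  Exact duplicate
#' elementary reactions (a catalytic step printed under two rows) are
#' deduplicated.
#'
#' @param reactionFile path to the reaction table (see
#'   \code{system.file("extdata", "reactions.tsv", package = "spineRD")}).
#' @param speciesFile path to the species table (diffusion constants and
#'   subunit compositions).
#' @return a \linkS4class{ReactionNetwork}
#' @examples
#' net <- loadNetwork()
#' net
#' @export
loadNetwork <- function(
    reactionFile = system.file("extdata", "reactions.tsv", package = "spineRD"),
    speciesFile = system.file("extdata", "species.tsv", package = "spineRD")) {

  spTab <- utils::read.delim(speciesFile, comment.char = "#",
                             stringsAsFactors = FALSE)
  if (anyDuplicated(spTab$name)) stop("duplicate species in species table")
  specIdx <- structure(seq_len(nrow(spTab)), names = spTab$name)

  # composition matrix
  comp <- lapply(spTab$composition, function(s) {
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(as.integer(vapply(kv, `[`, "", 2)),
                    vapply(kv, `[`, "", 1))
  })
  moieties <- sort(unique(unlist(lapply(comp, names))))
  compM <- matrix(0L, nrow(spTab), length(moieties),
                  dimnames = list(spTab$name, moieties))
  for (i in seq_along(comp)) compM[i, names(comp[[i]])] <- comp[[i]]

  lines <- readLines(reactionFile)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rowLines <- lines[keep]
  rows <- data.frame(raw = rowLines, stringsAsFactors = FALSE)

  elems <- list()
  rowMeta <- vector("list", length(rowLines))
  for (i in seq_along(rowLines)) {
    f <- strsplit(rowLines[i], "\t", fixed = TRUE)[[1]]
    eq <- trimws(f[1])
    kf <- .numOrNA(f[2])
    kb <- .numOrNA(if (length(f) >= 3) f[3] else "")
    kcat <- .numOrNA(if (length(f) >= 4) f[4] else "")
    flag <- trimws(if (length(f) >= 5) f[5] else "")
    if (is.na(kf)) stop("row '", eq, "': missing kf")
    if (!is.na(kcat) && is.na(kb))
      stop("row '", eq, "': kcat requires kb (enzyme triple)")
    p <- .parseEquation(eq, eq)
    if (p$type == "enzyme" && is.na(kcat))
      stop("row '", eq, "': enzyme equation requires kcat")
    if (p$type != "enzyme" && !is.na(kcat))
      stop("row '", eq, "': kcat given but equation has no complex product")
    rowMeta[[i]] <- list(eq = eq, type = p$type, kf = kf, kb = kb,
                         kcat = kcat, flag = flag)
    lhs <- .aggSide(p$lhs)
    rhs <- .aggSide(p$rhs)
    if (p$type == "irreversible") {
      elems[[length(elems) + 1]] <-
        .elementary(lhs, rhs, kf, i, "fwd", specIdx, eq)
    } else if (p$type == "reversible") {
      elems[[length(elems) + 1]] <-
        .elementary(lhs, rhs, kf, i, "fwd", specIdx, eq)
      if (!is.na(kb))
        elems[[length(elems) + 1]] <-
          .elementary(rhs, lhs, kb, i, "back", specIdx, eq)
    } else {
      mid <- .aggSide(p$mid)
      elems[[length(elems) + 1]] <-
        .elementary(lhs, mid, kf, i, "fwd", specIdx, eq)
      elems[[length(elems) + 1]] <-
        .elementary(mid, lhs, kb, i, "back", specIdx, eq)
      elems[[length(elems) + 1]] <-
        .elementary(mid, rhs, kcat, i, "cat", specIdx, eq)
    }
  }

  rows$type <- vapply(rowMeta, function(m) m$type, "")
  rows$kf <- vapply(rowMeta, function(m) m$kf, 0)
  rows$kb <- vapply(rowMeta, function(m) if (is.na(m$kb)) NA_real_ else m$kb, 0)
  rows$kcat <- vapply(rowMeta, function(m) if (is.na(m$kcat)) NA_real_ else m$kcat, 0)
  rows$flag <- vapply(rowMeta, function(m) m$flag, "")
  rows$equation <- vapply(rowMeta, function(m) m$eq, "")

  # deduplicate identical elementary reactions
  sig <- vapply(elems, function(e)
    paste(e$r1, e$r2, e$rate, paste(e$delta, collapse = ","), sep = "|"), "")
  keepE <- !duplicated(sig)
  elems <- elems[keepE]

  re <- data.frame(
    r1 = vapply(elems, function(e) e$r1, 1L),
    r2 = vapply(elems, function(e) e$r2, 1L),
    order = vapply(elems, function(e) e$order, 1L),
    selfPair = vapply(elems, function(e) isTRUE(e$selfPair), TRUE),
    rate = vapply(elems, function(e) e$rate, 0),
    row = vapply(elems, function(e) e$row, 1L),
    step = vapply(elems, function(e) e$step, ""),
    stringsAsFactors = FALSE)

  S <- matrix(0L, nrow(spTab), length(elems),
              dimnames = list(spTab$name, NULL))
  for (j in seq_along(elems)) S[, j] <- as.integer(elems[[j]]$delta)

  new("ReactionNetwork",
      species = spTab[, c("name", "D", "composition")],
      composition = compM, reactions = re, stoich = S, rows = rows)
}

#' Expand an enzyme row into its three elementary steps
#'
#' An enzyme-catalyzed row E + S <-> ES -> E + P with rates (kf, kb, kcat)
#' yields binding E + S -> ES at kf, unbinding ES -> E + S at kb and
#' catalysis ES -> E + P at kcat.  A pure binding row (no kcat) passes
#' through unchanged as forward/backward steps.
#'
#' @param network a \linkS4class{ReactionNetwork}
#' @param row row index into \code{network@rows}
#' @return data.frame of the elementary reactions generated by the row
#' @export
expandEnzymeSteps <- function(network, row) {
  network@reactions[network@reactions$row == row, , drop = FALSE]
}

#' Conserved moieties of the network
#'
#' Integer-weighted species combinations whose totals are invariant under
#' every elementary reaction, built from the per-species subunit
#' compositions and verified against the stoichiometric matrix: every
#' returned weight vector lies in the left null space of S.
#'
#' @param network a \linkS4class{ReactionNetwork}
#' @param verify if TRUE (default), drop (with a warning) any declared
#'   moiety that is not exactly conserved.
#' @return named list of integer weight vectors (species-length)
#' @export
conservedMoieties <- function(network, verify = TRUE) {
  out <- lapply(colnames(network@composition), function(m) {
    w <- network@composition[, m]
    storage.mode(w) <- "numeric"
    w
  })
  names(out) <- colnames(network@composition)
  if (verify && nrow(network@reactions)) {
    ok <- vapply(out, function(w)
      max(abs(crossprod(w, network@stoich))) == 0, TRUE)
    if (!all(ok))
      warning("moieties not conserved by the reaction list: ",
              paste(names(out)[!ok], collapse = ", "))
    out <- out[ok]
  }
  out
}

#' Deterministic-to-stochastic rate conversion
#'
#' Converts a macroscopic rate constant into the per-subvolume propensity
#' constant.  Unimolecular rates are volume independent; bimolecular rates
#' (nM^-1 s^-1) become c = kf * 1e9 / (N_A * V_litres) so that the
#' propensity is c * nA * nB events/s in a subvolume of volume V um^3.
#'
#' @param kf rate constant (s^-1 or nM^-1 s^-1)
#' @param order reaction order, 1 or 2
#' @param V subvolume volume (um^3)
#' @return propensity constant (s^-1 per molecule pair for order 2)
#' @export
stochasticRate <- function(kf, order, V) {
  if (!all(order %in% 1:2)) stop("order must be 1 or 2")
  if (any(V <= 0)) stop("V must be > 0")
  ifelse(order == 1, kf, kf / (.NAV * V))
}

#' Serialize a network's reaction table
#'
#' Writes the reaction rows back to a file, bit-exactly reproducing the
#' definition file the network was loaded from (comments excluded when
#' \code{comments = FALSE}).
#'
#' @param network a \linkS4class{ReactionNetwork}
#' @param path output file
#' @param sourceFile optionally, the original file whose comment lines are
#'   interleaved to reproduce it byte-for-byte
#' @return invisibly, the lines written
#' @export
writeReactionTable <- function(network, path, sourceFile = NULL) {
  if (!is.null(sourceFile)) {
    lines <- readLines(sourceFile)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    lines[keep] <- network@rows$raw
  } else {
    lines <- network@rows$raw
  }
  writeLines(lines, path)
  invisible(lines)
}

# ---- internal network editing used by SpatialConfig ----

.setDiffusion <- function(network, species, D) {
  i <- match(species, network@species$name)
  if (anyNA(i)) stop("unknown species: ",
                     paste(species[is.na(i)], collapse = ", "))
  network@species$D[i] <- D
  network
}

.dropReactionRows <- function(network, rowIdx) {
  keep <- !network@reactions$row %in% rowIdx
  network@reactions <- network@reactions[keep, , drop = FALSE]
  network@stoich <- network@stoich[, keep, drop = FALSE]
  network
}

# DARPP-32-containing species that normally diffuse
.d32Diffusible <- c("DARPP32", "DARPP32_PKAc", "p34DARPP32",
                    "p75DARPP32", "p75DARPP32_PKAc")
.d32PKABound <- c("DARPP32_PKAc", "p75DARPP32_PKAc")

#' Apply a spatial configuration's kinetic variants to the network
#'
#' Adjusts diffusion constants (dopamine slow-down, DARPP-32 freeze modes)
#' and removes the phosphoThr75/PKAc binding when blocked.
#'
#' @param network a \linkS4class{ReactionNetwork}
#' @param config a \linkS4class{SpatialConfig}
#' @return the modified network
#' @export
applyConfig <- function(network, config) {
  network <- .setDiffusion(network, "Da", config@dopamineD)
  if (config@d32DiffusionMode == "frozen")
    network <- .setDiffusion(network, .d32Diffusible, 0)
  if (config@d32DiffusionMode == "pka.bound.frozen")
    network <- .setDiffusion(network, .d32PKABound, 0)
  if (config@pT75PKABlock) {
    i1 <- match("p75DARPP32", network@species$name)
    i2 <- match("PKAc", network@species$name)
    re <- network@reactions
    tgt <- unique(re$row[(re$r1 %in% c(i1, i2)) & (re$r2 %in% c(i1, i2)) &
                           re$order == 2])
    # only the plain binding row (2 elementary reactions), not enzyme rows
    tgt <- tgt[network@rows$type[tgt] == "reversible"]
    network <- .dropReactionRows(network, tgt)
  }
  network
}
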