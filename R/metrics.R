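# Readouts: species-group aggregation, window statistics, fold changes,
# percent GluA1 phosphorylation, exponential gradient fits and the
# cAMP-vs-colocalization regression.

#' Standard species groups
#'
#' Weighted species sets for the reported readouts.  Phospho groups count
#' every species carrying the phosphosite (free and complexed);
#' \code{GluA1tot} and \code{D32tot} are the conserved moiety totals.
#'
#' @param network a \linkS4class{ReactionNetwork}
#' @return named list of numeric weight vectors (one weight per species)
#' @export
speciesGroups <- function(network) {
  spn <- network@species$name
  w0 <- stats::setNames(numeric(length(spn)), spn)
  pick <- function(sel, weight = 1) {
    w <- w0; w[sel] <- weight; w
  }
  pCaMKII <- c("CaMKIIp", "CaMKIIpCamCa4", "CaMKIIpPP1", "CaMKIIpCamCa4PP1",
               "GluA1_CaMKIIp", "GluA1_CaMKIIpCamCa4",
               "pS845GluA1_CaMKIIp", "pS845GluA1_CaMKIIpCamCa4")
  list(
    pThr34 = pick(grepl("^p34DARPP32", spn)),
    pThr75 = pick(grepl("^p75DARPP32", spn)),
    pS845 = pick(grepl("^pS845", spn)),
    pS831 = pick(grepl("pS831", spn) & !grepl("^pS845", spn)) +
      pick(grepl("^pS845pS831", spn)),
    phosphoCaMKII = pick(intersect(pCaMKII, spn)) +
      pick(intersect("pComplex", spn)),
    GluA1tot = stats::setNames(as.numeric(network@composition[, "GluA1"]), spn),
    D32tot = stats::setNames(as.numeric(network@composition[, "DARPP32"]), spn),
    cAMP = pick("cAMP"),
    PKAc = pick("PKAc"),
    Da = pick("Da"),
    Ca = pick("Ca"))
}

# time series (nM) of a weighted species group over selected groups
.groupSeries <- function(trajectory, weights, regions = NULL) {
  gsel <- if (is.null(regions)) seq_len(nrow(trajectory@groups))
  else {
    m <- which(trajectory@groups$name %in% regions)
    if (!length(m)) stop("no matching recording groups: ",
                         paste(regions, collapse = ", "))
    m
  }
  w <- weights[trajectory@species]
  w[is.na(w)] <- 0
  cnt <- trajectory@counts[, gsel, , drop = FALSE]
  num <- apply(cnt, 1, function(m) sum(m %*% w))
  vol <- sum(trajectory@groups$volume[gsel])
  num / (vol * .NAV)
}

#' Concentration time series of a species group
#'
#' @param trajectory a \linkS4class{Trajectory}
#' @param weights named weight vector (see \code{\link{speciesGroups}}) or
#'   a species name
#' @param regions recording-group names to pool (NULL = whole morphology)
#' @return numeric vector (nM) along \code{recordTimes(trajectory)}
#' @export
groupConcentration <- function(trajectory, weights, regions = NULL) {
  if (is.character(weights)) {
    w <- stats::setNames(numeric(length(trajectory@species)),
                         trajectory@species)
    w[weights] <- 1
    weights <- w
  }
  .groupSeries(trajectory, weights, regions)
}

#' Window average (or integral) of a species group
#'
#' Trapezoidal time average of the group concentration over [t0, t1] in
#' the selected regions; \code{mode = "sum"} returns the time integral
#' (summed activity, nM s).
#'
#' @param trajectory a \linkS4class{Trajectory}
#' @param weights group weights or species name
#' @param t0,t1 window bounds (s)
#' @param regions recording groups to pool (NULL = all)
#' @param mode "average" or "sum"
#' @return scalar (nM, or nM s for "sum")
#' @export
windowAverage <- function(trajectory, weights, t0, t1, regions = NULL,
                          mode = c("average", "sum")) {
  mode <- match.arg(mode)
  tt <- trajectory@time
  if (t0 >= t1) stop("empty window")
  sel <- tt >= t0 - 1e-9 & tt <= t1 + 1e-9
  if (sum(sel) < 2) stop("window [", t0, ",", t1,
                         "] contains fewer than 2 records")
  y <- groupConcentration(trajectory, weights, regions)[sel]
  x <- tt[sel]
  integral <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  if (mode == "sum") integral else integral / (x[length(x)] - x[1])
}

#' Fold change of a species group relative to a baseline window
#'
#' @param trajectory a \linkS4class{Trajectory}
#' @param weights group weights or species name
#' @param baselineWindow c(t0, t1) of the baseline average
#' @param responseMode "peak" (maximum) or "window" (average)
#' @param responseWindow c(t0, t1) of the response
#' @param regions recording groups to pool
#' @return response statistic divided by baseline average
#' @export
foldChange <- function(trajectory, weights, baselineWindow,
                       responseMode = c("peak", "window"),
                       responseWindow, regions = NULL) {
  responseMode <- match.arg(responseMode)
  base <- windowAverage(trajectory, weights, baselineWindow[1],
                        baselineWindow[2], regions)
  if (base <= 0) stop("zero baseline")
  resp <- if (responseMode == "peak") {
    tt <- trajectory@time
    sel <- tt >= responseWindow[1] - 1e-9 & tt <= responseWindow[2] + 1e-9
    max(groupConcentration(trajectory, weights, regions)[sel])
  } else {
    windowAverage(trajectory, weights, responseWindow[1], responseWindow[2],
                  regions)
  }
  resp / base
}

#' Percent of GluA1 phosphorylated on Ser845
#'
#' 100 x (all Ser845-phosphorylated forms, phosphorylated or not on
#' Ser831, including phosphatase/kinase complexes) / total GluA1 moiety.
#'
#' @param trajectory a \linkS4class{Trajectory}
#' @param network a \linkS4class{ReactionNetwork}
#' @param regions recording groups to pool (default: whole morphology)
#' @return numeric vector (percent) along the trajectory times
#' @export
percentPhosphoGluA1 <- function(trajectory, network, regions = NULL) {
  gr <- speciesGroups(network)
  num <- .groupSeries(trajectory, gr$pS845, regions)
  den <- .groupSeries(trajectory, gr$GluA1tot, regions)
  if (all(den <= 0)) stop("no GluA1 in the selected regions")
  100 * num / den
}

#' Fit a single-exponential spatial gradient
#'
#' Nonlinear least squares of C(x) = C0 exp(-x/lambda) + b.  The baseline
#' b can be fixed (recommended for cAMP, at the run's basal concentration)
#' or fitted.  A flat profile is flagged non-identifiable instead of
#' returning a decay length.
#'
#' @param positions axial positions (um)
#' @param values concentrations (nM)
#' @param baseline fixed baseline (nM), or NULL to fit it
#' @return object of class "gradientFit": list with \code{lambda},
#'   \code{se}, \code{C0}, \code{b}, \code{identifiable}, \code{fit}
#' @export
fitExponentialGradient <- function(positions, values, baseline = NULL) {
  if (length(positions) < 5) stop("need at least 5 positions")
  o <- order(positions)
  x <- positions[o]; y <- values[o]
  rng <- max(y) - min(y)
  if (rng <= 1e-9 * max(abs(y), 1e-12) || rng == 0) {
    return(structure(list(lambda = NA_real_, se = NA_real_,
                          C0 = NA_real_, b = mean(y),
                          identifiable = FALSE, fit = NULL),
                     class = "gradientFit"))
  }
  bFix <- !is.null(baseline)
  b0 <- if (bFix) baseline else min(y)
  # log-linear starting values on the positive excess (guarded: fall back
  # to range-based starts when the tail is noise dominated)
  exc <- pmax(y - b0, rng * 1e-6)
  lmfit <- stats::lm(log(exc) ~ x)
  slope <- stats::coef(lmfit)[2]
  lam0 <- if (is.finite(slope) && slope < -1e-6) -1 / slope
  else max(x) / 3
  lam0 <- min(max(lam0, 1e-2), 10 * max(x))
  C00 <- max(y[1] - b0, rng)
  fit <- try(if (bFix) {
    minpack.lm::nlsLM(y ~ C0 * exp(-x / lambda) + b0,
                      start = list(C0 = C00, lambda = lam0),
                      lower = c(0, 1e-3), control = list(maxiter = 200))
  } else {
    minpack.lm::nlsLM(y ~ C0 * exp(-x / lambda) + b,
                      start = list(C0 = C00, lambda = lam0, b = b0),
                      lower = c(0, 1e-3, -Inf),
                      control = list(maxiter = 200))
  }, silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(lambda = NA_real_, se = NA_real_, C0 = NA_real_,
                          b = b0, identifiable = FALSE, fit = NULL),
                     class = "gradientFit"))
  }
  cf <- summary(fit)$coefficients
  if (!all(c("C0", "lambda") %in% rownames(cf))) {
    return(structure(list(lambda = NA_real_, se = NA_real_, C0 = NA_real_,
                          b = b0, identifiable = FALSE, fit = NULL),
                     class = "gradientFit"))
  }
  structure(list(lambda = cf["lambda", 1], se = cf["lambda", 2],
                 C0 = cf["C0", 1],
                 b = if (bFix) b0 else cf["b", 1],
                 identifiable = TRUE, fit = fit),
            class = "gradientFit")
}

#' @export
print.gradientFit <- function(x, ...) {
  if (!x$identifiable) cat("gradientFit: non-identifiable (flat profile)\n")
  else cat("gradientFit: lambda =", signif(x$lambda, 4), "+/-",
           signif(x$se, 3), "um, C0 =", signif(x$C0, 4),
           "nM, b =", signif(x$b, 4), "nM\n")
  invisible(x)
}

#' Axial concentration profile of a species group
#'
#' Window-averaged concentration per axial recording group (dendritic
#' bins), with positions measured from the release site.
#'
#' @param trajectory a \linkS4class{Trajectory} recorded with
#'   \code{groups = "axial"}
#' @param weights group weights or species name
#' @param t0,t1 averaging window (s)
#' @param releaseX axial position of the release site (um)
#' @return data.frame with \code{x} (distance, um) and \code{value} (nM)
#' @export
axialProfile <- function(trajectory, weights, t0, t1, releaseX = 0) {
  gsel <- which(startsWith(trajectory@groups$name, "x"))
  if (!length(gsel)) stop("trajectory was not recorded with axial groups")
  vals <- vapply(gsel, function(g)
    windowAverage(trajectory, weights, t0, t1,
                  regions = trajectory@groups$name[g]), 0)
  data.frame(x = abs(trajectory@groups$x[gsel] - releaseX), value = vals)
}

#' Regression of PKA activity on local cAMP and colocalization
#'
#' Ordinary least squares of per-run PKA activity on the run's local cAMP
#' concentration (continuous) and a colocalization indicator (binary),
#' mirroring the analysis of the 2x2 anchoring design.
#'
#' @param runs data.frame with columns \code{cAMP}, \code{coloc} (0/1 or
#'   logical) and \code{activity}
#' @return list with \code{r.squared}, \code{p} (named vector of predictor
#'   p values) and the fitted \code{model}
#' @export
activityRegression <- function(runs) {
  stopifnot(all(c("cAMP", "coloc", "activity") %in% names(runs)))
  if (nrow(runs) < 4) stop("need at least 4 runs")
  runs$coloc <- as.numeric(runs$coloc)
  fit <- stats::lm(activity ~ cAMP + coloc, data = runs)
  sm <- summary(fit)
  qrr <- qr(stats::model.matrix(fit))
  if (qrr$rank < 3) {
    cf <- sm$coefficients
    p <- stats::setNames(rep(NA_real_, 2), c("cAMP", "coloc"))
    p[rownames(cf)[-1]] <- cf[-1, 4]
  } else {
    p <- sm$coefficients[c("cAMP", "coloc"), 4]
  }
  list(r.squared = sm$r.squared, p = p, model = fit)
}
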