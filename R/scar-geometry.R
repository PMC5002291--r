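# 8-connected component labels of a logical mask.
.label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nextId <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    nextId <- nextId + 1L
    stack <- list(c(r, c))
    lab[r, c] <- nextId
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1L] + dr; cc <- p[2L] + dc
        if ((dr != 0L || dc != 0L) && rr >= 1L && rr <= nr &&
            cc >= 1L && cc <= nc && mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nextId
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Moore-neighbor boundary trace of one 8-connected component.
# Returns the perimeter in mm. `wAx`/`wDiag` weight axial and diagonal
# chain steps; the default Kulpa weights (0.948, 1.340/sqrt(2) relative to
# the step length) correct the systematic overestimate of smooth contours
# by the plain Freeman chain.
.tracePerimeter <- function(comp, mmML, mmAP, wAx, wDiag) {
  pts <- which(comp, arr.ind = TRUE)
  if (nrow(pts) == 1L) return(2 * (mmML + mmAP))
  nr <- nrow(comp); nc <- ncol(comp)
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && comp[r, c]
  # clockwise Moore neighborhood starting at W
  dirs <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  # start: topmost, then leftmost pixel; its W and N neighbors are outside
  ord <- order(pts[, 1L], pts[, 2L])
  start <- pts[ord[1L], ]
  cur <- start
  entry <- 1L  # index in dirs of the backtrack (outside) neighbor: W
  per <- 0
  startEntry <- NA_integer_
  maxSteps <- 8L * nrow(pts) + 8L
  steps <- 0L
  repeat {
    found <- FALSE
    k <- entry
    for (s in 1:8) {
      k <- k %% 8L + 1L
      rr <- cur[1L] + dirs[k, 1L]; cc <- cur[2L] + dirs[k, 2L]
      if (inside(rr, cc)) {
        diag <- dirs[k, 1L] != 0L && dirs[k, 2L] != 0L
        per <- per + if (diag) wDiag * sqrt(mmML^2 + mmAP^2)
                     else wAx * (if (dirs[k, 1L] == 0L) mmML else mmAP)
        # new backtrack: the previously checked (outside) neighbor,
        # expressed relative to the new current pixel
        prev <- if (s == 1L) entry else (k - 2L) %% 8L + 1L
        pr <- cur[1L] + dirs[prev, 1L]; pc <- cur[2L] + dirs[prev, 2L]
        cur <- c(rr, cc)
        entry <- which(dirs[, 1L] == pr - cur[1L] & dirs[, 2L] == pc - cur[2L])
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel (cannot happen here)
    steps <- steps + 1L
    if (cur[1L] == start[1L] && cur[2L] == start[2L]) {
      if (is.na(startEntry)) startEntry <- entry
      else if (entry == startEntry) break
      if (steps > 1L && entry == 1L) break
    }
    if (steps >= maxSteps) break
  }
  per
}

.chainWeights <- function(weights = c("kulpa", "freeman")) {
  weights <- match.arg(weights)
  if (weights == "kulpa") c(ax = 0.948, diag = 1.340 / sqrt(2)) else
    c(ax = 1, diag = 1)
}

# Descriptors of one compartment sub-mask. Rows/cols are canvas indices of
# the compartment; mm coordinates are relative to the compartment centre,
# anterior positive, medial (+column) positive.
.compartmentDescriptors <- function(worn, mmML, mmAP, wAx, wDiag) {
  empty <- !any(worn)
  if (empty) {
    return(list(area = 0, perimeter = 0, centroid_ml = 0, centroid_ap = 0,
                ml_stretch = 0, ap_stretch = 0, i_ap = 0, i_ml = 0,
                shape_factor = 0, aspect_ratio = 0, solidity = 0,
                empty = TRUE))
  }
  pxArea <- mmML * mmAP
  idx <- which(worn, arr.ind = TRUE)
  rowc <- (1 + nrow(worn)) / 2
  colc <- (1 + ncol(worn)) / 2
  xml <- (idx[, 2L] - colc) * mmML
  yap <- (rowc - idx[, 1L]) * mmAP
  area <- nrow(idx) * pxArea
  cml <- mean(xml); cap <- mean(yap)
  mlStretch <- (max(idx[, 2L]) - min(idx[, 2L]) + 1L) * mmML
  apStretch <- (max(idx[, 1L]) - min(idx[, 1L]) + 1L) * mmAP
  iAp <- sum((xml - cml)^2) * pxArea
  iMl <- sum((yap - cap)^2) * pxArea
  lab <- .label8(worn)
  per <- sum(vapply(seq_len(max(lab)), function(id)
    .tracePerimeter(lab == id, mmML, mmAP, wAx, wDiag), numeric(1L)))
  list(area = area, perimeter = per, centroid_ml = cml, centroid_ap = cap,
       ml_stretch = mlStretch, ap_stretch = apStretch,
       i_ap = iAp, i_ml = iMl,
       shape_factor = if (per > 0) 4 * pi * area / per^2 else 0,
       aspect_ratio = if (apStretch > 0) mlStretch / apStretch else 0,
       solidity = area / (mlStretch * apStretch),
       empty = FALSE)
}

#' Geometric wear-scar descriptors
#'
#' Computes, separately for the medial and lateral compartments of a
#' right-normalized binary image (medial = right canvas half), the
#' geometric parameters used to characterize wear scars: area (worn-pixel
#' count times pixel area, mm^2), perimeter (corrected 8-connected
#' boundary chain length, mm), centroid (mm offsets from the compartment
#' centre, anterior and medial positive), bounding-box ML/AP stretches
#' (mm), second area moments about the centroid axes (mm^4), circularity
#' shape factor 4*pi*A/P^2 (1 for a disk), stretch aspect ratio and
#' solidity (area over bounding-box area), plus a whole-component
#' symmetry index in [0, 1] combining medial/lateral area balance with
#' AP-centroid alignment. An empty compartment yields zeroed descriptors
#' and \code{empty = TRUE} rather than an error.
#'
#' @param image a standardized, right-normalized [WearScarImage-class].
#' @param weights perimeter chain weighting: \code{"kulpa"} (default;
#'   0.948 axial / 1.340 diagonal, asymptotically unbiased on smooth
#'   contours) or \code{"freeman"} (1 and sqrt(2)).
#' @return one-row data.frame with \code{med_*} and \code{lat_*} columns
#'   and \code{symmetry_index}.
#' @export
computeDescriptors <- function(image, weights = c("kulpa", "freeman")) {
  stopifnot(is(image, "WearScarImage"))
  w <- .chainWeights(match.arg(weights))
  px <- image@pixels
  nc <- ncol(px)
  half <- nc %/% 2L
  mmML <- image@mmPerPxML; mmAP <- image@mmPerPxAP
  lat <- .compartmentDescriptors(px[, seq_len(half), drop = FALSE] == 0L,
                                 mmML, mmAP, w["ax"], w["diag"])
  med <- .compartmentDescriptors(px[, (half + 1L):nc, drop = FALSE] == 0L,
                                 mmML, mmAP, w["ax"], w["diag"])
  sym <- if (med$empty && lat$empty) NA_real_ else {
    areaBal <- 1 - abs(med$area - lat$area) / (med$area + lat$area)
    apSpan <- nrow(px) * mmAP
    apBal <- 1 - min(abs(med$centroid_ap - lat$centroid_ap) / apSpan, 1)
    areaBal * apBal
  }
  out <- c(stats::setNames(med, paste0("med_", names(med))),
           stats::setNames(lat, paste0("lat_", names(lat))),
           list(symmetry_index = sym))
  as.data.frame(out)
}

#' Descriptor table for a list of images
#'
#' @param images list of standardized right-normalized
#'   [WearScarImage-class] objects.
#' @param weights see [computeDescriptors()].
#' @return data.frame, one row per component, keyed by
#'   \code{component_id}.
#' @export
descriptorTable <- function(images, weights = "kulpa") {
  rows <- lapply(images, function(im) {
    cbind(data.frame(component_id = componentId(im),
                     stringsAsFactors = FALSE),
          computeDescriptors(im, weights = weights))
  })
  do.call(rbind, rows)
}

#' One-way ANOVA of a descriptor across clusters
#'
#' Clusters with a single member carry no within-group variance and are
#' excluded before fitting; at least two usable clusters are required.
#'
#' @param table data.frame holding the descriptor and cluster columns.
#' @param descriptor name of the numeric descriptor column.
#' @param cluster name of the cluster id column (default
#'   \code{"cluster"}).
#' @return list with \code{F, p, df1, df2, nGroups}.
#' @export
anovaByCluster <- function(table, descriptor, cluster = "cluster") {
  stopifnot(descriptor %in% names(table), cluster %in% names(table))
  y <- table[[descriptor]]
  g <- table[[cluster]]
  keep <- g %in% names(which(table(g) >= 2L))
  y <- y[keep]; g <- factor(g[keep])
  if (nlevels(g) < 2L)
    stop("fewer than 2 clusters with >= 2 members")
  if (stats::var(y) == 0)  # no variation at all: F = 0 by convention
    return(list(F = 0, p = 1, df1 = nlevels(g) - 1L,
                df2 = length(y) - nlevels(g), nGroups = nlevels(g)))
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1L]]
  list(F = s[["F value"]][1L], p = s[["Pr(>F)"]][1L],
       df1 = s[["Df"]][1L], df2 = s[["Df"]][2L], nGroups = nlevels(g))
}

#' Per-cluster regression of a descriptor on a covariate
#'
#' Ordinary least squares of the descriptor on the covariate within each
#' cluster, keeping only clusters with more than three components carrying
#' a non-missing covariate value (the study inclusion rule). A row is
#' flagged when the association is both significant (p < 0.05) and
#' meaningful (R^2 > 0.4).
#'
#' @param table data.frame with descriptor, covariate and cluster columns.
#' @param descriptor,covariate column names.
#' @param cluster cluster id column name (default \code{"cluster"}).
#' @param pThreshold,r2Threshold flagging thresholds (defaults 0.05, 0.4).
#' @return data.frame with one row per included cluster: \code{cluster,
#'   descriptor, covariate, n, slope, intercept, p, r2, flagged}; clusters
#'   failing the inclusion rule are skipped (attribute
#'   \code{"skipped"} lists them).
#' @export
covariateRegression <- function(table, descriptor, covariate,
                                cluster = "cluster",
                                pThreshold = 0.05, r2Threshold = 0.4) {
  stopifnot(all(c(descriptor, covariate, cluster) %in% names(table)))
  ids <- sort(unique(table[[cluster]]))
  rows <- list(); skipped <- integer(0)
  for (k in ids) {
    sub <- table[table[[cluster]] == k &
                   !is.na(table[[covariate]]) & !is.na(table[[descriptor]]), ]
    if (nrow(sub) <= 3L) { skipped <- c(skipped, k); next }
    fit <- stats::lm(sub[[descriptor]] ~ sub[[covariate]])
    sm <- summary(fit)
    slope <- stats::coef(fit)[2L]
    pv <- sm$coefficients[2L, 4L]
    r2 <- sm$r.squared
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = k, descriptor = descriptor, covariate = covariate,
      n = nrow(sub), slope = unname(slope),
      intercept = unname(stats::coef(fit)[1L]),
      p = pv, r2 = r2,
      flagged = (pv < pThreshold) && (r2 > r2Threshold),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), descriptor = character(0),
               covariate = character(0), n = integer(0), slope = numeric(0),
               intercept = numeric(0), p = numeric(0), r2 = numeric(0),
               flagged = logical(0))
  attr(out, "skipped") <- skipped
  out
}

#' Binomial cluster-enrichment tail probability
#'
#' Exact upper-tail probability \code{P(X >= k)} for
#' \code{X ~ Binomial(n, p)}, computed by direct summation of the
#' probability mass function. Used for the chance probability that
#' \code{k} of \code{n} simulator-tested components land in one cluster
#' when the success probability is the fraction of retrieved components
#' in that cluster.
#'
#' @param nTrials number of trials n (>= 0).
#' @param kSuccesses observed successes k, \code{0 <= k <= n}.
#' @param pSuccess success probability in \code{[0, 1]}.
#' @return \code{P(X >= k)}.
#' @examples
#' binomialEnrichment(6, 5, 9 / 75)
#' @export
binomialEnrichment <- function(nTrials, kSuccesses, pSuccess) {
  if (nTrials < 0 || kSuccesses < 0 || kSuccesses > nTrials)
    stop("require 0 <= kSuccesses <= nTrials")
  if (pSuccess < 0 || pSuccess > 1) stop("pSuccess must lie in [0, 1]")
  if (kSuccesses == 0) return(1)
  sum(stats::dbinom(kSuccesses:nTrials, nTrials, pSuccess))
}
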