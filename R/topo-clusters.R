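#' Compute the u-matrix of a map
#'
#' For every neuron, the mean Euclidean distance between its codebook
#' vector and those of its lattice-adjacent neurons (4-neighborhood);
#' corner neurons average over 2 neighbors, edge neurons over 3. Short
#' distances mean similar neurons: low-valued "valleys" are clusters and
#' high-valued "ridges" are cluster boundaries.
#'
#' @param model a [SOFMModel-class]; a warning is issued if untrained.
#' @return a [UMatrix-class].
#' @export
uMatrix <- function(model) {
  stopifnot(is(model, "SOFMModel"))
  if (!model@trained)
    warning("computing a u-matrix from an untrained model")
  nr <- model@gridRows; nc <- model@gridCols
  W <- model@codebook
  idx <- function(r, c) (r - 1L) * nc + c
  vals <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    w <- W[idx(r, c), ]
    nb <- list()
    if (r > 1L) nb <- c(nb, idx(r - 1L, c))
    if (r < nr) nb <- c(nb, idx(r + 1L, c))
    if (c > 1L) nb <- c(nb, idx(r, c - 1L))
    if (c < nc) nb <- c(nb, idx(r, c + 1L))
    nb <- unlist(nb)
    d <- sqrt(rowSums((W[nb, , drop = FALSE] -
                         matrix(w, length(nb), ncol(W), byrow = TRUE))^2))
    vals[r, c] <- mean(d)
  }
  new("UMatrix", values = vals)
}

# Label 4-connected components of a logical matrix; 0 elsewhere.
# Component ids are assigned in order of each component's minimum
# row-major cell index, so labeling is deterministic.
.labelComponents4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nextId <- 0L
  # row-major scan order
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    nextId <- nextId + 1L
    queue <- list(c(r, c))
    lab[r, c] <- nextId
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (d in list(c(p[1L] - 1L, p[2L]), c(p[1L] + 1L, p[2L]),
                     c(p[1L], p[2L] - 1L), c(p[1L], p[2L] + 1L))) {
        if (d[1L] >= 1L && d[1L] <= nr && d[2L] >= 1L && d[2L] <= nc &&
            mask[d[1L], d[2L]] && lab[d[1L], d[2L]] == 0L) {
          lab[d[1L], d[2L]] <- nextId
          queue <- c(queue, list(d))
        }
      }
    }
  }
  lab
}

#' Delineate clusters on the u-matrix
#'
#' Automates the customary visual reading of the color-coded u-matrix.
#' Two methods are provided, both deterministic:
#' \describe{
#'   \item{threshold}{neurons whose u-value is at or below
#'     \code{quantile(u, q)} become cluster seeds; 4-connected seed
#'     regions are the clusters, remaining neurons are ridge (label 0).}
#'   \item{watershed}{neurons are flooded in order of increasing u-value;
#'     a neuron touching no labeled basin opens a new one, a neuron
#'     touching several is a ridge unless all but one of those basins are
#'     shallower than \code{tol} above their minimum, in which case they
#'     merge.}
#' }
#' Cluster ids are contiguous from 1, ordered by each cluster's minimum
#' row-major neuron index.
#'
#' @param um a [UMatrix-class].
#' @param method \code{"threshold"} or \code{"watershed"}.
#' @param q quantile in \code{(0, 1]} for the threshold method.
#' @param tol merge tolerance for the watershed method; defaults to 10% of
#'   the u-value range.
#' @return a [ClusterMap-class].
#' @export
delineateClusters <- function(um, method = c("threshold", "watershed"),
                              q = 0.5, tol = NULL) {
  stopifnot(is(um, "UMatrix"))
  method <- match.arg(method)
  u <- um@values
  if (method == "threshold") {
    if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
    thr <- stats::quantile(u, q, names = FALSE)
    lab <- .labelComponents4(u <= thr)
  } else {
    if (is.null(tol)) tol <- diff(range(u)) * 0.1
    lab <- .watershedGrid(u, tol)
  }
  .asClusterMap(lab)
}

.asClusterMap <- function(lab) {
  ids <- unique(lab[lab > 0L])
  # relabel by minimum row-major neuron index
  labT <- t(lab)  # row-major order = column-major of the transpose
  minIdx <- vapply(ids, function(id) min(which(labT == id)), numeric(1L))
  ord <- ids[order(minIdx)]
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_along(ord)) out[lab == ord[k]] <- k
  new("ClusterMap", labels = out, nClusters = length(ord))
}

.watershedGrid <- function(u, tol) {
  nr <- nrow(u); nc <- ncol(u)
  # stable processing order: increasing u, ties by row-major index
  cells <- expand.grid(c = seq_len(nc), r = seq_len(nr))[, c("r", "c")]
  uu <- u[cbind(cells$r, cells$c)]
  ord <- order(uu, seq_len(nrow(cells)))
  lab <- matrix(0L, nr, nc)
  basinMin <- numeric(0)
  parent <- integer(0)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in ord) {
    r <- cells$r[k]; c <- cells$c[k]
    nbl <- integer(0)
    for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L)))
      if (d[1L] >= 1L && d[1L] <= nr && d[2L] >= 1L && d[2L] <= nc &&
          lab[d[1L], d[2L]] > 0L)
        nbl <- c(nbl, findRoot(lab[d[1L], d[2L]]))
    nbl <- sort(unique(nbl))
    if (length(nbl) == 0L) {
      id <- length(basinMin) + 1L
      basinMin[id] <- u[r, c]
      parent[id] <- id
      lab[r, c] <- id
    } else if (length(nbl) == 1L) {
      lab[r, c] <- nbl
    } else {
      # merge basins shallower than tol into the deepest neighbor basin,
      # but only when this neuron physically joins them (gets labeled);
      # if >= 2 deep basins meet here the neuron is a ridge and no merge
      # happens, keeping every cluster 4-connected
      deepest <- nbl[which.min(basinMin[nbl])]
      shallow <- setdiff(nbl[u[r, c] - basinMin[nbl] < tol], deepest)
      remaining <- setdiff(nbl, shallow)
      if (length(remaining) == 1L) {
        for (s in shallow) parent[s] <- deepest
        lab[r, c] <- deepest
      } else {
        lab[r, c] <- 0L
      }
    }
  }
  # resolve union-find roots
  out <- matrix(0L, nr, nc)
  pos <- lab > 0L
  out[pos] <- vapply(lab[pos], findRoot, integer(1L))
  out
}

#' Assign a component to an existing cluster structure
#'
#' Finds the best-matching unit of each input and returns that neuron's
#' cluster id; no learning occurs. When the BMU is a ridge neuron the id
#' of the nearest labeled neuron by lattice distance is used (ties resolve
#' to the lower cluster id, then the lower neuron index).
#'
#' @param model a trained [SOFMModel-class].
#' @param cmap a [ClusterMap-class] for the same lattice.
#' @param x input vector or samples x dimension matrix.
#' @return integer vector of cluster ids.
#' @export
assignCluster <- function(model, cmap, x) {
  stopifnot(is(model, "SOFMModel"), is(cmap, "ClusterMap"))
  if (cmap@nClusters < 1L) stop("cluster map has no clusters")
  nr <- model@gridRows; nc <- model@gridCols
  stopifnot(identical(dim(cmap@labels), c(nr, nc)))
  bmu <- findBMU(model, x)
  g <- .gridCoords(nr, nc)
  labVec <- as.vector(t(cmap@labels))  # row-major neuron order
  labeled <- which(labVec > 0L)
  vapply(bmu, function(b) {
    if (labVec[b] > 0L) return(labVec[b])
    d2 <- (g[labeled, 1L] - g[b, 1L])^2 + (g[labeled, 2L] - g[b, 2L])^2
    cand <- labeled[d2 == min(d2)]
    ids <- labVec[cand]
    min(ids)
  }, integer(1L))
}

#' Cluster composition by component source
#'
#' Cross-tabulates cluster assignments against the source labels and
#' reports, per cluster, the fraction of all retrieved components
#' (revision + postmortem) that fall in it — the quantity used to set the
#' success probability of the binomial co-clustering test.
#'
#' @param assignments integer cluster ids, one per component.
#' @param sources character vector of source labels (postmortem, revision,
#'   simulator).
#' @return data.frame with one row per cluster: counts per source,
#'   \code{total}, and \code{frac_retrieved}.
#' @export
compositionTable <- function(assignments, sources) {
  stopifnot(length(assignments) == length(sources))
  bad <- setdiff(unique(sources), .SOURCES)
  if (length(bad)) stop("unknown source label(s): ", paste(bad, collapse = ", "))
  ids <- sort(unique(assignments))
  nRetrTotal <- sum(sources %in% c("revision", "postmortem"))
  rows <- lapply(ids, function(k) {
    s <- sources[assignments == k]
    data.frame(cluster = k,
               revision = sum(s == "revision"),
               postmortem = sum(s == "postmortem"),
               simulator = sum(s == "simulator"),
               total = length(s),
               frac_retrieved = if (nRetrTotal > 0)
                 sum(s %in% c("revision", "postmortem")) / nRetrTotal else NA_real_)
  })
  do.call(rbind, rows)
}

#' Export a u-matrix as CSV and as a color-mapped PNG
#'
#' The PNG uses a light-to-dark ramp: light cells are valleys (clusters),
#' dark cells are ridges (boundaries).
#'
#' @param um a [UMatrix-class].
#' @param csvPath,pngPath output files (either may be NULL to skip).
#' @param scalePx integer magnification of the PNG.
#' @return invisibly, NULL.
#' @export
exportUMatrix <- function(um, csvPath = NULL, pngPath = NULL, scalePx = 16L) {
  stopifnot(is(um, "UMatrix"))
  if (!is.null(csvPath))
    utils::write.table(um@values, csvPath, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  if (!is.null(pngPath)) {
    v <- um@values
    rng <- range(v)
    z <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else v * 0
    img <- 1 - z  # light = valley, dark = ridge
    big <- img[rep(seq_len(nrow(img)), each = scalePx),
               rep(seq_len(ncol(img)), each = scalePx)]
    png::writePNG(big, pngPath)
  }
  invisible(NULL)
}

#' Export a cluster map as CSV
#'
#' One row per neuron: \code{neuron_row, neuron_col, cluster_id} (0 =
#' ridge).
#'
#' @param cmap a [ClusterMap-class].
#' @param path output CSV.
#' @return invisibly, the path.
#' @export
exportClusterMap <- function(cmap, path) {
  stopifnot(is(cmap, "ClusterMap"))
  lab <- cmap@labels
  df <- data.frame(neuron_row = rep(seq_len(nrow(lab)), times = ncol(lab)),
                   neuron_col = rep(seq_len(ncol(lab)), each = nrow(lab)),
                   cluster_id = as.vector(lab))
  df <- df[order(df$neuron_row, df$neuron_col), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
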