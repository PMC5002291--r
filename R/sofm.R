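#' Neighborhood-radius schedule
#'
#' Per-epoch radius, linearly interpolated from the initial to the final
#' radius over the given number of epochs.
#'
#' @param initial,final initial and final neighborhood radii (grid units);
#'   \code{initial >= final > 0}.
#' @param nEpochs number of epochs (>= 1).
#' @return numeric vector of per-epoch radii.
#' @export
radiusSchedule <- function(initial = 4, final = 1, nEpochs = 10L) {
  if (!(initial >= final && final > 0)) stop("require initial >= final > 0")
  if (nEpochs < 1L) stop("nEpochs must be >= 1")
  seq(initial, final, length.out = nEpochs)
}

#' Two-phase training schedule
#'
#' The customary rough/fine split: a rough phase shrinking the radius from
#' \code{initial} to \code{final}, then a fine phase holding the final
#' radius.
#'
#' @param initial,final radii as in [radiusSchedule()].
#' @param roughEpochs,fineEpochs epochs in each phase.
#' @return numeric vector of per-epoch radii.
#' @export
twoPhaseSchedule <- function(initial = 4, final = 1, roughEpochs = 10L,
                             fineEpochs = 40L) {
  c(radiusSchedule(initial, final, roughEpochs),
    rep(final, fineEpochs))
}

#' Learning-rate schedule (sequential training only)
#'
#' @param initial,final rates in \code{(0, 1]}, decayed linearly across
#'   epochs. The batch algorithm has no learning rate and ignores this.
#' @param nEpochs number of epochs.
#' @return numeric vector of per-epoch rates.
#' @export
learningRateSchedule <- function(initial = 0.5, final = 0.02, nEpochs = 10L) {
  if (any(c(initial, final) <= 0) || any(c(initial, final) > 1))
    stop("learning rates must lie in (0, 1]")
  seq(initial, final, length.out = nEpochs)
}

# Integer (row, col) lattice coordinates of neurons in row-major order.
.gridCoords <- function(rows, cols) {
  cbind(row = rep(seq_len(rows), each = cols),
        col = rep(seq_len(cols), times = rows))
}

# Squared grid distances between all neuron pairs (nm x nm).
.gridDist2 <- function(rows, cols) {
  g <- .gridCoords(rows, cols)
  outer(g[, 1L], g[, 1L], "-")^2 + outer(g[, 2L], g[, 2L], "-")^2
}

#' Initialize a self-organizing map
#'
#' @param rows,cols lattice dimensions (>= 1).
#' @param data numeric matrix (samples x dimensions); required for
#'   \code{mode = "sample"} and used for the value range in
#'   \code{mode = "uniform_random"}.
#' @param dim input dimension; inferred from \code{data} when supplied.
#' @param mode \code{"sample"} draws codebook vectors uniformly with
#'   replacement from the data rows; \code{"uniform_random"} draws each
#'   weight uniformly within the per-dimension data range (or [0, 1]).
#' @param seed integer seed; initialization is deterministic given it.
#' @param kernel neighborhood kernel for subsequent training.
#' @return an untrained [SOFMModel-class].
#' @export
sofmInit <- function(rows, cols, data = NULL, dim = NULL,
                     mode = c("sample", "uniform_random"), seed = 1L,
                     kernel = c("gaussian", "bubble")) {
  mode <- match.arg(mode)
  kernel <- match.arg(kernel)
  if (rows < 1L || cols < 1L) stop("grid dimensions must be >= 1")
  if (!is.null(data)) {
    data <- as.matrix(data)
    if (!is.null(dim) && dim != ncol(data))
      stop(sprintf("dim = %d does not match data dimension %d", dim, ncol(data)))
    dim <- ncol(data)
  }
  if (is.null(dim)) stop("supply data or dim")
  nm <- as.integer(rows) * as.integer(cols)
  cb <- withSeed(seed, {
    if (mode == "sample") {
      if (is.null(data)) stop("mode = 'sample' requires data")
      data[sample.int(nrow(data), nm, replace = TRUE), , drop = FALSE]
    } else {
      lo <- if (is.null(data)) rep(0, dim) else apply(data, 2L, min)
      hi <- if (is.null(data)) rep(1, dim) else apply(data, 2L, max)
      matrix(stats::runif(nm * dim), nm, dim) *
        matrix(hi - lo, nm, dim, byrow = TRUE) +
        matrix(lo, nm, dim, byrow = TRUE)
    }
  })
  dimnames(cb) <- NULL
  new("SOFMModel", gridRows = as.integer(rows), gridCols = as.integer(cols),
      codebook = cb, kernel = kernel, trained = FALSE,
      schedule = list(), trainingLog = numeric(0))
}

# Squared Euclidean distances samples x neurons; clamps fp negatives.
.dist2ToCodebook <- function(X, W) {
  d2 <- matrix(rowSums(X^2), nrow(X), nrow(W)) +
    matrix(rowSums(W^2), nrow(X), nrow(W), byrow = TRUE) -
    2 * tcrossprod(X, W)
  d2[d2 < 0] <- 0
  d2
}

#' Best-matching unit
#'
#' Index (row-major) of the neuron whose codebook vector has the smallest
#' Euclidean distance to the input; ties resolve to the lowest index.
#'
#' @param model a [SOFMModel-class].
#' @param x a vector of codebook dimension, or a samples x dimension
#'   matrix.
#' @return integer vector of neuron indices (one per sample).
#' @export
findBMU <- function(model, x) {
  stopifnot(is(model, "SOFMModel"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != ncol(model@codebook))
    stop(sprintf("input dimension %d does not match codebook dimension %d",
                 ncol(X), ncol(model@codebook)))
  d2 <- .dist2ToCodebook(X, model@codebook)
  max.col(-d2, ties.method = "first")
}

#' Neighborhood weights around a winning neuron
#'
#' Gaussian kernel \code{h(j) = exp(-d^2(j, bmu) / (2 r^2))} with \code{d}
#' the Euclidean lattice distance, so \code{h(bmu) = 1} and weights are
#' monotone non-increasing in distance; the bubble kernel is the indicator
#' \code{d <= r}.
#'
#' @param model a [SOFMModel-class].
#' @param bmu neuron index (row-major).
#' @param radius neighborhood radius, > 0.
#' @param kernel override of the model's kernel.
#' @return numeric vector of weights in \code{[0, 1]}, one per neuron.
#' @export
neighborhoodWeights <- function(model, bmu, radius, kernel = model@kernel) {
  stopifnot(is(model, "SOFMModel"))
  if (radius <= 0) stop("radius must be > 0")
  d2 <- .gridDist2(model@gridRows, model@gridCols)[, bmu]
  if (kernel == "gaussian") exp(-d2 / (2 * radius^2))
  else as.numeric(sqrt(d2) <= radius)
}

#' Train a self-organizing map
#'
#' Batch mode updates every codebook vector once per epoch to the
#' neighborhood-weighted mean of the data,
#' \code{w_j <- sum_i h(j, bmu(x_i)) x_i / sum_i h(j, bmu(x_i))};
#' neurons receiving zero total neighborhood mass in an epoch (possible
#' with the bubble kernel) keep their previous weights. Sequential mode
#' presents samples one at a time in a seeded random order per epoch and
#' applies \code{w_j <- w_j + alpha h (x - w_j)}. The quantization error
#' after each epoch is recorded in the training log.
#'
#' @param model an initialized [SOFMModel-class].
#' @param data samples x dimension matrix (>= 1 row).
#' @param radii per-epoch neighborhood radii, e.g. from
#'   [radiusSchedule()] or [twoPhaseSchedule()].
#' @param mode \code{"batch"} (default) or \code{"sequential"}.
#' @param lrSchedule per-epoch learning rates (sequential mode only); must
#'   match \code{length(radii)}. Ignored in batch mode.
#' @param seed integer seed driving the sample presentation order.
#' @return the trained [SOFMModel-class].
#' @export
sofmTrain <- function(model, data, radii = twoPhaseSchedule(),
                      mode = c("batch", "sequential"), lrSchedule = NULL,
                      seed = 1L) {
  stopifnot(is(model, "SOFMModel"))
  mode <- match.arg(mode)
  X <- as.matrix(data)
  if (nrow(X) < 1L) stop("training data is empty")
  if (ncol(X) != ncol(model@codebook))
    stop("data dimension does not match codebook dimension")
  nEpochs <- length(radii)
  if (mode == "sequential") {
    if (is.null(lrSchedule))
      lrSchedule <- learningRateSchedule(nEpochs = nEpochs)
    if (length(lrSchedule) != nEpochs)
      stop("lrSchedule length must match the radius schedule")
  }
  W <- model@codebook
  D2grid <- .gridDist2(model@gridRows, model@gridCols)
  qlog <- numeric(nEpochs)
  orders <- withSeed(seed, lapply(seq_len(nEpochs),
                                  function(e) sample.int(nrow(X))))
  for (e in seq_len(nEpochs)) {
    r <- radii[e]
    H <- if (model@kernel == "gaussian") exp(-D2grid / (2 * r^2))
         else (D2grid <= r^2) * 1
    if (mode == "batch") {
      bmu <- max.col(-.dist2ToCodebook(X, W), ties.method = "first")
      Hb <- H[, bmu, drop = FALSE]          # neurons x samples
      mass <- rowSums(Hb)
      Wnew <- Hb %*% X
      ok <- mass > 0
      Wnew[ok, ] <- Wnew[ok, , drop = FALSE] / mass[ok]
      Wnew[!ok, ] <- W[!ok, , drop = FALSE]
      W <- Wnew
    } else {
      alpha <- lrSchedule[e]
      for (i in orders[[e]]) {
        x <- X[i, ]
        d2 <- rowSums(W^2) - 2 * as.numeric(W %*% x) + sum(x^2)
        b <- which.min(d2)
        h <- H[, b]
        W <- W + alpha * h * (matrix(x, nrow(W), ncol(W), byrow = TRUE) - W)
      }
    }
    qlog[e] <- mean(sqrt(.rowMins(.dist2ToCodebook(X, W))))
  }
  dimnames(W) <- NULL
  model@codebook <- W
  model@trained <- TRUE
  model@schedule <- list(radii = radii, mode = mode,
                         lrSchedule = if (mode == "sequential") lrSchedule,
                         seed = as.integer(seed))
  model@trainingLog <- qlog
  model
}

.rowMins <- function(m) m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]

#' Quantization error
#'
#' Mean Euclidean distance between each sample and its best-matching
#' unit — the goodness-of-fit measure used to compare map configurations.
#'
#' @param model a [SOFMModel-class].
#' @param data samples x dimension matrix (non-empty).
#' @return mean BMU distance.
#' @export
quantizationError <- function(model, data) {
  stopifnot(is(model, "SOFMModel"))
  X <- as.matrix(data)
  if (nrow(X) < 1L) stop("data is empty")
  mean(sqrt(.rowMins(.dist2ToCodebook(X, model@codebook))))
}

#' Serialize a map to a flat text file
#'
#' Header lines carry the lattice dimensions, kernel, trained flag,
#' radius schedule and training log; the codebook follows as CSV rows with
#' full double precision, so [readSOFM()] round-trips exactly.
#'
#' @param model a [SOFMModel-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeSOFM <- function(model, path) {
  stopifnot(is(model, "SOFMModel"))
  con <- file(path, "wb")
  on.exit(close(con))
  num <- function(x) paste(sprintf("%.17g", x), collapse = ",")
  writeLines(c("scarSOM-SOFM-v1",
               sprintf("grid %d %d", model@gridRows, model@gridCols),
               sprintf("dim %d", ncol(model@codebook)),
               sprintf("kernel %s", model@kernel),
               sprintf("trained %d", as.integer(model@trained)),
               paste0("radii ", num(model@schedule$radii %||% numeric(0))),
               paste0("log ", num(model@trainingLog))), con)
  writeLines(apply(model@codebook, 1L, num), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname writeSOFM
#' @export
readSOFM <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "scarSOM-SOFM-v1") stop("not a scarSOM model file: ", path)
  grid <- as.integer(strsplit(lines[2L], " ")[[1L]][2:3])
  dimn <- as.integer(strsplit(lines[3L], " ")[[1L]][2L])
  kernel <- strsplit(lines[4L], " ")[[1L]][2L]
  trained <- as.logical(as.integer(strsplit(lines[5L], " ")[[1L]][2L]))
  parseNums <- function(line) {
    s <- sub("^[a-z]+ ?", "", line)
    if (nchar(s) == 0L) numeric(0) else as.numeric(strsplit(s, ",")[[1L]])
  }
  radii <- parseNums(lines[6L])
  qlog <- parseNums(lines[7L])
  cb <- t(vapply(lines[-(1:7)],
                 function(l) as.numeric(strsplit(l, ",")[[1L]]),
                 numeric(dimn), USE.NAMES = FALSE))
  new("SOFMModel", gridRows = grid[1L], gridCols = grid[2L], codebook = cb,
      kernel = kernel, trained = trained,
      schedule = if (length(radii)) list(radii = radii) else list(),
      trainingLog = qlog)
}
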