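#' @import methods
NULL

STD_ROWS <- 170L
STD_COLS <- 220L

.SIDES   <- c("left", "right", "unknown")
.SOURCES <- c("postmortem", "revision", "simulator", "unknown")

#' Binary wear-scar image of a tibial polyethylene insert
#'
#' Holds a standardized binary bitmap of the articulating surface of one
#' tibial insert, together with its pixel calibration and component-level
#' metadata. Pixels follow the worn/unworn convention used throughout the
#' package: \code{0} = black = worn, \code{1} = white = unworn. Rows run
#' anterior (row 1) to posterior; columns run lateral (column 1) to medial
#' on a right-side image.
#'
#' @slot pixels integer matrix of 0/1 values, rows x columns (AP x ML).
#' @slot mmPerPxML,mmPerPxAP calibration, millimetres per pixel along the
#'   medial-lateral (columns) and anterior-posterior (rows) axes.
#' @slot side implantation side: \code{"left"}, \code{"right"} or
#'   \code{"unknown"}.
#' @slot source retrieval source: \code{"postmortem"}, \code{"revision"},
#'   \code{"simulator"} or \code{"unknown"}.
#' @slot componentId component label.
#' @slot timeInHost months in host (\code{NA} if unknown).
#' @slot ageAtSurgery patient age at surgery, years (\code{NA} if unknown).
#'
#' @seealso [WearScarImage()] for the constructor, [standardizeImage()],
#'   [encodeImage()], [toRightSide()].
#' @exportClass WearScarImage
setClass("WearScarImage",
  representation(
    pixels       = "matrix",
    mmPerPxML    = "numeric",
    mmPerPxAP    = "numeric",
    side         = "character",
    source       = "character",
    componentId  = "character",
    timeInHost   = "numeric",
    ageAtSurgery = "numeric"
  ),
  prototype(
    mmPerPxML = 0.35, mmPerPxAP = 0.35,
    side = "unknown", source = "unknown", componentId = "",
    timeInHost = NA_real_, ageAtSurgery = NA_real_
  )
)

setValidity("WearScarImage", function(object) {
  px <- object@pixels
  if (!is.matrix(px) || length(px) == 0L)
    return("pixels must be a non-empty matrix")
  if (!all(px %in% c(0L, 1L)))
    return("pixels must contain only 0 (worn) and 1 (unworn)")
  if (length(object@mmPerPxML) != 1L || length(object@mmPerPxAP) != 1L ||
      object@mmPerPxML <= 0 || object@mmPerPxAP <= 0)
    return("calibration must be a positive scalar per axis")
  if (!(object@side %in% .SIDES)) return("invalid side label")
  if (!(object@source %in% .SOURCES)) return("invalid source label")
  TRUE
})

#' Construct a WearScarImage
#'
#' @param pixels binary matrix (rows = AP, columns = ML); any numeric matrix
#'   of 0/1 values is accepted and stored as integer.
#' @param mmPerPxML,mmPerPxAP calibration in mm per pixel (defaults 0.35).
#' @param side,source,componentId,timeInHost,ageAtSurgery metadata; see the
#'   class documentation.
#' @return a [WearScarImage-class] object.
#' @examples
#' img <- WearScarImage(matrix(1L, 170, 220))
#' sum(pixels(img) == 0)  # no worn pixels
#' @export
WearScarImage <- function(pixels, mmPerPxML = 0.35, mmPerPxAP = 0.35,
                          side = "unknown", source = "unknown",
                          componentId = "", timeInHost = NA_real_,
                          ageAtSurgery = NA_real_) {
  storage.mode(pixels) <- "integer"
  new("WearScarImage", pixels = pixels,
      mmPerPxML = as.numeric(mmPerPxML), mmPerPxAP = as.numeric(mmPerPxAP),
      side = side, source = source, componentId = as.character(componentId),
      timeInHost = as.numeric(timeInHost),
      ageAtSurgery = as.numeric(ageAtSurgery))
}

#' Self-organizing feature map model
#'
#' A rectangular lattice of \code{gridRows x gridCols} neurons, each holding
#' one codebook vector of the input dimension. Neurons are indexed in
#' row-major order (index \code{(r-1)*gridCols + c}), and grid distance
#' between neurons is the Euclidean distance of their integer (row, col)
#' coordinates.
#'
#' @slot gridRows,gridCols lattice dimensions.
#' @slot codebook numeric matrix, one row per neuron (row-major neuron
#'   order), one column per input dimension.
#' @slot kernel neighborhood kernel, \code{"gaussian"} or \code{"bubble"}.
#' @slot trained logical flag set by [sofmTrain()].
#' @slot schedule list describing the training schedule actually used.
#' @slot trainingLog numeric vector of per-epoch quantization errors.
#' @exportClass SOFMModel
setClass("SOFMModel",
  representation(
    gridRows    = "integer",
    gridCols    = "integer",
    codebook    = "matrix",
    kernel      = "character",
    trained     = "logical",
    schedule    = "list",
    trainingLog = "numeric"
  ),
  prototype(kernel = "gaussian", trained = FALSE, schedule = list(),
            trainingLog = numeric(0))
)

setValidity("SOFMModel", function(object) {
  nm <- object@gridRows * object@gridCols
  if (object@gridRows < 1L || object@gridCols < 1L)
    return("grid dimensions must be >= 1")
  if (nrow(object@codebook) != nm)
    return("codebook must have gridRows*gridCols rows")
  if (!(object@kernel %in% c("gaussian", "bubble")))
    return("kernel must be 'gaussian' or 'bubble'")
  TRUE
})

#' U-matrix of a trained map
#'
#' Per-neuron mean Euclidean codebook distance to the lattice-adjacent
#' neurons (4-neighborhood); corner neurons average over 2 neighbors and
#' edge neurons over 3. Low values ("valleys") mark clusters, high values
#' ("ridges") mark cluster boundaries.
#'
#' @slot values numeric matrix, gridRows x gridCols, all values >= 0.
#' @exportClass UMatrix
setClass("UMatrix", representation(values = "matrix"))

setValidity("UMatrix", function(object) {
  if (any(object@values < -1e-12)) return("u-matrix values must be >= 0")
  TRUE
})

#' Cluster labeling of a map lattice
#'
#' Maps each neuron to a cluster id (positive integer) or to the ridge
#' (label 0, unlabeled). Every cluster is a 4-connected region of the grid
#' and ids are contiguous from 1, ordered by each cluster's minimum
#' row-major neuron index.
#'
#' @slot labels integer matrix, gridRows x gridCols; 0 marks ridge neurons.
#' @slot nClusters number of clusters.
#' @exportClass ClusterMap
setClass("ClusterMap",
  representation(labels = "matrix", nClusters = "integer"))

setValidity("ClusterMap", function(object) {
  lab <- object@labels
  if (!all(lab >= 0L)) return("labels must be >= 0 (0 = ridge)")
  k <- object@nClusters
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) != k || (k > 0L && !identical(ids, seq_len(k))))
    return("cluster ids must be contiguous from 1")
  for (id in ids) {
    if (!.isConnected4(lab == id))
      return(sprintf("cluster %d is not 4-connected on the grid", id))
  }
  TRUE
})

# TRUE iff the TRUE cells of a logical matrix form one 4-connected region
.isConnected4 <- function(mask) {
  idx <- which(mask)
  if (length(idx) <= 1L) return(TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  queue <- idx[1L]
  seen[queue] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
    for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
      if (d[1L] >= 1L && d[1L] <= nr && d[2L] >= 1L && d[2L] <= nc &&
          mask[d[1L], d[2L]] && !seen[d[1L], d[2L]]) {
        j <- (d[2L] - 1L) * nr + d[1L]
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  all(seen[idx])
}
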