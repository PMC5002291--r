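#' Accessors for scarSOM classes
#'
#' Small accessor generics: \code{pixels()} returns the binary pixel matrix
#' of a [WearScarImage-class]; \code{side()}, \code{sourceLabel()} and
#' \code{componentId()} return its metadata; \code{calibration()} the mm/px
#' pair; \code{codebook()} the neuron-by-dimension weight matrix of a
#' [SOFMModel-class]; \code{gridSize()} its lattice dimensions;
#' \code{isTrained()} its training flag; \code{trainingLog()} the per-epoch
#' quantization errors; \code{umValues()} the value matrix of a
#' [UMatrix-class]; \code{clusterLabels()} and \code{nClusters()} the
#' labeling of a [ClusterMap-class].
#'
#' @param x an object of the documented class.
#' @return the slot value described above.
#' @name accessors
#' @aliases pixels side sourceLabel componentId calibration codebook
#'   gridSize isTrained trainingLog umValues clusterLabels nClusters
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("side", function(x) standardGeneric("side"))
#' @rdname accessors
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))
#' @rdname accessors
#' @export
setGeneric("componentId", function(x) standardGeneric("componentId"))
#' @rdname accessors
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))
#' @rdname accessors
#' @export
setGeneric("codebook", function(x) standardGeneric("codebook"))
#' @rdname accessors
#' @export
setGeneric("gridSize", function(x) standardGeneric("gridSize"))
#' @rdname accessors
#' @export
setGeneric("isTrained", function(x) standardGeneric("isTrained"))
#' @rdname accessors
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))
#' @rdname accessors
#' @export
setGeneric("umValues", function(x) standardGeneric("umValues"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname accessors
setMethod("pixels", "WearScarImage", function(x) x@pixels)
#' @rdname accessors
setMethod("side", "WearScarImage", function(x) x@side)
#' @rdname accessors
setMethod("sourceLabel", "WearScarImage", function(x) x@source)
#' @rdname accessors
setMethod("componentId", "WearScarImage", function(x) x@componentId)
#' @rdname accessors
setMethod("calibration", "WearScarImage",
          function(x) c(ml = x@mmPerPxML, ap = x@mmPerPxAP))
#' @rdname accessors
setMethod("codebook", "SOFMModel", function(x) x@codebook)
#' @rdname accessors
setMethod("gridSize", "SOFMModel",
          function(x) c(rows = x@gridRows, cols = x@gridCols))
#' @rdname accessors
setMethod("isTrained", "SOFMModel", function(x) x@trained)
#' @rdname accessors
setMethod("trainingLog", "SOFMModel", function(x) x@trainingLog)
#' @rdname accessors
setMethod("umValues", "UMatrix", function(x) x@values)
#' @rdname accessors
setMethod("clusterLabels", "ClusterMap", function(x) x@labels)
#' @rdname accessors
setMethod("nClusters", "ClusterMap", function(x) x@nClusters)

setMethod("show", "WearScarImage", function(object) {
  cat(sprintf(
    "WearScarImage '%s': %d x %d px, %.2f x %.2f mm/px, side=%s, source=%s\n",
    object@componentId, nrow(object@pixels), ncol(object@pixels),
    object@mmPerPxML, object@mmPerPxAP, object@side, object@source))
  cat(sprintf("  worn pixels: %d (%.1f%%)\n", sum(object@pixels == 0L),
              100 * mean(object@pixels == 0L)))
})

setMethod("show", "SOFMModel", function(object) {
  cat(sprintf("SOFMModel: %d x %d lattice, input dim %d, kernel=%s, %s\n",
              object@gridRows, object@gridCols, ncol(object@codebook),
              object@kernel,
              if (object@trained) "trained" else "untrained"))
  if (length(object@trainingLog))
    cat(sprintf("  final quantization error: %.4f\n",
                utils::tail(object@trainingLog, 1L)))
})

setMethod("show", "UMatrix", function(object) {
  v <- object@values
  cat(sprintf("UMatrix: %d x %d, range [%.4g, %.4g]\n",
              nrow(v), ncol(v), min(v), max(v)))
})

setMethod("show", "ClusterMap", function(object) {
  cat(sprintf("ClusterMap: %d x %d lattice, %d clusters, %d ridge neurons\n",
              nrow(object@labels), ncol(object@labels), object@nClusters,
              sum(object@labels == 0L)))
})
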