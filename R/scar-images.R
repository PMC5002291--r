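#' Read a binary wear-scar mask from disk
#'
#' Supports portable bitmaps (PBM, both the ASCII \code{P1} and packed
#' binary \code{P4} dialects) and PNG. PBM stores 1 = black; that bit is
#' flipped on read so that the in-memory convention is always 0 = black =
#' worn, 1 = white = unworn. Grayscale or colour PNG input is averaged
#' across channels and thresholded at mid-intensity.
#'
#' @param path file to read.
#' @param format \code{"auto"} (by extension/magic), \code{"pbm"} or
#'   \code{"png"}.
#' @param metadata optional one-row data.frame (or list) with fields
#'   \code{side}, \code{source}, \code{component_id}, \code{time_in_host},
#'   \code{age_at_surgery} used to populate the image metadata.
#' @param mmPerPxML,mmPerPxAP calibration to attach.
#' @return a [WearScarImage-class].
#' @seealso [writeMask()], [readCohortImages()]
#' @export
readMask <- function(path, format = c("auto", "pbm", "png"), metadata = NULL,
                     mmPerPxML = 0.35, mmPerPxAP = 0.35) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mask, file not found: ", path)
  if (file.size(path) == 0L) stop("cannot read mask, empty file: ", path)
  if (format == "auto") {
    magic <- readBin(path, "raw", n = 2L)
    format <- if (identical(rawToChar(magic), "P1") ||
                  identical(rawToChar(magic), "P4")) "pbm"
              else if (grepl("\\.png$", path, ignore.case = TRUE) ||
                       identical(magic, as.raw(c(0x89, 0x50)))) "png"
              else stop("unrecognized image format: ", path)
  }
  px <- if (format == "pbm") .readPBM(path) else .readPNGMask(path)
  img <- WearScarImage(px, mmPerPxML = mmPerPxML, mmPerPxAP = mmPerPxAP)
  if (!is.null(metadata)) {
    md <- as.list(metadata)
    if (!is.null(md$side)) img@side <- as.character(md$side)
    if (!is.null(md$source)) img@source <- as.character(md$source)
    if (!is.null(md$component_id)) img@componentId <- as.character(md$component_id)
    if (!is.null(md$time_in_host)) img@timeInHost <- as.numeric(md$time_in_host)
    if (!is.null(md$age_at_surgery)) img@ageAtSurgery <- as.numeric(md$age_at_surgery)
    validObject(img)
  }
  img
}

.readPBM <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P1", "P4")) stop("not a PBM file: ", path)
  # tokenize header (magic, width, height) byte-wise, skipping comments;
  # the pixel payload of P4 may contain nul bytes so the file cannot be
  # converted to one string
  isDigit <- function(b) b >= as.raw(0x30) && b <= as.raw(0x39)
  pos <- 3L
  tokens <- character(0)
  nRaw <- length(raw)
  while (length(tokens) < 2L && pos <= nRaw) {
    b <- raw[pos]
    if (b == as.raw(0x23)) { # '#': comment to end of line
      while (pos <= nRaw && raw[pos] != as.raw(0x0a)) pos <- pos + 1L
    } else if (isDigit(b)) {
      start <- pos
      while (pos <= nRaw && isDigit(raw[pos])) pos <- pos + 1L
      tokens <- c(tokens, rawToChar(raw[start:(pos - 1L)]))
      next
    }
    pos <- pos + 1L
  }
  w <- as.integer(tokens[1L]); h <- as.integer(tokens[2L])
  if (is.na(w) || is.na(h) || w < 1L || h < 1L)
    stop("corrupt PBM header: ", path)
  if (magic == "P1") {
    body <- rawToChar(raw[pos:nRaw])
    body <- gsub("#[^\n]*", "", body)
    bits <- as.integer(strsplit(gsub("[^01]", "", body), "")[[1L]])
    if (length(bits) < w * h) stop("truncated P1 data: ", path)
    bitmat <- matrix(bits[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE)
  } else {
    pos <- pos + 1L  # single whitespace after height
    bytesPerRow <- ceiling(w / 8)
    need <- h * bytesPerRow
    body <- raw[pos:(pos + need - 1L)]
    if (length(body) < need) stop("truncated P4 data: ", path)
    bytes <- as.integer(body)
    # unpack MSB-first
    bits <- matrix(0L, nrow = 8L, ncol = need)
    for (b in 1:8) bits[b, ] <- bitwAnd(bitwShiftR(bytes, 8L - b), 1L)
    allbits <- matrix(as.vector(bits), nrow = bytesPerRow * 8L, ncol = h)
    bitmat <- t(allbits[seq_len(w), , drop = FALSE])
  }
  px <- 1L - bitmat  # PBM: 1 = black; internal: 0 = black/worn
  storage.mode(px) <- "integer"
  px
}

.readPNGMask <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:min(3L, dim(arr)[3L]),
                                              drop = FALSE], c(1L, 2L), mean)
  px <- ifelse(arr < 0.5, 0L, 1L)
  storage.mode(px) <- "integer"
  px
}

#' Write a binary wear-scar mask to disk
#'
#' PBM output flips the worn/unworn bit (PBM stores 1 = black); PNG output
#' is 8-bit grayscale with values 0 and 1 only. Round trips through
#' [readMask()] are bit-exact for every format.
#'
#' @param image a [WearScarImage-class].
#' @param path output file.
#' @param format \code{"pbm"} (ASCII P1), \code{"pbm4"} (binary P4) or
#'   \code{"png"}.
#' @return invisibly, the path.
#' @export
writeMask <- function(image, path, format = c("pbm", "pbm4", "png")) {
  stopifnot(is(image, "WearScarImage"))
  format <- match.arg(format)
  px <- image@pixels
  h <- nrow(px); w <- ncol(px)
  black <- 1L - px  # PBM convention
  if (format == "pbm") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P1", paste(w, h)), con)
    writeLines(apply(black, 1L, paste, collapse = " "), con)
  } else if (format == "pbm4") {
    bytesPerRow <- ceiling(w / 8)
    padded <- cbind(black, matrix(0L, h, bytesPerRow * 8L - w))
    # pack each row MSB-first
    weights <- 2L^(7:0)
    rowsRaw <- apply(padded, 1L, function(r) {
      m <- matrix(r, nrow = 8L)
      as.raw(colSums(m * weights))
    })
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P4\n%d %d\n", w, h), con, eos = NULL)
    writeBin(as.raw(rowsRaw), con)
  } else {
    png::writePNG(matrix(as.numeric(px), h, w), path)
  }
  invisible(path)
}

#' Mirror an image about its vertical axis
#'
#' Flips columns (the medial-lateral axis) and swaps the side label;
#' mirroring twice restores the original image.
#'
#' @param image a [WearScarImage-class].
#' @return the mirrored image.
#' @export
mirrorImage <- function(image) {
  stopifnot(is(image, "WearScarImage"))
  image@pixels <- image@pixels[, rev(seq_len(ncol(image@pixels))), drop = FALSE]
  image@side <- switch(image@side, left = "right", right = "left", "unknown")
  image
}

#' Normalize an image to right implantation side
#'
#' Left-side images are mirrored about the vertical axis and relabeled
#' right; right-side images pass through unchanged. Components with
#' unknown side must first be classified with [inferSide()].
#'
#' @param image a [WearScarImage-class] with a known side.
#' @return a right-side [WearScarImage-class].
#' @export
toRightSide <- function(image) {
  stopifnot(is(image, "WearScarImage"))
  switch(image@side,
    right = image,
    left = mirrorImage(image),
    stop("implantation side is unknown; call inferSide() first"))
}

#' Infer the implantation side by mirror distance to a reference cohort
#'
#' Compares the encoded image, as-is and mirrored, against a reference set
#' of right-normalized images: the orientation with the smaller mean
#' Euclidean distance to the references wins. An exact tie is resolved to
#' \code{"right"}. This deterministic rule stands in for a trained
#' side-classification network; it relies on the anatomical asymmetry of
#' wear (the medial scar tends to be larger).
#'
#' @param image a [WearScarImage-class] with the same dimensions as the
#'   references.
#' @param reference non-empty list of right-normalized
#'   [WearScarImage-class] objects.
#' @return \code{"left"} or \code{"right"}.
#' @export
inferSide <- function(image, reference) {
  stopifnot(is(image, "WearScarImage"))
  if (length(reference) == 0L) stop("reference set is empty")
  dims <- dim(image@pixels)
  refMat <- t(vapply(reference, function(r) {
    stopifnot(identical(dim(r@pixels), dims))
    as.numeric(t(r@pixels))
  }, numeric(prod(dims))))
  v <- as.numeric(t(image@pixels))
  vm <- as.numeric(t(image@pixels[, rev(seq_len(dims[2L])), drop = FALSE]))
  dAs <- mean(sqrt(rowSums(sweep(refMat, 2L, v)^2)))
  dMir <- mean(sqrt(rowSums(sweep(refMat, 2L, vm)^2)))
  if (dAs <= dMir) "right" else "left"
}

#' Standardize an image to the analysis dimensions
#'
#' Nearest-neighbor resampling to the target grid (default 170 rows x 220
#' columns), which preserves binarity; the calibration is rescaled so the
#' physical extent is unchanged.
#'
#' @param image a [WearScarImage-class] of any size.
#' @param targetRows,targetCols target dimensions.
#' @return a standardized [WearScarImage-class].
#' @export
standardizeImage <- function(image, targetRows = 170L, targetCols = 220L) {
  stopifnot(is(image, "WearScarImage"))
  if (targetRows < 1L || targetCols < 1L)
    stop("target dimensions must be positive")
  px <- image@pixels
  nr <- nrow(px); nc <- ncol(px)
  if (nr == targetRows && nc == targetCols) return(image)
  ri <- pmin(pmax(floor((seq_len(targetRows) - 0.5) * nr / targetRows) + 1L, 1L), nr)
  ci <- pmin(pmax(floor((seq_len(targetCols) - 0.5) * nc / targetCols) + 1L, 1L), nc)
  image@pixels <- px[ri, ci, drop = FALSE]
  image@mmPerPxAP <- image@mmPerPxAP * nr / targetRows
  image@mmPerPxML <- image@mmPerPxML * nc / targetCols
  image
}

#' Encode a standardized image as a binary row vector
#'
#' Row-major flattening of the 170 x 220 pixel grid into a vector of
#' exactly 37,400 zeros and ones — the input representation fed to the
#' map's input layer (one input neuron per pixel). [decodeImage()] inverts
#' the operation exactly.
#'
#' @param image a standardized [WearScarImage-class].
#' @param expectedDims required dimensions, default \code{c(170, 220)}.
#' @return integer vector of 0/1, length \code{prod(expectedDims)}.
#' @export
encodeImage <- function(image, expectedDims = c(170L, 220L)) {
  stopifnot(is(image, "WearScarImage"))
  if (!identical(dim(image@pixels), as.integer(expectedDims)))
    stop(sprintf("image is %d x %d; standardize to %d x %d before encoding",
                 nrow(image@pixels), ncol(image@pixels),
                 expectedDims[1L], expectedDims[2L]))
  as.integer(t(image@pixels))
}

#' @rdname encodeImage
#' @param v encoded vector.
#' @param rows,cols dimensions of the decoded pixel grid.
#' @param ... further arguments passed to [WearScarImage()].
#' @export
decodeImage <- function(v, rows = 170L, cols = 220L, ...) {
  stopifnot(length(v) == rows * cols, all(v %in% c(0L, 1L)))
  WearScarImage(matrix(as.integer(v), rows, cols, byrow = TRUE), ...)
}

#' Read a directory of mask images with a sidecar metadata CSV
#'
#' @param dir directory containing mask files.
#' @param metadataCsv CSV keyed by \code{component_id} with columns
#'   \code{file, side, source} and optionally \code{time_in_host,
#'   age_at_surgery}.
#' @param mmPerPxML,mmPerPxAP calibration.
#' @return list of [WearScarImage-class] objects.
#' @export
readCohortImages <- function(dir, metadataCsv, mmPerPxML = 0.35,
                             mmPerPxAP = 0.35) {
  md <- utils::read.csv(metadataCsv, stringsAsFactors = FALSE)
  stopifnot(all(c("component_id", "file") %in% names(md)))
  lapply(seq_len(nrow(md)), function(i)
    readMask(file.path(dir, md$file[i]), metadata = md[i, , drop = FALSE],
             mmPerPxML = mmPerPxML, mmPerPxAP = mmPerPxAP))
}
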