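## Readers/writers for ion-count images, label masks, and ROI tables.
##
## Raster convention: row-major, 0-based pixel indices, origin top-left,
## square pixels of side pixelSize (um). TIFF images are multi-page, one
## 16-bit page per channel, with a YAML sidecar (<path>.yaml) recording
## channel order, pixel size and metadata. The text dialect writes one
## whitespace-separated integer matrix per channel as <stem>_<channel>.txt.

MAX_TIFF_COUNT <- 65535L

sidecarPath <- function(path) paste0(path, ".yaml")

writeSidecar <- function(path, channels, pixelSize, metadata) {
  yaml::write_yaml(list(channels = as.list(channels),
                        pixel_size = pixelSize,
                        metadata = metadata),
                   sidecarPath(path))
}

readSidecar <- function(path) {
  sc <- sidecarPath(path)
  if (!file.exists(sc)) return(NULL)
  yaml::read_yaml(sc)
}

#' Write an ion-count image to disk
#'
#' TIFF format stores one 16-bit page per channel (counts above 65535 are
#' refused); text format writes one integer matrix per channel to
#' \code{<stem>_<channel>.txt}. Both write a YAML sidecar with channel
#' order, pixel size and metadata so the round-trip is lossless.
#'
#' @param image an \linkS4class{IonCountImage}.
#' @param path output path (for text format, the stem without extension).
#' @param format \code{"tiff"} or \code{"text"}.
#' @return \code{path}, invisibly.
#' @export
writeIonImage <- function(image, path, format = c("tiff", "text")) {
  format <- match.arg(format)
  stopifnot(is(image, "IonCountImage"))
  ch <- image@channels
  if (format == "tiff") {
    mx <- max(vapply(ch, max, numeric(1)))
    if (mx > MAX_TIFF_COUNT)
      stop("counts exceed 16-bit TIFF range (", MAX_TIFF_COUNT, ")")
    pages <- lapply(ch, function(m) m / MAX_TIFF_COUNT)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    for (nm in names(ch)) {
      utils::write.table(ch[[nm]], paste0(path, "_", nm, ".txt"),
                         row.names = FALSE, col.names = FALSE)
    }
  }
  writeSidecar(path, names(ch), image@pixelSize, image@metadata)
  invisible(path)
}

#' Read an ion-count image from disk
#'
#' Inverse of \code{\link{writeIonImage}}. Channel names are taken from the
#' YAML sidecar when present, otherwise from the \code{channels} argument
#' (TIFF page order / text filename suffixes). Non-integer or negative data
#' are rejected.
#'
#' @param path path given to \code{writeIonImage}.
#' @param format \code{"tiff"} or \code{"text"}.
#' @param channels channel names, required when no sidecar exists.
#' @param pixelSize fallback pixel size when no sidecar exists.
#' @return an \linkS4class{IonCountImage}.
#' @export
readIonImage <- function(path, format = c("tiff", "text"), channels = NULL,
                         pixelSize = 1) {
  format <- match.arg(format)
  sc <- readSidecar(path)
  if (!is.null(sc)) {
    channels <- unlist(sc$channels)
    pixelSize <- sc$pixel_size %||% pixelSize
  }
  if (is.null(channels))
    stop("channel names must be supplied or embedded in a sidecar")
  if (format == "tiff") {
    if (!file.exists(path)) stop("file not found: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != length(channels))
      stop("channel count mismatch between TIFF pages and channel names")
    data <- lapply(pages, function(p) {
      m <- round(p * MAX_TIFF_COUNT)
      storage.mode(m) <- "integer"
      m
    })
  } else {
    data <- lapply(channels, function(nm) {
      f <- paste0(path, "_", nm, ".txt")
      if (!file.exists(f)) stop("file not found: ", f)
      m <- as.matrix(utils::read.table(f, header = FALSE))
      dimnames(m) <- NULL
      if (any(m < 0)) stop("negative counts in ", f)
      if (any(m != round(m))) stop("non-integer counts in ", f)
      storage.mode(m) <- "integer"
      m
    })
  }
  names(data) <- channels
  dims <- unique(lapply(data, dim))
  if (length(dims) != 1L) stop("channel shape mismatch")
  IonCountImage(data, pixelSize = pixelSize,
                metadata = if (!is.null(sc)) sc$metadata %||% list() else list())
}

#' Write / read a compartment label mask
#'
#' Stored as a single 16-bit TIFF page (or an integer text matrix), with a
#' YAML sidecar holding the class map and provenance.
#'
#' @param mask a \linkS4class{CompartmentMask}.
#' @param path output path.
#' @param format \code{"tiff"} or \code{"text"}.
#' @return \code{path}, invisibly.
#' @export
writeLabelMask <- function(mask, path, format = c("tiff", "text")) {
  format <- match.arg(format)
  stopifnot(is(mask, "CompartmentMask"))
  if (format == "tiff") {
    tiff::writeTIFF(mask@labels / MAX_TIFF_COUNT, path, bits.per.sample = 16L)
  } else {
    utils::write.table(mask@labels, paste0(path, ".txt"),
                       row.names = FALSE, col.names = FALSE)
  }
  yaml::write_yaml(list(class_map = as.list(COMPARTMENT_CODES),
                        provenance = rapply(mask@provenance, as.vector,
                                            how = "replace")),
                   sidecarPath(path))
  invisible(path)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path, format = c("tiff", "text")) {
  format <- match.arg(format)
  labels <- if (format == "tiff") {
    m <- round(tiff::readTIFF(path) * MAX_TIFF_COUNT)
    storage.mode(m) <- "integer"
    m
  } else {
    m <- as.matrix(utils::read.table(paste0(path, ".txt"), header = FALSE))
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    m
  }
  sc <- readSidecar(path)
  CompartmentMask(labels,
                  provenance = if (!is.null(sc)) sc$provenance %||% list()
                               else list())
}

#' Write an ROI quantification table to CSV
#'
#' One row per ROI: cell id, ROI id, compartment class, pixel area, pooled
#' counts per channel, atom percent values with standard errors, and
#' enrichment calls when present. Duplicate (cell, ROI) keys are refused.
#'
#' @param quants data.frame as produced by \code{\link{quantifyRois}}
#'   (optionally augmented with enrichment calls).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeRoiTable <- function(quants, path) {
  stopifnot(is.data.frame(quants))
  if (nrow(quants) > 0) {
    key <- paste(quants$cell_id, quants$roi_id, quants$class)
    if (anyDuplicated(key)) stop("duplicate (cell, ROI) keys")
  }
  utils::write.csv(quants, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRoiTable
#' @export
readRoiTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
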