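#' @import methods
NULL

## Compartment label convention used everywhere in the package:
## 0 = background, 1 = host(N), 2 = host(-N), 3 = diazoplast.
COMPARTMENT_CODES <- c(background = 0L, host_N = 1L, host_minusN = 2L,
                       diazoplast = 3L)

## Ion species measured on the nanoSIMS raster. CN- carries nitrogen
## (12C14N- vs 12C15N-), C2- carries carbon (12C12C- vs 13C12C-), 32S-
## tracks protein abundance.
ION_CHANNELS <- c("C14N", "C15N", "C2", "C13C", "S32")

#' Multi-channel ion-count image
#'
#' Per-pixel integer secondary-ion counts for a fixed set of mass channels
#' acquired on a common raster grid. Channels are stored as a named list of
#' integer matrices of identical dimension; the raster convention is
#' row-major, origin top-left, square pixels of side \code{pixelSize} (in
#' micrometres).
#'
#' @slot channels named list of non-negative integer matrices, one per mass
#'   channel; names drawn from \code{C14N, C15N, C2, C13C, S32}.
#' @slot pixelSize side length of a pixel in micrometres.
#' @slot metadata free-form list of acquisition metadata.
#' @export
setClass("IonCountImage",
  representation(channels = "list", pixelSize = "numeric", metadata = "list"),
  prototype(channels = list(), pixelSize = 1, metadata = list()))

setValidity("IonCountImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel required")
  nm <- names(ch)
  if (is.null(nm) || anyDuplicated(nm)) return("channel names must be unique")
  bad <- setdiff(nm, ION_CHANNELS)
  if (length(bad)) return(paste("unknown channel name(s):",
                                paste(bad, collapse = ", ")))
  dims <- lapply(ch, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    return("all channels must share the same raster shape")
  for (i in seq_along(ch)) {
    x <- ch[[i]]
    if (!is.matrix(x)) return("channel data must be matrices")
    if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
      return(sprintf("channel %s must hold non-negative integer counts", nm[i]))
  }
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  TRUE
})

#' Construct an IonCountImage
#'
#' @param channels named list of integer count matrices (names from
#'   \code{C14N, C15N, C2, C13C, S32}).
#' @param pixelSize pixel side length in micrometres.
#' @param metadata optional list of metadata.
#' @return an \linkS4class{IonCountImage}.
#' @examples
#' img <- IonCountImage(list(C14N = matrix(5L, 4, 4)), pixelSize = 0.25)
#' channelNames(img)
#' @export
IonCountImage <- function(channels, pixelSize = 1, metadata = list()) {
  channels <- lapply(channels, function(x) {
    storage.mode(x) <- "integer"
    x
  })
  new("IonCountImage", channels = channels, pixelSize = pixelSize,
      metadata = metadata)
}

#' @describeIn IonCountImage channel names present in the image
#' @param x an \code{IonCountImage}.
#' @export
channelNames <- function(x) names(x@channels)

#' Extract one channel's count matrix
#'
#' @param x an \linkS4class{IonCountImage}.
#' @param name channel name.
#' @return integer matrix of counts.
#' @export
getChannel <- function(x, name) {
  if (!name %in% names(x@channels))
    stop("channel not present: ", name, call. = FALSE)
  x@channels[[name]]
}

#' @describeIn IonCountImage pixel size in micrometres
#' @export
pixelSize <- function(x) x@pixelSize

setMethod("show", "IonCountImage", function(object) {
  d <- dim(object@channels[[1]])
  cat("IonCountImage:", d[1], "x", d[2], "px,",
      length(object@channels), "channel(s):",
      paste(names(object@channels), collapse = ", "), "\n")
  cat("  pixel size:", object@pixelSize, "um\n")
})

#' Compartment label mask
#'
#' Integer label raster assigning every pixel to one compartment class:
#' 0 background, 1 host(N), 2 host(-N), 3 diazoplast. \code{provenance}
#' records the segmentation parameters and derived thresholds that produced
#' the mask.
#'
#' @slot labels integer matrix of class codes.
#' @slot provenance list of segmentation parameters and derived values.
#' @export
setClass("CompartmentMask",
  representation(labels = "matrix", provenance = "list"),
  prototype(provenance = list()))

setValidity("CompartmentMask", function(object) {
  l <- object@labels
  if (any(is.na(l)) || !all(l %in% COMPARTMENT_CODES))
    return("labels must be codes 0 (background), 1 (host_N), 2 (host_minusN), 3 (diazoplast)")
  TRUE
})

#' Construct a CompartmentMask
#' @param labels integer matrix with codes 0-3.
#' @param provenance optional list describing how the mask was produced.
#' @return a \linkS4class{CompartmentMask}.
#' @export
CompartmentMask <- function(labels, provenance = list()) {
  storage.mode(labels) <- "integer"
  new("CompartmentMask", labels = labels, provenance = provenance)
}

#' @describeIn CompartmentMask the label raster
#' @param x a \code{CompartmentMask}.
#' @export
maskLabels <- function(x) x@labels

setMethod("show", "CompartmentMask", function(object) {
  tab <- table(factor(object@labels, levels = COMPARTMENT_CODES,
                      labels = names(COMPARTMENT_CODES)))
  cat("CompartmentMask:", nrow(object@labels), "x", ncol(object@labels),
      "px\n  pixels per class:\n")
  print(tab)
})

#' Ground truth for one simulated cell
#'
#' Bookkeeping object emitted by the simulator: the true compartment label
#' image, the true isotope atom fractions per compartment (instrument
#' baseline included), activity flags, and compartment volumes under the
#' sphere/spheroid geometric model.
#'
#' @slot labels integer matrix of true compartment codes.
#' @slot atom15N named numeric, true 15N atom fraction per compartment.
#' @slot atom13C named numeric, true 13C atom fraction per compartment.
#' @slot active logical, whether the cell's diazoplast fixed 15N2.
#' @slot activeC logical, whether the cell fixed 13C-bicarbonate.
#' @slot volumes named numeric, compartment volumes in cubic micrometres.
#' @slot cellId integer cell index.
#' @export
setClass("GroundTruth",
  representation(labels = "matrix", atom15N = "numeric", atom13C = "numeric",
                 active = "logical", activeC = "logical", volumes = "numeric",
                 cellId = "integer"))

setValidity("GroundTruth", function(object) {
  if (!all(object@labels %in% COMPARTMENT_CODES))
    return("labels must use compartment codes 0-3")
  need <- names(COMPARTMENT_CODES)
  if (!all(need %in% names(object@atom15N)) ||
      !all(need %in% names(object@atom13C)))
    return("atom fractions must be named for all four compartment classes")
  if (any(object@atom15N < 0 | object@atom15N > 1) ||
      any(object@atom13C < 0 | object@atom13C > 1))
    return("atom fractions must lie in [0, 1]")
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth for cell", object@cellId,
      if (object@active) "(15N-active)" else "(inactive)", "\n")
  cat("  true 15N atom%:",
      paste(sprintf("%s=%.4f", names(object@atom15N), 100 * object@atom15N),
            collapse = ", "), "\n")
  cat("  volumes (um^3):",
      paste(sprintf("%s=%.1f", names(object@volumes), object@volumes),
            collapse = ", "), "\n")
})

#' Natural-abundance calibration
#'
#' Mean and across-ROI standard deviation of the atom percent measured in
#' unlabeled control ROIs, and the derived enrichment threshold
#' mean + 3 SD. Measurements strictly above the threshold are called
#' enriched.
#'
#' @slot isotope \code{"15N"} or \code{"13C"}.
#' @slot mean mean control atom percent.
#' @slot sd across-ROI standard deviation of control atom percent.
#' @slot threshold enrichment cutoff, \code{mean + 3 * sd} (atom percent).
#' @slot nControls number of control ROIs used.
#' @export
setClass("NaturalAbundanceCalibration",
  representation(isotope = "character", mean = "numeric", sd = "numeric",
                 threshold = "numeric", nControls = "integer"))

setValidity("NaturalAbundanceCalibration", function(object) {
  if (!object@isotope %in% c("15N", "13C")) return("isotope must be 15N or 13C")
  if (object@sd < 0) return("sd must be non-negative")
  if (object@threshold < object@mean) return("threshold must be >= mean")
  TRUE
})

setMethod("show", "NaturalAbundanceCalibration", function(object) {
  cat(sprintf(
    "NaturalAbundanceCalibration (%s): mean %.4f%% +/- %.4f%% (n = %d)\n",
    object@isotope, object@mean, object@sd, object@nControls))
  cat(sprintf("  enrichment threshold (mean + 3 SD): %.4f%%\n",
              object@threshold))
})

#' Host-symbiont nitrogen transfer estimate
#'
#' Result of the volume-weighted mass balance: the host-vs-diazoplast
#' excess-enrichment slope, the regression fit quality, the
#' diazoplast:host(N) volume ratio, and the implied fraction of newly fixed
#' nitrogen residing in the host, with a bootstrap percentile confidence
#' interval.
#'
#' @slot slope host:diazoplast excess-enrichment slope.
#' @slot r2 regression R-squared (uncentered for through-origin fits).
#' @slot volumeRatio diazoplast:host(N) volume ratio.
#' @slot transferFraction fraction of fixed N transferred to the host.
#' @slot ciLow,ciHigh bootstrap percentile interval for the fraction.
#' @slot nCells number of paired cells in the regression.
#' @slot nBootstrap number of bootstrap resamples.
#' @slot seed RNG seed used for the bootstrap.
#' @export
setClass("TransferEstimate",
  representation(slope = "numeric", r2 = "numeric", volumeRatio = "numeric",
                 transferFraction = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", nCells = "integer",
                 nBootstrap = "integer", seed = "integer"))

setValidity("TransferEstimate", function(object) {
  f <- object@transferFraction
  if (f < 0 || f > 1) return("transferFraction must lie in [0, 1]")
  if (object@ciLow > f || object@ciHigh < f)
    return("confidence interval must bracket the point estimate")
  TRUE
})

setMethod("show", "TransferEstimate", function(object) {
  cat(sprintf("TransferEstimate: slope %.3f (R2 = %.3f), volume ratio %.3f\n",
              object@slope, object@r2, object@volumeRatio))
  cat(sprintf("  transferred fraction: %.3f [%.3f, %.3f] (n = %d cells, B = %d)\n",
              object@transferFraction, object@ciLow, object@ciHigh,
              object@nCells, object@nBootstrap))
})
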