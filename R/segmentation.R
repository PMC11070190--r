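#' Segmentation parameters
#'
#' Parameters for partitioning a cell raster into diazoplast, host(N),
#' host(-N) and background from the CN- and C2- channels. The diazoplast
#' rule finds seed pixels above \code{diazoplastQuantile} of the within-cell
#' smoothed CN signal, then classifies at the midpoint between the host and
#' seed CN levels and keeps components passing area and circularity
#' (4*pi*A/P^2) filters; a component level below \code{contrastMin} times
#' the host level means no diazoplast is present. host(-N) pixels sit at
#' background CN but carry C2 density at least \code{c2RatioMin} times the
#' within-cell median.
#'
#' @param smoothingSigma Gaussian smoothing sigma in pixels (shot-noise
#'   suppression before thresholding).
#' @param backgroundMethod \code{"otsu"} or \code{"fixed"} cell/background
#'   separation.
#' @param fixedBackground count threshold used when
#'   \code{backgroundMethod = "fixed"}.
#' @param diazoplastQuantile within-cell CN quantile for diazoplast seeds.
#' @param minDiazoplastArea,maxDiazoplastArea component area bounds (px).
#' @param circularityMin minimum circularity for diazoplast components.
#' @param contrastMin minimum diazoplast:host CN level ratio.
#' @param c2RatioMin minimum C2 density relative to the cell median for
#'   host(-N).
#' @return a named list of validated parameters.
#' @export
segmentationParams <- function(smoothingSigma = 1, backgroundMethod = "otsu",
                               fixedBackground = NULL,
                               diazoplastQuantile = 0.90,
                               minDiazoplastArea = 20,
                               maxDiazoplastArea = Inf,
                               circularityMin = 0.6, contrastMin = 1.5,
                               c2RatioMin = 1.5) {
  stopifnot(smoothingSigma >= 0,
            backgroundMethod %in% c("otsu", "fixed"),
            diazoplastQuantile > 0, diazoplastQuantile <= 1,
            circularityMin > 0, circularityMin <= 1,
            minDiazoplastArea <= maxDiazoplastArea,
            contrastMin >= 1, c2RatioMin > 0)
  if (backgroundMethod == "fixed" && is.null(fixedBackground))
    stop("fixedBackground required when backgroundMethod = 'fixed'")
  list(smoothingSigma = smoothingSigma, backgroundMethod = backgroundMethod,
       fixedBackground = fixedBackground,
       diazoplastQuantile = diazoplastQuantile,
       minDiazoplastArea = minDiazoplastArea,
       maxDiazoplastArea = maxDiazoplastArea,
       circularityMin = circularityMin, contrastMin = contrastMin,
       c2RatioMin = c2RatioMin)
}

smoothChannel <- function(m, sigma) {
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

totalCN <- function(image) {
  cn <- matrix(as.numeric(getChannel(image, "C14N")),
               nrow(getChannel(image, "C14N")))
  if ("C15N" %in% channelNames(image)) cn <- cn + getChannel(image, "C15N")
  cn
}

#' Segment the cell footprint from the CN- signal
#'
#' The summed CN- image (12C14N- + 12C15N-) is Gaussian-smoothed, separated
#' from background by Otsu's threshold (or a fixed count level), and the
#' largest connected above-background component is retained with holes
#' filled — so nitrogen-depleted interior compartments stay inside the cell
#' footprint.
#'
#' @param image an \linkS4class{IonCountImage} with a \code{C14N} channel.
#' @param params parameters from \code{\link{segmentationParams}}.
#' @return logical matrix (\code{TRUE} inside the cell) with attributes
#'   \code{threshold} (counts) and \code{backgroundLevel}.
#' @export
segmentCell <- function(image, params = segmentationParams()) {
  if (!"C14N" %in% channelNames(image))
    stop("image must contain a C14N channel")
  sm <- smoothChannel(totalCN(image), params$smoothingSigma)
  rng <- range(sm)
  if (diff(rng) <= 0)
    stop("empty image: no above-background pixels")
  thr <- if (params$backgroundMethod == "otsu") {
    norm <- (sm - rng[1]) / diff(rng)
    rng[1] + diff(rng) * EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  } else {
    params$fixedBackground
  }
  fg <- sm > thr
  if (!any(fg)) stop("empty image: no above-background pixels")
  lab <- EBImage::bwlabel(EBImage::Image(fg))
  tab <- tabulate(as.integer(lab))
  keep <- which.max(tab)
  mask <- matrix(as.integer(lab) == keep, nrow(sm), ncol(sm))
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask))) > 0
  attr(mask, "threshold") <- thr
  attr(mask, "backgroundLevel") <- stats::median(sm[!mask])
  mask
}

#' Partition a cell into diazoplast, host(N) and host(-N) compartments
#'
#' Within the cell footprint, diazoplasts are the spherical high-CN
#' components (seeded at the \code{diazoplastQuantile} of the smoothed CN
#' signal, classified at the host/diazoplast midpoint level, filtered by
#' area and circularity); host(-N) compartments have background-level CN
#' but high C2 density (storage bodies: lipid droplets or vacuoles);
#' host(N) is the remaining cytoplasmic area. The three classes are
#' disjoint and cover the cell mask exactly. An absent diazoplast is a
#' valid outcome (zero diazoplast components).
#'
#' @param image an \linkS4class{IonCountImage} with \code{C14N} and
#'   \code{C2} channels.
#' @param cellMask logical matrix from \code{\link{segmentCell}}.
#' @param params parameters from \code{\link{segmentationParams}}.
#' @return a \linkS4class{CompartmentMask} whose provenance records the
#'   parameters and the derived count thresholds.
#' @export
segmentCompartments <- function(image, cellMask,
                                params = segmentationParams()) {
  if (!any(cellMask)) stop("cell mask is empty")
  smCN <- smoothChannel(totalCN(image), params$smoothingSigma)
  smC2 <- smoothChannel(getChannel(image, "C2"), params$smoothingSigma)

  bgLevel <- if (all(cellMask)) 0 else stats::median(smCN[!cellMask])
  cellVals <- smCN[cellMask]
  seedThr <- stats::quantile(cellVals, params$diazoplastQuantile, names = FALSE)
  seeds <- cellMask & smCN >= seedThr
  diazLevel <- stats::median(smCN[seeds])
  hostLevel <- stats::median(smCN[cellMask & smCN < seedThr])

  diazMask <- matrix(FALSE, nrow(smCN), ncol(smCN))
  nDiaz <- 0L
  if (is.finite(diazLevel) && diazLevel >= params$contrastMin * hostLevel) {
    diazThr <- (hostLevel + diazLevel) / 2
    cand <- cellMask & smCN >= diazThr
    # watershed on the distance map separates touching diazoplasts before
    # the shape filters
    lab <- EBImage::watershed(EBImage::distmap(EBImage::Image(cand)))
    nObj <- max(as.integer(lab))
    if (nObj > 0) {
      shp <- EBImage::computeFeatures.shape(lab)
      area <- shp[, "s.area"]
      perim <- pmax(shp[, "s.perimeter"], 1)
      circ <- 4 * pi * area / perim^2
      ok <- which(area >= params$minDiazoplastArea &
                  area <= params$maxDiazoplastArea &
                  circ >= params$circularityMin)
      if (length(ok)) {
        diazMask <- matrix(as.integer(lab) %in% ok, nrow(smCN), ncol(smCN))
        nDiaz <- length(ok)
      }
    }
  } else {
    diazThr <- NA_real_
  }

  lowThr <- (bgLevel + hostLevel) / 2
  c2med <- stats::median(smC2[cellMask])
  lowCN <- cellMask & !diazMask & smCN <= lowThr
  vacMask <- lowCN & smC2 >= params$c2RatioMin * c2med

  labels <- matrix(COMPARTMENT_CODES[["background"]], nrow(smCN), ncol(smCN))
  labels[cellMask] <- COMPARTMENT_CODES[["host_N"]]
  labels[vacMask] <- COMPARTMENT_CODES[["host_minusN"]]
  labels[diazMask] <- COMPARTMENT_CODES[["diazoplast"]]

  CompartmentMask(labels, provenance = list(
    params = params,
    backgroundLevel = bgLevel, hostLevel = hostLevel,
    diazoplastLevel = diazLevel, seedThreshold = seedThr,
    lowCNThreshold = lowThr, c2Median = c2med,
    nDiazoplastComponents = nDiaz))
}

#' Extract per-component ROIs from a compartment mask
#'
#' One ROI per connected component per compartment class, with pixel and
#' physical area, centroid (row/col, pixel units) and equivalent-circle
#' radius.
#'
#' @param mask a \linkS4class{CompartmentMask}.
#' @param pixelSize pixel side in micrometres.
#' @return data.frame with columns \code{roi_id}, \code{class},
#'   \code{component}, \code{area_px}, \code{area_um2},
#'   \code{centroid_row}, \code{centroid_col}, \code{equiv_radius_um}.
#' @export
extractRois <- function(mask, pixelSize = 1) {
  labels <- maskLabels(mask)
  out <- list()
  for (class in c("host_N", "host_minusN", "diazoplast")) {
    bin <- labels == COMPARTMENT_CODES[[class]]
    if (!any(bin)) next
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(bin)))
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      a <- nrow(idx)
      out[[length(out) + 1L]] <- data.frame(
        roi_id = paste0(class, "_", k), class = class, component = k,
        area_px = a, area_um2 = a * pixelSize^2,
        centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]),
        equiv_radius_um = sqrt(a / pi) * pixelSize)
    }
  }
  if (!length(out)) {
    return(data.frame(roi_id = character(), class = character(),
                      component = integer(), area_px = integer(),
                      area_um2 = numeric(), centroid_row = numeric(),
                      centroid_col = numeric(), equiv_radius_um = numeric()))
  }
  do.call(rbind, out)
}

#' Correlation between sulfur and nitrogen signals across ROIs
#'
#' Pearson correlation of per-ROI mean 32S- and 12C14N- densities across
#' diazoplast and host(N) ROIs. A strong correlation indicates the CN-
#' signal tracks protein abundance.
#'
#' @param image an \linkS4class{IonCountImage}.
#' @param mask a \linkS4class{CompartmentMask} for the same raster.
#' @return list with \code{correlation}, \code{n} (ROIs used) and
#'   \code{status} (\code{"ok"}, \code{"missing_channel"} or
#'   \code{"undefined"}).
#' @export
sulfurCorrelation <- function(image, mask) {
  if (!"S32" %in% channelNames(image))
    return(list(correlation = NA_real_, n = 0L, status = "missing_channel"))
  rois <- extractRois(mask, pixelSize(image))
  rois <- rois[rois$class %in% c("diazoplast", "host_N"), , drop = FALSE]
  if (nrow(rois) < 3)
    stop("at least 3 diazoplast/host(N) ROIs required")
  labels <- maskLabels(mask)
  s32 <- getChannel(image, "S32"); c14n <- getChannel(image, "C14N")
  means <- t(vapply(seq_len(nrow(rois)), function(i) {
    bin <- labels == COMPARTMENT_CODES[[rois$class[i]]]
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(bin)))
    idx <- lab == rois$component[i]
    c(mean(s32[idx]), mean(c14n[idx]))
  }, numeric(2)))
  if (stats::sd(means[, 1]) == 0 || stats::sd(means[, 2]) == 0)
    return(list(correlation = NA_real_, n = nrow(rois),
                status = "undefined"))
  list(correlation = stats::cor(means[, 1], means[, 2]), n = nrow(rois),
       status = "ok")
}
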