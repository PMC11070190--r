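#' Isotope atom percent with counting-statistics uncertainty
#'
#' Atom percent is the heavy-isotopologue share of the summed isotopologue
#' counts, \code{100 * heavy / (heavy + light)} — for nitrogen,
#' 12C15N- / (12C15N- + 12C14N-); for carbon, 13C12C- / (13C12C- + 12C12C-).
#' Under the Poisson count model, the heavy count conditional on the total
#' is binomial, so the standard error is the binomial
#' \code{100 * sqrt(p (1 - p) / n)}. A zero total yields an undefined
#' (flagged) result rather than an error.
#'
#' @param heavy heavy-isotopologue counts (vectorised).
#' @param light light-isotopologue counts.
#' @return data.frame with columns \code{atom_pct}, \code{se},
#'   \code{defined}.
#' @examples
#' atomPercent(377, 99623)   # the scale of unlabeled 15N controls
#' atomPercent(500, 500)     # 50% with SE ~ 1.58%
#' @export
atomPercent <- function(heavy, light) {
  stopifnot(length(heavy) == length(light),
            all(heavy >= 0), all(light >= 0))
  total <- heavy + light
  p <- ifelse(total > 0, heavy / total, NA_real_)
  se <- ifelse(total > 0, 100 * sqrt(p * (1 - p) / total), NA_real_)
  data.frame(atom_pct = 100 * p, se = se, defined = total > 0)
}

## Pool counts over a pixel index set and form the ratio-of-sums estimate.
poolAtomPercent <- function(heavyMat, lightMat, idx) {
  atomPercent(sum(heavyMat[idx]), sum(lightMat[idx]))
}

#' Quantify isotope enrichment per ROI
#'
#' Counts are pooled over each ROI's pixels before the ratio is taken
#' (ratio-of-sums; per-pixel ratios are undefined or biased at low counts).
#' Both isotopes are computed when the required channels are present;
#' otherwise the corresponding columns are \code{NA}.
#'
#' @param image an \linkS4class{IonCountImage}.
#' @param mask the \linkS4class{CompartmentMask} for the same raster.
#' @param rois ROI table from \code{\link{extractRois}}; computed from
#'   \code{mask} when omitted.
#' @param cellId cell identifier recorded in the output.
#' @return data.frame with one row per ROI: \code{cell_id}, \code{roi_id},
#'   \code{class}, \code{area_px}, pooled channel counts
#'   (\code{n_C14N}, \code{n_C15N}, \code{n_C2}, \code{n_C13C},
#'   \code{n_S32}), \code{atom15N}, \code{se15N}, \code{atom13C},
#'   \code{se13C}.
#' @export
quantifyRois <- function(image, mask, rois = NULL, cellId = 1L) {
  if (is.null(rois)) rois <- extractRois(mask, pixelSize(image))
  labels <- maskLabels(mask)
  chans <- channelNames(image)
  has15N <- all(c("C14N", "C15N") %in% chans)
  has13C <- all(c("C2", "C13C") %in% chans)

  compLabels <- lapply(c(host_N = "host_N", host_minusN = "host_minusN",
                         diazoplast = "diazoplast"), function(class) {
    bin <- labels == COMPARTMENT_CODES[[class]]
    if (any(bin)) as.matrix(EBImage::bwlabel(EBImage::Image(bin))) else NULL
  })

  rows <- lapply(seq_len(nrow(rois)), function(i) {
    lab <- compLabels[[rois$class[i]]]
    idx <- lab == rois$component[i]
    counts <- vapply(ION_CHANNELS, function(nm) {
      if (nm %in% chans) sum(getChannel(image, nm)[idx]) else NA_real_
    }, numeric(1))
    a15 <- if (has15N) poolAtomPercent(getChannel(image, "C15N"),
                                       getChannel(image, "C14N"), idx)
           else data.frame(atom_pct = NA_real_, se = NA_real_, defined = FALSE)
    a13 <- if (has13C) poolAtomPercent(getChannel(image, "C13C"),
                                       getChannel(image, "C2"), idx)
           else data.frame(atom_pct = NA_real_, se = NA_real_, defined = FALSE)
    data.frame(cell_id = cellId, roi_id = rois$roi_id[i],
               class = rois$class[i], area_px = rois$area_px[i],
               n_C14N = counts[["C14N"]], n_C15N = counts[["C15N"]],
               n_C2 = counts[["C2"]], n_C13C = counts[["C13C"]],
               n_S32 = counts[["S32"]],
               atom15N = a15$atom_pct, se15N = a15$se,
               atom13C = a13$atom_pct, se13C = a13$se)
  })
  if (!length(rows)) {
    return(data.frame(cell_id = integer(), roi_id = character(),
                      class = character(), area_px = integer(),
                      n_C14N = numeric(), n_C15N = numeric(),
                      n_C2 = numeric(), n_C13C = numeric(),
                      n_S32 = numeric(), atom15N = numeric(),
                      se15N = numeric(), atom13C = numeric(),
                      se13C = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibrate natural abundance from unlabeled control ROIs
#'
#' The unweighted mean and across-ROI standard deviation of the control
#' atom percent define the enrichment threshold \code{mean + 3 * SD}: the
#' natural-abundance band observed in unlabeled samples. The SD is the
#' across-measurement scatter (capturing instrument variability), not the
#' per-ROI counting-statistics SE.
#'
#' @param controlQuants data.frame of control ROI quantifications with an
#'   \code{atom15N} or \code{atom13C} column (e.g. from
#'   \code{\link{quantifyRois}}), or a numeric vector of control atom
#'   percents.
#' @param isotope \code{"15N"} or \code{"13C"}.
#' @return a \linkS4class{NaturalAbundanceCalibration}.
#' @examples
#' calibrateNaturalAbundance(c(0.375, 0.377, 0.379), "15N")
#' @export
calibrateNaturalAbundance <- function(controlQuants,
                                      isotope = c("15N", "13C")) {
  isotope <- match.arg(isotope)
  vals <- if (is.data.frame(controlQuants)) {
    col <- if (isotope == "15N") "atom15N" else "atom13C"
    controlQuants[[col]]
  } else {
    as.numeric(controlQuants)
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) < 3)
    stop("at least 3 control ROI measurements required")
  m <- mean(vals); s <- stats::sd(vals)
  new("NaturalAbundanceCalibration", isotope = isotope, mean = m, sd = s,
      threshold = m + 3 * s, nControls = length(vals))
}

#' Classify enrichment against a natural-abundance calibration
#'
#' A measurement is enriched iff its atom percent is strictly above the
#' calibration threshold (mean + 3 SD of unlabeled controls). Undefined
#' atom percents yield \code{NA} (unclassified).
#'
#' @param atomPct numeric atom percent value(s), or a data.frame with an
#'   \code{atom15N} / \code{atom13C} column matching the calibration.
#' @param calibration a \linkS4class{NaturalAbundanceCalibration}.
#' @return logical vector (\code{NA} where unclassified).
#' @export
classifyEnrichment <- function(atomPct, calibration) {
  stopifnot(is(calibration, "NaturalAbundanceCalibration"))
  if (is.data.frame(atomPct)) {
    col <- if (calibration@isotope == "15N") "atom15N" else "atom13C"
    atomPct <- atomPct[[col]]
  }
  atomPct > calibration@threshold
}

## Pool a cell's ROIs of one class into a single ratio-of-sums atom%.
poolCellClass <- function(quants, class, heavyCol, lightCol) {
  sub <- quants[quants$class == class, , drop = FALSE]
  if (nrow(sub) == 0 || all(is.na(sub[[heavyCol]]))) return(NULL)
  atomPercent(sum(sub[[heavyCol]], na.rm = TRUE),
              sum(sub[[lightCol]], na.rm = TRUE))
}

#' Population activity summary and isotope co-classification
#'
#' A cell contains an actively fixing diazoplast iff its pooled diazoplast
#' ROI is 15N-enriched; it is carbon-fixing iff its pooled host(N) ROI is
#' 13C-enriched. Returns the two fractions with Wilson 95 percent
#' intervals and the 2x2 co-classification table over cells with both
#' calls defined.
#'
#' @param quants data.frame of ROI quantifications over many cells
#'   (columns as from \code{\link{quantifyRois}}, stacked).
#' @param calibration15N 15N \linkS4class{NaturalAbundanceCalibration}.
#' @param calibration13C optional 13C calibration; when omitted only the
#'   nitrogen side is classified.
#' @return list with \code{n_cells}, \code{fraction_active} (estimate +
#'   Wilson bounds), \code{fraction_fixing_c} (or \code{NULL}),
#'   \code{co_classification} 2x2 table, and the per-cell call data.frame.
#' @export
activitySummary <- function(quants, calibration15N, calibration13C = NULL) {
  cells <- split(quants, quants$cell_id)
  calls <- do.call(rbind, lapply(cells, function(q) {
    d <- poolCellClass(q, "diazoplast", "n_C15N", "n_C14N")
    h <- poolCellClass(q, "host_N", "n_C13C", "n_C2")
    data.frame(cell_id = q$cell_id[1],
               diazoplast_atom15N = if (!is.null(d)) d$atom_pct else NA_real_,
               host_atom13C = if (!is.null(h)) h$atom_pct else NA_real_)
  }))
  if (all(is.na(calls$diazoplast_atom15N)))
    stop("no diazoplast ROIs available for classification")
  calls$active15N <- classifyEnrichment(calls$diazoplast_atom15N,
                                        calibration15N)
  hasN <- !is.na(calls$active15N)
  wN <- wilsonInterval(sum(calls$active15N[hasN]), sum(hasN))

  fixC <- NULL; coTab <- NULL
  if (!is.null(calibration13C)) {
    calls$fixing13C <- classifyEnrichment(calls$host_atom13C, calibration13C)
    hasC <- !is.na(calls$fixing13C)
    if (any(hasC)) {
      wC <- wilsonInterval(sum(calls$fixing13C[hasC]), sum(hasC))
      fixC <- list(estimate = wC[["estimate"]], lower = wC[["lower"]],
                   upper = wC[["upper"]], n = sum(hasC))
    }
    both <- hasN & hasC
    if (any(both)) {
      coTab <- table(factor(ifelse(calls$active15N[both], "15N_active",
                                   "15N_inactive"),
                            levels = c("15N_active", "15N_inactive")),
                     factor(ifelse(calls$fixing13C[both], "13C_fixing",
                                   "13C_nonfixing"),
                            levels = c("13C_fixing", "13C_nonfixing")))
    }
  }
  list(n_cells = nrow(calls),
       fraction_active = list(estimate = wN[["estimate"]],
                              lower = wN[["lower"]], upper = wN[["upper"]],
                              n = sum(hasN)),
       fraction_fixing_c = fixC,
       co_classification = coTab,
       cell_calls = calls)
}
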