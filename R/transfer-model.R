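#' Excess enrichment above natural abundance
#'
#' Converts an atom percent to the excess atom fraction above the
#' calibrated natural-abundance baseline:
#' \code{(atom_pct - calibration mean) / 100}. Excess is proportional to
#' newly incorporated tracer. Negative excesses (measurement noise around
#' the baseline) are passed through unclamped.
#'
#' @param atomPct atom percent value(s).
#' @param calibration a \linkS4class{NaturalAbundanceCalibration}.
#' @return excess atom fraction(s).
#' @export
excessEnrichment <- function(atomPct, calibration) {
  stopifnot(is(calibration, "NaturalAbundanceCalibration"))
  (atomPct - calibration@mean) / 100
}

#' Regress host excess enrichment on diazoplast excess enrichment
#'
#' Least-squares fit of paired per-cell excess 15N enrichments, host(N) on
#' diazoplast, through the origin by default (a cell whose diazoplast fixed
#' nothing has no transferred nitrogen). For the through-origin fit the
#' reported R-squared uses the uncentered total sum of squares; with an
#' intercept the usual centered form is used.
#'
#' @param cells data.frame with numeric columns \code{x_d} (diazoplast
#'   excess) and \code{x_h} (host excess); at least 3 complete pairs.
#' @param intercept include an intercept term.
#' @return list with \code{slope}, \code{r2}, \code{intercept_value},
#'   \code{n}, and the underlying \code{lm} fit.
#' @export
fitHostVsDiazoplast <- function(cells, intercept = FALSE) {
  stopifnot(is.data.frame(cells), all(c("x_d", "x_h") %in% names(cells)))
  cells <- cells[stats::complete.cases(cells[, c("x_d", "x_h")]), ,
                 drop = FALSE]
  if (nrow(cells) < 3) stop("at least 3 paired cells required")
  if (length(unique(cells$x_d)) == 1L)
    stop("degenerate design: all diazoplast excesses identical")
  fit <- if (intercept) stats::lm(x_h ~ x_d, data = cells)
         else stats::lm(x_h ~ 0 + x_d, data = cells)
  slope <- unname(stats::coef(fit)[["x_d"]])
  res <- stats::residuals(fit)
  ssRes <- sum(res^2)
  ssTot <- if (intercept) sum((cells$x_h - mean(cells$x_h))^2)
           else sum(cells$x_h^2)
  list(slope = slope,
       r2 = if (ssTot > 0) 1 - ssRes / ssTot else NA_real_,
       intercept_value = if (intercept) unname(stats::coef(fit)[1]) else 0,
       n = nrow(cells), fit = fit)
}

#' Fraction of fixed nitrogen transferred to the host
#'
#' Volume-weighted mass balance: with equal nitrogen density per unit
#' volume across compartments, the newly fixed nitrogen in a compartment is
#' proportional to excess enrichment times volume. With host excess equal
#' to \code{s} times the diazoplast excess and a diazoplast:host(N) volume
#' ratio \code{v}, the host share of the newly fixed nitrogen is
#' \deqn{f = s V_h / (s V_h + V_d) = s / (s + v).}
#' At the reported slope 0.9 and volume ratio 0.06 this gives 0.9375, the
#' "roughly 93 percent transferred" headline.
#'
#' @param slope host:diazoplast excess-enrichment slope (>= 0).
#' @param volumeRatio diazoplast:host(N) volume ratio (> 0 unless
#'   \code{slope > 0}).
#' @return transfer fraction in [0, 1].
#' @examples
#' transferFraction(0.9, 0.06)
#' @export
transferFraction <- function(slope, volumeRatio) {
  stopifnot(slope >= 0, volumeRatio >= 0)
  if (slope == 0 && volumeRatio == 0)
    stop("transfer fraction undefined for slope = volume ratio = 0")
  slope / (slope + volumeRatio)
}

#' Bootstrap the transfer estimate over cells
#'
#' Cells are resampled with replacement \code{B} times; each resample
#' refits the through-origin slope and maps it through the mass balance,
#' giving a percentile confidence interval for the transferred fraction.
#' Resamples with a degenerate design (all diazoplast excesses equal) are
#' dropped; more than 10 percent degenerate draws is an error.
#'
#' @param cells paired cell data.frame (see
#'   \code{\link{fitHostVsDiazoplast}}); at least 5 cells.
#' @param volumeRatio diazoplast:host(N) volume ratio.
#' @param B number of bootstrap resamples (>= 100).
#' @param seed integer RNG seed.
#' @param conf confidence level for the percentile interval.
#' @param intercept passed to the regression.
#' @return a \linkS4class{TransferEstimate}.
#' @export
bootstrapTransfer <- function(cells, volumeRatio, B = 1000L, seed = 1L,
                              conf = 0.95, intercept = FALSE) {
  stopifnot(B >= 100)
  cells <- cells[stats::complete.cases(cells[, c("x_d", "x_h")]), ,
                 drop = FALSE]
  if (nrow(cells) < 5) stop("at least 5 paired cells required")
  point <- fitHostVsDiazoplast(cells, intercept = intercept)
  f0 <- transferFraction(max(point$slope, 0), volumeRatio)
  set.seed(as.integer(seed))
  fs <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(cells), replace = TRUE)
    sub <- cells[idx, , drop = FALSE]
    if (length(unique(sub$x_d)) == 1L) next
    sl <- tryCatch(fitHostVsDiazoplast(sub, intercept = intercept)$slope,
                   error = function(e) NA_real_)
    if (!is.na(sl)) fs[b] <- transferFraction(max(sl, 0), volumeRatio)
  }
  nBad <- sum(is.na(fs))
  if (nBad > 0.1 * B)
    stop(sprintf("bootstrap degenerate in %d of %d resamples", nBad, B))
  qs <- stats::quantile(fs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  new("TransferEstimate", slope = point$slope, r2 = point$r2,
      volumeRatio = volumeRatio, transferFraction = f0,
      ciLow = min(qs[1], f0), ciHigh = max(qs[2], f0),
      nCells = nrow(cells), nBootstrap = as.integer(B),
      seed = as.integer(seed))
}

#' Paired cell records from ROI quantifications
#'
#' Builds the regression input: per cell, the pooled diazoplast and host(N)
#' excess 15N enrichments (ratio-of-sums within each class), keeping only
#' cells where both compartments were measured.
#'
#' @param quants stacked ROI quantification table over cells.
#' @param calibration 15N \linkS4class{NaturalAbundanceCalibration}.
#' @return data.frame with \code{cell_id}, \code{x_d}, \code{x_h}.
#' @export
cellRecords <- function(quants, calibration) {
  cells <- split(quants, quants$cell_id)
  out <- do.call(rbind, lapply(cells, function(q) {
    d <- poolCellClass(q, "diazoplast", "n_C15N", "n_C14N")
    h <- poolCellClass(q, "host_N", "n_C15N", "n_C14N")
    if (is.null(d) || is.null(h) || !d$defined || !h$defined) return(NULL)
    data.frame(cell_id = q$cell_id[1],
               x_d = excessEnrichment(d$atom_pct, calibration),
               x_h = excessEnrichment(h$atom_pct, calibration))
  }))
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(), x_d = numeric(), x_h = numeric())
  }
  rownames(out) <- NULL
  out
}
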