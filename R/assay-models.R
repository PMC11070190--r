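## Diel acetylene-reduction-assay rate processing and efficiency-corrected
## relative qPCR expression.

#' Chlorophyll-normalized nitrogenase activity rate
#'
#' \code{rate = raw / (chlorophyll * duration)}: ethylene produced per
#' microgram chlorophyll per hour.
#'
#' @param raw ethylene amount produced during the assay.
#' @param chlorophyll chlorophyll content, micrograms (> 0).
#' @param duration assay duration, hours (> 0).
#' @return normalized rate(s).
#' @export
normalizeRate <- function(raw, chlorophyll, duration) {
  if (any(chlorophyll <= 0)) stop("chlorophyll must be positive")
  if (any(duration <= 0)) stop("duration must be positive")
  raw / (chlorophyll * duration)
}

#' Day/night contrast of a diel activity series
#'
#' Phase means over replicates, their ratio, the timepoint of maximal mean
#' rate, and a "no clear diel pattern" flag raised when the day:night
#' ratio falls inside \code{[1/ratioCut, ratioCut]} — the flat profile of
#' the diazoplast, as opposed to the night-restricted activity of its
#' free-living relative.
#'
#' @param series data.frame with columns \code{time}, \code{phase}
#'   (\code{"day"}/\code{"night"}), \code{rate} (and optionally
#'   \code{replicate}); at least 2 timepoints per phase.
#' @param ratioCut fold-difference defining a clear diel pattern.
#' @return list with \code{day_mean}, \code{night_mean},
#'   \code{day_night_ratio}, \code{peak_time}, \code{peak_phase},
#'   \code{no_diel_pattern}.
#' @export
dielContrast <- function(series, ratioCut = 2) {
  stopifnot(is.data.frame(series),
            all(c("time", "phase", "rate") %in% names(series)),
            ratioCut >= 1)
  for (ph in c("day", "night")) {
    if (length(unique(series$time[series$phase == ph])) < 2)
      stop("at least 2 timepoints required in phase: ", ph)
  }
  dayMean <- mean(series$rate[series$phase == "day"])
  nightMean <- mean(series$rate[series$phase == "night"])
  ratio <- dayMean / nightMean
  byTime <- stats::aggregate(rate ~ time + phase, data = series, FUN = mean)
  pk <- byTime[which.max(byTime$rate), ]
  list(day_mean = dayMean, night_mean = nightMean,
       day_night_ratio = ratio,
       peak_time = pk$time, peak_phase = pk$phase,
       no_diel_pattern = ratio >= 1 / ratioCut && ratio <= ratioCut)
}

#' Treatment effect on activity rates
#'
#' Percent reduction of the treated series relative to the matched control,
#' \code{100 * (1 - mean_treated / mean_control)}, with a bootstrap
#' percentile confidence interval over replicates and a Welch t-test on
#' per-replicate mean rates as an annotation.
#'
#' @param control,treated data.frames with columns \code{time},
#'   \code{replicate}, \code{rate}; matching timepoint sets, at least 2
#'   replicates each.
#' @param B bootstrap resamples.
#' @param seed integer RNG seed.
#' @param conf confidence level.
#' @return list with \code{reduction_pct}, \code{ci_low}, \code{ci_high},
#'   \code{p_value}, \code{mean_control}, \code{mean_treated}.
#' @export
treatmentEffect <- function(control, treated, B = 2000L, seed = 1L,
                            conf = 0.95) {
  stopifnot(is.data.frame(control), is.data.frame(treated))
  if (!setequal(unique(control$time), unique(treated$time)))
    stop("control and treated series must share timepoints")
  repC <- stats::aggregate(rate ~ replicate, data = control, FUN = mean)$rate
  repT <- stats::aggregate(rate ~ replicate, data = treated, FUN = mean)$rate
  if (length(repC) < 2 || length(repT) < 2)
    stop("at least 2 replicates required in each series")
  mC <- mean(repC); mT <- mean(repT)
  if (mC == 0) stop("control mean rate is zero; reduction undefined")
  red <- 100 * (1 - mT / mC)
  set.seed(as.integer(seed))
  boots <- vapply(seq_len(B), function(b) {
    bc <- mean(sample(repC, replace = TRUE))
    bt <- mean(sample(repT, replace = TRUE))
    if (bc == 0) NA_real_ else 100 * (1 - bt / bc)
  }, numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  pv <- tryCatch(stats::t.test(repC, repT)$p.value,
                 error = function(e) NA_real_)
  list(reduction_pct = red, ci_low = qs[1], ci_high = qs[2],
       p_value = pv, mean_control = mC, mean_treated = mT,
       n_control = length(repC), n_treated = length(repT))
}

#' Combine several reference-gene Cq values
#'
#' Reference genes are combined as the geometric mean of their Cq-implied
#' expression levels; the effective reference Cq is the value whose level
#' equals that geometric mean. With a single shared efficiency this reduces
#' to the arithmetic mean of the reference Cqs.
#'
#' @param cqs numeric vector or matrix (rows = samples) of reference Cqs.
#' @param efficiency amplification factor per cycle, in (1, 2].
#' @return effective reference Cq per sample.
#' @export
combineReferenceCq <- function(cqs, efficiency = 2) {
  if (efficiency <= 1 || efficiency > 2) stop("efficiency must lie in (1, 2]")
  if (is.matrix(cqs)) rowMeans(cqs) else mean(cqs)
}

#' Efficiency-corrected relative expression and fold changes
#'
#' Each record's relative level is
#' \code{efficiency ^ (Cq_reference - Cq_target)} (the classical
#' 2^-deltaCt when efficiency is 2). Per gene and condition, levels are
#' summarized by their geometric mean; the fold change per gene is the
#' night:day ratio of geometric means (or the ratio of the second to the
#' first condition present).
#'
#' @param records data.frame with columns \code{gene}, \code{condition},
#'   \code{cq_target}, \code{cq_reference}, \code{efficiency}.
#' @param conditions optional length-2 character giving the denominator
#'   and numerator conditions of the fold change (defaults to
#'   \code{c("day", "night")} when present).
#' @return list with \code{levels} (per-record relative levels appended),
#'   \code{summary} (gene x condition geometric means), \code{folds}
#'   (per-gene fold change with a Welch t-test on log levels).
#' @export
relativeExpression <- function(records, conditions = NULL) {
  stopifnot(is.data.frame(records),
            all(c("gene", "condition", "cq_target", "cq_reference",
                  "efficiency") %in% names(records)))
  if (any(records$cq_target <= 0 | records$cq_reference <= 0))
    stop("Cq values must be positive")
  if (any(records$efficiency <= 1 | records$efficiency > 2))
    stop("efficiency must lie in (1, 2]")
  records$level <- records$efficiency ^
    (records$cq_reference - records$cq_target)

  summ <- stats::aggregate(level ~ gene + condition, data = records,
                           FUN = geoMean)
  conds <- unique(records$condition)
  if (is.null(conditions)) {
    conditions <- if (all(c("day", "night") %in% conds)) c("day", "night")
                  else conds[seq_len(min(2, length(conds)))]
  }
  folds <- NULL
  if (length(conditions) == 2 && all(conditions %in% conds)) {
    folds <- do.call(rbind, lapply(unique(records$gene), function(g) {
      a <- records$level[records$gene == g &
                           records$condition == conditions[1]]
      b <- records$level[records$gene == g &
                           records$condition == conditions[2]]
      if (!length(a) || !length(b)) return(NULL)
      pv <- if (length(a) >= 2 && length(b) >= 2)
        tryCatch(stats::t.test(log(a), log(b))$p.value,
                 error = function(e) NA_real_) else NA_real_
      data.frame(gene = g, denominator = conditions[1],
                 numerator = conditions[2],
                 fold_change = geoMean(b) / geoMean(a), p_value = pv)
    }))
  }
  list(levels = records, summary = summ, folds = folds)
}
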