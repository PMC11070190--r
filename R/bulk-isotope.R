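## Delta-notation arithmetic for bulk IRMS measurements.

#' VPDB 13C/12C reference ratio
#' @export
VPDB_RATIO <- 0.0111802

#' Convert between delta notation and isotope ratios
#'
#' \code{deltaToRatio} maps a per-mil delta value versus a standard to the
#' heavy:light isotope ratio \code{R = R_std * (1 + delta / 1000)};
#' \code{ratioToDelta} is its exact inverse. Deltas at or below -1000 per
#' mil would imply a non-positive ratio and are rejected.
#'
#' @param delta delta value(s), per mil vs the standard.
#' @param ratio isotope ratio(s).
#' @param standardRatio the standard's isotope ratio (default VPDB 13C/12C).
#' @return numeric vector.
#' @examples
#' deltaToRatio(-19)                  # unlabeled biomass
#' ratioToDelta(deltaToRatio(2837))   # round-trip
#' @export
deltaToRatio <- function(delta, standardRatio = VPDB_RATIO) {
  stopifnot(standardRatio > 0)
  if (any(delta <= -1000))
    stop("delta must exceed -1000 per mil (ratio would be non-positive)")
  standardRatio * (1 + delta / 1000)
}

#' @rdname deltaToRatio
#' @export
ratioToDelta <- function(ratio, standardRatio = VPDB_RATIO) {
  stopifnot(standardRatio > 0, all(ratio >= 0))
  1000 * (ratio / standardRatio - 1)
}

#' Convert between isotope ratios and atom percent
#'
#' \code{ratioToAtomPercent} maps a heavy:light ratio to the heavy-atom
#' percentage \code{100 R / (1 + R)}; \code{atomPercentToRatio} is its
#' exact inverse for atom percent below 100. Links the bulk delta scale to
#' the nanoSIMS atom percent scale.
#'
#' @param ratio isotope ratio(s), >= 0.
#' @param atomPct atom percent value(s), in [0, 100).
#' @return numeric vector.
#' @examples
#' ratioToAtomPercent(VPDB_RATIO)   # ~1.1056%
#' @export
ratioToAtomPercent <- function(ratio) {
  stopifnot(all(ratio >= 0))
  100 * ratio / (1 + ratio)
}

#' @rdname ratioToAtomPercent
#' @export
atomPercentToRatio <- function(atomPct) {
  stopifnot(all(atomPct >= 0))
  if (any(atomPct >= 100))
    stop("inverse undefined at atom percent = 100")
  p <- atomPct / 100
  p / (1 - p)
}

#' Compare bulk delta-13C measurements across conditions
#'
#' Per-condition mean, SD and n, pairwise Welch t-tests, and an enrichment
#' call per non-control condition reusing the 3-SD convention: a condition
#' is enriched when its mean exceeds the control mean plus three control
#' SDs. (The 3-SD rule here mirrors the single-cell convention; it is a
#' package convention for bulk data, not an inferential test.)
#'
#' @param samples data.frame with columns \code{condition} and
#'   \code{delta}; at least 2 samples in each of at least 2 conditions.
#' @param control name of the control condition.
#' @return list with \code{summary} (per-condition table including
#'   \code{enriched}), and \code{tests} (pairwise Welch results).
#' @export
compareConditions <- function(samples, control = "control") {
  stopifnot(is.data.frame(samples),
            all(c("condition", "delta") %in% names(samples)))
  conds <- unique(samples$condition)
  if (length(conds) < 2) stop("at least two conditions required")
  n <- table(samples$condition)
  if (any(n < 2)) stop("at least 2 samples required per condition")
  if (!control %in% conds)
    stop("control condition not found: ", control)

  summ <- do.call(rbind, lapply(conds, function(cc) {
    d <- samples$delta[samples$condition == cc]
    data.frame(condition = cc, n = length(d), mean = mean(d),
               sd = stats::sd(d))
  }))
  ctrl <- summ[summ$condition == control, ]
  cut <- ctrl$mean + 3 * ctrl$sd
  summ$enriched <- summ$condition != control & summ$mean > cut

  pairs <- utils::combn(conds, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    a <- samples$delta[samples$condition == pr[1]]
    b <- samples$delta[samples$condition == pr[2]]
    tt <- stats::t.test(a, b)
    data.frame(condition_a = pr[1], condition_b = pr[2],
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  }))
  list(summary = summ, control_threshold = cut, tests = tests)
}
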