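#' Simulation configuration for nanoSIMS-like single-cell images
#'
#' Describes the study conditions emulated by the synthetic-data generator:
#' one focal diatom cell per raster, an elliptical host containing several
#' spherical diazoplasts and nitrogen-depleted storage compartments
#' (host(-N)), Poisson ion counts per pixel and channel, and a labeled /
#' unlabeled population structure in which a stated fraction of cells carry
#' actively fixing diazoplasts whose host enrichment is a fixed multiple of
#' the diazoplast enrichment.
#'
#' Count densities are expected counts per pixel for the summed CN- and C2-
#' isotopologue pairs; the isotopologue split is binomial with the
#' compartment's true atom fraction. The 32S- channel is Poisson with mean
#' proportional to the CN- density (sulfur tracks protein). Natural
#' abundances are the physical constants for air nitrogen and VPDB-scale
#' carbon; the instrument offsets shift the simulated baseline to the values
#' measured in unlabeled controls (0.377 atom% 15N, 1.74 atom% 13C).
#'
#' @slot gridSize raster rows and columns (pixels).
#' @slot pixelSize pixel side, micrometres.
#' @slot hostAxes host ellipse semi-major and semi-minor axes, micrometres.
#' @slot nDiazoplasts diazoplasts per cell.
#' @slot diazoplastRadius diazoplast radius, micrometres.
#' @slot vacuoleFraction fraction of host area occupied by host(-N) discs.
#' @slot nVacuoles number of host(-N) discs.
#' @slot cnDensity expected CN- counts/pixel per compartment (named).
#' @slot c2Density expected C2- counts/pixel per compartment (named).
#' @slot s32Factor 32S- density as a multiple of CN- density.
#' @slot nat15N,nat13C natural isotope atom fractions.
#' @slot offset15N,offset13C additive instrument offsets (atom fraction).
#' @slot fracActive fraction of cells with 15N-fixing diazoplasts.
#' @slot fracFixingC fraction of cells fixing 13C-bicarbonate.
#' @slot enrichmentMean,enrichmentCV lognormal mean and CV of the diazoplast
#'   excess 15N atom fraction in active cells.
#' @slot c13EnrichmentMean mean host(N) excess 13C atom fraction in
#'   carbon-fixing cells (same CV as 15N).
#' @slot hostRatio host excess 15N as a multiple of diazoplast excess.
#' @slot maxPlacementRetries rejection-sampling retry bound per disc.
#' @slot seed global RNG seed fanned out to all draws.
#' @export
setClass("SimConfig",
  representation(gridSize = "integer", pixelSize = "numeric",
                 hostAxes = "numeric", nDiazoplasts = "integer",
                 diazoplastRadius = "numeric", vacuoleFraction = "numeric",
                 nVacuoles = "integer", cnDensity = "numeric",
                 c2Density = "numeric", s32Factor = "numeric",
                 nat15N = "numeric", nat13C = "numeric",
                 offset15N = "numeric", offset13C = "numeric",
                 fracActive = "numeric", fracFixingC = "numeric",
                 enrichmentMean = "numeric", enrichmentCV = "numeric",
                 c13EnrichmentMean = "numeric", hostRatio = "numeric",
                 maxPlacementRetries = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  fr <- c(object@vacuoleFraction, object@fracActive, object@fracFixingC,
          object@nat15N, object@nat13C)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  if (any(object@cnDensity < 0) || any(object@c2Density < 0))
    return("count densities must be non-negative")
  need <- names(COMPARTMENT_CODES)
  if (!all(need %in% names(object@cnDensity)) ||
      !all(need %in% names(object@c2Density)))
    return("count densities must be named for all four compartment classes")
  if (object@hostRatio < 0) return("hostRatio must be non-negative")
  if (object@diazoplastRadius >= min(object@hostAxes))
    return("diazoplast radius must be smaller than the host semi-minor axis")
  ext <- object@hostAxes / (object@gridSize[2:1] * object@pixelSize / 2)
  if (any(ext >= 1)) return("host ellipse must fit inside the grid")
  TRUE
})

#' Construct a SimConfig
#'
#' Defaults reproduce the study conditions: a ~20 um long host (10 x 5 um
#' semi-axes) containing four diazoplasts of radius 1.55 um, giving a
#' diazoplast:host volume ratio of about 6 percent under the
#' sphere/spheroid model; 70 percent of cells active after the 12-h light
#' incubation; host excess 15N equal to 0.9 times the diazoplast excess;
#' baselines of 0.377 atom% 15N and 1.74 atom% 13C in unlabeled material.
#'
#' @param gridSize,pixelSize,hostAxes,nDiazoplasts,diazoplastRadius
#'   geometry; see slot documentation.
#' @param vacuoleFraction,nVacuoles host(-N) storage-compartment geometry.
#' @param cnDensity,c2Density,s32Factor expected counts per pixel.
#' @param nat15N,nat13C,offset15N,offset13C isotope baselines.
#' @param fracActive,fracFixingC,enrichmentMean,enrichmentCV,
#'   c13EnrichmentMean,hostRatio population labeling structure.
#' @param maxPlacementRetries,seed plumbing.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- SimConfig(seed = 7)
#' cfg
#' @export
SimConfig <- function(gridSize = c(128L, 128L), pixelSize = 0.25,
                      hostAxes = c(10, 5), nDiazoplasts = 4L,
                      diazoplastRadius = 1.55, vacuoleFraction = 0.10,
                      nVacuoles = 2L,
                      cnDensity = c(background = 2, host_N = 100,
                                    host_minusN = 5, diazoplast = 200),
                      c2Density = c(background = 2, host_N = 80,
                                    host_minusN = 150, diazoplast = 80),
                      s32Factor = 0.3,
                      nat15N = 0.003663, nat13C = 0.0111,
                      offset15N = 0.000107, offset13C = 0.0063,
                      fracActive = 0.70, fracFixingC = 0.90,
                      enrichmentMean = 0.01, enrichmentCV = 0.5,
                      c13EnrichmentMean = 0.02, hostRatio = 0.9,
                      maxPlacementRetries = 100L, seed = 1L) {
  new("SimConfig", gridSize = as.integer(gridSize), pixelSize = pixelSize,
      hostAxes = as.numeric(hostAxes), nDiazoplasts = as.integer(nDiazoplasts),
      diazoplastRadius = diazoplastRadius, vacuoleFraction = vacuoleFraction,
      nVacuoles = as.integer(nVacuoles), cnDensity = cnDensity,
      c2Density = c2Density, s32Factor = s32Factor, nat15N = nat15N,
      nat13C = nat13C, offset15N = offset15N, offset13C = offset13C,
      fracActive = fracActive, fracFixingC = fracFixingC,
      enrichmentMean = enrichmentMean, enrichmentCV = enrichmentCV,
      c13EnrichmentMean = c13EnrichmentMean, hostRatio = hostRatio,
      maxPlacementRetries = as.integer(maxPlacementRetries),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@gridSize[1], "x", object@gridSize[2], "px at",
      object@pixelSize, "um/px\n")
  cat(sprintf("  host %g x %g um; %d diazoplast(s) r = %g um; vacuole fraction %g\n",
              object@hostAxes[1], object@hostAxes[2], object@nDiazoplasts,
              object@diazoplastRadius, object@vacuoleFraction))
  cat(sprintf("  baseline 15N %.4f%%, 13C %.4f%%; frac active %.2f; host ratio %.2f; seed %d\n",
              100 * (object@nat15N + object@offset15N),
              100 * (object@nat13C + object@offset13C),
              object@fracActive, object@hostRatio, object@seed))
})

## Baseline atom fractions as measured on the instrument.
baseline15N <- function(config) config@nat15N + config@offset15N
baseline13C <- function(config) config@nat13C + config@offset13C

## Pixel-centre coordinate grids in micrometres (x along columns, y along
## rows, origin top-left).
pixelGrid <- function(config) {
  nr <- config@gridSize[1]; nc <- config@gridSize[2]
  px <- config@pixelSize
  list(x = matrix(rep((seq_len(nc) - 0.5) * px, each = nr), nr, nc),
       y = matrix(rep((seq_len(nr) - 0.5) * px, times = nc), nr, nc))
}

#' Generate the compartment geometry for one simulated cell
#'
#' Draws one host ellipse centred on the grid, places \code{nDiazoplasts}
#' non-overlapping diazoplast discs and \code{nVacuoles} host(-N) discs
#' strictly inside it by rejection sampling, and computes compartment
#' volumes under a prolate-spheroid (host) / sphere (diazoplast, vacuole)
#' model.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param cellIndex integer cell id recorded in the result.
#' @return a \linkS4class{GroundTruth} with the label image and volumes;
#'   atom fractions are initialised to the unlabeled baseline and the cell
#'   marked inactive (the population simulator overwrites these).
#' @examples
#' truth <- makeCellGeometry(SimConfig(seed = 1))
#' table(truth@labels)
#' @export
makeCellGeometry <- function(config, cellIndex = 1L) {
  g <- pixelGrid(config)
  a <- config@hostAxes[1]; b <- config@hostAxes[2]
  cx <- config@gridSize[2] * config@pixelSize / 2
  cy <- config@gridSize[1] * config@pixelSize / 2
  labels <- matrix(COMPARTMENT_CODES[["background"]],
                   config@gridSize[1], config@gridSize[2])
  inHost <- ((g$x - cx) / a)^2 + ((g$y - cy) / b)^2 <= 1
  labels[inHost] <- COMPARTMENT_CODES[["host_N"]]

  rv <- if (config@vacuoleFraction > 0 && config@nVacuoles > 0) {
    sqrt(config@vacuoleFraction * a * b / config@nVacuoles)
  } else 0
  radii <- c(rep(config@diazoplastRadius, config@nDiazoplasts),
             rep(rv, if (rv > 0) config@nVacuoles else 0L))
  codes <- c(rep(COMPARTMENT_CODES[["diazoplast"]], config@nDiazoplasts),
             rep(COMPARTMENT_CODES[["host_minusN"]],
                 if (rv > 0) config@nVacuoles else 0L))

  # keep discs a few pixels clear of the host boundary so interior
  # compartments stay resolvable (and topologically interior) on the raster
  inset <- 3 * config@pixelSize
  if (length(radii) && max(radii) + inset >= b)
    stop("geometry infeasible: disc radius exceeds host semi-minor axis")
  placeAll <- function() {
    centres <- matrix(numeric(0), 0, 2)
    placed <- numeric(0)
    for (i in seq_along(radii)) {
      r <- radii[i]
      ok <- FALSE
      for (try in seq_len(config@maxPlacementRetries)) {
        # uniform in the ellipse shrunk by r + inset
        u <- sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
        px <- cx + (a - r - inset) * u * cos(th)
        py <- cy + (b - r - inset) * u * sin(th)
        if (nrow(centres) == 0 ||
            all(sqrt((centres[, 1] - px)^2 + (centres[, 2] - py)^2) >
                placed + r + 2 * config@pixelSize)) {
          ok <- TRUE; break
        }
      }
      if (!ok) return(NULL)
      centres <- rbind(centres, c(px, py)); placed <- c(placed, r)
    }
    centres
  }
  centres <- NULL
  for (attempt in seq_len(100L)) {
    centres <- placeAll()
    if (!is.null(centres)) break
  }
  if (is.null(centres))
    stop("geometry infeasible: could not place ", length(radii),
         " non-overlapping discs after bounded retries")
  for (i in seq_along(radii)) {
    disc <- (g$x - centres[i, 1])^2 + (g$y - centres[i, 2])^2 <= radii[i]^2
    labels[disc] <- codes[i]
  }

  vols <- c(background = 0,
            host_N = 4 / 3 * pi * a * b^2,
            host_minusN = if (rv > 0) config@nVacuoles * 4 / 3 * pi * rv^3 else 0,
            diazoplast = config@nDiazoplasts * 4 / 3 * pi *
              config@diazoplastRadius^3)
  base <- c(background = baseline15N(config), host_N = baseline15N(config),
            host_minusN = baseline15N(config), diazoplast = baseline15N(config))
  base13 <- c(background = baseline13C(config), host_N = baseline13C(config),
              host_minusN = baseline13C(config), diazoplast = baseline13C(config))
  new("GroundTruth", labels = labels, atom15N = base, atom13C = base13,
      active = FALSE, activeC = FALSE, volumes = vols,
      cellId = as.integer(cellIndex))
}

#' Simulate a multi-channel ion-count image from a ground-truth cell
#'
#' Per pixel, the summed CN- count is Poisson with the compartment's CN-
#' density and is split binomially between 12C15N- and 12C14N- by the
#' compartment's true 15N atom fraction; the C2- pair is split likewise by
#' the true 13C fraction; 32S- is Poisson with mean proportional to the CN-
#' density. With \code{noiseless = TRUE}, counts are set to their rounded
#' expectations (used to verify segmentation on noise-free rasters).
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param config the \linkS4class{SimConfig} used to build \code{truth}.
#' @param seed optional integer seed set before drawing.
#' @param noiseless logical; emit expected rather than sampled counts.
#' @return an \linkS4class{IonCountImage} with channels
#'   \code{C14N, C15N, C2, C13C, S32}.
#' @export
simulateIonImage <- function(truth, config, seed = NULL, noiseless = FALSE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  labels <- truth@labels
  n <- length(labels)
  C14N <- C15N <- C2 <- C13C <- S32 <- integer(n)
  for (class in names(COMPARTMENT_CODES)) {
    idx <- which(labels == COMPARTMENT_CODES[[class]])
    if (!length(idx)) next
    cn <- config@cnDensity[[class]]
    c2 <- config@c2Density[[class]]
    p15 <- truth@atom15N[[class]]
    p13 <- truth@atom13C[[class]]
    if (noiseless) {
      cnTot <- rep.int(round(cn), length(idx))
      c2Tot <- rep.int(round(c2), length(idx))
      heavyN <- round(cnTot * p15)
      heavyC <- round(c2Tot * p13)
      s <- rep.int(round(config@s32Factor * cn), length(idx))
    } else {
      cnTot <- stats::rpois(length(idx), cn)
      c2Tot <- stats::rpois(length(idx), c2)
      heavyN <- stats::rbinom(length(idx), cnTot, p15)
      heavyC <- stats::rbinom(length(idx), c2Tot, p13)
      s <- stats::rpois(length(idx), config@s32Factor * cn)
    }
    C15N[idx] <- heavyN; C14N[idx] <- cnTot - heavyN
    C13C[idx] <- heavyC; C2[idx] <- c2Tot - heavyC
    S32[idx] <- s
  }
  dims <- dim(labels)
  IonCountImage(list(C14N = matrix(C14N, dims[1], dims[2]),
                     C15N = matrix(C15N, dims[1], dims[2]),
                     C2 = matrix(C2, dims[1], dims[2]),
                     C13C = matrix(C13C, dims[1], dims[2]),
                     S32 = matrix(S32, dims[1], dims[2])),
                pixelSize = config@pixelSize,
                metadata = list(cell_id = truth@cellId,
                                active = truth@active,
                                noiseless = noiseless))
}

#' Simulate a labeled cell population with ground truth
#'
#' Each cell is active (15N2-fixing diazoplast) with probability
#' \code{fracActive} and carbon-fixing with probability \code{fracFixingC}.
#' Active cells draw a diazoplast excess 15N atom fraction from a lognormal
#' with mean \code{enrichmentMean} and CV \code{enrichmentCV}; the host(N)
#' excess is \code{hostRatio} times the diazoplast excess. Carbon-fixing
#' cells enrich host(N) by a lognormal excess with mean
#' \code{c13EnrichmentMean}; the host(-N) storage compartment receives 1.5x
#' and the diazoplast 0.8x that excess (fixed carbon accumulates in storage
#' and is shared with the symbiont). Inactive cells stay at the unlabeled
#' baseline. All randomness derives from \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param nCells number of cells (>= 1).
#' @param noiseless emit expectation images instead of Poisson draws.
#' @return list of length \code{nCells}; each element is
#'   \code{list(image = IonCountImage, truth = GroundTruth)}.
#' @examples
#' pop <- simulatePopulation(SimConfig(seed = 3), 2)
#' pop[[1]]$truth@active
#' @export
simulatePopulation <- function(config, nCells, noiseless = FALSE) {
  stopifnot(nCells >= 1)
  seeds <- fanOutSeeds(config@seed, nCells + 1L)
  set.seed(seeds[1])
  active <- stats::runif(nCells) < config@fracActive
  activeC <- stats::runif(nCells) < config@fracFixingC
  lp <- lognormalParams(config@enrichmentMean, max(config@enrichmentCV, 1e-12))
  e15 <- stats::rlnorm(nCells, lp$meanlog, lp$sdlog)
  lpc <- lognormalParams(config@c13EnrichmentMean,
                         max(config@enrichmentCV, 1e-12))
  e13 <- stats::rlnorm(nCells, lpc$meanlog, lpc$sdlog)

  lapply(seq_len(nCells), function(i) {
    set.seed(seeds[i + 1L])
    truth <- makeCellGeometry(config, cellIndex = i)
    if (active[i]) {
      truth@active <- TRUE
      truth@atom15N[["diazoplast"]] <-
        min(1, baseline15N(config) + e15[i])
      truth@atom15N[["host_N"]] <-
        min(1, baseline15N(config) + config@hostRatio * e15[i])
    }
    if (activeC[i]) {
      truth@activeC <- TRUE
      truth@atom13C[["host_N"]] <- min(1, baseline13C(config) + e13[i])
      truth@atom13C[["host_minusN"]] <-
        min(1, baseline13C(config) + 1.5 * e13[i])
      truth@atom13C[["diazoplast"]] <-
        min(1, baseline13C(config) + 0.8 * e13[i])
    }
    list(image = simulateIonImage(truth, config, noiseless = noiseless),
         truth = truth)
  })
}

#' Simulate pooled isotopologue counts for control ROIs
#'
#' Draws \code{n} ROIs whose total isotopologue count is Poisson with mean
#' \code{totalCounts} and whose heavy-isotope count is binomial with the
#' given atom fraction — the counting-statistics model behind the
#' natural-abundance calibration.
#'
#' @param n number of ROIs.
#' @param totalCounts expected pooled count per ROI.
#' @param atomFraction true heavy-isotope atom fraction.
#' @param seed integer seed.
#' @return data.frame with columns \code{heavy}, \code{light}.
#' @export
simulateControlCounts <- function(n, totalCounts, atomFraction, seed = 1L) {
  stopifnot(n >= 1, totalCounts > 0, atomFraction >= 0, atomFraction <= 1)
  set.seed(as.integer(seed))
  tot <- stats::rpois(n, totalCounts)
  heavy <- stats::rbinom(n, tot, atomFraction)
  data.frame(heavy = heavy, light = tot - heavy)
}

#' Simulate bulk IRMS delta-13C measurements
#'
#' Gaussian measurement model about a true delta value (per mil vs VPDB).
#'
#' @param trueDelta true delta-13C in per mil.
#' @param noiseSd measurement standard deviation in per mil (>= 0).
#' @param n number of replicate measurements.
#' @param seed integer seed.
#' @return numeric vector of delta values.
#' @examples
#' simulateBulkIRMS(-19, 2, 5, seed = 1)
#' @export
simulateBulkIRMS <- function(trueDelta, noiseSd, n, seed = 1L) {
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  stats::rnorm(n, trueDelta, noiseSd)
}

#' Canonical diel acetylene-reduction profiles
#'
#' \code{"flat"} emulates the diazoplast (activity throughout the diel
#' cycle, no clear pattern); \code{"night_peaked"} emulates the free-living
#' relative, with activity restricted to the night and peaking 4 h into it.
#' Hours 0-12 are day, 12-24 night.
#'
#' @param type profile shape.
#' @param level rate scale (activity per ug chlorophyll per hour).
#' @return data.frame with columns \code{time}, \code{phase}, \code{rate}.
#' @export
dielProfile <- function(type = c("flat", "night_peaked"), level = 1) {
  type <- match.arg(type)
  time <- c(1, 4, 8, 11, 13, 16, 20, 23)
  phase <- rep(c("day", "night"), each = 4)
  rate <- switch(type,
    flat = rep(level, 8),
    night_peaked = level * c(0.05, 0.05, 0.05, 0.05, 0.5, 1, 0.6, 0.2))
  data.frame(time = time, phase = phase, rate = rate)
}

#' Simulate paired control / treated diel ARA series
#'
#' Replicated rates are drawn around the base profile with multiplicative
#' Gaussian noise; the treated series mean is \code{treatmentFactor} times
#' the control mean at every timepoint (e.g. 0.4 for the dark / DCMU
#' inhibition of daytime nitrogenase activity).
#'
#' @param baseProfile data.frame with \code{time}, \code{phase},
#'   \code{rate} (all rates >= 0), e.g. from \code{\link{dielProfile}}.
#' @param treatmentFactor multiplicative treatment effect (>= 0).
#' @param noiseCV coefficient of variation of the multiplicative noise.
#' @param nReplicates replicates per timepoint per series.
#' @param seed integer seed.
#' @return list with data.frames \code{control} and \code{treated}, columns
#'   \code{time}, \code{phase}, \code{replicate}, \code{rate}.
#' @export
simulateDielARA <- function(baseProfile, treatmentFactor = 1, noiseCV = 0.1,
                            nReplicates = 6L, seed = 1L) {
  stopifnot(is.data.frame(baseProfile),
            all(c("time", "phase", "rate") %in% names(baseProfile)))
  if (any(baseProfile$rate < 0)) stop("base profile rates must be >= 0")
  if (treatmentFactor < 0) stop("treatmentFactor must be >= 0")
  set.seed(as.integer(seed))
  draw <- function(meanRates) {
    do.call(rbind, lapply(seq_len(nReplicates), function(r) {
      noisy <- meanRates * pmax(0, 1 + stats::rnorm(length(meanRates), 0, noiseCV))
      data.frame(time = baseProfile$time, phase = baseProfile$phase,
                 replicate = r, rate = noisy)
    }))
  }
  list(control = draw(baseProfile$rate),
       treated = draw(treatmentFactor * baseProfile$rate))
}

#' Simulate an RT-qPCR quantification-cycle table
#'
#' Two conditions are generated for one gene: the first at relative level 1
#' (target Cq equal to the reference Cq), the second offset by
#' \code{-log(trueFold) / log(efficiency)} cycles so that the
#' efficiency-corrected fold change between conditions is \code{trueFold}.
#' Gaussian noise of SD \code{noiseSd} cycles is added to every Cq.
#'
#' @param trueFold true fold change of condition 2 relative to condition 1
#'   (> 0), e.g. 10 for the night:day contrast of glycogen phosphorylase in
#'   the free-living relative.
#' @param efficiency amplification factor per cycle, in (1, 2].
#' @param cqRef reference-gene quantification cycle.
#' @param noiseSd Cq noise SD in cycles.
#' @param n replicates per condition.
#' @param seed integer seed.
#' @param gene gene label.
#' @param conditions length-2 character, condition labels.
#' @return data.frame with columns \code{gene}, \code{condition},
#'   \code{replicate}, \code{cq_target}, \code{cq_reference},
#'   \code{efficiency}.
#' @export
simulateQPCR <- function(trueFold, efficiency = 2, cqRef = 20,
                         noiseSd = 0.2, n = 4L, seed = 1L, gene = "gene",
                         conditions = c("day", "night")) {
  if (trueFold <= 0) stop("trueFold must be positive")
  if (efficiency <= 1 || efficiency > 2)
    stop("efficiency must lie in (1, 2]")
  stopifnot(n >= 1, length(conditions) == 2L)
  set.seed(as.integer(seed))
  offset <- -log(trueFold) / log(efficiency)
  out <- do.call(rbind, lapply(1:2, function(k) {
    data.frame(gene = gene, condition = conditions[k], replicate = seq_len(n),
               cq_target = cqRef + (k - 1) * offset +
                 stats::rnorm(n, 0, noiseSd),
               cq_reference = cqRef + stats::rnorm(n, 0, noiseSd),
               efficiency = efficiency)
  }))
  rownames(out) <- NULL
  out
}
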