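test_that("atom percent and its binomial SE follow the closed form", {
  expect_equal(atomPercent(0, 1000)$atom_pct, 0)
  expect_equal(atomPercent(377, 99623)$atom_pct, 0.377)
  half <- atomPercent(500, 500)
  expect_equal(half$atom_pct, 50)
  expect_equal(half$se, 100 * sqrt(0.25 / 1000), tolerance = 1e-12)
  # zero total: flagged, not an error
  z <- atomPercent(0, 0)
  expect_false(z$defined)
  expect_true(is.na(z$atom_pct))
})

test_that("atom percent is scale-invariant with sqrt(k) SE shrinkage", {
  for (k in c(4, 25, 100)) {
    a <- atomPercent(37, 963)
    b <- atomPercent(37 * k, 963 * k)
    expect_equal(b$atom_pct, a$atom_pct, tolerance = 1e-12)
    expect_equal(b$se, a$se / sqrt(k), tolerance = 1e-12)
  }
  expect_true(all(atomPercent(c(0, 5, 10), c(10, 5, 0))$atom_pct >= 0))
  expect_true(all(atomPercent(c(0, 5, 10), c(10, 5, 0))$atom_pct <= 100))
})

test_that("a single-pixel ROI equals the pixel's atom percent", {
  img <- IonCountImage(list(C14N = matrix(c(80L, 0L, 0L, 0L), 2, 2),
                            C15N = matrix(c(20L, 0L, 0L, 0L), 2, 2),
                            C2 = matrix(0L, 2, 2), C13C = matrix(0L, 2, 2)))
  labels <- matrix(0L, 2, 2); labels[1, 1] <- 3L
  q <- quantifyRois(img, CompartmentMask(labels))
  expect_equal(q$atom15N, atomPercent(20, 80)$atom_pct)
})

test_that("pooled ROI estimates recover a known enrichment within 3 SE", {
  cfg <- smallConfig(seed = 41)
  set.seed(41)
  truth <- makeCellGeometry(cfg)
  truth@atom15N[["diazoplast"]] <- 0.01   # 1.0 atom%
  img <- simulateIonImage(truth, cfg, seed = 41)
  cm <- CompartmentMask(truth@labels)
  q <- quantifyRois(img, cm)
  d <- q[q$class == "diazoplast", ]
  for (i in seq_len(nrow(d)))
    expect_lt(abs(d$atom15N[i] - 1.0), 3 * d$se15N[i])
  # storage compartment accumulates the most C2 signal per pixel
  expect_gt(mean(q$n_C2[q$class == "host_minusN"] /
                   q$area_px[q$class == "host_minusN"]),
            mean(q$n_C2[q$class == "host_N"] / q$area_px[q$class == "host_N"]))
})

test_that("missing channels mark the isotope unavailable", {
  img <- IonCountImage(list(C14N = matrix(50L, 4, 4),
                            C15N = matrix(1L, 4, 4)))
  labels <- matrix(1L, 4, 4)
  q <- quantifyRois(img, CompartmentMask(labels))
  expect_false(is.na(q$atom15N))
  expect_true(is.na(q$atom13C))
})

test_that("natural-abundance calibration implements mean + 3 SD", {
  calA <- calibrateNaturalAbundance(rep(0.377, 3), "15N")
  expect_equal(calA@threshold, 0.377)
  # equally spaced controls with mean 0.377 and SD exactly 0.012
  calB <- calibrateNaturalAbundance(c(0.365, 0.377, 0.389), "15N")
  expect_equal(calB@mean, 0.377)
  expect_equal(calB@sd, 0.012)
  expect_equal(calB@threshold, 0.377 + 3 * 0.012)
  expect_error(calibrateNaturalAbundance(c(0.377, 0.378), "15N"),
               "at least 3")
})

test_that("calibration recovers simulated control baselines", {
  counts <- simulateControlCounts(30, 1e5, 0.00377, seed = 42)
  ap <- atomPercent(counts$heavy, counts$light)
  cal <- calibrateNaturalAbundance(ap$atom_pct, "15N")
  pooledSE <- 100 * sqrt(0.00377 * (1 - 0.00377) /
                           sum(counts$heavy + counts$light))
  expect_lt(abs(cal@mean - 0.377), 3 * pooledSE * sqrt(30))
  # ratio-of-sums over all controls agrees with the calibration mean
  pooled <- atomPercent(sum(counts$heavy), sum(counts$light))
  expect_lt(abs(pooled$atom_pct - cal@mean), 3 * pooled$se)
})

test_that("enrichment calls are strict and monotone", {
  cal <- calibrateNaturalAbundance(c(0.365, 0.377, 0.389), "15N")
  expect_false(classifyEnrichment(cal@threshold, cal))
  expect_true(classifyEnrichment(1.2, cal))
  expect_true(is.na(classifyEnrichment(NA_real_, cal)))
  # monotone in atom%
  x <- seq(0, 2, by = 0.05)
  calls <- classifyEnrichment(x, cal)
  expect_true(all(diff(as.integer(calls)) >= 0))
})

test_that("unlabeled measurements are rarely called enriched", {
  ctrl <- simulateControlCounts(50, 1e5, 0.00377, seed = 43)
  cal <- calibrateNaturalAbundance(
    atomPercent(ctrl$heavy, ctrl$light)$atom_pct, "15N")
  probe <- simulateControlCounts(500, 1e5, 0.00377, seed = 44)
  calls <- classifyEnrichment(atomPercent(probe$heavy, probe$light)$atom_pct,
                              cal)
  expect_lte(mean(calls), 0.01)
})

test_that("median bias of recovered enrichment is below one SE", {
  # 100 ROIs at diazoplast-scale counting depth and 1.377 atom% truth
  truthPct <- 1.377
  counts <- simulateControlCounts(100, 96000, truthPct / 100, seed = 45)
  ap <- atomPercent(counts$heavy, counts$light)
  expect_lt(abs(median(ap$atom_pct) - truthPct), median(ap$se))
})

test_that("activity summary classifies cells from pooled compartment counts", {
  cfg <- smallConfig(seed = 46, fracActive = 0)
  pop <- simulatePopulation(cfg, 6)
  q <- quantifyPopulation(pop)
  ctrl <- simulateControlCounts(20, 2e5, 0.00377, seed = 47)
  cal <- calibrateNaturalAbundance(
    atomPercent(ctrl$heavy, ctrl$light)$atom_pct, "15N")
  act <- activitySummary(q, cal)
  expect_equal(act$fraction_active$estimate, 0)
  expect_equal(act$n_cells, 6)
  # no diazoplast ROIs anywhere is an error
  qHost <- q[q$class == "host_N", ]
  expect_error(activitySummary(qHost, cal), "no diazoplast")
})
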