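test_that("uniform images fail with an empty-image error", {
  flat <- IonCountImage(list(C14N = matrix(2L, 32, 32)))
  expect_error(segmentCell(flat), "empty image")
})

test_that("cell mask covers nearly all true cell pixels", {
  cfg <- smallConfig(seed = 31)
  pop <- simulatePopulation(cfg, 3)
  for (cell in pop) {
    m <- segmentCell(cell$image)
    trueCell <- cell$truth@labels > 0
    expect_gt(sum(m & trueCell) / sum(trueCell), 0.95)
  }
})

test_that("only the largest connected component is retained", {
  # two blobs of different size on a flat background
  cn <- matrix(2L, 48, 48)
  cn[5:14, 5:14] <- 120L        # 100 px blob
  cn[30:45, 30:45] <- 120L      # 256 px blob
  img <- IonCountImage(list(C14N = cn))
  m <- segmentCell(img)
  expect_false(any(m[5:14, 5:14]))
  expect_true(all(m[34:41, 34:41]))
})

test_that("compartment classes agree with ground truth on noisy rasters", {
  cfg <- SimConfig(seed = 32)
  pop <- simulatePopulation(cfg, 5)
  for (cell in pop) {
    m <- segmentCell(cell$image)
    cm <- segmentCompartments(cell$image, m)
    tl <- cell$truth@labels; sl <- maskLabels(cm)
    inCell <- tl > 0
    expect_gt(mean(sl[inCell] == tl[inCell]), 0.90)
    # compartment CN ordering: diazoplast > host(N) > host(-N)
    cn <- getChannel(cell$image, "C14N")
    expect_gt(mean(cn[sl == 3]), mean(cn[sl == 1]))
    expect_gt(mean(cn[sl == 1]), mean(cn[sl == 2]))
  }
})

test_that("classes are disjoint, exhaustive, and deterministic", {
  cfg <- smallConfig(seed = 33)
  pop <- simulatePopulation(cfg, 1)
  img <- pop[[1]]$image
  m <- segmentCell(img)
  cmA <- segmentCompartments(img, m)
  cmB <- segmentCompartments(img, m)
  expect_identical(maskLabels(cmA), maskLabels(cmB))
  # partition of the cell mask: labeled iff inside the mask
  expect_identical(maskLabels(cmA) > 0,
                   matrix(as.vector(m), nrow(m), ncol(m)))
  expect_equal(sum(maskLabels(cmA) > 0), sum(m))
})

test_that("noiseless rasters are recovered exactly away from class boundaries", {
  for (s in c(34, 35)) {
    cfg <- SimConfig(seed = s)
    set.seed(s)
    truth <- makeCellGeometry(cfg)
    img <- simulateIonImage(truth, cfg, noiseless = TRUE)
    cm <- segmentCompartments(img, segmentCell(img))
    tl <- truth@labels
    keep <- tl > 0 & !boundaryBand(tl)
    expect_equal(mean(maskLabels(cm)[keep] == tl[keep]), 1)
  }
})

test_that("cells without diazoplasts yield zero diazoplast components", {
  cfg <- smallConfig(seed = 36, nDiazoplasts = 0L)
  pop <- simulatePopulation(cfg, 1)
  cm <- segmentCompartments(pop[[1]]$image, segmentCell(pop[[1]]$image))
  expect_equal(cm@provenance$nDiazoplastComponents, 0)
  expect_false(any(maskLabels(cm) == 3))
  expect_true(any(maskLabels(cm) == 1))
  expect_true(any(maskLabels(cm) == 2))
})

test_that("ROI extraction conserves pixel counts and geometry", {
  cfg <- smallConfig(seed = 37)
  pop <- simulatePopulation(cfg, 1)
  cm <- segmentCompartments(pop[[1]]$image, segmentCell(pop[[1]]$image))
  rois <- extractRois(cm, pixelSize = 0.25)
  for (cls in unique(rois$class)) {
    expect_equal(sum(rois$area_px[rois$class == cls]),
                 sum(maskLabels(cm) == classCode(cls)))
  }
  expect_equal(rois$area_um2, rois$area_px * 0.25^2)
})

test_that("equivalent radius of a rasterized disc matches its true radius", {
  labels <- matrix(0L, 64, 64)
  r <- 10.5
  labels[(row(labels) - 32)^2 + (col(labels) - 32)^2 <= r^2] <- 3L
  rois <- extractRois(CompartmentMask(labels), pixelSize = 1)
  expect_equal(nrow(rois), 1)
  expect_lt(abs(rois$equiv_radius_um - r) / r, 0.05)
})

test_that("sulfur tracks the nitrogen signal across protein-rich ROIs", {
  cfg <- smallConfig(seed = 38)
  pop <- simulatePopulation(cfg, 1)
  img <- pop[[1]]$image
  cm <- segmentCompartments(img, segmentCell(img))
  res <- sulfurCorrelation(img, cm)
  expect_equal(res$status, "ok")
  expect_gte(res$correlation, 0.9)
  # constant sulfur channel: correlation undefined, flagged
  chans <- img@channels
  chans$S32 <- matrix(7L, nrow(chans$S32), ncol(chans$S32))
  res2 <- sulfurCorrelation(IonCountImage(chans, pixelSize(img)), cm)
  expect_equal(res2$status, "undefined")
  expect_true(is.na(res2$correlation))
  # missing channel: explicit skip status
  res3 <- sulfurCorrelation(IonCountImage(chans["C14N"], pixelSize(img)), cm)
  expect_equal(res3$status, "missing_channel")
})

test_that("sulfur correlation requires at least three ROIs", {
  labels <- matrix(0L, 32, 32)
  labels[5:10, 5:10] <- 1L
  labels[20:25, 20:25] <- 3L
  img <- IonCountImage(list(C14N = matrix(5L, 32, 32),
                            S32 = matrix(2L, 32, 32)))
  expect_error(sulfurCorrelation(img, CompartmentMask(labels)), "3")
})
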