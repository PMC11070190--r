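test_that("degenerate geometry yields only host and background", {
  cfg <- smallConfig(nDiazoplasts = 0L, vacuoleFraction = 0)
  set.seed(1)
  truth <- makeCellGeometry(cfg)
  expect_setequal(unique(as.vector(truth@labels)), c(0L, 1L))
  expect_equal(truth@volumes[["diazoplast"]], 0)
  expect_equal(truth@volumes[["host_minusN"]], 0)
})

test_that("default geometry reproduces the ~6% diazoplast:host volume ratio", {
  cfg <- SimConfig()
  set.seed(2)
  truth <- makeCellGeometry(cfg)
  # closed form: 4 spheres r = 1.55 um over a 10 x 5 um prolate spheroid
  expect_equal(truth@volumes[["diazoplast"]] / truth@volumes[["host_N"]],
               4 * 1.55^3 / (10 * 5^2), tolerance = 1e-12)
  expect_equal(truth@volumes[["host_N"]], 4 / 3 * pi * 10 * 5^2,
               tolerance = 1e-12)
})

test_that("requested number of diazoplasts appear as distinct components", {
  cfg <- SimConfig(nDiazoplasts = 4L)
  set.seed(3)
  truth <- makeCellGeometry(cfg)
  lab <- EBImage::bwlabel(EBImage::Image(truth@labels == 3L))
  expect_equal(max(lab), 4)
})

test_that("label image partitions the grid", {
  for (s in 1:3) {
    set.seed(s)
    truth <- makeCellGeometry(smallConfig(seed = s))
    counts <- table(factor(truth@labels, levels = 0:3))
    expect_equal(sum(counts), prod(dim(truth@labels)))
  }
})

test_that("infeasible geometry fails explicitly", {
  cfg <- smallConfig()
  expect_error(SimConfig(gridSize = c(64L, 64L), hostAxes = c(10, 5)),
               "fit inside the grid")
  # disc too large for the host
  expect_error({
    set.seed(1)
    makeCellGeometry(smallConfig(diazoplastRadius = 2.4))
  }, "infeasible")
})

test_that("zero count densities give an all-zero image", {
  cfg <- smallConfig(cnDensity = c(background = 0, host_N = 0,
                                   host_minusN = 0, diazoplast = 0),
                     c2Density = c(background = 0, host_N = 0,
                                   host_minusN = 0, diazoplast = 0),
                     s32Factor = 0)
  set.seed(1)
  truth <- makeCellGeometry(cfg)
  img <- simulateIonImage(truth, cfg, seed = 1)
  for (nm in channelNames(img)) expect_true(all(getChannel(img, nm) == 0))
})

test_that("pooled isotopologue split converges to the true atom fraction", {
  # ~1e4 pixels at CN density 200 and 15N fraction 0.00377
  cfg <- SimConfig(seed = 9)
  set.seed(9)
  truth <- makeCellGeometry(cfg)
  truth@atom15N[] <- 0.00377
  img <- simulateIonImage(truth, cfg, seed = 9)
  heavy <- sum(getChannel(img, "C15N")); light <- sum(getChannel(img, "C14N"))
  p <- heavy / (heavy + light)
  se <- sqrt(0.00377 * (1 - 0.00377) / (heavy + light))
  expect_lt(abs(p - 0.00377), 3 * se)
})

test_that("host(-N) has background CN counts but high C2 counts", {
  cfg <- SimConfig(seed = 4)
  set.seed(4)
  truth <- makeCellGeometry(cfg)
  img <- simulateIonImage(truth, cfg, seed = 4)
  cn <- getChannel(img, "C14N"); c2 <- getChannel(img, "C2")
  vac <- truth@labels == 2L; host <- truth@labels == 1L
  bg <- truth@labels == 0L
  expect_lt(mean(cn[vac]), 0.2 * mean(cn[host]))
  expect_lt(abs(mean(cn[vac]) - mean(cn[bg])), 5)
  expect_gt(mean(c2[vac]), mean(c2[host]))
})

test_that("population simulation is reproducible and respects labeling structure", {
  cfg <- smallConfig(seed = 7, fracActive = 0.7)
  popA <- simulatePopulation(cfg, 5)
  popB <- simulatePopulation(cfg, 5)
  for (i in 1:5) {
    expect_identical(popA[[i]]$image@channels, popB[[i]]$image@channels)
    expect_identical(popA[[i]]$truth@labels, popB[[i]]$truth@labels)
  }
  base <- cfg@nat15N + cfg@offset15N
  for (cell in popA) {
    t <- cell$truth
    if (t@active) {
      # host excess is exactly hostRatio times the diazoplast excess
      expect_equal((t@atom15N[["host_N"]] - base) /
                     (t@atom15N[["diazoplast"]] - base),
                   cfg@hostRatio, tolerance = 1e-9)
    } else {
      expect_equal(unname(t@atom15N[["diazoplast"]]), base, tolerance = 1e-12)
    }
  }
})

test_that("fully inactive populations stay at natural abundance", {
  cfg <- smallConfig(seed = 11, fracActive = 0, fracFixingC = 0)
  pop <- simulatePopulation(cfg, 4)
  base <- cfg@nat15N + cfg@offset15N
  for (cell in pop)
    expect_true(all(abs(cell$truth@atom15N - base) < 1e-12))
})

test_that("realized active fraction is binomially consistent with frac_active", {
  cfg <- smallConfig(seed = 13, fracActive = 0.7)
  pop <- simulatePopulation(cfg, 200)
  frac <- mean(vapply(pop, function(c) c$truth@active, logical(1)))
  bounds <- 0.7 + c(-1, 1) * 1.96 * sqrt(0.7 * 0.3 / 200)
  expect_gt(frac, bounds[1]); expect_lt(frac, bounds[2])
})

test_that("bulk IRMS simulation follows the Gaussian model", {
  expect_equal(simulateBulkIRMS(-19, 0, 5, seed = 1), rep(-19, 5))
  x <- simulateBulkIRMS(-19, 2, 100, seed = 2)
  expect_lt(abs(mean(x) + 19), 3 * 2 / sqrt(100))
  expect_error(simulateBulkIRMS(-19, -1, 5), "non-negative")
})

test_that("diel ARA simulation applies the treatment factor", {
  prof <- dielProfile("flat")
  sim <- simulateDielARA(prof, treatmentFactor = 1, noiseCV = 0, seed = 1)
  expect_equal(mean(sim$treated$rate), mean(sim$control$rate))
  expect_error(simulateDielARA(transform(prof, rate = -rate - 1), 0.4),
               ">= 0")
})

test_that("qPCR simulation hits the exact Cq offset", {
  tab <- simulateQPCR(trueFold = 1, noiseSd = 0, seed = 1)
  expect_equal(tab$cq_target, tab$cq_reference)
  tab10 <- simulateQPCR(trueFold = 10, efficiency = 2, noiseSd = 0, seed = 1)
  night <- tab10[tab10$condition == "night", ]
  dCq <- night$cq_target[1] - night$cq_reference[1]
  expect_equal(dCq, -log2(10), tolerance = 1e-9)
  expect_error(simulateQPCR(trueFold = 0), "positive")
  expect_error(simulateQPCR(trueFold = 2, efficiency = 2.5), "efficiency")
})
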