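test_that("rate normalization divides by chlorophyll and duration", {
  expect_equal(normalizeRate(0, 2, 1), 0)
  expect_equal(normalizeRate(10, 2, 1), 5)
  expect_equal(normalizeRate(10, 4, 1), normalizeRate(10, 2, 1) / 2)
  expect_error(normalizeRate(10, 0, 1), "chlorophyll")
  expect_error(normalizeRate(10, 2, 0), "duration")
})

test_that("diel contrast flags flat series and finds the night peak", {
  flat <- simulateDielARA(dielProfile("flat"), noiseCV = 0, seed = 1)$control
  res <- dielContrast(flat)
  expect_equal(res$day_night_ratio, 1)
  expect_true(res$no_diel_pattern)

  peaked <- simulateDielARA(dielProfile("night_peaked"), noiseCV = 0.05,
                            seed = 2)$control
  resP <- dielContrast(peaked)
  expect_false(resP$no_diel_pattern)
  expect_equal(resP$peak_time, 16)       # 4 h into the night
  expect_equal(resP$peak_phase, "night")

  dayOnly <- flat[flat$phase == "day", ]
  expect_error(dielContrast(dayOnly), "night")
})

test_that("diel flag transitions monotonically with effect size", {
  flags <- vapply(c(1, 1.5, 4, 10), function(k) {
    prof <- dielProfile("flat")
    prof$rate[prof$phase == "night"] <- k
    s <- simulateDielARA(prof, noiseCV = 0.02, seed = 3)$control
    dielContrast(s)$no_diel_pattern
  }, logical(1))
  expect_true(all(diff(as.integer(flags)) <= 0))
  expect_true(flags[1]); expect_false(flags[4])
})

test_that("treatment effect recovers exact and simulated reductions", {
  mk <- function(rates) do.call(rbind, lapply(seq_along(rates), function(r)
    data.frame(time = c(4, 8), replicate = r, rate = rates[r])))
  expect_equal(treatmentEffect(mk(c(10, 10, 10)), mk(c(10, 10, 10)),
                               B = 200)$reduction_pct, 0)
  expect_equal(treatmentEffect(mk(c(10, 10, 10)), mk(c(4, 4, 4)),
                               B = 200)$reduction_pct, 60)
  expect_error(treatmentEffect(mk(c(0, 0)), mk(c(1, 1)), B = 200), "zero")
  # invariance to common rescaling
  set.seed(4)
  c1 <- mk(rnorm(6, 10, 1)); t1 <- mk(rnorm(6, 4, 0.4))
  c2 <- transform(c1, rate = rate * 7); t2 <- transform(t1, rate = rate * 7)
  e1 <- treatmentEffect(c1, t1, B = 200, seed = 5)
  e2 <- treatmentEffect(c2, t2, B = 200, seed = 5)
  expect_equal(e1$reduction_pct, e2$reduction_pct, tolerance = 1e-12)
  expect_equal(e1$ci_low, e2$ci_low, tolerance = 1e-10)
})

test_that("simulated photosynthesis inhibition recovers a ~60% reduction", {
  sim <- simulateDielARA(dielProfile("flat"), treatmentFactor = 0.4,
                         noiseCV = 0.1, nReplicates = 6, seed = 6)
  eff <- treatmentEffect(sim$control, sim$treated, B = 500, seed = 7)
  expect_lt(abs(eff$reduction_pct - 60), 10)
  expect_lt(eff$p_value, 0.01)
})

test_that("relative expression matches the classical 2^-ddCt", {
  rec <- simulateQPCR(trueFold = 10, efficiency = 2, noiseSd = 0, seed = 8)
  res <- relativeExpression(rec)
  expect_equal(res$folds$fold_change, 10, tolerance = 1e-9)
  # oracle identity on arbitrary noisy Cqs: eff = 2 reduces to 2^-ddCt
  set.seed(9)
  rec2 <- simulateQPCR(trueFold = 4, efficiency = 2, noiseSd = 0.3, seed = 9)
  res2 <- relativeExpression(rec2)
  dct <- rec2$cq_target - rec2$cq_reference
  ddct <- mean(dct[rec2$condition == "night"]) -
    mean(dct[rec2$condition == "day"])
  expect_equal(res2$folds$fold_change, 2^(-ddct), tolerance = 1e-9)
})

test_that("relative expression levels and input validation", {
  rec <- data.frame(gene = "glgP", condition = "day", replicate = 1,
                    cq_target = 22, cq_reference = 22, efficiency = 2)
  expect_equal(relativeExpression(rec)$levels$level, 1)
  bad <- transform(rec, efficiency = 2.4)
  expect_error(relativeExpression(bad), "efficiency")
  expect_error(relativeExpression(transform(rec, cq_target = -1)),
               "positive")
})

test_that("simulated night upregulation is recovered at or above 10-fold", {
  rec <- simulateQPCR(trueFold = 10, efficiency = 2, noiseSd = 0.2,
                      n = 6, seed = 10, gene = "glgP")
  res <- relativeExpression(rec)
  expect_gt(res$folds$fold_change, 10 / 1.5)
  expect_lt(res$folds$fold_change, 10 * 1.5)
})

test_that("reference genes combine by geometric mean of implied levels", {
  expect_equal(combineReferenceCq(c(20, 22), 2), 21)
  m <- matrix(c(20, 22, 18, 20), 2, 2)
  expect_equal(combineReferenceCq(m, 2), c(19, 21))
  expect_error(combineReferenceCq(c(20, 22), 2.5), "efficiency")
})
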