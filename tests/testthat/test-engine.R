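test_that("the neutral clone is a deterministic full binary expansion", {
  rec <- simulateClone(neutralParameters(), seed = 1, lineage = TRUE)
  expect_identical(peakSize(rec), 1024)       # exactly 2^10
  expect_false(isTumor(rec))
  expect_identical(rec@births, 2047)          # 2^11 - 1 cells ever born
  expect_identical(rec@deaths, 1024)          # every leaf dies
  tr <- lineageTree(rec)
  expect_identical(max(tr@d), 11L)            # ten divisions then death
  expect_identical(sum(tr@fate == 1L), 1023L) # internal divisions
  expect_true(all(tr@d[tr@fate == 2L] == 11L))
  # generation tracks division depth in the neutral model
  expect_identical(tr@gBirth, tr@d)
})

test_that("living-cell accounting balances at every event", {
  rec <- simulateClone(modelParameters(), seed = 5)
  ser <- countSeries(rec)
  expect_true(all(diff(ser$cells) %in% c(-1, 1)))
  expect_identical(ser$cells[nrow(ser)], 0)   # extinction
  expect_identical(max(ser$cells), peakSize(rec))
  expect_equal(2 * sum(diff(ser$cells) == 1) + 1, rec@births)
  expect_equal(sum(diff(ser$cells) == -1), rec@deaths)
  expect_gt(lifespanDays(rec), 0)
})

test_that("a degenerate detection threshold flags a tumor at birth", {
  rec <- simulateClone(modelParameters(detectThreshold = 1), seed = 1,
                      series = FALSE, snapshot = TRUE)
  expect_true(isTumor(rec))
  expect_identical(rec@timeToDetectionDays, 0)
  expect_identical(nrow(cellSnapshot(rec)), 1L)
})

test_that("cohorts are reproducible and order-independent by seed", {
  p <- modelParameters()
  a <- simulateCohort(30, p, seed = 11)
  b <- simulateCohort(30, p, seed = 11)
  expect_identical(cloneTable(a), cloneTable(b))
  # the same clone index gives the same clone regardless of cohort size
  big <- cloneTable(simulateCohort(12, p, seed = 11))
  expect_identical(big[1:12, ], cloneTable(a)[1:12, ])
  single <- simulateClone(p, seed = 11, cloneIndex = 3, series = FALSE)
  expect_identical(peakSize(single), cloneTable(a)$peak[3])
})

test_that("neutral cohorts never transform and report a zero lower bound", {
  cs <- simulateCohort(5, neutralParameters(), seed = 1)
  expect_equal(nTumors(cs), 0)
  expect_equal(tumorProbability(cs), 0)
  expect_equal(unname(confInt(cs)[1]), 0)
  expect_equal(median(cloneTable(cs)$peak), 1024)
})

test_that("peak and lifespan medians are stable across disjoint cohorts", {
  p <- modelParameters()
  a <- cloneTable(simulateCohort(1000, p, seed = 21))
  b <- cloneTable(simulateCohort(1000, p, seed = 22))
  expect_lt(abs(median(a$peak) - median(b$peak)) / median(a$peak), 0.01)
})

test_that("phenotype runs validate their initializer", {
  expect_error(phenotype(k = -0.1, alpha = 3.66, g = 17))
  expect_error(phenotype(k = 0.18, alpha = 3.66, g = 0))
  ph <- ticcPhenotype()
  expect_identical(ph@d, 17)                  # depth carried from history
  expect_identical(ticscPhenotype()@k, 0)
})

test_that("a senescent normal phenotype never spawns a tumor", {
  # k = 4, strongly negative alpha, past the programmed limit: death
  # precedes any expansion
  cs <- simulateFromPhenotype(phenotype(k = 4, alpha = -5, g = 12), n = 8,
                              params = modelParameters(), seed = 2)
  expect_equal(nTumors(cs), 0)
  expect_equal(tumorProbability(cs), 0)
  expect_true(all(cloneTable(cs)$peak <= 2))
})

test_that("phenotype roots honor the differentiation identity", {
  # root k = k_p(g) + mutationSum must reproduce the requested k exactly
  p <- modelParameters()
  rec <- simulateClone(neutralParameters(), seed = 1,
                       phenotype = phenotype(k = 0.18, alpha = 3.66,
                                             g = 17),
                       series = FALSE, lineage = TRUE)
  tr <- lineageTree(rec)
  expect_identical(tr@d[1], 17L)
  expect_identical(tr@gBirth[1], 17L)
})

test_that("the Garwood interval reproduces printed incidence bounds", {
  ci <- poissonExactCI(8, 305505000)
  expect_identical(signif(unname(ci[1]), 6), 1.13053e-8)
  # the printed upper bound is reproduced to ~5 significant figures (the
  # exact Garwood value is 5.15972e-8 in both R and an independent
  # reference implementation)
  expect_lt(abs(unname(ci[2]) - 5.15998e-8) / 5.15998e-8, 1e-4)
  expect_identical(unname(poissonExactCI(0, 100)[1]), 0)
  expect_error(poissonExactCI(8, 100, level = 1.2))
  # independent reference: the exact Poisson test's interval
  ref <- stats::poisson.test(8, conf.level = 0.95)$conf.int / 305505000
  expect_equal(unname(poissonExactCI(8, 305505000)), as.numeric(ref),
               tolerance = 1e-10)
})

test_that("the event-count guard censors pathological runs", {
  rec <- simulateClone(modelParameters(), seed = 4, maxEvents = 50,
                      series = FALSE)
  expect_true(rec@censored)
})

test_that("the series memory guard refuses oversized recordings", {
  expect_error(simulateClone(modelParameters(), seed = 5,
                             seriesBudget = 100),
               "series budget")
  expect_silent(rec <- simulateClone(modelParameters(), seed = 5,
                                     seriesBudget = 100, force = TRUE))
})
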