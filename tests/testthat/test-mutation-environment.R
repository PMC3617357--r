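test_that("environment draws are degenerate when betaSd = 0", {
  p <- modelParameters(betaSd = 0)
  expect_identical(drawEnvironment(10, p, seed = 1), rep(5, 10))
})

test_that("environment draws reproduce the configured moments", {
  x <- drawEnvironment(1e5, modelParameters(), seed = 99)
  expect_lt(abs(mean(x) - 5), 0.01)
  expect_lt(abs(sd(x) - 0.5), 0.01)
})

test_that("samplers are deterministic under a fixed seed", {
  p <- modelParameters()
  expect_identical(drawEnvironment(100, p, seed = 7),
                   drawEnvironment(100, p, seed = 7))
  expect_false(identical(drawEnvironment(100, p, seed = 7),
                         drawEnvironment(100, p, seed = 8)))
  expect_identical(drawMutationEffects(50, mutationModel(), seed = 3),
                   drawMutationEffects(50, mutationModel(), seed = 3))
  expect_identical(perturbInheritedAlpha(2.9, 50, p, seed = 3),
                   perturbInheritedAlpha(2.9, 50, p, seed = 3))
})

test_that("mutation-effect draws follow the configured family", {
  expect_identical(drawMutationEffects(2,
    mutationModel("pointmass", value = 0), seed = 1), c(0, 0))
  expect_identical(drawMutationEffects(0, mutationModel(), seed = 1),
                   numeric(0))
  # empirical mean within 3 SE of the closed-form mixture mean
  spec <- mutationModel()
  x <- drawMutationEffects(1e6, spec, seed = 11)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mutationEffectMean(spec)), 3 * se)
  # rare strong hits on both sides of a narrow bulk
  expect_lt(quantile(x, 1e-3), -0.15)       # de-differentiating tail
  expect_gt(quantile(x, 1 - 1e-3), 0.3)     # re-differentiating hits
  expect_lt(mean(abs(x) > 0.3), 0.02)       # the bulk is near-neutral
})

test_that("unknown mutation families are rejected", {
  expect_error(mutationModel("zipf"))
  expect_error(new("MutationModel", family = "levy",
                   params = c(value = 1)) |> validObject())
  expect_error(validObject(new("MutationModel", family = "mixture",
                               params = c(gaussMean = 0, gaussSd = -1,
                                          tailProb = 0.5,
                                          tailScale = 0.1))))
})

test_that("inherited alpha is perturbed by zero-mean noise", {
  p <- modelParameters()
  expect_identical(
    perturbInheritedAlpha(3.2, 5, modelParameters(inheritanceNoiseSd = 0),
                          seed = 2),
    rep(3.2, 5))
  x <- perturbInheritedAlpha(3.2, 1e5, p, seed = 2)
  expect_lt(abs(mean(x) - 3.2), 0.005)
  expect_lt(abs(sd(x) - p@inheritanceNoiseSd), 0.005)
})

test_that("the neutral configuration is fully deterministic", {
  p <- neutralParameters()
  r1 <- simulateClone(p, seed = 1)
  r2 <- simulateClone(p, seed = 2)      # no randomness left to differ
  expect_identical(countSeries(r1), countSeries(r2))
  expect_identical(peakSize(r1), peakSize(r2))
})
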