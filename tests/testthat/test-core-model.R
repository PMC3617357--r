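test_that("programmed proliferation is linear, signed and validated", {
  p <- modelParameters()
  expect_equal(programmedProliferation(c(1, 10, 11), p),
               c(15.3, 0, -1.7))
  g <- 1:15
  expect_true(all(diff(programmedProliferation(g, p)) < 0))
  expect_error(programmedProliferation(0, p))
  expect_error(programmedProliferation(2.5, p))
})

test_that("programmed differentiation saturates near 4 at the limit", {
  p <- modelParameters()
  expect_equal(programmedDifferentiation(0, p), 0)
  expect_equal(programmedDifferentiation(1, p),
               3.78 * (1 - exp(-0.4)) + 0.03, tolerance = 1e-12)
  # terminally differentiated cells carry k ~ 4.0 (within 5%)
  expect_lt(abs(programmedDifferentiation(10, p) - 4) / 4, 0.05)
  expect_true(all(diff(programmedDifferentiation(0:30, p)) > 0))
  expect_error(programmedDifferentiation(-1, p))
})

test_that("un-mutated cells die after the programmed window despite beta", {
  # alpha* = alpha_p + beta/k_p must turn negative past the limit so that
  # normal clones live 10-12 divisions
  p <- modelParameters()
  g <- (p@gLimit + 1):(p@gLimit + 5)
  astar <- programmedProliferation(g, p) +
    p@betaMean / programmedDifferentiation(g, p)
  expect_true(all(astar < 0))
})

test_that("constant-alpha propagation divides at exactly 1/alpha", {
  p <- modelParameters()
  for (a in c(0.5, 2, 7)) {
    res <- propagateCell(c(t = 0, alpha = a, c = 0, s = 1, g = 17), p,
                         mutationSum = -programmedDifferentiation(17, p),
                         beta = 0)
    expect_identical(res$event, "division")
    expect_equal(res$t, 1 / a, tolerance = 1e-9)
    expect_equal(res$alpha, a, tolerance = 1e-12)
  }
})

test_that("linear-alpha propagation crosses at the quadratic root", {
  # k = 0, beta = 5, alpha0 = -1: c(t) = -t + 2.5 t^2 hits +1 at
  # (1 + sqrt(11))/5
  p <- modelParameters()
  res <- propagateCell(c(t = 0, alpha = -1, c = 0, s = 1, g = 17), p,
                       mutationSum = -programmedDifferentiation(17, p),
                       beta = 5)
  expect_identical(res$event, "division")
  expect_equal(res$t, (1 + sqrt(11)) / 5, tolerance = 1e-9)
})

test_that("a cell pinned at its programmed rate drifts by beta alone", {
  # alpha = alpha_p and beta = 0: dalpha/dt = 0, so division at 1/alpha_p
  p <- modelParameters()
  g <- 4L
  ap <- programmedProliferation(g, p)
  res <- propagateCell(c(t = 0, alpha = ap, c = 0, s = 1, g = g), p,
                       mutationSum = 0, beta = 0)
  expect_identical(res$event, "division")
  expect_equal(res$alpha, ap, tolerance = 1e-9)
  expect_equal(res$t, 1 / ap, tolerance = 1e-9)
})

test_that("propagation rejects dead or malformed states", {
  p <- modelParameters()
  expect_error(propagateCell(c(t = 0, alpha = 1, c = 1, s = 1, g = 1), p))
  expect_error(propagateCell(c(t = 0, alpha = 1, c = -1, s = 1, g = 1), p))
  expect_error(propagateCell(c(t = 0, alpha = 1, c = 0, s = 0, g = 1), p))
})

test_that("k is clamped at zero and g never decreases", {
  p <- modelParameters()
  res <- propagateCell(c(t = 0, alpha = 3, c = 0, s = 0.4, g = 12), p,
                       mutationSum = -50, beta = 5)
  expect_identical(res$k, 0)         # clamped, not negative
  expect_gte(res$g, 12)
  # a senescing cell (alpha* < 0) keeps its generation
  res2 <- propagateCell(c(t = 0, alpha = 0.5, c = 0, s = 1, g = 12), p,
                        mutationSum = 0, beta = 5)
  expect_identical(res2$event, "death")
  expect_identical(res2$g, 12L)
})

test_that("event propagation censors when nothing can happen", {
  # alpha pinned at 0 with no drive: parameter pathology reported as
  # censoring, not an event
  p <- modelParameters(betaSd = 0, betaMean = 0)
  res <- propagateCell(c(t = 0, alpha = 0, c = 0, s = 1, g = 17), p,
                       mutationSum = -programmedDifferentiation(17, p),
                       beta = 0, tStop = 12)
  expect_identical(res$event, "censored")
  expect_equal(res$t, 12)
})

test_that("closed-form propagation matches the Euler oracle", {
  p <- modelParameters()
  st <- randomCellStates(150, seed = 421)
  for (i in seq_len(nrow(st))) {
    msum <- st$k[i] - programmedDifferentiation(st$g[i], p)
    state <- c(t = 0, alpha = st$alpha[i], c = st$c[i], s = st$s[i],
               g = st$g[i])
    cf <- propagateCell(state, p, mutationSum = msum, beta = st$beta[i],
                        tStop = 24)
    eu <- eulerPropagate(state, p, msum, st$beta[i], tStop = 24)
    expect_identical(cf$event, eu$event)
    expect_equal(cf$g, eu$g)
    if (cf$event == "censored")
      expect_lt(abs(cf$alpha - eu$alpha), 1e-2)
    expect_lt(oracleDeviationRefined(state, p, msum, st$beta[i], 24, cf,
                                        eu),
              1e-3)
  }
})
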