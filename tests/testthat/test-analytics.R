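test_that("clone statistics use midpoint medians and n-1 SDs", {
  expect_equal(cloneStats(data.frame(peak = 1024,
                                     lifespanDays = 500))["peak", ],
               data.frame(median = 1024, sd = 0, min = 1024, max = 1024,
                          n = 1, row.names = "peak"))
  st <- cloneStats(data.frame(peak = c(1024, 1030, 1040),
                              lifespanDays = c(500, 576, 600)))
  expect_identical(st["peak", "median"], 1030)
  expect_identical(st["lifespanDays", "median"], 576)
  # even-sized: midpoint of the central pair
  st2 <- cloneStats(data.frame(peak = c(1024, 1043), lifespanDays = 1:2))
  expect_identical(st2["peak", "median"], 1033.5)
  expect_equal(st["peak", "sd"], sd(c(1024, 1030, 1040)))
  expect_error(cloneStats(data.frame()))
})

test_that("cdf tables are monotone, complete and consistent with medians", {
  snap <- makeFixture("toy-snapshot")
  cdfs <- tumorCdfs(snap)
  for (v in c("d", "k", "alpha")) {
    tab <- cdfs[[v]]
    expect_true(all(diff(tab$cumprob) >= 0))
    expect_identical(tab$cumprob[nrow(tab)], 1)
    expect_true(all(diff(tab$breakpoint) > 0))
  }
  # hand-computed medians of the 20-cell fixture
  expect_equal(unname(cdfs$medians["k"]), 0.85)
  expect_identical(unname(cdfs$medians["alpha"]), 5.25)
  expect_identical(unname(cdfs$medians["d"]), 42)
  expect_identical(cdfs$stemFraction, 0.1)
  # degenerate snapshot: a single step
  dg <- tumorCdfs(data.frame(d = rep(44, 5), k = rep(0.3, 5),
                             alpha = rep(10, 5)))
  expect_true(all(dg$k$cumprob %in% c(0, 1)))
  expect_error(tumorCdfs(data.frame()))
})

test_that("cdf values equal hand-counted fractions", {
  snap <- data.frame(d = c(40, 41, 41, 44, 47), k = c(0, 0, 0.2, 0.5, 1.2),
                     alpha = c(-1, 2, 8, 8, 20))
  tab <- cdfTable(snap$k, c(0, 0.3, 0.6, 1.5))
  expect_equal(tab$cumprob, c(2, 3, 4, 5) / 5)
  expect_equal(cdfTable(snap$d, c(40, 44, 47))$cumprob, c(1, 4, 5) / 5)
})

test_that("the stem fraction counts cells at the zero clamp", {
  expect_identical(stemFraction(data.frame(k = c(0.2, 0.5, 1))), 0)
  expect_identical(stemFraction(data.frame(k = c(0, 0, rep(0.4, 8)))), 0.2)
  expect_error(stemFraction(data.frame(k = numeric(0))))
})

test_that("MRCA tables aggregate across tumors with exact degenerates", {
  tr <- makeFixture("toy-tree")
  tab1 <- mrcaTable(list(tr), x = c(1, 0.5))
  # single tumor: median = min = max in every row
  for (v in c("d", "alpha", "k")) {
    expect_identical(tab1[[v]]$median, tab1[[v]]$min)
    expect_identical(tab1[[v]]$median, tab1[[v]]$max)
    expect_identical(tab1[[v]]$sd, c(0, 0))
  }
  expect_identical(tab1$d$median[1], 1)        # x = 1 row is the root
  tab2 <- mrcaTable(list(tr, tr, tr), x = c(1, 0.5))
  expect_identical(tab2$d$sd, c(0, 0))
  # accepts precomputed phenotype tables interchangeably
  tab3 <- mrcaTable(list(mrcaPhenotypes(tr, c(1, 0.5)), tr), c(1, 0.5))
  expect_identical(tab3$d$median, tab1$d$median)
  expect_error(mrcaTable(list()))
})

test_that("the median cancer cell is the component-wise median", {
  one <- medianCell(data.frame(d = 44, g = 45, k = 0.3, alpha = 10.3))
  expect_identical(one$k, 0.3)
  expect_identical(one$d, 44)
  expect_identical(one$g, 45)
  expect_identical(
    medianCell(data.frame(d = 1:3, k = c(0, 0.3, 0.6),
                          alpha = c(1, 2, 9)))$k, 0.3)
  mc <- medianCell(makeFixture("toy-snapshot"))
  expect_equal(unlist(mc), c(k = 0.85, alpha = 5.25, d = 42, g = 43))
})

test_that("the KS statistic and p-value match the trivial cases", {
  same <- ksTwoSample(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$statistic, 0)
  expect_identical(same$p.value, 1)
  disj <- ksTwoSample(1:5, 11:15)
  expect_identical(disj$statistic, 1)
  expect_identical(ksTwoSample(c(1, 2, 3, 4), c(3, 4, 5, 6))$statistic,
                   0.5)
  expect_error(ksTwoSample(1, 1:5))
})

test_that("the KS test agrees with the reference implementation", {
  set.seed(808)
  for (i in 1:100) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    a <- rnorm(n1, sample(0:1, 1), 1)
    b <- rgamma(n2, shape = 2)
    ours <- ksTwoSample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_lt(abs(ours$statistic - unname(ref$statistic)), 1e-6)
    expect_lt(abs(ours$p.value - ref$p.value),
              1e-3 * max(ref$p.value, 1e-12))
  }
})
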