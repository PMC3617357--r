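test_that("the binary ID scheme appends daughter digits", {
  expect_identical(childCode("1", 2), "12")
  expect_identical(childCode("1", 1), "11")
  expect_identical(childCode("12", 1), "121")
  expect_error(childCode("1", 3))
  expect_error(childCode("30", 1))
  # codes are digit strings, so depth 47 (beyond 64-bit integers) is fine
  deep <- Reduce(childCode, rep(2, 46), accumulate = FALSE, init = "1")
  expect_identical(nchar(deep), 47L)
})

test_that("lineage codes reconstruct the ID scheme from a tree", {
  tr <- makeFixture("toy-tree")
  expect_identical(lineageCode(tr, 1), "1")
  expect_identical(lineageCode(tr), c("1", "11", "12", "111", "112",
                                      "121", "122"))
  expect_identical(tr@d, nchar(lineageCode(tr)) |> as.integer())
})

test_that("descendant counts satisfy additivity on small trees", {
  tr <- LineageTree(parent = c(0L, 1L, 1L), alive = c(FALSE, TRUE, TRUE))
  expect_identical(descendantCounts(tr), c(2L, 1L, 1L))
  tr2 <- makeFixture("toy-tree")   # full depth-2 binary + root, 4 leaves
  expect_identical(descendantCounts(tr2), c(4L, 2L, 2L, 1L, 1L, 1L, 1L))
  expect_identical(tr2@finalMass, 4L)
})

test_that("descendant counts equal a brute-force recount on random trees", {
  for (seed in 1:5) {
    rt <- randomTree(200, seed)
    cnt <- descendantCounts(rt$parent, rt$alive)
    expect_identical(cnt, bruteCounts(rt$parent, rt$alive))
    # additivity at every internal node
    kids <- split(seq_along(rt$parent)[-1], rt$parent[-1])
    for (p in names(kids))
      expect_identical(cnt[as.integer(p)],
                       sum(cnt[kids[[p]]]) + as.integer(
                         rt$alive[as.integer(p)]))
  }
})

test_that("orphan or out-of-order parents are rejected", {
  expect_error(descendantCounts(c(0L, 3L, 1L), c(TRUE, TRUE, TRUE)),
               "orphan")
})

test_that("MRCA(1) is the root and ties break lexicographically", {
  tr <- makeFixture("toy-tree")
  m1 <- mrcaFraction(tr, 1)
  expect_identical(m1$code, "1")
  expect_identical(m1$d, 1L)
  # both depth-2 children cover half the mass; "11" wins the tie
  expect_identical(mrcaFraction(tr, 0.5)$code, "11")
  expect_error(mrcaFraction(tr, 0))
  expect_error(mrcaFraction(tr, 1.5))
})

test_that("MRCA matches brute-force search on random trees", {
  for (seed in 11:14) {
    rt <- randomTree(400, seed)
    tr <- LineageTree(parent = rt$parent, alive = rt$alive)
    for (x in c(1, 0.99, 0.9, 0.5, 0.25))
      expect_identical(mrcaFraction(tr, x)$node, bruteMrca(tr, x))
    # depth of MRCA(x) is non-increasing in x
    dep <- vapply(c(0.25, 0.5, 0.9, 0.99, 1),
                  function(x) mrcaFraction(tr, x)$d, integer(1))
    expect_true(all(diff(dep) <= 0))
  }
})

test_that("Newick export is valid and round-trips through ape", {
  skip_if_not_installed("ape")
  tr <- makeFixture("toy-tree")
  nwk <- asNewick(tr)
  ph <- ape::read.tree(text = nwk)
  expect_identical(sort(ph$tip.label), c("111", "112", "121", "122"))
  expect_identical(sort(ph$node.label), c("1", "11", "12"))
  expect_identical(ape::Ntip(ph), 4L)
  # branch lengths are lifespans in days (1 month = 30 days)
  expect_equal(sort(unique(ph$edge.length)), 30)
  # a simulated neutral clone round-trips too
  rec <- simulateClone(neutralParameters(), seed = 1, lineage = TRUE)
  ph2 <- ape::read.tree(text = asNewick(lineageTree(rec)))
  expect_identical(ape::Ntip(ph2), 1024L)
})

test_that("annotated Newick carries phenotype comments", {
  tr <- makeFixture("toy-tree")
  nwk <- asNewick(tr, annotate = TRUE)
  expect_match(nwk, "\\[&d=1,g=2,k=1.3,alpha=8\\]")
})
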