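test_that("replica composition instantiates sets x stages nodes", {
  pipe <- toyPipeline(5)
  sets <- list(toyParams(1, 1, 1, 1, 1), toyParams(1, 1, 1, 1, 2),
               toyParams(1, 1, 1, 1, 3))
  g <- replicaGraph(pipe, sets, list(value = 0), inputId = "in1")
  expect_equal(nRuns(g), 15)
  g1 <- replicaGraph(pipe, sets[1], list(value = 0), inputId = "in1")
  expect_equal(nRuns(g1), 5)    # one set: the plain pipeline
})

test_that("compact composition merges common prefixes into a trie", {
  pipe <- toyPipeline(5)
  input <- list(value = 0)
  # three sets differing only in the last stage: 4 shared + 3 leaves
  sets <- list(toyParams(1, 1, 1, 1, 1), toyParams(1, 1, 1, 1, 2),
               toyParams(1, 1, 1, 1, 3))
  expect_equal(nRuns(compactCompose(pipe, sets, input, inputId = "in1")), 7)
  # all sets identical: node count equals the stage count
  same <- list(toyParams(1, 1, 1, 1, 1), toyParams(1, 1, 1, 1, 1))
  expect_equal(nRuns(compactCompose(pipe, same, input, inputId = "in1")), 5)
  # sets differing at stage 1: no merging at all
  div <- list(toyParams(1, 1, 1, 1, 1), toyParams(2, 1, 1, 1, 1))
  expect_equal(nRuns(compactCompose(pipe, div, input, inputId = "in1")), 10)
})

test_that("compact never exceeds replica and matches it iff first stages differ", {
  pipe <- toyPipeline(3)
  input <- list(value = 0)
  set.seed(31)
  for (rep_ in 1:20) {
    sets <- lapply(1:4, function(i) toyParams(sample(1:2, 1), sample(1:3, 1),
                                              sample(1:4, 1)))
    nC <- nRuns(compactCompose(pipe, sets, input, inputId = "x"))
    nR <- nRuns(replicaGraph(pipe, sets, input, inputId = "x"))
    expect_lte(nC, nR)
    firstBindings <- vapply(sets, function(s) s$p1, numeric(1))
    if (nC == nR) expect_false(any(duplicated(firstBindings)))
    if (!any(duplicated(firstBindings))) expect_equal(nC, nR)
  }
})

test_that("compact execution reproduces replica outputs with fewer runs", {
  pipe <- toyPipeline(4)
  input <- list(value = 10)
  sets <- list(toyParams(1, 2, 3, 4), toyParams(1, 2, 3, 9), toyParams(1, 5, 3, 4))
  rep_ <- executeGraph(replicaGraph(pipe, sets, input, "x"), pipe, input)
  cmp <- executeGraph(compactCompose(pipe, sets, input, "x"), pipe, input)
  expect_identical(rep_$outputs, cmp$outputs)
  expect_equal(rep_$outputs[[1]]$value, 20)
  expect_lt(cmp$stats$runs, rep_$stats$runs)
  expect_equal(cmp$stats$savings, 1 - cmp$stats$runs / 12)
})

test_that("compact and replica execution agree on the reference pipeline", {
  co <- testCohort()
  sp <- watershedSpace()
  d <- designMatrix(monteCarloDesign(6, paramCount(sp), seed = 44))
  pts <- lapply(seq_len(nrow(d)), function(i) fromUnit(sp, d[i, ]))
  pipe <- watershedPipeline()
  input <- list(tile = co$tiles[[3]])
  r <- runBatch(pipe, pts, input, mode = "replica")
  c_ <- runBatch(pipe, pts, input, mode = "compact")
  for (i in seq_along(pts))
    expect_identical(r$outputs[[i]]$mask, c_$outputs[[i]]$mask)
})

test_that("a warm store serves a repeated execution without any stage runs", {
  pipe <- toyPipeline(3)
  input <- list(value = 0)
  sets <- list(toyParams(1, 2, 3), toyParams(1, 2, 4))
  st <- resultStore(capacity = 100)
  g <- compactCompose(pipe, sets, input, "x")
  first <- executeGraph(g, pipe, input, store = st)
  expect_equal(first$stats$runs, 4)
  second <- executeGraph(g, pipe, input, store = st)
  expect_equal(second$stats$runs, 0)
  expect_equal(second$stats$hits1, 4)
  expect_identical(first$outputs, second$outputs)
})

test_that("a zero-capacity level 1 spills everything without changing results", {
  pipe <- toyPipeline(3)
  input <- list(value = 1)
  sets <- list(toyParams(2, 2, 2))
  st <- resultStore(capacity = 0)
  r1 <- executeGraph(compactCompose(pipe, sets, input, "x"), pipe, input, store = st)
  expect_equal(storeStats(st)$l1entries, 0)
  expect_gt(storeStats(st)$l2entries, 0)
  r2 <- executeGraph(compactCompose(pipe, sets, input, "x"), pipe, input, store = st)
  expect_equal(r2$stats$runs, 0)
  expect_equal(r2$stats$hits2, 3)
  expect_identical(r1$outputs, r2$outputs)
})

test_that("FIFO evicts oldest-inserted, LRU least-recently-accessed", {
  st <- resultStore(capacity = 2, policy = "FIFO")
  storePut(st, "a", 1); storePut(st, "b", 2); storePut(st, "c", 3)
  expect_equal(storeLevel(st, "a"), 2L)    # demoted one level
  expect_equal(storeLevel(st, "b"), 1L)
  expect_equal(storeLevel(st, "c"), 1L)
  expect_equal(storeGet(st, "a"), 1)       # still retrievable from level 2

  st <- resultStore(capacity = 2, policy = "LRU")
  storePut(st, "a", 1); storePut(st, "b", 2)
  storeGet(st, "a")                        # refresh a
  storePut(st, "c", 3)
  expect_equal(storeLevel(st, "b"), 2L)
  expect_equal(storeLevel(st, "a"), 1L)
})

test_that("hit counters are monotone and level-2 eviction deletes", {
  st <- resultStore(capacity = 1, l2capacity = 1, policy = "FIFO")
  storePut(st, "a", 1); storePut(st, "b", 2); storePut(st, "c", 3)
  # a fell off the end of the hierarchy
  expect_true(is.na(storeLevel(st, "a")))
  expect_null(storeGet(st, "a"))
  s1 <- storeStats(st)
  storeGet(st, "c")
  s2 <- storeStats(st)
  expect_gte(s2$hits1, s1$hits1)
  expect_gte(s2$hits2, s1$hits2)
  expect_gte(s2$misses, s1$misses)
})

test_that("level-2 hits promote entries back to level 1", {
  st <- resultStore(capacity = 1, policy = "FIFO")
  storePut(st, "a", 1); storePut(st, "b", 2)
  expect_equal(storeLevel(st, "a"), 2L)
  storeGet(st, "a")
  expect_equal(storeLevel(st, "a"), 1L)
  expect_equal(storeLevel(st, "b"), 2L)    # displaced by the promotion
})

test_that("stage failures carry the failing node identity", {
  pipe <- new("SegPipeline", stages = list(
    list(name = "boom", params = "p1",
         fn = function(input, p) stop("kaput"))))
  g <- compactCompose(pipe, list(list(p1 = 1)), list(value = 0), "x")
  expect_error(executeGraph(g, pipe, list(value = 0)), "stage 'boom'.*kaput")
})

test_that("input identity distinguishes files and objects by content", {
  f1 <- tempfile(); writeLines("aaa", f1)
  f2 <- tempfile(); writeLines("aaa", f2)
  f3 <- tempfile(); writeLines("bbb", f3)
  expect_equal(inputIdentity(f1), inputIdentity(f2))
  expect_false(inputIdentity(f1) == inputIdentity(f3))
  expect_equal(inputIdentity(list(1, "x")), inputIdentity(list(1, "x")))
  expect_false(inputIdentity(list(1)) == inputIdentity(list(2)))
})
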