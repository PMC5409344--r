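# Geometric fixtures for the pipeline stages.

flatTile <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# Dark disk (or two) on a bright field.
diskTile <- function(h = 48, w = 48, centers = list(c(24, 24)), radius = 8,
                     fg = c(100, 50, 140), bg = c(235, 225, 235)) {
  tile <- flatTile(h, w, bg)
  for (ch in 1:3) {
    plane <- tile[, , ch]
    for (ct in centers) {
      ys <- matrix(rep(seq_len(h), w), h, w)
      xs <- matrix(rep(seq_len(w), each = h), h, w)
      inside <- (ys - ct[1])^2 + (xs - ct[2])^2 <= radius^2
      plane[inside] <- fg[ch]
    }
    tile[, , ch] <- plane
  }
  tile
}

test_that("background detection flags a pixel when any channel dips", {
  white <- flatTile(8, 8, c(255, 255, 255))
  expect_equal(sum(backgroundDetect(white, 254, 254, 254)), 0)
  dark <- flatTile(8, 8, c(10, 10, 10))
  expect_equal(sum(backgroundDetect(dark, 220, 220, 220)), 64)
  px <- flatTile(2, 2, c(200, 230, 230))    # r = 200 < R = 220 -> tissue
  expect_equal(backgroundDetect(px, 220, 220, 220)[1, 1], 1L)
  px2 <- flatTile(2, 2, c(230, 230, 200))   # b = 200 < B -> tissue
  expect_equal(backgroundDetect(px2, 220, 220, 220)[1, 1], 1L)
  px3 <- flatTile(2, 2, c(230, 230, 230))   # no channel below threshold
  expect_equal(sum(backgroundDetect(px3, 220, 220, 220)), 0)
})

test_that("candidate extraction finds a contrasted disk and nothing on flat tiles", {
  flat <- flatTile(32, 32, c(150, 150, 150))
  tissue <- matrix(1L, 32, 32)
  expect_equal(sum(candidateNuclei(flat, tissue, 10, 4)), 0)
  tile <- diskTile()
  tissue <- backgroundDetect(tile, 220, 220, 220)
  cand <- candidateNuclei(tile, tissue, 40, 20)
  expect_equal(max(segstudy:::cc_label_cpp(cand, 8L)), 1)   # one component
  expect_gt(sum(cand), 100)
})

test_that("raising either candidate threshold never adds components", {
  tile <- diskTile(centers = list(c(14, 14), c(34, 34)), radius = 6)
  tissue <- backgroundDetect(tile, 220, 220, 220)
  nComp <- function(g1, g2)
    max(segstudy:::cc_label_cpp(candidateNuclei(tile, tissue, g1, g2), 8L))
  counts <- vapply(seq(2, 40, 2), function(g2) nComp(40, g2), numeric(1))
  expect_true(all(diff(counts) <= 0))
  counts1 <- vapply(seq(5, 80, 5), function(g1) nComp(g1, 20), numeric(1))
  expect_true(all(diff(counts1) <= 0))
})

test_that("the size filter honors area bounds and connectivity", {
  m <- matrix(0L, 6, 6); m[1:3] <- 1L                 # area-3 component
  expect_equal(sum(sizeFilter(m, minArea = 4)), 0)
  expect_equal(sizeFilter(m, minArea = 0, maxArea = Inf), m)
  expect_equal(sum(sizeFilter(m, maxArea = 2)), 0)
  diag2 <- matrix(0L, 4, 4); diag2[cbind(c(2, 3), c(2, 3))] <- 1L
  expect_equal(sum(sizeFilter(diag2, minArea = 2, connectivity = "8-conn")), 2)
  expect_equal(sum(sizeFilter(diag2, minArea = 2, connectivity = "4-conn")), 0)
  expect_error(sizeFilter(m, minArea = 5, maxArea = 2), "minArea")
})

test_that("hole filling closes interior holes and keeps border-connected ones", {
  solid <- matrix(1L, 5, 5)
  expect_equal(fillHoles(solid), solid)
  ring <- matrix(0L, 7, 7); ring[2:6, 2:6] <- 1L; ring[3:5, 3:5] <- 0L
  filled <- fillHoles(ring)
  expect_equal(filled[2:6, 2:6], matrix(1L, 5, 5))
  openBox <- matrix(0L, 7, 7); openBox[2:6, 2:6] <- 1L
  openBox[3:5, 3:5] <- 0L; openBox[1:5, 4] <- 0L      # channel to the border
  expect_equal(fillHoles(openBox), openBox)
})

test_that("watershed splitting separates touching nuclei and partitions foreground", {
  one <- matrix(0L, 30, 30)
  ys <- row(one); xs <- col(one)
  one[(ys - 15)^2 + (xs - 15)^2 <= 64] <- 1L
  lab1 <- watershedSplit(one, "8-conn", MinSizePl = 5)
  expect_equal(max(lab1), 1)
  expect_equal((lab1 > 0) * 1L, one)                  # exact partition
  # two circles, centers 1.5 radii apart -> two distance maxima
  two <- matrix(0L, 40, 60)
  ys <- row(two); xs <- col(two)
  two[(ys - 20)^2 + (xs - 24)^2 <= 100] <- 1L
  two[(ys - 20)^2 + (xs - 39)^2 <= 100] <- 1L
  lab2 <- watershedSplit(two, "8-conn", MinSizePl = 5)
  expect_equal(max(lab2), 2)
  expect_equal((lab2 > 0) * 1L, two)
  # components below MinSizePl are dropped
  two[3, 3] <- 1L
  lab3 <- watershedSplit(two, "8-conn", MinSizePl = 5)
  expect_equal(sum(lab3 > 0), sum(two) - 1)
})

test_that("the full pipeline is deterministic and parameter-pure", {
  co <- testCohort()
  tile <- co$tiles[[1]]
  defaults <- defaultPoint(watershedSpace())
  r1 <- runPipeline(tile, defaults)
  r2 <- runPipeline(tile, defaults)
  expect_identical(r1$mask, r2$mask)
  # undeclared parameters (T1/T2, Dummy) cannot change any stage output
  tweaked <- defaults
  tweaked$T1 <- 2.5; tweaked$T2 <- 7.5; tweaked$Dummy <- 0.9
  r3 <- runPipeline(tile, tweaked)
  expect_identical(r1$mask, r3$mask)
  expect_identical(r1$stages, r3$stages)
})

test_that("generator-matched parameters segment the synthetic cohort well", {
  co <- testCohort()
  defaults <- defaultPoint(watershedSpace())
  dice <- vapply(seq_along(co$tiles), function(i)
    diceCoef(runPipeline(co$tiles[[i]], defaults)$mask, co$masks[[i]]),
    numeric(1))
  expect_gt(mean(dice), 0.7)     # frozen regression floor
  # an all-background tile segments to an empty mask
  m <- runPipeline(flatTile(32, 32, c(240, 240, 240)), defaults)$mask
  expect_equal(sum(m), 0)
})

test_that("output area shrinks as thresholds and minimum areas grow", {
  co <- testCohort()
  tile <- co$tiles[[2]]
  defaults <- defaultPoint(watershedSpace())
  areas <- vapply(c(10, 20, 30, 40), function(g2)
    sum(runPipeline(tile, modifyList(defaults, list(G2 = g2)))$mask),
    numeric(1))
  expect_true(all(diff(areas) <= 0))
  areasMin <- vapply(c(2, 20, 40), function(ms)
    sum(runPipeline(tile, modifyList(defaults, list(MinSizeSeg = ms)))$mask),
    numeric(1))
  expect_true(all(diff(areasMin) <= 0))
})
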