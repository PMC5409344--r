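test_that("correlation matches the two-pass product-moment oracle", {
  pearsonOracle <- function(x, y) {
    xb <- mean(x); yb <- mean(y)
    sum((x - xb) * (y - yb)) / sqrt(sum((x - xb)^2) * sum((y - yb)^2))
  }
  set.seed(7)
  for (i in 1:100) {
    x <- rnorm(25); y <- rnorm(25)
    expect_equal(correlation(x, y, "cc"), pearsonOracle(x, y), tolerance = 1e-12)
  }
  x <- seq(-1, 1, length.out = 21)
  expect_equal(correlation(x, 2 * x + 1, "cc"), 1.0)
  expect_equal(correlation(x, x^3, "rcc"), 1.0)    # monotone rank invariance
  expect_equal(correlation(x, -x, "cc"), -1.0)
  expect_equal(correlation(x, -x, "rcc"), -1.0)
})

test_that("correlation preconditions are enforced", {
  expect_error(correlation(1:2, 1:2), "at least 3")
  expect_error(correlation(rep(1, 5), 1:5), "zero variance")
  x <- seq(0, 1, length.out = 30)
  expect_equal(correlation(x, exp(x), "rcc"),
               correlation(2 * x + 3, exp(x)^2, "rcc"))  # monotone transforms
  expect_equal(correlation(x, sin(x), "cc"), correlation(sin(x), x, "cc"))
})

test_that("partial correlation equals simple correlation on orthogonal designs", {
  # 2-level full factorial: main-effect and interaction contrasts are
  # exactly orthogonal, so regressing out the other parameters changes
  # nothing when the output is orthogonal to them too
  X <- as.matrix(expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), x3 = c(-1, 1)))
  y <- 2 * X[, 1] + 0.5 * X[, 1] * X[, 2] * X[, 3]
  for (i in 1:3)
    expect_equal(partialCorrelation(X, y, i, "pcc"),
                 correlation(X[, i], y, "cc"), tolerance = 1e-10)
  # with output contributions from the other (orthogonal) parameters the
  # partial coefficient exceeds the simple one: shared variance is removed
  set.seed(3)
  y2 <- 2 * X[, 1] - 3 * X[, 2] + rnorm(8, 0, 0.1)
  expect_gt(abs(partialCorrelation(X, y2, 1, "pcc")),
            abs(correlation(X[, 1], y2, "cc")))
})

test_that("partial correlation matches the explicit two-regression oracle", {
  residOracle <- function(v, Z) {
    fit <- lm.fit(cbind(1, Z), v)
    fit$residuals
  }
  set.seed(11)
  n <- 200
  x1 <- runif(n)
  x2 <- x1 + rnorm(n, 0, 0.3)   # correlated regressors
  X <- cbind(x1, x2)
  y <- x1 + x2 + rnorm(n, 0, 0.05)
  pcc1 <- partialCorrelation(X, y, 1, "pcc")
  oracle <- cor(residOracle(X[, 1], X[, -1]), residOracle(y, X[, -1]))
  expect_equal(pcc1, oracle, tolerance = 1e-12)
  # ranked variant equals the oracle on ranked data
  Xr <- apply(X, 2, rank); yr <- rank(y)
  expect_equal(partialCorrelation(X, y, 1, "prcc"),
               cor(residOracle(Xr[, 1], Xr[, -1]), residOracle(yr, Xr[, -1])),
               tolerance = 1e-12)
})

test_that("independent outputs give near-zero partial correlations", {
  set.seed(21)
  n <- 400
  X <- matrix(runif(n * 3), n, 3)
  y <- rnorm(n)
  for (i in 1:3)
    expect_lt(abs(partialCorrelation(X, y, i, "pcc")), 3 / sqrt(n))
})

test_that("rank-deficient designs are rejected", {
  X <- cbind(1:10, 2 * (1:10), rnorm(10))
  expect_error(partialCorrelation(X, rnorm(10), 3, "pcc"), "rank-deficient")
  expect_error(partialCorrelation(matrix(runif(6), 3, 2), runif(3), 1),
               "n > k")
})

test_that("the correlation report covers all four coefficients", {
  set.seed(5)
  X <- matrix(runif(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + 0.2 * rnorm(40)
  rep <- correlationReport(X, y)
  expect_equal(rep$param, c("a", "b", "c"))
  expect_true(all(abs(as.matrix(rep[, c("cc", "pcc", "rcc", "prcc")])) <= 1))
  expect_gt(rep$cc[1], 0.8)
  path <- tempfile(fileext = ".csv")
  writeImportanceReport(rep, path)
  expect_equal(nrow(read.csv(path)), 3)
})

test_that("Saltelli designs have the n(k+2) block structure", {
  d <- saltelliDesign(200, 8, seed = 1)
  expect_equal(nRuns(d), 2000)
  expect_equal(nRuns(saltelliDesign(200, 5, seed = 1)), 1400)
  m <- designMatrix(d)
  A <- m[1:200, ]; B <- m[201:400, ]
  AB3 <- m[(2 + 3 - 1) * 200 + 401:600 - 400, ]   # rows of the third cross block
  AB3 <- m[(1 + 3) * 200 + seq_len(200), ]
  expect_equal(AB3[, 3], B[, 3])
  expect_equal(AB3[, -3], A[, -3])
  expect_error(saltelliDesign(1, 3), "n >= 2")
  # quasi variants use disjoint index blocks for A and B
  dh <- saltelliDesign(16, 2, sampler = "halton")
  mh <- designMatrix(dh)
  expect_false(any(duplicated(rbind(mh[1:16, ], mh[17:32, ]))))
})

test_that("VBD recovers additive variance shares", {
  d <- saltelliDesign(4096, 2, seed = 7)
  y <- apply(designMatrix(d), 1, function(u) u[1] + 2 * u[2])
  v <- suppressMessages(vbdEstimate(d, y))
  expect_equal(v$table$si, c(0.2, 0.8), tolerance = 0.03)
  expect_equal(v$table$sti, c(0.2, 0.8), tolerance = 0.03)
  expect_equal(v$sumSi, 1, tolerance = 0.02)      # additive model
  expect_equal(v$V, 5 / 12, tolerance = 0.02)
})

test_that("a parameter the output ignores gets zero indices", {
  d <- saltelliDesign(2048, 3, seed = 13)
  y <- apply(designMatrix(d), 1, function(u) u[1] + u[2]^2)
  v <- suppressMessages(vbdEstimate(d, y))
  expect_equal(v$table$si[3], 0, tolerance = 0.02)
  expect_equal(v$table$sti[3], 0, tolerance = 0.02)
})

test_that("VBD rejects degenerate outputs and miscounted runs", {
  d <- saltelliDesign(16, 2, seed = 1)
  expect_error(vbdEstimate(d, rep(1, nRuns(d))), "zero variance")
  expect_error(vbdEstimate(d, rep(1, 10)), "expected")
})

test_that("non-additive models have main-effect sums below one", {
  # Ishigami: strong x1-x3 interaction
  d <- saltelliDesign(4096, 3, seed = 5)
  X <- -pi + 2 * pi * designMatrix(d)
  y <- sin(X[, 1]) + 7 * sin(X[, 2])^2 + 0.1 * X[, 3]^4 * sin(X[, 1])
  v <- suppressMessages(vbdEstimate(d, y))
  expect_lt(v$sumSi, 0.85)
  expect_gt(v$table$sti[1], v$table$si[1])   # interactions load onto ST1
})

test_that("index estimates are stable across seeds", {
  est <- vapply(1:10, function(s) {
    d <- saltelliDesign(512, 2, seed = s)
    y <- apply(designMatrix(d), 1, function(u) u[1] + 2 * u[2])
    suppressMessages(vbdEstimate(d, y))$table$si[2]
  }, numeric(1))
  se <- sd(est)
  expect_lt(abs(mean(est) - 0.8), 3 * se / sqrt(10) + 0.02)
})
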