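# Analytic objectives: scores in [0, 1], maximized at known points.

sphereObjective <- function(k, p = 101) {
  sp <- unitSpace(k, p = p)   # fine grid so snapping barely moves points
  makeObjective(sp, function(pt) {
    u <- unlist(pt)
    1 - sum((u - 0.5)^2)
  })
}

test_that("Nelder-Mead approaches a convex optimum within the budget", {
  obj <- sphereObjective(4)
  res <- tune(obj, "nm", budget = 100, seed = 3)
  expect_lte(res@evaluations, 100)
  expect_gt(res@bestScore, 0.99)   # within 0.01 of the optimum value 1
  best <- unlist(res@bestPoint)
  expect_true(all(abs(best - 0.5) < 0.15))
})

test_that("a 1-D quadratic converges to the bracketing vertex", {
  sp <- unitSpace(1, p = 101)
  obj <- makeObjective(sp, function(pt) 1 - (pt$u1 - 0.3)^2)
  res <- tune(obj, "nm", budget = 50, seed = 1)
  expect_lt(abs(res@bestPoint$u1 - 0.3), 0.05)
})

test_that("tuning is deterministic given the seed", {
  for (m in c("nm", "pro", "ga")) {
    r1 <- tune(sphereObjective(3), m, budget = 40, seed = 11)
    r2 <- tune(sphereObjective(3), m, budget = 40, seed = 11)
    expect_identical(r1@history, r2@history)
  }
})

test_that("budgets are never exceeded and thresholds stop early", {
  for (m in c("nm", "pro", "ga")) {
    res <- tune(sphereObjective(3), m, budget = 30, seed = 7)
    expect_lte(res@evaluations, 30)
  }
  # threshold 0 runs to the budget on an objective that cannot reach 1
  resB <- tune(sphereObjective(2), "ga", budget = 25, threshold = 0, seed = 2)
  expect_equal(resB@stopReason, "budget")
  expect_equal(resB@evaluations, 25)
  # a generous threshold stops at first success
  sp <- unitSpace(2, p = 5)
  objT <- makeObjective(sp, function(pt) 1)
  resT <- tune(objT, "nm", budget = 50, threshold = 0.5, seed = 1)
  expect_equal(resT@stopReason, "threshold")
  expect_lt(resT@evaluations, 50)
})

test_that("best-so-far curves are monotone for every method", {
  for (m in c("nm", "pro", "ga")) {
    res <- tune(sphereObjective(3), m, budget = 60, seed = 13)
    expect_true(all(diff(cummax(res@history$score)) >= 0))
    expect_equal(res@bestScore, max(res@history$score))
  }
})

test_that("every evaluated point lies on the space's native grid", {
  sp <- parameterSpace(
    parameterSpec("a", "discrete", low = 2, high = 40, step = 2, default = 20),
    parameterSpec("conn", "categorical", values = c("4-conn", "8-conn"),
                  default = "8-conn"))
  obj <- makeObjective(sp, function(pt)
    (pt$a / 40 + (pt$conn == "4-conn")) / 2)
  res <- tune(obj, "ga", budget = 30, seed = 5)
  expect_true(all(res@history$a %in% seq(2, 40, 2)))
  expect_true(all(res@history$conn %in% c("4-conn", "8-conn")))
})

test_that("PRO evaluates batches and improves monotonically on convex objectives", {
  calls <- new.env(); calls$sizes <- integer(0)
  sp <- unitSpace(4, p = 101)
  obj <- makeObjective(sp,
    fn = function(pt) 1 - sum((unlist(pt) - 0.5)^2),
    batchFn = function(points) {
      calls$sizes <- c(calls$sizes, length(points))
      vapply(points, function(pt) 1 - sum((unlist(pt) - 0.5)^2), numeric(1))
    })
  res <- tune(obj, "pro", budget = 80, seed = 9)
  expect_gt(res@bestScore, 0.99)
  expect_gt(max(calls$sizes), 1)    # k points evaluated per iteration
})

test_that("PRO and NM agree on the 1-D optimum", {
  r1 <- tune(sphereObjective(1), "nm", budget = 40, seed = 3)
  r2 <- tune(sphereObjective(1), "pro", budget = 40, seed = 3)
  expect_equal(r1@bestPoint$u1, r2@bestPoint$u1, tolerance = 0.02)
})

test_that("the GA solves a one-max style problem over binary genes", {
  sp <- parameterSpace(lapply(1:6, function(i)
    parameterSpec(paste0("b", i), "categorical", values = c("off", "on"),
                  default = "off")))
  obj <- makeObjective(sp, function(pt)
    mean(unlist(pt) == "on"))
  res <- tune(obj, "ga", budget = 100, seed = 21)
  expect_equal(res@bestScore, 1)   # brute-force optimum: all genes on
})

test_that("a GA without variation or selection pressure goes static", {
  sp <- unitSpace(3, p = 5)
  obj <- makeObjective(sp, function(pt) mean(unlist(pt)))
  res <- tune(obj, "ga", budget = 100, seed = 4,
              control = list(popSize = 6, crossover = 0, mutation = 0,
                             elitism = 6))
  # after the initial population no new points can appear
  expect_equal(res@evaluations, 6)
})

test_that("invalid configurations are rejected", {
  expect_error(tune(sphereObjective(5), "nm", budget = 4), "too small")
  expect_error(tune(sphereObjective(2), "ga", budget = 5,
                    control = list(popSize = 10)), "too small")
  expect_error(tune(sphereObjective(2), "annealing"), "arg")
})

test_that("duplicate snapped points are served from the log without cost", {
  sp <- unitSpace(2, p = 3)   # coarse grid forces collisions
  count <- new.env(); count$n <- 0
  obj <- makeObjective(sp, function(pt) {
    count$n <- count$n + 1
    mean(unlist(pt))
  })
  res <- tune(obj, "nm", budget = 100, seed = 6)
  # the workflow ran exactly once per distinct grid point
  expect_equal(count$n, res@evaluations)
  expect_equal(count$n, nrow(unique(res@history[, c("u1", "u2")])))
  expect_lte(res@evaluations, 9)   # 3x3 grid
})

test_that("the ensemble returns the best of the three methods", {
  ens <- ensembleTune(sphereObjective(2), budget = 30, seed = 15)
  expect_equal(ens$best@bestScore,
               max(vapply(ens$results, function(r) r@bestScore, numeric(1))))
  expect_true(ens$method %in% c("nm", "pro", "ga"))
})

test_that("tuning histories round-trip through CSV", {
  res <- tune(sphereObjective(2), "nm", budget = 20, seed = 8)
  path <- tempfile(fileext = ".csv")
  writeTuningHistory(res, path)
  h <- read.csv(path)
  expect_equal(nrow(h), nrow(res@history))
  expect_equal(h$score, res@history$score)
})
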