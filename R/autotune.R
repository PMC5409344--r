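# Black-box parameter auto-tuning: maximize a segmentation-quality metric
# over the parameter space with Nelder-Mead, Parallel Rank Order or a
# Genetic Algorithm. Optimizers move in unit space; every candidate is
# snapped onto the native parameter grid at evaluation time, and repeated
# snapped points are served from the evaluation log without re-running
# the workflow (they cost nothing against the budget).

#' Wrap a scoring function as a tuning objective
#'
#' The function receives a complete native-unit parameter point and must
#' return a score in `[0, 1]` to be maximized (for mask metrics, Dice or
#' Jaccard against the reference masks). An optional `batchFn` evaluates
#' a list of points at once — the hook the segmentation objective uses to
#' route batches through the compact-composition executor.
#'
#' @param space a [ParameterSpace-class].
#' @param fn function(point) -> score in `[0, 1]`.
#' @param batchFn optional function(list-of-points) -> numeric scores.
#' @return an objective (list) for [tune()].
#' @export
makeObjective <- function(space, fn, batchFn = NULL) {
  env <- new.env(parent = emptyenv())
  env$log <- list()
  env$memo <- new.env(parent = emptyenv())
  env$charged <- 0L
  env$budget <- Inf
  env$threshold <- 0
  env$hitThreshold <- FALSE
  env$exhausted <- FALSE
  structure(list(space = space, fn = fn, batchFn = batchFn, env = env),
            class = "segstudyObjective")
}

#' Segmentation-quality objective over an image cohort
#'
#' Scores a parameter point by the unweighted mean of the chosen metric
#' between the pipeline's output mask and the reference mask across all
#' image/reference pairs. Batches of candidate points are executed as one
#' compact workflow graph per tile, so candidates sharing a computation
#' prefix run the shared stages once.
#'
#' @param space a [ParameterSpace-class].
#' @param tiles list of RGB tiles.
#' @param masks list of reference masks (binary or labeled).
#' @param pipeline a [SegPipeline-class] (default the bundled watershed
#'   pipeline).
#' @param metric "dice" or "jaccard".
#' @param store optional [ResultStore-class] shared across evaluations.
#' @return an objective for [tune()].
#' @export
segObjective <- function(space, tiles, masks, pipeline = watershedPipeline(),
                         metric = c("dice", "jaccard"), store = NULL) {
  metric <- match.arg(metric)
  stopifnot(length(tiles) == length(masks), length(tiles) >= 1)
  mfun <- if (metric == "dice") diceCoef else jaccardCoef
  refs <- lapply(masks, asBinaryMask)
  inputs <- lapply(tiles, function(t) list(tile = t))
  ids <- vapply(inputs, inputIdentity, character(1))
  scoreBatch <- function(points) {
    per <- matrix(NA_real_, nrow = length(points), ncol = length(tiles))
    for (ti in seq_along(tiles)) {
      graph <- buildGraph(pipeline, points, inputs[[ti]], inputId = ids[ti],
                          mode = "compact")
      out <- executeGraph(graph, pipeline, inputs[[ti]], store = store)
      per[, ti] <- vapply(out$outputs, function(o) mfun(o$mask, refs[[ti]]),
                          numeric(1))
    }
    rowMeans(per)
  }
  makeObjective(space, fn = function(point) scoreBatch(list(point)),
                batchFn = scoreBatch)
}

# Snap, memoize, charge the budget and log a single unit-space candidate.
# Returns the score, or NA once the budget is exhausted.
objEvaluate <- function(obj, u) {
  objEvaluateBatch(obj, list(u))[1]
}

objEvaluateBatch <- function(obj, us) {
  env <- obj$env
  us <- lapply(us, function(u) snapUnit(obj$space, pmin(pmax(u, 0), 1)))
  points <- lapply(us, function(u) fromUnit(obj$space, u))
  keys <- vapply(points, canonicalPoint, character(1))
  scores <- rep(NA_real_, length(us))
  for (i in seq_along(keys))
    if (exists(keys[i], envir = env$memo, inherits = FALSE))
      scores[i] <- get(keys[i], envir = env$memo)
  need <- which(is.na(scores) & !duplicated(keys))
  room <- max(0L, env$budget - env$charged)
  if (length(need) > room) {
    need <- head(need, room)
    env$exhausted <- TRUE
  }
  if (length(need)) {
    newScores <- if (!is.null(obj$batchFn) && length(need) > 1)
      obj$batchFn(points[need])
    else vapply(points[need], obj$fn, numeric(1))
    for (j in seq_along(need)) {
      i <- need[j]
      s <- newScores[j]
      assign(keys[i], s, envir = env$memo)
      env$charged <- env$charged + 1L
      env$log[[length(env$log) + 1L]] <-
        c(list(ordinal = env$charged), points[[i]], list(score = s))
      if ((1 - s) <= env$threshold) env$hitThreshold <- TRUE
    }
    # resolve duplicates of freshly computed keys
    for (i in seq_along(keys))
      if (is.na(scores[i]) && exists(keys[i], envir = env$memo, inherits = FALSE))
        scores[i] <- get(keys[i], envir = env$memo)
  }
  if (env$charged >= env$budget) env$exhausted <- TRUE
  scores
}

objDone <- function(obj) obj$env$hitThreshold || obj$env$exhausted

objResult <- function(obj) {
  env <- obj$env
  hist <- do.call(rbind, lapply(env$log, function(row)
    as.data.frame(row, stringsAsFactors = FALSE)))
  if (is.null(hist)) stop("no evaluations were performed", call. = FALSE)
  best <- which.max(hist$score)
  bestPoint <- as.list(hist[best, setdiff(names(hist), c("ordinal", "score")),
                            drop = FALSE])
  reason <- if (env$hitThreshold) "threshold"
            else if (env$exhausted) "budget" else "converged"
  new("TuningResult", bestPoint = bestPoint, bestScore = hist$score[best],
      history = hist, evaluations = env$charged, stopReason = reason)
}

setMethod("show", "TuningResult", function(object) {
  cat(sprintf("TuningResult: best score %.4f after %d evaluations (stop: %s)\n",
              object@bestScore, object@evaluations, object@stopReason))
  cat("best point:\n")
  str <- vapply(object@bestPoint, function(v) paste(format(v)), character(1))
  cat(paste0("  ", names(object@bestPoint), " = ", str, collapse = "\n"), "\n")
})

initialSimplex <- function(obj, spread = 0.25) {
  space <- obj$space
  u0 <- toUnit(space, defaultPoint(space))
  k <- length(u0)
  V <- matrix(rep(u0, k + 1), nrow = k + 1, byrow = TRUE)
  for (i in seq_len(k))
    V[i + 1, i] <- if (u0[i] + spread <= 1) u0[i] + spread else u0[i] - spread
  V
}

#' Tune workflow parameters against a quality objective
#'
#' Dispatches to one of three derivative-free optimizers and runs until
#' the evaluation budget is exhausted or the error estimate
#' `1 - score` drops to `threshold`. All methods are deterministic given
#' the seed; the best-so-far score over the evaluation log is
#' non-decreasing by construction.
#'
#' `method = "nm"`: standard Nelder-Mead with reflection/expansion/
#' contraction/shrink (coefficients 1, 2, 0.5, 0.5) on a simplex of k+1
#' vertices started at the space's default point plus k axis-perturbed
#' vertices.
#'
#' `method = "pro"`: Parallel Rank Order, a Nelder-Mead variant that per
#' iteration reflects all k non-best vertices through the best vertex and
#' evaluates them as one batch (routed through the compact-composition
#' executor when the objective supports it), expanding batch-wise on
#' improvement and contracting toward the best vertex otherwise.
#'
#' `method = "ga"`: generational genetic algorithm; each parameter is a
#' gene, selection is a size-2 tournament, one-point crossover with
#' probability `C = 0.5`, per-gene uniform-reset mutation with
#' probability `M = 0.3`, elitism 1, population 10. The initial
#' population is random (the space's defaults are not seeded into it).
#'
#' @param objective from [makeObjective()] or [segObjective()].
#' @param method "nm", "pro" or "ga".
#' @param budget maximum number of objective evaluations (default 100).
#' @param threshold stop once `1 - score <= threshold` (0 runs to budget).
#' @param seed integer seed.
#' @param control method-specific settings: `popSize`, `crossover`,
#'   `mutation`, `elitism` (GA); `spread` (initial simplex).
#' @return a [TuningResult-class].
#' @export
tune <- function(objective, method = c("nm", "pro", "ga"), budget = 100,
                 threshold = 0, seed = NULL, control = list()) {
  method <- match.arg(method)
  k <- paramCount(objective$space)
  if (method %in% c("nm", "pro") && budget < k + 2)
    stop(sprintf("budget %d too small to initialize a %d-vertex simplex",
                 budget, k + 1), call. = FALSE)
  popSize <- control$popSize %||% 10
  if (method == "ga" && budget < popSize)
    stop("budget too small for the initial GA population", call. = FALSE)
  objective$env$budget <- budget
  objective$env$threshold <- threshold
  withLocalSeed(seed, switch(method,
    nm = tuneNelderMead(objective, control),
    pro = tuneParallelRankOrder(objective, control),
    ga = tuneGeneticAlgorithm(objective, control)))
  objResult(objective)
}

tuneNelderMead <- function(obj, control) {
  V <- initialSimplex(obj, control$spread %||% 0.25)
  k <- ncol(V)
  f <- vapply(seq_len(nrow(V)), function(i) 1 - objEvaluate(obj, V[i, ]),
              numeric(1))
  if (objDone(obj) || anyNA(f)) return(invisible())
  maxIter <- control$maxIter %||% (50L * as.integer(min(obj$env$budget, 1e6)))
  stagnation <- 0L
  for (iter in seq_len(maxIter)) {
    charged0 <- obj$env$charged
    ord <- order(f)
    V <- V[ord, , drop = FALSE]; f <- f[ord]
    if (max(dist(V)) < 1e-8) break
    centroid <- colMeans(V[seq_len(k), , drop = FALSE])
    xr <- centroid + (centroid - V[k + 1, ])
    fr <- 1 - objEvaluate(obj, xr)
    if (objDone(obj) || is.na(fr)) break
    if (fr < f[1]) {
      xe <- centroid + 2 * (centroid - V[k + 1, ])
      fe <- 1 - objEvaluate(obj, xe)
      if (objDone(obj) || is.na(fe)) break
      if (fe < fr) { V[k + 1, ] <- xe; f[k + 1] <- fe }
      else         { V[k + 1, ] <- xr; f[k + 1] <- fr }
    } else if (fr < f[k]) {
      V[k + 1, ] <- xr; f[k + 1] <- fr
    } else {
      xc <- centroid + 0.5 * (V[k + 1, ] - centroid)
      fc <- 1 - objEvaluate(obj, xc)
      if (objDone(obj) || is.na(fc)) break
      if (fc < f[k + 1]) { V[k + 1, ] <- xc; f[k + 1] <- fc }
      else {
        for (i in 2:(k + 1)) {
          V[i, ] <- V[1, ] + 0.5 * (V[i, ] - V[1, ])
          f[i] <- 1 - objEvaluate(obj, V[i, ])
          if (objDone(obj) || is.na(f[i])) return(invisible())
        }
      }
    }
    # all candidate points served from the log: the simplex has settled
    # onto visited grid points and no budget is being spent
    stagnation <- if (obj$env$charged == charged0) stagnation + 1L else 0L
    if (stagnation >= 25L) break
  }
  invisible()
}

tuneParallelRankOrder <- function(obj, control) {
  V <- initialSimplex(obj, control$spread %||% 0.25)
  k <- ncol(V)
  f <- 1 - objEvaluateBatch(obj, lapply(seq_len(nrow(V)), function(i) V[i, ]))
  if (objDone(obj) || anyNA(f)) return(invisible())
  maxIter <- control$maxIter %||% (50L * as.integer(min(obj$env$budget, 1e6)))
  stagnation <- 0L
  for (iter in seq_len(maxIter)) {
    charged0 <- obj$env$charged
    ord <- order(f)
    V <- V[ord, , drop = FALSE]; f <- f[ord]
    if (max(dist(V)) < 1e-8) break
    best <- V[1, ]
    refl <- lapply(2:(k + 1), function(i) best + (best - V[i, ]))
    fr <- 1 - objEvaluateBatch(obj, refl)
    if (objDone(obj) || anyNA(fr)) break
    improved <- min(fr) < f[1]
    if (improved) {
      expa <- lapply(2:(k + 1), function(i) best + 2 * (best - V[i, ]))
      fe <- 1 - objEvaluateBatch(obj, expa)
      if (objDone(obj) || anyNA(fe)) break
      for (i in 2:(k + 1)) {
        cand <- rbind(V[i, ], refl[[i - 1]], expa[[i - 1]])
        fc <- c(f[i], fr[i - 1], fe[i - 1])
        b <- which.min(fc)
        V[i, ] <- cand[b, ]; f[i] <- fc[b]
      }
    } else {
      cont <- lapply(2:(k + 1), function(i) best + 0.5 * (V[i, ] - best))
      fc <- 1 - objEvaluateBatch(obj, cont)
      if (objDone(obj) || anyNA(fc)) break
      for (i in 2:(k + 1))
        if (fc[i - 1] < f[i]) { V[i, ] <- cont[[i - 1]]; f[i] <- fc[i - 1] }
    }
    stagnation <- if (obj$env$charged == charged0) stagnation + 1L else 0L
    if (stagnation >= 25L) break
  }
  invisible()
}

tuneGeneticAlgorithm <- function(obj, control) {
  k <- paramCount(obj$space)
  popSize <- control$popSize %||% 10
  C <- control$crossover %||% 0.5
  M <- control$mutation %||% 0.3
  elitism <- control$elitism %||% 1
  pop <- lapply(seq_len(popSize), function(i) runif(k))
  fit <- objEvaluateBatch(obj, pop)
  if (objDone(obj) || anyNA(fit)) return(invisible())
  maxGen <- control$generations %||% 1000L
  stagnation <- 0L
  for (gen in seq_len(maxGen)) {
    charged0 <- obj$env$charged
    ord <- order(fit, decreasing = TRUE)
    newPop <- pop[ord[seq_len(min(elitism, popSize))]]
    while (length(newPop) < popSize) {
      pick <- function() {
        ij <- sample.int(popSize, 2)
        pop[[ij[which.max(fit[ij])]]]
      }
      a <- pick()
      child <- a
      if (runif(1) < C && k >= 2) {
        b <- pick()
        cp <- sample.int(k - 1, 1)
        child <- c(a[seq_len(cp)], b[(cp + 1):k])
      }
      mut <- runif(k) < M
      child[mut] <- runif(sum(mut))
      newPop[[length(newPop) + 1L]] <- child
    }
    pop <- newPop
    fit <- objEvaluateBatch(obj, pop)
    if (objDone(obj) || anyNA(fit)) break
    stagnation <- if (obj$env$charged == charged0) stagnation + 1L else 0L
    if (stagnation >= 25L) break
  }
  invisible()
}

#' Run all three tuners and keep the best result
#'
#' A convenience ensemble: NM, PRO and GA each get the full budget on a
#' fresh copy of the objective; the result with the highest best score
#' wins (ties go to the earlier method).
#'
#' @inheritParams tune
#' @return list with `best` (a [TuningResult-class]), `method` (winning
#'   method name) and `results` (all three).
#' @export
ensembleTune <- function(objective, budget = 100, threshold = 0, seed = NULL,
                         control = list()) {
  methods <- c("nm", "pro", "ga")
  results <- lapply(seq_along(methods), function(i) {
    fresh <- makeObjective(objective$space, objective$fn, objective$batchFn)
    tune(fresh, methods[i], budget = budget, threshold = threshold,
         seed = if (is.null(seed)) NULL else deriveSeed(seed, i),
         control = control)
  })
  names(results) <- methods
  scores <- vapply(results, function(r) r@bestScore, numeric(1))
  list(best = results[[which.max(scores)]],
       method = methods[which.max(scores)], results = results)
}

#' Write a tuning history as CSV
#'
#' One row per charged evaluation: ordinal, the native-unit point and the
#' score.
#'
#' @param result a [TuningResult-class].
#' @param path CSV file path.
#' @export
writeTuningHistory <- function(result, path) {
  write.csv(result@history, path, row.names = FALSE)
  invisible(path)
}
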