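# Morris one-at-a-time (MOAT) screening: design generation, elementary
# effects and the mu/mu*/sigma summaries used to prune parameters.

#' Unit-space MOAT step size
#'
#' For a space partitioned into `p` levels, the screening step is
#' `p / (2(p - 1))` — slightly larger than half the unit range — so the
#' elementary effects probe the space globally. Two-value categorical
#' parameters always flip, i.e. use a step of 1.
#'
#' @param p number of grid levels (>= 2; even values make the step an
#'   integer number of grid cells, odd values draw a warning).
#' @return the unit-space step magnitude.
#' @examples
#' moatDelta(20)  # 10/19
#' @export
moatDelta <- function(p) {
  stopifnot(p >= 2)
  if (p %% 2 != 0)
    warning("odd p: MOAT step p/(2(p-1)) does not land on the level grid")
  p / (2 * (p - 1))
}

# Per-parameter step expressed in integer grid cells.
deltaSteps <- function(s, p) {
  if (s$kind == "categorical") {
    m <- length(s$values)
    if (m < 2) stop(sprintf("parameter '%s' has a single value", s$name))
    ceiling(m / 2)
  } else ceiling(p / 2)
}

#' Generate a Morris screening design
#'
#' Builds `r` random trajectories of `k + 1` points on the `p`-level unit
#' grid; within a trajectory, each of the `k` free parameters is perturbed
#' exactly once by a signed step of magnitude [moatDelta()] (categorical
#' parameters flip), in a random order, from a random feasible base point.
#' The total run count is `r * (k + 1)`.
#'
#' @param space a [ParameterSpace-class].
#' @param r number of trajectories (typically 5 to 15).
#' @param seed integer seed.
#' @param p grid levels (defaults to the space's `p`).
#' @return a [MOATDesign-class].
#' @examples
#' sp <- parameterSpace(parameterSpec("a", "continuous", 0, 1),
#'                      parameterSpec("b", "continuous", 0, 1))
#' nRuns(moatDesign(sp, r = 4, seed = 1))  # 4 * (2 + 1) = 12
#' @export
moatDesign <- function(space, r, seed = NULL, p = space@p) {
  stopifnot(r >= 1)
  fs <- freeSpecs(space)
  k <- length(fs)
  if (k < 1) stop("space has no free parameters")
  if (p %% 2 != 0 && any(vapply(fs, function(s) s$kind != "categorical", logical(1))))
    warning("odd p: MOAT step rounded up to the nearest whole number of grid cells")

  info <- lapply(fs, function(s) {
    nl <- if (s$kind == "categorical") length(s$values) else p
    st <- deltaSteps(s, p)
    if (st > nl - 1)
      stop(sprintf("parameter '%s': no feasible base level for the MOAT step", s$name))
    list(nLevels = nl, steps = st, delta = st / (nl - 1))
  })
  delta <- setNames(vapply(info, function(z) z$delta, numeric(1)),
                    vapply(fs, function(s) s$name, character(1)))

  withLocalSeed(seed, {
    rows <- matrix(NA_real_, nrow = r * (k + 1), ncol = k)
    pert <- vector("list", r * k)
    traj <- integer(r * (k + 1))
    pi <- 0L
    for (t in seq_len(r)) {
      signs <- sample(c(-1, 1), k, replace = TRUE)
      base <- vapply(seq_len(k), function(i) {
        nl <- info[[i]]$nLevels; st <- info[[i]]$steps
        # base levels admitting the signed step without leaving [0, 1]
        lv <- if (signs[i] > 0) 0:(nl - 1 - st) else st:(nl - 1)
        lv[sample.int(length(lv), 1)] / (nl - 1)
      }, numeric(1))
      order_ <- sample.int(k)
      off <- (t - 1) * (k + 1)
      rows[off + 1, ] <- base
      x <- base
      for (j in seq_len(k)) {
        i <- order_[j]
        sd_ <- signs[i] * info[[i]]$delta
        x[i] <- x[i] + sd_
        rows[off + j + 1, ] <- x
        pi <- pi + 1L
        pert[[pi]] <- data.frame(trajectory = t, param = i,
                                 row_before = off + j, row_after = off + j + 1,
                                 sdelta = sd_)
      }
      traj[off + seq_len(k + 1)] <- t
    }
    rows <- pmin(pmax(rows, 0), 1)  # guard FP drift at the bounds
    colnames(rows) <- names(delta)
    new("MOATDesign", design = rows, scheme = "moat",
        seed = as.numeric(seed %||% NA), blockInfo = list(trajectory = traj),
        r = r, delta = delta, perturb = do.call(rbind, pert))
  })
}

setMethod("show", "MOATDesign", function(object) {
  cat(sprintf("MOATDesign: r = %d trajectories, k = %d parameters, %d runs\n",
              object@r, ncol(object@design), nrow(object@design)))
})

#' Elementary effects and Morris summaries
#'
#' For every one-at-a-time move in the design, the elementary effect is
#' the output change divided by the signed step actually taken (a
#' negative step uses a negative denominator; categorical flips use a
#' denominator of +/-1). Summaries per parameter: mu (mean EE), mu* (mean
#' |EE|) and sigma (sample standard deviation of the EEs, n-1
#' denominator — r is small).
#'
#' @param design a [MOATDesign-class].
#' @param y numeric vector of workflow outputs, one per design row, in
#'   row order.
#' @return an [ElementaryEffects-class].
#' @export
elementaryEffects <- function(design, y) {
  if (length(y) != nrow(design@design))
    stop(sprintf("expected %d outputs, got %d", nrow(design@design), length(y)),
         call. = FALSE)
  k <- ncol(design@design)
  pt <- design@perturb
  ee <- matrix(NA_real_, nrow = design@r, ncol = k,
               dimnames = list(NULL, colnames(design@design)))
  for (i in seq_len(nrow(pt)))
    ee[pt$trajectory[i], pt$param[i]] <-
      (y[pt$row_after[i]] - y[pt$row_before[i]]) / pt$sdelta[i]
  new("ElementaryEffects",
      ee = ee,
      mu = colMeans(ee),
      muStar = colMeans(abs(ee)),
      sigma = apply(ee, 2, stats::sd))
}

setMethod("show", "ElementaryEffects", function(object) {
  cat(sprintf("ElementaryEffects over r = %d trajectories:\n", nrow(object@ee)))
  print(data.frame(mu = object@mu, mu.star = object@muStar,
                   sigma = object@sigma))
})

#' Classify parameters from their MOAT summaries
#'
#' Each parameter is scored by `max(mu*, sigma)` and classified as
#' influential (score at or above the high threshold), medium, or
#' non-influential (below the low threshold; candidates for fixing at
#' their defaults). The default rule is relative — thresholds at 10% and
#' 1% of the largest score across parameters — so it is invariant to the
#' scale of the output metric.
#'
#' @param effects an [ElementaryEffects-class].
#' @param tHi,tLo absolute thresholds; if omitted, the relative defaults
#'   are used.
#' @return data.frame with columns `param`, `mu`, `mu.star`, `sigma`,
#'   `score`, `class`.
#' @export
screenParameters <- function(effects, tHi = NULL, tLo = NULL) {
  score <- pmax(effects@muStar, effects@sigma)
  if (is.null(tHi) || is.null(tLo)) {
    m <- max(score)
    if (is.null(tHi)) tHi <- 0.1 * m
    if (is.null(tLo)) tLo <- 0.01 * m
  }
  cls <- if (max(score) == 0) rep("non-influential", length(score))
         else ifelse(score >= tHi, "influential",
              ifelse(score >= tLo, "medium", "non-influential"))
  data.frame(param = names(effects@mu), mu = effects@mu,
             mu.star = effects@muStar, sigma = effects@sigma,
             score = score, class = cls, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a MOAT screening report as CSV
#'
#' One row per parameter with mu, mu*, sigma and the screening class.
#'
#' @param report output of [screenParameters()].
#' @param path CSV file path.
#' @export
writeMOATReport <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
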