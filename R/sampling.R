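# Space-filling designs over the unit hypercube for the importance phase.

newDesign <- function(design, scheme, seed = NA_real_, blockInfo = list(),
                      class = "DesignMatrix", ...) {
  new(class, design = design, scheme = scheme, seed = as.numeric(seed %||% NA),
      blockInfo = blockInfo, ...)
}

#' @describeIn monteCarloDesign matrix of sample points (rows in `[0,1]^k`).
#' @export
setMethod("designMatrix", "DesignMatrix", function(x) x@design)

#' @describeIn monteCarloDesign number of workflow runs the design requires.
#' @export
setMethod("nRuns", "DesignMatrix", function(x) nrow(x@design))

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("%s: %d points in [0,1]^%d (scheme '%s', seed %s)\n",
              class(object), nrow(object@design), ncol(object@design),
              object@scheme,
              if (is.na(object@seed)) "none" else format(object@seed)))
})

#' Sampling designs on the unit hypercube
#'
#' `monteCarloDesign` draws `n` i.i.d. uniform points; `lhsDesign` draws a
#' Latin hypercube (each column has exactly one sample in each of the `n`
#' equal strata); `haltonDesign` and `hammersleyDesign` produce
#' quasi-random low-discrepancy sequences (column i of a Halton design
#' uses the radical-inverse sequence in the i-th prime base; a Hammersley
#' design replaces the first column by the regular grid `(i-1)/n`). All
#' are deterministic given their seed; the quasi sequences take no seed.
#'
#' @param n number of points (>= 1).
#' @param k dimension; the quasi sequences support k up to 20 (the first
#'   20 primes serve as bases).
#' @param seed integer seed.
#' @param skip number of initial Halton indices to skip (default 0; skip
#'   1 to avoid the origin-adjacent first point if desired).
#' @return a [DesignMatrix-class].
#' @examples
#' designMatrix(haltonDesign(4, 1))  # 1/2, 1/4, 3/4, 1/8
#' @export
monteCarloDesign <- function(n, k, seed = NULL) {
  stopifnot(n >= 1, k >= 1)
  d <- withLocalSeed(seed, matrix(runif(n * k), nrow = n, ncol = k))
  newDesign(d, "monte-carlo", seed)
}

#' @rdname monteCarloDesign
#' @export
lhsDesign <- function(n, k, seed = NULL) {
  stopifnot(n >= 1, k >= 1)
  d <- withLocalSeed(seed, lhs::randomLHS(n, k))
  newDesign(d, "lhs", seed)
}

.PRIMES20 <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29,
               31, 37, 41, 43, 47, 53, 59, 61, 67, 71)

# Radical inverse of integer i (>= 1) in the given base.
radicalInverse <- function(i, base) {
  r <- 0
  f <- 1 / base
  while (i > 0) {
    r <- r + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  r
}

#' @rdname monteCarloDesign
#' @export
haltonDesign <- function(n, k, skip = 0) {
  stopifnot(n >= 1, k >= 1)
  if (k > length(.PRIMES20))
    stop(sprintf("Halton/Hammersley designs support k <= %d", length(.PRIMES20)),
         call. = FALSE)
  idx <- seq_len(n) + skip
  d <- vapply(seq_len(k), function(j)
    vapply(idx, radicalInverse, numeric(1), base = .PRIMES20[j]),
    numeric(n))
  d <- matrix(d, nrow = n, ncol = k)
  newDesign(d, "halton", blockInfo = list(skip = skip))
}

#' @rdname monteCarloDesign
#' @export
hammersleyDesign <- function(n, k, skip = 0) {
  stopifnot(n >= 1, k >= 1)
  if (k == 1) {
    d <- matrix((seq_len(n) - 1) / n, ncol = 1)
  } else {
    h <- designMatrix(haltonDesign(n, k - 1, skip = skip))
    d <- cbind((seq_len(n) - 1) / n, h)
  }
  newDesign(d, "hammersley", blockInfo = list(skip = skip))
}

#' Export / import a design in native units
#'
#' Writes one row per point with a header of parameter names; unit-space
#' rows are snapped onto each parameter's native grid via [fromUnit()].
#'
#' @param design a [DesignMatrix-class].
#' @param space the [ParameterSpace-class] giving native units.
#' @param path CSV file path.
#' @export
writeDesignCSV <- function(design, space, path) {
  d <- designMatrix(design)
  rows <- lapply(seq_len(nrow(d)), function(i) {
    pt <- fromUnit(space, d[i, ])
    as.data.frame(pt, stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDesignCSV
#' @export
readDesignCSV <- function(space, path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  d <- t(apply(df, 1, function(row) {
    pt <- as.list(row)
    num <- vapply(space@specs, function(s) s$kind != "categorical", logical(1))
    names(num) <- vapply(space@specs, function(s) s$name, character(1))
    for (nm in names(pt)) if (isTRUE(num[nm])) pt[[nm]] <- as.numeric(pt[[nm]])
    toUnit(space, pt)
  }))
  newDesign(matrix(d, nrow = nrow(df)), "imported")
}
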