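# Phase-2 importance measures: correlation coefficients (CC, PCC, RCC,
# PRCC) and variance-based decomposition on Saltelli designs.

#' Correlation between a parameter and the workflow output
#'
#' `kind = "cc"` is Pearson's correlation coefficient; `kind = "rcc"` is
#' Spearman's rank correlation — the same formula applied to average-ranked
#' data, useful when the parameter-output relation is monotone but not
#' linear.
#'
#' @param x,y paired samples (>= 3, non-zero variance in both).
#' @param kind "cc" or "rcc".
#' @return the coefficient, in `[-1, 1]`.
#' @export
correlation <- function(x, y, kind = c("cc", "rcc")) {
  kind <- match.arg(kind)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired samples")
  if (kind == "rcc") { x <- rank(x); y <- rank(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance input")
  stats::cor(x, y)
}

# Residuals of the least-squares regression of v on the columns of Z
# (with intercept). Errors on rank deficiency.
regressOut <- function(v, Z) {
  X <- cbind(1, Z)
  q <- qr(X)
  if (q$rank < ncol(X))
    stop("rank-deficient design: collinear parameter columns", call. = FALSE)
  as.vector(v - X %*% qr.coef(q, v))
}

#' Partial (rank) correlation of one parameter with the output
#'
#' Correlation between parameter `i` and the output after the effects of
#' the other parameters are regressed out of both: the Pearson correlation
#' of the two residual vectors. For `kind = "prcc"` all columns and the
#' output are average-ranked first. On an orthogonal design the partial
#' and simple correlations coincide (exactly so when the output carries
#' no contribution from the other parameters; otherwise removing their
#' shared variance makes the partial coefficient the larger of the two).
#'
#' @param X numeric matrix of parameter samples (n rows, k columns).
#' @param y output vector of length n.
#' @param i column index of the parameter of interest.
#' @param kind "pcc" or "prcc".
#' @return the coefficient, in `[-1, 1]`.
#' @export
partialCorrelation <- function(X, y, i, kind = c("pcc", "prcc")) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X) + 1)
    stop("need n > k + 1 samples for partial correlation")
  if (kind == "prcc") { X <- apply(X, 2, rank); y <- rank(y) }
  if (ncol(X) == 1) return(stats::cor(X[, 1], y))
  rx <- regressOut(X[, i], X[, -i, drop = FALSE])
  ry <- regressOut(y, X[, -i, drop = FALSE])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined partial correlation: zero residual variance")
  stats::cor(rx, ry)
}

#' All four importance coefficients for every parameter
#'
#' @param X parameter sample matrix (columns named by parameter).
#' @param y output vector.
#' @return data.frame with columns `param`, `cc`, `pcc`, `rcc`, `prcc`.
#' @export
correlationReport <- function(X, y) {
  X <- as.matrix(X)
  nm <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  data.frame(
    param = nm,
    cc = vapply(seq_len(ncol(X)), function(i) correlation(X[, i], y, "cc"), numeric(1)),
    pcc = vapply(seq_len(ncol(X)), function(i) partialCorrelation(X, y, i, "pcc"), numeric(1)),
    rcc = vapply(seq_len(ncol(X)), function(i) correlation(X[, i], y, "rcc"), numeric(1)),
    prcc = vapply(seq_len(ncol(X)), function(i) partialCorrelation(X, y, i, "prcc"), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Saltelli design for variance-based decomposition
#'
#' Draws two independent base blocks A and B of `n` points each and forms
#' the k cross matrices AB(i) (A with column i replaced from B). The
#' stacked design has `n * (k + 2)` rows in the order A, B, AB(1) ...
#' AB(k) — the evaluation order [vbdEstimate()] expects.
#'
#' @param n base sample size (>= 2).
#' @param k number of parameters.
#' @param sampler "monte-carlo" (default), "lhs", "halton" or "hammersley".
#' @param seed integer seed (ignored by the quasi sequences, which use
#'   disjoint index blocks instead).
#' @return a [SaltelliDesign-class].
#' @examples
#' nRuns(saltelliDesign(200, 8, seed = 1))  # 200 * 10 = 2000
#' @export
saltelliDesign <- function(n, k,
                           sampler = c("monte-carlo", "lhs", "halton", "hammersley"),
                           seed = NULL) {
  stopifnot(n >= 2, k >= 1)
  sampler <- match.arg(sampler)
  blocks <- switch(sampler,
    "monte-carlo" = list(designMatrix(monteCarloDesign(n, k, deriveSeed(seed %||% 0, 1))),
                         designMatrix(monteCarloDesign(n, k, deriveSeed(seed %||% 0, 2)))),
    "lhs" = list(designMatrix(lhsDesign(n, k, deriveSeed(seed %||% 0, 1))),
                 designMatrix(lhsDesign(n, k, deriveSeed(seed %||% 0, 2)))),
    "halton" = { h <- designMatrix(haltonDesign(2 * n, k))
                 list(h[seq_len(n), , drop = FALSE], h[n + seq_len(n), , drop = FALSE]) },
    "hammersley" = { h <- designMatrix(hammersleyDesign(2 * n, k))
                     list(h[seq_len(n), , drop = FALSE], h[n + seq_len(n), , drop = FALSE]) })
  A <- blocks[[1]]; B <- blocks[[2]]
  cross <- lapply(seq_len(k), function(i) { M <- A; M[, i] <- B[, i]; M })
  stacked <- do.call(rbind, c(list(A, B), cross))
  role <- c(rep("A", n), rep("B", n),
            rep(paste0("AB", seq_len(k)), each = n))
  new("SaltelliDesign", design = stacked, scheme = "saltelli",
      seed = as.numeric(seed %||% NA),
      blockInfo = list(role = role, sampler = sampler), n = n, k = k)
}

setMethod("show", "SaltelliDesign", function(object) {
  cat(sprintf("SaltelliDesign: n = %d base samples, k = %d parameters, %d runs\n",
              object@n, object@k, nrow(object@design)))
})

#' Estimate Sobol main and total effect indices
#'
#' First-order indices use the Saltelli (2010) estimator
#' `S_i = mean(y_B * (y_ABi - y_A)) / V` and total effects the Jansen
#' estimator `ST_i = mean((y_A - y_ABi)^2) / (2 V)`, with `V` the sample
#' variance over the A and B outputs. Small negative `S_i` are legitimate
#' finite-sample estimates of near-zero indices and are reported as-is;
#' the sum of main effects is reported both with and without them.
#'
#' @param design a [SaltelliDesign-class].
#' @param y outputs ordered as the design's rows (A, B, AB(1)..AB(k)).
#' @param names optional parameter names for the report.
#' @return list with `table` (data.frame `param`, `si`, `sti`),
#'   `V` (total output variance), `sumSi` and `sumSiPositive`.
#' @export
vbdEstimate <- function(design, y, names = NULL) {
  n <- design@n; k <- design@k
  if (length(y) != n * (k + 2))
    stop(sprintf("expected %d outputs, got %d", n * (k + 2), length(y)),
         call. = FALSE)
  yA <- y[seq_len(n)]
  yB <- y[n + seq_len(n)]
  V <- stats::var(c(yA, yB))
  if (V == 0) stop("degenerate output: zero variance over the base blocks")
  # centering leaves the estimator's expectation unchanged and sharply
  # reduces its Monte-Carlo variance
  ctr <- mean(c(yA, yB))
  yAc <- yA - ctr; yBc <- yB - ctr
  si <- sti <- numeric(k)
  for (i in seq_len(k)) {
    yAB <- y[(1 + i) * n + seq_len(n)] - ctr
    si[i] <- mean(yBc * (yAB - yAc)) / V
    sti[i] <- mean((yAc - yAB)^2) / (2 * V)
  }
  nm <- names %||% colnames(design@design) %||% paste0("x", seq_len(k))
  flagged <- which(sti + 1e-9 < si)
  if (length(flagged))
    message("finite-sample estimates with ST_i < S_i for: ",
            paste(nm[flagged], collapse = ", "))
  list(table = data.frame(param = nm, si = si, sti = sti,
                          row.names = NULL, stringsAsFactors = FALSE),
       V = V, sumSi = sum(si), sumSiPositive = sum(pmax(si, 0)))
}

#' Write importance reports as CSV
#'
#' @param report a [correlationReport()] data.frame or [vbdEstimate()] list.
#' @param path CSV file path.
#' @export
writeImportanceReport <- function(report, path) {
  if (is.list(report) && !is.data.frame(report)) report <- report$table
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
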