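# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All exported stochastic operations route through this.
withLocalSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a master seed and an index, staying within the
# 32-bit integer range R requires.
deriveSeed <- function(master, index) {
  as.integer((as.double(master) * 1103515245 + 12345 * as.double(index)) %% 2147483647)
}

# Canonical string form of a native-unit parameter value (content keys,
# memoization). Numbers printed with full precision, stable across calls.
canonicalValue <- function(v) {
  if (is.character(v)) v else format(v, digits = 17, scientific = TRUE, trim = TRUE)
}

canonicalPoint <- function(point) {
  paste(names(point),
        vapply(point, canonicalValue, character(1)),
        sep = "=", collapse = ";")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
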