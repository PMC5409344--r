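#' Declare a single workflow parameter
#'
#' A parameter is continuous, discrete-numeric (a numeric range walked in
#' fixed steps, as in area thresholds `[2, 4, ..., 40]`) or categorical
#' (an ordered list of values, as in a 4-conn/8-conn propagation
#' neighborhood). A parameter flagged `dummy` is declared to the study but
#' consumed by no workflow stage; its apparent effect measures the
#' stochastic (or, for deterministic workflows, zero) component of the
#' output. A `fixed` parameter is held at its default and excluded from
#' designs, the usual fate of parameters screened out after MOAT.
#'
#' @param name parameter name (unique within a space).
#' @param kind "continuous", "discrete" or "categorical".
#' @param low,high range bounds in native units (numeric kinds).
#' @param step native-unit increment for discrete parameters; `high - low`
#'   must be an integer multiple of it.
#' @param values ordered vector of admissible values (categorical).
#' @param default default native value; must lie in the range/list.
#' @param dummy flag marking a control parameter ignored by the workflow.
#' @param fixed hold at default and exclude from designs.
#' @return a parameter specification (named list) for [parameterSpace()].
#' @examples
#' parameterSpec("G1", "discrete", low = 5, high = 80, step = 5, default = 40)
#' parameterSpec("Watershed", "categorical", values = c("4-conn", "8-conn"),
#'               default = "8-conn")
#' @export
parameterSpec <- function(name, kind = c("continuous", "discrete", "categorical"),
                          low = NULL, high = NULL, step = NULL, values = NULL,
                          default = NULL, dummy = FALSE, fixed = FALSE) {
  kind <- match.arg(kind)
  if (is.null(default)) {
    default <- if (kind == "categorical") values[1] else {
      mid <- (low + high) / 2
      if (kind == "discrete") low + round((mid - low) / step) * step else mid
    }
  }
  spec <- list(name = name, kind = kind, low = low, high = high, step = step,
               values = values, default = default, dummy = isTRUE(dummy),
               fixed = isTRUE(fixed))
  err <- validateSpec(spec)
  if (!is.null(err)) stop(err, call. = FALSE)
  spec
}

# Returns NULL if valid, else an error message.
validateSpec <- function(s) {
  req <- c("name", "kind", "default", "dummy", "fixed")
  if (!all(req %in% names(s))) return("malformed parameter spec")
  who <- function(msg) sprintf("parameter '%s': %s", s$name, msg)
  if (s$kind %in% c("continuous", "discrete")) {
    if (is.null(s$low) || is.null(s$high) || !(s$low < s$high))
      return(who("low < high required"))
    if (s$kind == "discrete") {
      if (is.null(s$step) || s$step <= 0) return(who("step > 0 required"))
      m <- (s$high - s$low) / s$step
      if (abs(m - round(m)) > 1e-8)
        return(who("(high - low) must be an integer multiple of step"))
    }
    if (s$default < s$low || s$default > s$high)
      return(who("default outside range"))
  } else if (s$kind == "categorical") {
    if (is.null(s$values) || length(s$values) < 1 || anyDuplicated(s$values))
      return(who("categorical values must be non-empty and unique"))
    if (!s$default %in% s$values) return(who("default not in value list"))
  } else return(who("unknown kind"))
  NULL
}

#' Assemble a parameter space
#'
#' @param ... parameter specifications from [parameterSpec()] (or a single
#'   list of them).
#' @param p number of grid levels used when the space is discretized for
#'   sensitivity analysis (default 20, the partition used throughout).
#' @return a [ParameterSpace-class] object.
#' @examples
#' sp <- parameterSpace(
#'   parameterSpec("a", "continuous", low = 0, high = 1),
#'   parameterSpec("b", "discrete", low = 2, high = 40, step = 2),
#'   p = 20)
#' paramCount(sp)
#' @export
parameterSpace <- function(..., p = 20) {
  specs <- list(...)
  if (length(specs) == 1 && is.list(specs[[1]]) && is.null(specs[[1]]$name))
    specs <- specs[[1]]
  new("ParameterSpace", specs = specs, p = p)
}

#' @describeIn parameterSpace names of the parameters (all, or only the
#'   non-fixed ones with `free = TRUE`).
#' @param x,space a `ParameterSpace`.
#' @param free return only non-fixed parameters.
#' @export
setMethod("paramNames", "ParameterSpace", function(x, free = FALSE) {
  s <- if (free) freeSpecs(x) else x@specs
  vapply(s, function(z) z$name, character(1))
})

#' @describeIn parameterSpace number of non-fixed parameters `k`.
#' @export
setMethod("paramCount", "ParameterSpace", function(x) length(freeSpecs(x)))

setMethod("show", "ParameterSpace", function(object) {
  cat(sprintf("ParameterSpace: %d parameters (k = %d free), p = %d levels\n",
              length(object@specs), paramCount(object), object@p))
  for (s in object@specs) {
    rng <- switch(s$kind,
      continuous = sprintf("[%g, %g]", s$low, s$high),
      discrete = sprintf("[%g, %g] step %g", s$low, s$high, s$step),
      categorical = paste0("{", paste(s$values, collapse = ", "), "}"))
    tags <- c(if (s$dummy) "dummy", if (s$fixed) "fixed")
    cat(sprintf("  %-12s %-11s %-24s default %s%s\n", s$name, s$kind, rng,
                s$default, if (length(tags)) paste0(" [", paste(tags, collapse = ","), "]") else ""))
  }
})

freeSpecs <- function(space) Filter(function(s) !s$fixed, space@specs)

specByName <- function(space, nm) {
  for (s in space@specs) if (s$name == nm) return(s)
  stop(sprintf("unknown parameter '%s'", nm), call. = FALSE)
}

#' Hold screened-out parameters fixed at their defaults
#'
#' After MOAT screening, non-influential parameters are fixed at their
#' default values and excluded from subsequent designs (their count no
#' longer enters `k`).
#'
#' @param space a [ParameterSpace-class].
#' @param names parameter names to fix.
#' @return the updated space.
#' @export
fixParameters <- function(space, names) {
  space@specs <- lapply(space@specs, function(s) {
    if (s$name %in% names) s$fixed <- TRUE
    s
  })
  validObject(space)
  space
}

#' Default parameter point of a space
#'
#' @param space a [ParameterSpace-class].
#' @return named list of native-unit defaults, one entry per parameter
#'   (fixed parameters included).
#' @export
defaultPoint <- function(space) {
  setNames(lapply(space@specs, function(s) s$default),
           vapply(space@specs, function(s) s$name, character(1)))
}

unitOfValue <- function(s, v) {
  if (s$kind == "categorical") {
    i <- match(v, s$values)
    if (is.na(i)) stop(sprintf("parameter '%s': value '%s' not in list",
                               s$name, v), call. = FALSE)
    m <- length(s$values)
    if (m == 1) 0 else (i - 1) / (m - 1)
  } else {
    if (v < s$low - 1e-9 || v > s$high + 1e-9)
      stop(sprintf("parameter '%s': value %g outside [%g, %g]",
                   s$name, v, s$low, s$high), call. = FALSE)
    (v - s$low) / (s$high - s$low)
  }
}

# Snap ties (exactly halfway) to the lower grid value: idx = ceiling(z - 1/2).
snapIndex <- function(z) as.integer(ceiling(z - 0.5 - 1e-12))

valueOfUnit <- function(s, u) {
  if (u < -1e-9 || u > 1 + 1e-9)
    stop(sprintf("parameter '%s': unit value %g outside [0, 1]", s$name, u),
         call. = FALSE)
  u <- min(max(u, 0), 1)
  if (s$kind == "categorical") {
    m <- length(s$values)
    if (m == 1) return(s$values[1])
    s$values[snapIndex(u * (m - 1)) + 1L]
  } else if (s$kind == "discrete") {
    nsteps <- round((s$high - s$low) / s$step)
    s$low + min(snapIndex(u * nsteps), nsteps) * s$step
  } else {
    s$low + u * (s$high - s$low)
  }
}

#' Map a native-unit point to the unit hypercube
#'
#' Continuous and discrete parameters map affinely (low -> 0, high -> 1);
#' a categorical with m values maps to m equispaced levels by list
#' position. Only the non-fixed parameters enter the unit vector (fixed
#' ones are pinned to their defaults).
#'
#' @param space a [ParameterSpace-class].
#' @param point named list/vector of native values covering at least the
#'   free parameters.
#' @return numeric vector in `[0,1]^k`, named by parameter.
#' @examples
#' sp <- parameterSpace(parameterSpec("B", "discrete", 210, 240, step = 10))
#' toUnit(sp, list(B = 225))   # 0.5
#' @export
setMethod("toUnit", "ParameterSpace", function(space, point) {
  fs <- freeSpecs(space)
  u <- vapply(fs, function(s) {
    if (!s$name %in% names(point))
      stop(sprintf("point is missing parameter '%s'", s$name), call. = FALSE)
    unitOfValue(s, point[[s$name]])
  }, numeric(1))
  setNames(u, vapply(fs, function(s) s$name, character(1)))
})

#' Map a unit-hypercube vector back to native units
#'
#' Inverse of [toUnit()]: discrete parameters snap to the nearest
#' step-grid value and categoricals to the nearest level (exact halfway
#' ties resolve to the lower value). Fixed parameters are filled with
#' their defaults so the result is a complete workflow point.
#'
#' @param space a [ParameterSpace-class].
#' @param u numeric vector in `[0,1]^k` over the free parameters.
#' @return named list of native values, one per parameter of the space.
#' @export
setMethod("fromUnit", "ParameterSpace", function(space, u) {
  fs <- freeSpecs(space)
  if (length(u) != length(fs))
    stop(sprintf("unit vector has %d components, space has k = %d",
                 length(u), length(fs)), call. = FALSE)
  point <- defaultPoint(space)
  for (i in seq_along(fs)) point[[fs[[i]]$name]] <- valueOfUnit(fs[[i]], u[i])
  point
})

#' Unit-space grid levels of each free parameter
#'
#' Numeric parameters are partitioned uniformly into `p` levels
#' `{0, 1/(p-1), ..., 1}`; a categorical with m values keeps its m native
#' levels regardless of `p` (so a 2-value neighborhood parameter has
#' levels `{0, 1}`).
#'
#' @param space a [ParameterSpace-class].
#' @param p number of levels (defaults to the space's `p`).
#' @return named list of unit-space level vectors, one per free parameter.
#' @export
setMethod("levelGrid", "ParameterSpace", function(space, p) {
  if (missing(p)) p <- space@p
  if (p < 2) stop("p must be >= 2", call. = FALSE)
  fs <- freeSpecs(space)
  out <- lapply(fs, function(s) {
    if (s$kind == "categorical") {
      m <- length(s$values)
      if (m == 1) 0 else seq(0, 1, length.out = m)
    } else seq(0, 1, length.out = p)
  })
  setNames(out, vapply(fs, function(s) s$name, character(1)))
})

# Snap a unit vector onto each parameter's native grid image (discrete /
# categorical parameters only; continuous pass through). Used at
# evaluation time so designs stay scheme-pure.
snapUnit <- function(space, u) {
  fs <- freeSpecs(space)
  vapply(seq_along(fs), function(i) {
    s <- fs[[i]]
    unitOfValue(s, valueOfUnit(s, u[i]))
  }, numeric(1))
}

#' Read or write a parameter space as a YAML config
#'
#' One entry per parameter: name, kind, low/high/step or value list,
#' default, dummy and fixed flags, plus the top-level level count `p`. The
#' bundled file `system.file("extdata", "watershed_space.yaml", package =
#' "segstudy")` describes the watershed workflow's 15-parameter space.
#'
#' @param path file path.
#' @return `readParameterSpace` returns a [ParameterSpace-class];
#'   `writeParameterSpace` returns `path` invisibly.
#' @export
readParameterSpace <- function(path) {
  cfg <- yaml::read_yaml(path)
  specs <- lapply(cfg$parameters, function(e) {
    parameterSpec(name = e$name, kind = e$kind,
                  low = e$low, high = e$high, step = e$step,
                  values = if (!is.null(e$values)) as.character(e$values),
                  default = e$default,
                  dummy = isTRUE(e$dummy), fixed = isTRUE(e$fixed))
  })
  parameterSpace(specs, p = cfg$p %||% 20)
}

#' @rdname readParameterSpace
#' @param space a [ParameterSpace-class] to serialize.
#' @export
writeParameterSpace <- function(space, path) {
  entries <- lapply(space@specs, function(s) {
    e <- list(name = s$name, kind = s$kind)
    if (s$kind == "categorical") e$values <- as.list(s$values)
    else { e$low <- s$low; e$high <- s$high; if (s$kind == "discrete") e$step <- s$step }
    e$default <- s$default
    if (s$dummy) e$dummy <- TRUE
    if (s$fixed) e$fixed <- TRUE
    e
  })
  yaml::write_yaml(list(p = space@p, parameters = entries), path)
  invisible(path)
}
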