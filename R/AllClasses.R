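#' ParameterSpace: a typed, ordered collection of workflow parameters
#'
#' Holds the ordered parameter specifications of a segmentation workflow
#' together with the number of grid levels `p` used when the space is
#' discretized for sensitivity analysis. Individual specifications are
#' created with [parameterSpec()].
#'
#' @slot specs list of parameter specifications (see [parameterSpec()]).
#' @slot p number of grid levels for SA discretization (>= 2).
#' @seealso [parameterSpace()], [toUnit()], [fromUnit()], [levelGrid()]
#' @export
setClass("ParameterSpace",
         representation(specs = "list", p = "numeric"))

setValidity("ParameterSpace", function(object) {
  msgs <- character(0)
  nm <- vapply(object@specs, function(s) s$name, character(1))
  if (anyDuplicated(nm)) msgs <- c(msgs, "parameter names must be unique")
  if (length(object@p) != 1 || object@p < 2) msgs <- c(msgs, "p must be >= 2")
  for (s in object@specs) {
    err <- validateSpec(s)
    if (!is.null(err)) msgs <- c(msgs, err)
  }
  if (length(msgs)) msgs else TRUE
})

#' DesignMatrix: an ordered set of points in the unit hypercube
#'
#' Rows are sample points in `[0,1]^k`; `scheme` records the generator
#' ("monte-carlo", "lhs", "halton", "hammersley", "moat" or "saltelli")
#' and `blockInfo` carries scheme-specific structure (trajectory indices,
#' Saltelli block roles).
#'
#' @slot design numeric matrix, one row per point, entries in `[0,1]`.
#' @slot scheme character scalar naming the sampling scheme.
#' @slot seed integer seed the design was generated from (NA if none).
#' @slot blockInfo list of scheme-specific annotations.
#' @export
setClass("DesignMatrix",
         representation(design = "matrix", scheme = "character",
                        seed = "numeric", blockInfo = "list"),
         prototype(seed = NA_real_, blockInfo = list()))

setValidity("DesignMatrix", function(object) {
  d <- object@design
  if (length(d) && (min(d) < 0 || max(d) > 1))
    return("design entries must lie in [0,1]")
  TRUE
})

#' MOATDesign: a Morris one-at-a-time screening design
#'
#' `r` trajectories of `k+1` points each; consecutive points within a
#' trajectory differ in exactly one parameter by a signed step of
#' magnitude `delta` (categorical parameters flip by 1). The `perturb`
#' table records, for every elementary effect, the design rows before and
#' after the move, the parameter moved and the signed step taken.
#'
#' @slot r number of trajectories.
#' @slot delta named vector of unit-space step magnitudes per parameter.
#' @slot perturb data.frame with columns `trajectory`, `param`,
#'   `row_before`, `row_after`, `sdelta`.
#' @export
setClass("MOATDesign", contains = "DesignMatrix",
         representation(r = "numeric", delta = "numeric",
                        perturb = "data.frame"))

#' SaltelliDesign: sample blocks for variance-based decomposition
#'
#' Stacks the base matrices A and B and the k cross matrices `AB(i)`
#' (A with column i replaced from B) in the evaluation order expected by
#' [vbdEstimate()]: A rows, B rows, then AB(1)..AB(k). Total rows
#' `n * (k + 2)`.
#'
#' @slot n base sample size.
#' @slot k number of parameters.
#' @export
setClass("SaltelliDesign", contains = "DesignMatrix",
         representation(n = "numeric", k = "numeric"))

setValidity("SaltelliDesign", function(object) {
  if (nrow(object@design) != object@n * (object@k + 2))
    return("row count must equal n * (k + 2)")
  TRUE
})

#' ElementaryEffects: per-parameter MOAT summaries
#'
#' Holds the r elementary effects per parameter and the Morris summaries:
#' mu (mean EE), mu* (mean absolute EE) and sigma (sample standard
#' deviation of the EEs).
#'
#' @slot ee numeric matrix, r rows (trajectories) by k columns (parameters).
#' @slot mu named numeric vector of mean elementary effects.
#' @slot muStar named numeric vector of mean absolute elementary effects.
#' @slot sigma named numeric vector of EE standard deviations (n-1).
#' @export
setClass("ElementaryEffects",
         representation(ee = "matrix", mu = "numeric",
                        muStar = "numeric", sigma = "numeric"))

setValidity("ElementaryEffects", function(object) {
  if (any(object@muStar + 1e-12 < abs(object@mu)))
    return("mu* must be >= |mu| for every parameter")
  if (any(object@sigma < 0)) return("sigma must be >= 0")
  TRUE
})

#' TuningResult: outcome of a black-box parameter tuning run
#'
#' @slot bestPoint named list, best parameter values in native units.
#' @slot bestScore best metric value reached (in `[0,1]` for mask metrics).
#' @slot history data.frame of evaluations in order: ordinal, one column
#'   per parameter (native units), `score`.
#' @slot evaluations number of objective evaluations charged to the budget.
#' @slot stopReason "budget" or "threshold".
#' @export
setClass("TuningResult",
         representation(bestPoint = "list", bestScore = "numeric",
                        history = "data.frame", evaluations = "numeric",
                        stopReason = "character"))

setValidity("TuningResult", function(object) {
  if (nrow(object@history) &&
      abs(max(object@history$score) - object@bestScore) > 1e-12)
    return("bestScore must equal the maximum of the history scores")
  TRUE
})

#' SegPipeline: a linear chain of pure segmentation stages
#'
#' Each stage is a list with a `name`, the subset of parameter names it
#' consumes (`params`) and a pure transform `fn(input, params)` returning
#' the stage output. Purity (same input and parameter values imply the
#' same output) is the contract the dataflow executor relies on to merge
#' common computation paths.
#'
#' @slot stages list of stage descriptors, executed in order.
#' @export
setClass("SegPipeline", representation(stages = "list"))

#' WorkflowGraph: instantiated stage graph for a batch of parameter sets
#'
#' Nodes are stage instances with bound parameter values; each node has a
#' content key of (stage name, bound values, parent key), so in compact
#' mode all parameter sets sharing a computation prefix share the same
#' nodes. Replica mode instantiates an independent chain per set.
#'
#' @slot nodes named list of node records (stage, params, parent, key).
#' @slot mode "replica" or "compact".
#' @slot leaves character vector: per parameter set, the key of its final
#'   node.
#' @slot inputId identity string of the graph input.
#' @export
setClass("WorkflowGraph",
         representation(nodes = "list", mode = "character",
                        leaves = "character", inputId = "character"))

setValidity("WorkflowGraph", function(object) {
  if (!object@mode %in% c("replica", "compact"))
    return("mode must be 'replica' or 'compact'")
  if (object@mode == "compact" &&
      anyDuplicated(vapply(object@nodes, function(n) n$key, character(1))))
    return("compact graphs must not repeat content keys")
  TRUE
})

#' ResultStore: bounded two-level store for stage outputs
#'
#' Level 1 is an in-memory store with a capacity bound; on insertion past
#' capacity an entry is demoted to level 2 (an on-disk spill directory,
#' also bounded; eviction from level 2 deletes). The eviction policy is
#' FIFO (oldest inserted) or LRU (least recently accessed). Hit and miss
#' counters are kept per level.
#'
#' @slot state environment holding entries, ordering metadata and counters.
#' @export
setClass("ResultStore", representation(state = "environment"))
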