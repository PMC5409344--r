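# Dataflow representation of a stage chain and the simultaneous-parameter
# evaluation (SPE) optimization: executing a batch of parameter sets as a
# compact graph in which instances sharing a computation prefix (same
# input data, same bound parameter values) run their common stages once.
# A bounded two-level result store memoizes stage outputs across
# executions.

#' Create a bounded two-level result store
#'
#' Level 1 is in-memory with `capacity` entries; inserting past capacity
#' demotes a victim to level 2, an on-disk spill directory (bounded by
#' `l2capacity`; eviction from level 2 deletes). `policy` selects the
#' victim: FIFO evicts the oldest-inserted entry, LRU the least recently
#' accessed. A level-2 hit promotes the entry back to level 1.
#'
#' @param capacity level-1 entry bound (0 sends everything to disk).
#' @param policy "FIFO" or "LRU".
#' @param spillDir level-2 directory (created on demand).
#' @param l2capacity level-2 entry bound.
#' @return a [ResultStore-class].
#' @export
resultStore <- function(capacity = 128, policy = c("FIFO", "LRU"),
                        spillDir = tempfile("segstudy_store_"),
                        l2capacity = Inf) {
  policy <- match.arg(policy)
  st <- new.env(parent = emptyenv())
  st$l1 <- new.env(parent = emptyenv())
  st$l1meta <- data.frame(key = character(0), inserted = numeric(0),
                          accessed = numeric(0), stringsAsFactors = FALSE)
  st$l2index <- data.frame(key = character(0), file = character(0),
                           inserted = numeric(0), accessed = numeric(0),
                           stringsAsFactors = FALSE)
  st$capacity <- capacity
  st$l2capacity <- l2capacity
  st$policy <- policy
  st$spillDir <- spillDir
  st$clock <- 0
  st$hits1 <- 0; st$hits2 <- 0; st$misses <- 0
  new("ResultStore", state = st)
}

storeTick <- function(st) { st$clock <- st$clock + 1; st$clock }

victimRow <- function(meta, policy) {
  if (policy == "FIFO") which.min(meta$inserted) else which.min(meta$accessed)
}

evictL2 <- function(st) {
  while (nrow(st$l2index) > st$l2capacity) {
    v <- victimRow(st$l2index, st$policy)
    unlink(st$l2index$file[v])
    st$l2index <- st$l2index[-v, , drop = FALSE]
  }
}

demoteToL2 <- function(st, key, value, inserted, accessed) {
  if (st$l2capacity <= 0) return(invisible())
  if (!dir.exists(st$spillDir)) dir.create(st$spillDir, recursive = TRUE)
  f <- file.path(st$spillDir, paste0("e", format(storeTick(st)), ".rds"))
  saveRDS(value, f)
  st$l2index <- rbind(st$l2index,
                      data.frame(key = key, file = f, inserted = inserted,
                                 accessed = accessed, stringsAsFactors = FALSE))
  evictL2(st)
}

#' Insert / retrieve a stage result
#'
#' `storeGet` returns the stored value or NULL (counting a hit at the
#' level that served it, or a miss); `storePut` inserts at level 1 and
#' triggers eviction as needed; `storeLevel` reports which level holds a
#' key (1, 2, or NA).
#'
#' @param store a [ResultStore-class].
#' @param key content key string.
#' @param value value to store.
#' @export
storePut <- function(store, key, value) {
  st <- store@state
  if (!is.null(storePeek(store, key))) return(invisible())  # already present
  t <- storeTick(st)
  if (st$capacity <= 0) {
    demoteToL2(st, key, value, t, t)
    return(invisible())
  }
  assign(key, value, envir = st$l1)
  st$l1meta <- rbind(st$l1meta,
                     data.frame(key = key, inserted = t, accessed = t,
                                stringsAsFactors = FALSE))
  while (nrow(st$l1meta) > st$capacity) {
    v <- victimRow(st$l1meta, st$policy)
    vk <- st$l1meta$key[v]
    demoteToL2(st, vk, get(vk, envir = st$l1),
               st$l1meta$inserted[v], st$l1meta$accessed[v])
    rm(list = vk, envir = st$l1)
    st$l1meta <- st$l1meta[-v, , drop = FALSE]
  }
  invisible()
}

# Lookup without touching counters or recency (internal).
storePeek <- function(store, key) {
  st <- store@state
  if (exists(key, envir = st$l1, inherits = FALSE)) return(get(key, envir = st$l1))
  i <- match(key, st$l2index$key)
  if (!is.na(i)) return(readRDS(st$l2index$file[i]))
  NULL
}

#' @rdname storePut
#' @export
storeGet <- function(store, key) {
  st <- store@state
  if (exists(key, envir = st$l1, inherits = FALSE)) {
    st$hits1 <- st$hits1 + 1
    st$l1meta$accessed[st$l1meta$key == key] <- storeTick(st)
    return(get(key, envir = st$l1))
  }
  i <- match(key, st$l2index$key)
  if (!is.na(i)) {
    st$hits2 <- st$hits2 + 1
    value <- readRDS(st$l2index$file[i])
    unlink(st$l2index$file[i])
    st$l2index <- st$l2index[-i, , drop = FALSE]
    storePut(store, key, value)   # promote
    return(value)
  }
  st$misses <- st$misses + 1
  NULL
}

#' @rdname storePut
#' @export
storeLevel <- function(store, key) {
  st <- store@state
  if (exists(key, envir = st$l1, inherits = FALSE)) return(1L)
  if (key %in% st$l2index$key) return(2L)
  NA_integer_
}

#' @rdname storePut
#' @export
storeStats <- function(store) {
  st <- store@state
  list(hits1 = st$hits1, hits2 = st$hits2, misses = st$misses,
       l1entries = nrow(st$l1meta), l2entries = nrow(st$l2index))
}

setMethod("show", "ResultStore", function(object) {
  s <- storeStats(object)
  st <- object@state
  cat(sprintf("ResultStore (%s, L1 cap %s, L2 cap %s): %d + %d entries, hits %d/%d, misses %d\n",
              st$policy, format(st$capacity), format(st$l2capacity),
              s$l1entries, s$l2entries, s$hits1, s$hits2, s$misses))
})

#' Identity string of a workflow input
#'
#' Files are identified by their MD5 digest; in-memory objects by the MD5
#' of their serialization. Two inputs with the same identity are treated
#' as the same data by the compact-composition merger.
#'
#' @param x a file path (character) or any R object.
#' @return a digest string.
#' @export
inputIdentity <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(unname(tools::md5sum(x)))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(x, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

bindStageParams <- function(stage, paramSet) {
  missing <- setdiff(stage$params, names(paramSet))
  if (length(missing))
    stop(sprintf("parameter set is missing %s for stage '%s'",
                 paste(missing, collapse = ", "), stage$name), call. = FALSE)
  paramSet[stage$params]
}

#' Instantiate a workflow graph for a batch of parameter sets
#'
#' `replicaGraph` builds an independent stage chain per parameter set
#' (node count = sets x stages). `compactCompose` merges instances into a
#' prefix trie keyed by content: a node is shared by all parameter sets
#' that agree on the stage's bound parameter values and share the parent
#' node, so common computation prefixes appear once. Executing either
#' graph yields identical per-set outputs; the compact graph just runs
#' shared stages once.
#'
#' @param pipeline a [SegPipeline-class].
#' @param paramSets list of named parameter lists (native units, each
#'   covering every parameter any stage declares).
#' @param input the workflow input (e.g. `list(tile = tile)`).
#' @param inputId optional precomputed [inputIdentity()] of `input`.
#' @return a [WorkflowGraph-class].
#' @export
replicaGraph <- function(pipeline, paramSets, input, inputId = NULL) {
  buildGraph(pipeline, paramSets, input, inputId, mode = "replica")
}

#' @rdname replicaGraph
#' @export
compactCompose <- function(pipeline, paramSets, input, inputId = NULL) {
  buildGraph(pipeline, paramSets, input, inputId, mode = "compact")
}

buildGraph <- function(pipeline, paramSets, input, inputId, mode) {
  stopifnot(length(paramSets) >= 1)
  if (is.null(inputId)) inputId <- inputIdentity(input)
  nodes <- list()
  seen <- new.env(parent = emptyenv())   # content key -> node id (compact)
  leaves <- character(length(paramSets))
  nid <- 0L
  for (si in seq_along(paramSets)) {
    ps <- paramSets[[si]]
    parentId <- NA_character_
    parentKey <- paste0("input:", inputId,
                        if (mode == "replica") paste0("#", si) else "")
    for (stage in pipeline@stages) {
      bound <- bindStageParams(stage, ps)
      key <- paste(parentKey, stage$name, canonicalPoint(bound), sep = " | ")
      if (mode == "compact" && exists(key, envir = seen, inherits = FALSE)) {
        id <- get(key, envir = seen)
      } else {
        nid <- nid + 1L
        id <- sprintf("n%05d", nid)
        nodes[[id]] <- list(id = id, stage = stage$name, params = bound,
                            parent = parentId, key = key)
        if (mode == "compact") assign(key, id, envir = seen)
      }
      parentId <- id
      parentKey <- key
    }
    leaves[si] <- parentId
  }
  new("WorkflowGraph", nodes = nodes, mode = mode, leaves = leaves,
      inputId = inputId)
}

#' @describeIn replicaGraph number of stage-instance nodes in the graph.
#' @param x a `WorkflowGraph`.
#' @export
setMethod("nRuns", "WorkflowGraph", function(x) length(x@nodes))

setMethod("show", "WorkflowGraph", function(object) {
  cat(sprintf("WorkflowGraph (%s): %d nodes, %d parameter sets, input %s\n",
              object@mode, length(object@nodes), length(object@leaves),
              substr(object@inputId, 1, 8)))
})

#' Execute a workflow graph
#'
#' Runs the graph's stage instances in dependency order; each node runs
#' at most once per execution. When a result store is supplied, a node
#' whose content key is already stored is served from the store instead
#' of running (so re-executing a graph against a warm store runs
#' nothing). Replica-mode content keys carry the instance index, so the
#' replica scheme never shares computation between instances — exactly
#' the baseline the compact scheme is measured against.
#'
#' @param graph a [WorkflowGraph-class].
#' @param pipeline the [SegPipeline-class] the graph was built from.
#' @param input the workflow input the graph was built for.
#' @param store optional [ResultStore-class].
#' @return list with `outputs` (per parameter set, the final stage
#'   output) and `stats` (nodes, stage runs, store hits per level, and
#'   the stage-execution savings ratio relative to the replica baseline).
#' @export
executeGraph <- function(graph, pipeline, input, store = NULL) {
  stageFns <- setNames(lapply(pipeline@stages, function(s) s$fn),
                       vapply(pipeline@stages, function(s) s$name, character(1)))
  results <- new.env(parent = emptyenv())
  runs <- 0L
  h1 <- h2 <- 0L
  if (!is.null(store)) { s0 <- storeStats(store) }
  for (node in graph@nodes) {
    value <- if (!is.null(store)) storeGet(store, node$key) else NULL
    if (is.null(value)) {
      parentOut <- if (is.na(node$parent)) input else get(node$parent, envir = results)
      value <- tryCatch(stageFns[[node$stage]](parentOut, node$params),
                        error = function(e)
                          stop(sprintf("stage '%s' (node %s) failed: %s",
                                       node$stage, node$id, conditionMessage(e)),
                               call. = FALSE))
      runs <- runs + 1L
      if (!is.null(store)) storePut(store, node$key, value)
    }
    assign(node$id, value, envir = results)
  }
  if (!is.null(store)) {
    s1 <- storeStats(store)
    h1 <- s1$hits1 - s0$hits1
    h2 <- s1$hits2 - s0$hits2
  }
  replicaRuns <- length(graph@leaves) * length(pipeline@stages)
  outputs <- lapply(graph@leaves, function(id) get(id, envir = results))
  list(outputs = outputs,
       stats = list(nodes = length(graph@nodes), runs = runs,
                    hits1 = h1, hits2 = h2,
                    replicaRuns = replicaRuns,
                    savings = 1 - runs / replicaRuns))
}

#' Evaluate a batch of parameter sets through the dataflow executor
#'
#' Convenience wrapper used by the SA and tuning drivers: composes the
#' batch (compact by default, so simultaneous-parameter-evaluation
#' merging applies), executes it and returns the final masks plus the
#' execution statistics.
#'
#' @param pipeline a [SegPipeline-class].
#' @param paramSets list of native-unit parameter sets.
#' @param input workflow input (e.g. `list(tile = tile)`).
#' @param mode "compact" or "replica".
#' @param store optional [ResultStore-class].
#' @return list with `outputs` and `stats` as in [executeGraph()].
#' @export
runBatch <- function(pipeline, paramSets, input, mode = c("compact", "replica"),
                     store = NULL) {
  mode <- match.arg(mode)
  graph <- buildGraph(pipeline, paramSets, input, inputId = NULL, mode = mode)
  executeGraph(graph, pipeline, input, store = store)
}
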