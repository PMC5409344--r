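# Shared fixtures, built in code.

# k continuous parameters on [0, 1] (identity unit mapping).
unitSpace <- function(k, p = 20) {
  parameterSpace(lapply(seq_len(k), function(i)
    parameterSpec(paste0("u", i), "continuous", low = 0, high = 1,
                  default = 0.5)), p = p)
}

# A small mixed space exercising all three parameter kinds.
mixedSpace <- function(p = 20) {
  parameterSpace(
    parameterSpec("B", "discrete", low = 210, high = 240, step = 10, default = 220),
    parameterSpec("G1", "discrete", low = 5, high = 80, step = 5, default = 40),
    parameterSpec("w", "continuous", low = 0, high = 10, default = 5),
    parameterSpec("conn", "categorical", values = c("4-conn", "8-conn"),
                  default = "8-conn"),
    p = p)
}

# Small synthetic cohort shared by pipeline-level tests (generation is
# cheap; memoise within a test run to keep the suite quick).
.cohortCache <- new.env(parent = emptyenv())
testCohort <- function(n = 6, masterSeed = 7) {
  key <- paste(n, masterSeed)
  if (!exists(key, envir = .cohortCache))
    assign(key, generateCohort(n, sceneConfig(), masterSeed = masterSeed),
           envir = .cohortCache)
  get(key, envir = .cohortCache)
}

# Watershed space whose G1/G2 defaults are shifted three grid levels below
# the generator-matched values (the degraded starting point for tuning).
degradedSpace <- function() {
  sp <- watershedSpace()
  sp@specs <- lapply(sp@specs, function(s) {
    if (s$name == "G1") s$default <- s$default - 3 * s$step
    if (s$name == "G2") s$default <- s$default - 3 * s$step
    s
  })
  validObject(sp)
  sp
}

# Toy 5-stage linear pipeline over scalars: each stage adds its parameter
# to the running value. Pure and cheap; used by the workflow tests.
toyPipeline <- function(nStages = 5) {
  new("SegPipeline", stages = lapply(seq_len(nStages), function(i) {
    pname <- paste0("p", i)
    list(name = paste0("stage", i), params = pname,
         fn = local({
           nm <- pname
           function(input, p) list(value = input$value + p[[nm]])
         }))
  }))
}

toyParams <- function(...) {
  vals <- list(...)
  setNames(vals, paste0("p", seq_along(vals)))
}

randomMask <- function(h, w, density = 0.4) {
  matrix(as.integer(runif(h * w) < density), h, w)
}
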