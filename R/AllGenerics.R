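# Generics for the core classes. Implementations live next to their class.

#' @export
setGeneric("paramNames", function(x, ...) standardGeneric("paramNames"))

#' @export
setGeneric("paramCount", function(x, ...) standardGeneric("paramCount"))

#' @export
setGeneric("designMatrix", function(x, ...) standardGeneric("designMatrix"))

#' @export
setGeneric("nRuns", function(x, ...) standardGeneric("nRuns"))

#' @export
setGeneric("toUnit", function(space, point) standardGeneric("toUnit"))

#' @export
setGeneric("fromUnit", function(space, u) standardGeneric("fromUnit"))

#' @export
setGeneric("levelGrid", function(space, p) standardGeneric("levelGrid"))
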