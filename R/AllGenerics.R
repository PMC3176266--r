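#' Accessor generics
#'
#' Small accessor family for the S4 containers: `bpLength()` returns the
#' number of positions of a structure; `basePairs()` its 0-based pair
#' matrix; `dotBracket()` a dot-bracket string; `freeEnergy()` the predicted
#' minimum free energy (kcal/mol); `foldedStructure()` the [PairTable-class]
#' of a fold; `neutralityScore()` and `mutantsEvaluated()` the components of
#' a [NeutralityValue-class]; `designedSequence()`, `shapeDistance()`,
#' `bpDeviation()`, `objectiveScore()` and `rankScore()` the components of a
#' [DesignResult-class]; `designResults()` the result list of a
#' [DesignSet-class].
#'
#' @param x object.
#' @return see details per accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bpLength", function(x) standardGeneric("bpLength"))

#' @rdname accessors
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

#' @rdname accessors
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' @rdname accessors
#' @export
setGeneric("freeEnergy", function(x) standardGeneric("freeEnergy"))

#' @rdname accessors
#' @export
setGeneric("foldedStructure", function(x) standardGeneric("foldedStructure"))

#' @rdname accessors
#' @export
setGeneric("neutralityScore", function(x) standardGeneric("neutralityScore"))

#' @rdname accessors
#' @export
setGeneric("mutantsEvaluated", function(x) standardGeneric("mutantsEvaluated"))

#' @rdname accessors
#' @export
setGeneric("designedSequence", function(x) standardGeneric("designedSequence"))

#' @rdname accessors
#' @export
setGeneric("shapeDistance", function(x) standardGeneric("shapeDistance"))

#' @rdname accessors
#' @export
setGeneric("bpDeviation", function(x) standardGeneric("bpDeviation"))

#' @rdname accessors
#' @export
setGeneric("objectiveScore", function(x) standardGeneric("objectiveScore"))

#' @rdname accessors
#' @export
setGeneric("rankScore", function(x) standardGeneric("rankScore"))

#' @rdname accessors
#' @export
setGeneric("designResults", function(x) standardGeneric("designResults"))
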