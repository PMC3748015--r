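#' @rdname Population-class
#' @param object,x an object.
#' @param ... passed on to methods.
#' @export
setGeneric("genotypes", function(x, ...) standardGeneric("genotypes"))

#' @rdname Population-class
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' @rdname Population-class
#' @export
setGeneric("genomeMapOf", function(x) standardGeneric("genomeMapOf"))

#' @rdname Population-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname GenomeMap-class
#' @param x an object.
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname FitResult-class
#' @param x an object.
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' @rdname FitResult-class
#' @export
setGeneric("sigmaE2", function(x) standardGeneric("sigmaE2"))

#' @rdname FitResult-class
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname FitResult-class
#' @export
setGeneric("iterations", function(x) standardGeneric("iterations"))
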