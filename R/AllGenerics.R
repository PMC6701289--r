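#' @name pdxsite-generics
#' @title Accessor generics
#' @description Small accessor generics used across the pipeline classes.
#' @param x an object.
#' @param ... passed on to methods.
NULL

#' @rdname pdxsite-generics
#' @export
setGeneric("classLabels", function(x, ...) standardGeneric("classLabels"))

#' @rdname pdxsite-generics
#' @export
setGeneric("classLevels", function(x, ...) standardGeneric("classLevels"))

#' @rdname pdxsite-generics
#' @export
setGeneric("exprsMatrix", function(x, ...) standardGeneric("exprsMatrix"))

#' @rdname pdxsite-generics
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))

#' @rdname pdxsite-generics
#' @export
setGeneric("rankedGenes", function(x, ...) standardGeneric("rankedGenes"))

#' @rdname pdxsite-generics
#' @export
setGeneric("riScores", function(x, ...) standardGeneric("riScores"))

#' @rdname pdxsite-generics
#' @export
setGeneric("confusionMatrix", function(x, ...) standardGeneric("confusionMatrix"))

#' @rdname pdxsite-generics
#' @export
setGeneric("mcc", function(x, ...) standardGeneric("mcc"))

#' @rdname pdxsite-generics
#' @export
setGeneric("overallAccuracy", function(x, ...) standardGeneric("overallAccuracy"))

#' @rdname pdxsite-generics
#' @export
setGeneric("perClassAccuracy", function(x, ...) standardGeneric("perClassAccuracy"))

#' @rdname pdxsite-generics
#' @export
setGeneric("defaultClass", function(x, ...) standardGeneric("defaultClass"))

#' @rdname pdxsite-generics
#' @export
setGeneric("ruleGenes", function(x, ...) standardGeneric("ruleGenes"))

#' @rdname pdxsite-generics
#' @export
setGeneric("markerMap", function(x, ...) standardGeneric("markerMap"))
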