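#' @title Accessor generics
#' @description Accessors for the core classes; see the class pages for
#'   details.
#' @param x,object an object of the documented classes.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trackPoints", function(x) standardGeneric("trackPoints"))

#' @rdname accessors
#' @export
setGeneric("trackIds", function(x) standardGeneric("trackIds"))

#' @rdname accessors
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("trackDurations", function(x) standardGeneric("trackDurations"))

#' @rdname accessors
#' @export
setGeneric("trackInfo", function(x) standardGeneric("trackInfo"))

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("radiusUm", function(x) standardGeneric("radiusUm"))

#' @rdname accessors
#' @export
setGeneric("msdTable", function(x) standardGeneric("msdTable"))

#' @rdname accessors
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @rdname accessors
#' @export
setGeneric("sdAccuracy", function(x) standardGeneric("sdAccuracy"))

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname accessors
#' @export
setGeneric("summaryTable", function(x) standardGeneric("summaryTable"))

#' @rdname accessors
#' @export
setGeneric("trackData", function(x) standardGeneric("trackData"))
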