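#' @rdname SVDataset-class
#' @param x an object
#' @export
setGeneric("adjacencies", function(x) standardGeneric("adjacencies"))

#' @rdname SVDataset-class
#' @export
setGeneric("svGenome", function(x) standardGeneric("svGenome"))

#' @rdname SVDataset-class
#' @export
setGeneric("cnSegments", function(x) standardGeneric("cnSegments"))

#' @rdname SVDataset-class
#' @export
setGeneric("cancerTypes", function(x) standardGeneric("cancerTypes"))

#' @rdname SVDataset-class
#' @export
setGeneric("breakends", function(x) standardGeneric("breakends"))

#' @rdname SVDataset-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SVClusters-class
#' @param x an object
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname SVClusters-class
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname SampleGraphSet-class
#' @param x an object
#' @export
setGeneric("graphVertices", function(x) standardGeneric("graphVertices"))

#' @rdname SampleGraphSet-class
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname SampleGraphSet-class
#' @export
setGeneric("edgeProvenance", function(x) standardGeneric("edgeProvenance"))

#' @rdname CycleSet-class
#' @param x an object
#' @export
setGeneric("cycles", function(x) standardGeneric("cycles"))
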