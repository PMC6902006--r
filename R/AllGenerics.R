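# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @rdname repository-accessors
#' @export
setGeneric("donors", function(x) standardGeneric("donors"))
#' @rdname repository-accessors
#' @export
setGeneric("biosamples", function(x) standardGeneric("biosamples"))
#' @rdname repository-accessors
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))
#' @rdname repository-accessors
#' @export
setGeneric("items", function(x) standardGeneric("items"))
#' @rdname repository-accessors
#' @export
setGeneric("caseStudies", function(x) standardGeneric("caseStudies"))
#' @rdname repository-accessors
#' @export
setGeneric("projects", function(x) standardGeneric("projects"))
#' @rdname repository-accessors
#' @export
setGeneric("experimentTypes", function(x) standardGeneric("experimentTypes"))
#' @rdname repository-accessors
#' @export
setGeneric("datasets", function(x) standardGeneric("datasets"))
#' @rdname repository-accessors
#' @export
setGeneric("replicateToItem", function(x) standardGeneric("replicateToItem"))
#' @rdname repository-accessors
#' @export
setGeneric("caseToItem", function(x) standardGeneric("caseToItem"))
#' @rdname repository-accessors
#' @export
setGeneric("rawPairs", function(x) standardGeneric("rawPairs"))
#' @rdname repository-accessors
#' @export
setGeneric("denormalizedView", function(x) standardGeneric("denormalizedView"))
#' @rdname repository-accessors
#' @export
setGeneric("itemCount", function(x) standardGeneric("itemCount"))

#' @rdname kb-accessors
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))
#' @rdname kb-accessors
#' @export
setGeneric("synonyms", function(x) standardGeneric("synonyms"))
#' @rdname kb-accessors
#' @export
setGeneric("termReferences", function(x) standardGeneric("termReferences"))
#' @rdname kb-accessors
#' @export
setGeneric("relationships", function(x) standardGeneric("relationships"))
#' @rdname kb-accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname kb-accessors
#' @export
setGeneric("termClosure", function(x) standardGeneric("termClosure"))
#' @rdname kb-accessors
#' @export
setGeneric("maxDepth", function(x) standardGeneric("maxDepth"))

#' @rdname ResultSet
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))

#' @rdname chainSignature
#' @export
setGeneric("chainSignature", function(x) standardGeneric("chainSignature"))
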