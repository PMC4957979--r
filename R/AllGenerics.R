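#' Accessor generics
#'
#' Accessors for the S4 containers in this package; see the class pages for
#' details of the underlying slots.
#'
#' @param object a package object.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("proteinLength", function(object) standardGeneric("proteinLength"))

#' @rdname accessors
#' @export
setGeneric("mutationRecords",
           function(object) standardGeneric("mutationRecords"))

#' @rdname accessors
#' @export
setGeneric("uniqueMutations",
           function(object, ...) standardGeneric("uniqueMutations"))

#' @rdname accessors
#' @export
setGeneric("classCounts", function(object, ...) standardGeneric("classCounts"))

#' @rdname accessors
#' @export
setGeneric("catalogLog", function(object) standardGeneric("catalogLog"))
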