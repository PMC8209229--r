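#' @rdname residueTable
#' @export
setGeneric("residueTable", function(x, ...) standardGeneric("residueTable"))

#' @rdname detectContacts
#' @export
setGeneric("detectContacts", function(x, ...) standardGeneric("detectContacts"))

#' @rdname computeSurfaceArea
#' @export
setGeneric("computeSurfaceArea", function(x, ...) standardGeneric("computeSurfaceArea"))

#' @rdname computeCentralities
#' @export
setGeneric("computeCentralities", function(x, ...) standardGeneric("computeCentralities"))

#' @rdname exportNetwork
#' @export
setGeneric("exportNetwork", function(x, ...) standardGeneric("exportNetwork"))
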