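#' @rdname dataset2d-access
#' @export
setGeneric("getRow", function(x, i, ...) standardGeneric("getRow"))

#' @rdname dataset2d-access
#' @export
setGeneric("getCol", function(x, j, ...) standardGeneric("getCol"))

#' @rdname dataset2d-access
#' @export
setGeneric("putRow", function(x, i, value, ...) standardGeneric("putRow"))

#' @rdname dataset2d-access
#' @export
setGeneric("putCol", function(x, j, value, ...) standardGeneric("putCol"))

#' @rdname gridBackend
#' @export
setGeneric("backendDims", function(x) standardGeneric("backendDims"))

#' @rdname gridBackend
#' @export
setGeneric("readRowValues", function(x, i) standardGeneric("readRowValues"))

#' @rdname gridBackend
#' @export
setGeneric("writeRowValues", function(x, i, value) standardGeneric("writeRowValues"))

#' @rdname gridBackend
#' @export
setGeneric("readColBlock", function(x, j, k) standardGeneric("readColBlock"))

#' @rdname gridBackend
#' @export
setGeneric("writeColBlock", function(x, j, value) standardGeneric("writeColBlock"))
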