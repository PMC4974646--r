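#' @rdname gridValues
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname pixelSize
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname nodataMask
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))

#' @rdname waterMask
#' @export
setGeneric("waterMask", function(x) standardGeneric("waterMask"))

#' @rdname landMask
#' @export
setGeneric("landMask", function(x) standardGeneric("landMask"))

#' @rdname exposureLayer
#' @export
setGeneric("exposureLayer", function(x, name) standardGeneric("exposureLayer"))

#' @rdname exposureFlag
#' @export
setGeneric("exposureFlag", function(x, name) standardGeneric("exposureFlag"))

#' @rdname exposureTable
#' @export
setGeneric("exposureTable", function(x) standardGeneric("exposureTable"))
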