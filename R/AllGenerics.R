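#' @rdname TwoChannelScene-class
#' @param object,x a \code{TwoChannelScene}
#' @export
setGeneric("greenChannel", function(x) standardGeneric("greenChannel"))

#' @rdname TwoChannelScene-class
#' @export
setGeneric("redChannel", function(x) standardGeneric("redChannel"))

#' @rdname TwoChannelScene-class
#' @export
setGeneric("sceneTruthOf", function(x) standardGeneric("sceneTruthOf"))

#' @rdname TwoChannelScene-class
#' @export
setGeneric("modalityOf", function(x) standardGeneric("modalityOf"))

#' @rdname TwoChannelScene-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname TwoChannelScene-class
#' @export
setGeneric("zStep", function(x) standardGeneric("zStep"))

#' @rdname TwoChannelScene-class
#' @export
setGeneric("sceneDepth", function(x) standardGeneric("sceneDepth"))
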