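#' @rdname nodeLabels
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname splitSigns
#' @export
setGeneric("splitSigns", function(W) standardGeneric("splitSigns"))

#' @rdname totalClustering
#' @export
setGeneric("totalClustering", function(W, ...) standardGeneric("totalClustering"))

#' @rdname globalEfficiency
#' @export
setGeneric("globalEfficiency", function(W) standardGeneric("globalEfficiency"))

#' @rdname nodeStrength
#' @export
setGeneric("nodeStrength", function(W) standardGeneric("nodeStrength"))
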