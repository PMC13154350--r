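#' @import methods
#' @importFrom stats cor sd pt rnorm runif dist cmdscale
#' @importFrom utils read.csv read.delim write.table head
NULL

#' @export
setGeneric("mz", function(x, ...) standardGeneric("mz"))

#' @export
setGeneric("rt", function(x, ...) standardGeneric("rt"))

#' @export
setGeneric("areas", function(x, ...) standardGeneric("areas"))

#' @export
setGeneric("ionMode", function(x, ...) standardGeneric("ionMode"))

#' @export
setGeneric("annotations", function(x, ...) standardGeneric("annotations"))

#' @export
setGeneric("featureIds", function(x, ...) standardGeneric("featureIds"))

#' @export
setGeneric("maxAreas", function(x, ...) standardGeneric("maxAreas"))

#' @export
setGeneric("filterMinArea", function(x, minArea, ...) standardGeneric("filterMinArea"))

#' @export
setGeneric("cliques", function(x, ...) standardGeneric("cliques"))

#' @export
setGeneric("basePeaks", function(x, ...) standardGeneric("basePeaks"))

#' @export
setGeneric("pseudoIons", function(x, ...) standardGeneric("pseudoIons"))

#' @export
setGeneric("corCoef", function(x, ...) standardGeneric("corCoef"))

#' @export
setGeneric("corPValues", function(x, ...) standardGeneric("corPValues"))

#' @export
setGeneric("isSignificant", function(x, ...) standardGeneric("isSignificant"))

#' @export
setGeneric("applySignificance", function(x, alpha = 0.01, bonferroni = FALSE)
  standardGeneric("applySignificance"))

#' @export
setGeneric("nodes", function(x, ...) standardGeneric("nodes"))

#' @export
setGeneric("edges", function(x, ...) standardGeneric("edges"))

#' @export
setGeneric("layoutCoords", function(x, ...) standardGeneric("layoutCoords"))

#' @export
setGeneric("networkMetrics", function(x, ...) standardGeneric("networkMetrics"))
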