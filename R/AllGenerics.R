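#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @export
setGeneric("meshNormals", function(x) standardGeneric("meshNormals"))

#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @export
setGeneric("meshEdges", function(x) standardGeneric("meshEdges"))

#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @export
setGeneric("totalAreaVolume", function(x, ...) standardGeneric("totalAreaVolume"))

#' @export
setGeneric("faceGeometry", function(x, ...) standardGeneric("faceGeometry"))

#' @export
setGeneric("reducedVolume", function(x, ...) standardGeneric("reducedVolume"))

#' @export
setGeneric("leafletFractions", function(x, leaflet = "outer")
  standardGeneric("leafletFractions"))

#' @export
setGeneric("peptideCounts", function(x) standardGeneric("peptideCounts"))

#' @export
setGeneric("totalEnergy", function(x, ...) standardGeneric("totalEnergy"))
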