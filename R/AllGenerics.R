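#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("rgbColours", function(x) standardGeneric("rgbColours"))

#' @rdname accessors
#' @export
setGeneric("hsvColours", function(x) standardGeneric("hsvColours"))

#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname accessors
#' @export
setGeneric("viewAreas", function(x) standardGeneric("viewAreas"))

#' @rdname accessors
#' @export
setGeneric("viewAngles", function(x) standardGeneric("viewAngles"))

#' @rdname accessors
#' @export
setGeneric("sliceCentroids", function(x) standardGeneric("sliceCentroids"))

#' @rdname accessors
#' @export
setGeneric("sliceAreas", function(x) standardGeneric("sliceAreas"))

#' @rdname accessors
#' @export
setGeneric("patchCurvatures", function(x) standardGeneric("patchCurvatures"))
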