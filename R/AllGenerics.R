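#' @rdname iouBoxes
#' @export
setGeneric("iouBoxes", function(a, b) standardGeneric("iouBoxes"))

#' @rdname maskToBox
#' @export
setGeneric("maskToBox", function(m) standardGeneric("maskToBox"))

#' @rdname medialEdgeX
#' @export
setGeneric("medialEdgeX", function(m, side) standardGeneric("medialEdgeX"))

#' @rdname verticalExtent
#' @export
setGeneric("verticalExtent", function(m) standardGeneric("verticalExtent"))

#' @rdname boxArea
#' @export
setGeneric("boxArea", function(a) standardGeneric("boxArea"))

#' Accessors for SinusDx objects
#'
#' Small accessor generics: slot access is internal, these are the
#' supported interface.
#'
#' @param x an object of the documented class.
#' @return The corresponding component.
#' @name accessors
#' @aliases frameId laterality detections gtLabel frameWidth frameHeight
#'   mmBox mmMethod diagnosisCall triggers iouMM iouMT
NULL

#' @rdname accessors
#' @export
setGeneric("frameId", function(x) standardGeneric("frameId"))
#' @rdname accessors
#' @export
setGeneric("laterality", function(x) standardGeneric("laterality"))
#' @rdname accessors
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))
#' @rdname accessors
#' @export
setGeneric("gtLabel", function(x) standardGeneric("gtLabel"))
#' @rdname accessors
#' @export
setGeneric("frameWidth", function(x) standardGeneric("frameWidth"))
#' @rdname accessors
#' @export
setGeneric("frameHeight", function(x) standardGeneric("frameHeight"))
#' @rdname accessors
#' @export
setGeneric("mmBox", function(x) standardGeneric("mmBox"))
#' @rdname accessors
#' @export
setGeneric("mmMethod", function(x) standardGeneric("mmMethod"))
#' @rdname accessors
#' @export
setGeneric("diagnosisCall", function(x) standardGeneric("diagnosisCall"))
#' @rdname accessors
#' @export
setGeneric("triggers", function(x) standardGeneric("triggers"))
#' @rdname accessors
#' @export
setGeneric("iouMM", function(x) standardGeneric("iouMM"))
#' @rdname accessors
#' @export
setGeneric("iouMT", function(x) standardGeneric("iouMT"))
#' @rdname accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))
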