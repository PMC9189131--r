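#' Accessor generics
#'
#' Small accessor family for the package's S4 containers; prefer these over
#' direct slot access.
#'
#' @param object an object of one of the package's S4 classes.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fps", function(object) standardGeneric("fps"))

#' @rdname accessors
#' @export
setGeneric("bouts", function(object) standardGeneric("bouts"))

#' @rdname accessors
#' @export
setGeneric("activeState", function(object) standardGeneric("activeState"))

#' @rdname accessors
#' @export
setGeneric("changedPixels", function(object) standardGeneric("changedPixels"))

#' @rdname accessors
#' @export
setGeneric("drOverR0", function(object) standardGeneric("drOverR0"))

#' @rdname accessors
#' @export
setGeneric("ratioR", function(object) standardGeneric("ratioR"))

#' @rdname accessors
#' @export
setGeneric("ratioR0", function(object) standardGeneric("ratioR0"))

#' @rdname accessors
#' @export
setGeneric("pixelThreshold", function(object) standardGeneric("pixelThreshold"))

#' @rdname accessors
#' @export
setGeneric("totalDuration", function(object) standardGeneric("totalDuration"))

#' @rdname accessors
#' @export
setGeneric("trueState", function(object) standardGeneric("trueState"))

#' @rdname accessors
#' @export
setGeneric("trials", function(object) standardGeneric("trials"))

#' @rdname accessors
#' @export
setGeneric("locomotionTraces", function(object)
  standardGeneric("locomotionTraces"))

#' Reconstruct the per-frame binary state of a bout partition
#'
#' @param object a [BoutSeries-class] or [GroundTruthSchedule-class].
#' @return logical vector, one element per frame, `TRUE` where the frame
#'   belongs to a motion bout.
#' @export
setGeneric("stateVector", function(object) standardGeneric("stateVector"))
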