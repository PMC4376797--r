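#' @rdname Trajectory-class
#' @param x,object an object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Trajectory-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Trajectory-class
#' @export
setGeneric("atomIds", function(x) standardGeneric("atomIds"))

#' @rdname Trajectory-class
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname Trajectory-class
#' @export
setGeneric("frameLabels", function(x) standardGeneric("frameLabels"))

#' @rdname Trajectory-class
#' @param i frame index.
#' @export
setGeneric("frameCoords", function(x, i = 1L) standardGeneric("frameCoords"))

#' @rdname RigidTransform-class
#' @param x an object carrying a transform.
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))

#' @rdname RigidTransform-class
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' @rdname MobilityReport-class
#' @export
setGeneric("frameStats", function(x) standardGeneric("frameStats"))

#' @rdname MobilityReport-class
#' @export
setGeneric("rmsf", function(x) standardGeneric("rmsf"))

#' @rdname MobilityReport-class
#' @export
setGeneric("lowFraction", function(x) standardGeneric("lowFraction"))

#' @rdname MobilityReport-class
#' @export
setGeneric("lowMembership", function(x) standardGeneric("lowMembership"))

#' @rdname MobilityReport-class
#' @export
setGeneric("alignedTrajectory", function(x) standardGeneric("alignedTrajectory"))

#' @rdname FrameAlignment-class
#' @export
setGeneric("lowSet", function(x) standardGeneric("lowSet"))

#' @rdname FrameAlignment-class
#' @export
setGeneric("msdAll", function(x) standardGeneric("msdAll"))
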