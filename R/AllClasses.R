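#' @import methods
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head write.table
#' @importFrom Rcpp sourceCpp
#' @useDynLib lovofit, .registration = TRUE
NULL

#' Proper rigid-body transform
#'
#' A proper rotation (3x3 orthogonal matrix with determinant +1) followed by a
#' translation, mapping coordinates as \eqn{x \to R x + t}.  All units are
#' Angstrom.
#'
#' @slot rotation 3x3 numeric matrix, orthogonal with det = +1 (tolerance 1e-8).
#' @slot translation numeric length-3 vector, Angstrom.
#'
#' @seealso [applyTransform()], [kearsleySuperpose()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    R <- object@rotation
    msg <- character()
    if (!all(dim(R) == c(3L, 3L)) || !is.numeric(R) || anyNA(R))
      msg <- c(msg, "rotation must be a finite 3x3 numeric matrix")
    else {
      if (max(abs(crossprod(R) - diag(3))) > 1e-8)
        msg <- c(msg, "rotation must be orthogonal (tolerance 1e-8)")
      if (abs(det(R) - 1) > 1e-8)
        msg <- c(msg, "rotation must be proper (det = +1)")
    }
    if (length(object@translation) != 3L || anyNA(object@translation))
      msg <- c(msg, "translation must be a finite length-3 numeric vector")
    if (length(msg)) msg else TRUE
  }
)

#' Result of a rigid-body superposition
#'
#' @slot transform a [RigidTransform-class] mapping the mobile frame onto the
#'   reference.
#' @slot rmsdFit RMSD (Angstrom) over the fitted subset after applying the
#'   transform.
#' @slot msdAll per-atom squared deviations (Angstrom^2) over *all* atoms of
#'   the frame after applying the transform.
#' @slot subset integer indices of the atoms that were fitted.
#'
#' @seealso [kearsleySuperpose()]
#' @export
setClass("Superposition",
  representation(transform = "RigidTransform", rmsdFit = "numeric",
                 msdAll = "numeric", subset = "integer"),
  validity = function(object) {
    if (length(object@rmsdFit) != 1L || object@rmsdFit < 0)
      return("rmsdFit must be a single non-negative number")
    if (any(object@msdAll < 0)) return("msdAll must be non-negative")
    want <- sqrt(mean(object@msdAll[object@subset]))
    if (abs(object@rmsdFit - want) > 1e-10 * max(1, want))
      return("rmsdFit must equal sqrt(mean msdAll over the fitted subset)")
    TRUE
  }
)

#' Options controlling the LOVO alignment
#'
#' @slot nStarts number of multistart initial subsets (default 100): the
#'   deterministic whole-structure start plus `nStarts - 1` random subsets.
#' @slot maxIterations iteration cap per start (default 200).
#' @slot convergenceTol tolerance on the change of MSD_L between iterations,
#'   Angstrom^2 (default 1e-9); convergence additionally requires the selected
#'   subset to be unchanged.
#' @slot seed integer seed for the random initial subsets (and, in trajectory
#'   runs, the base from which per-frame seeds are derived).
#'
#' @seealso [lovoOptions()]
#' @export
setClass("LovoOptions",
  representation(nStarts = "integer", maxIterations = "integer",
                 convergenceTol = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nStarts < 1L) msg <- c(msg, "nStarts must be >= 1")
    if (object@maxIterations < 1L) msg <- c(msg, "maxIterations must be >= 1")
    if (object@convergenceTol <= 0) msg <- c(msg, "convergenceTol must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Multi-frame C-alpha trajectory
#'
#' An ordered set of frames sharing one atom roster.  Coordinates are stored
#' as an `nAtoms x 3 x nFrames` array (Angstrom); the roster is a data frame
#' with one row per atom carrying the PDB identity fields used for round-trip
#' writing.
#'
#' @slot coords numeric array, `nAtoms x 3 x nFrames`.
#' @slot atoms data.frame with columns `id`, `name`, `resname`, `chain`,
#'   `resno`, `icode`; `id` values are unique and define the frame-to-frame
#'   correspondence.
#' @slot frameLabels numeric frame labels (model numbers or times).
#'
#' @seealso [readPDBTrajectory()], [syntheticTrajectory()], [Trajectory()]
#' @export
setClass("Trajectory",
  representation(coords = "array", atoms = "data.frame",
                 frameLabels = "numeric"),
  validity = function(object) {
    d <- dim(object@coords)
    msg <- character()
    if (length(d) != 3L || d[2] != 3L)
      msg <- c(msg, "coords must be an nAtoms x 3 x nFrames array")
    else {
      if (d[1] < 1L || d[3] < 1L)
        msg <- c(msg, "need at least one atom and one frame")
      if (!all(is.finite(object@coords)))
        msg <- c(msg, "all coordinates must be finite")
      if (nrow(object@atoms) != d[1])
        msg <- c(msg, "atoms roster must have one row per atom")
      if (length(object@frameLabels) != d[3])
        msg <- c(msg, "frameLabels must have one entry per frame")
    }
    if (!all(c("id", "name", "resname", "chain", "resno", "icode") %in%
             names(object@atoms)))
      msg <- c(msg, "atoms must have columns id, name, resname, chain, resno, icode")
    else if (anyDuplicated(object@atoms$id))
      msg <- c(msg, "atom ids must be unique")
    if (length(msg)) msg else TRUE
  }
)

#' Converged LOVO alignment of one frame
#'
#' @slot transform the accumulated [RigidTransform-class] mapping the original
#'   frame onto the reference.
#' @slot lowSet integer indices of the `nLow` atoms with the smallest squared
#'   deviations at convergence (the least-mobile subset).
#' @slot msdAll per-atom squared deviations (Angstrom^2) after the final
#'   transform.
#' @slot msdLowSum sum of the `nLow` smallest squared deviations, Angstrom^2
#'   (the LOVO objective).
#' @slot rmsdLow,rmsdHigh,rmsdTotal RMSD (Angstrom) over the low subset, its
#'   complement, and all atoms, under the same transform.
#' @slot nIterations iterations used; @slot converged whether the dual
#'   stopping rule was met within the iteration cap.
#' @slot msdLowPath per-iteration MSD_L values of the winning start
#'   (non-increasing).
#' @slot phi requested fraction; @slot nLow committed subset size
#'   `max(3, round(phi * nAtoms))`.
#'
#' @seealso [lovoAlign()], [lovoAlignFrame()]
#' @export
setClass("FrameAlignment",
  representation(transform = "RigidTransform", lowSet = "integer",
                 msdAll = "numeric", msdLowSum = "numeric",
                 rmsdLow = "numeric", rmsdHigh = "numeric",
                 rmsdTotal = "numeric", nIterations = "integer",
                 converged = "logical", msdLowPath = "numeric",
                 phi = "numeric", nLow = "integer"),
  validity = function(object) {
    n <- length(object@msdAll)
    nl <- object@nLow
    msg <- character()
    if (length(object@lowSet) != nl)
      msg <- c(msg, "lowSet must have nLow elements")
    tot <- n * object@rmsdTotal^2
    dec <- nl * object@rmsdLow^2 + (n - nl) * object@rmsdHigh^2
    if (abs(tot - dec) > 1e-8 * max(1, tot))
      msg <- c(msg, "sum-of-squares decomposition violated")
    if (length(msg)) msg else TRUE
  }
)

#' Per-trajectory mobility report
#'
#' Result of [alignTrajectory()]: per-frame RMSD time series, per-atom RMSF
#' and low-set membership, and the aligned coordinates.
#'
#' @slot phi fraction of atoms aligned; @slot nLow committed subset size.
#' @slot frameStats data.frame with columns `frame`, `rmsd_L`, `rmsd_H`,
#'   `rmsd_T`, `iters`, `converged` (one row per frame).
#' @slot rmsf per-atom RMSF, Angstrom, relative to the reference coordinates.
#' @slot lowFraction per-atom fraction of frames in which the atom belonged to
#'   the low (least-mobile) set.
#' @slot lowMembership logical `nAtoms x nFrames` matrix of per-frame low-set
#'   membership.
#' @slot alignedCoords `nAtoms x 3 x nFrames` array of transformed coordinates.
#' @slot rotations,translations the per-frame rigid motions applied
#'   (`3 x 3 x nFrames` array and `3 x nFrames` matrix).
#' @slot atoms,frameLabels the roster and labels of the input trajectory.
#' @slot referenceCoords the reference coordinates used, `nAtoms x 3`.
#' @slot options the [LovoOptions-class] used.
#'
#' @seealso [alignTrajectory()], [computeRMSF()], [writeAnnotatedPDB()]
#' @export
setClass("MobilityReport",
  representation(phi = "numeric", nLow = "integer", frameStats = "data.frame",
                 rmsf = "numeric", lowFraction = "numeric",
                 lowMembership = "matrix", alignedCoords = "array",
                 rotations = "array", translations = "matrix",
                 atoms = "data.frame", frameLabels = "numeric",
                 referenceCoords = "matrix", options = "LovoOptions"),
  validity = function(object) {
    msg <- character()
    if (any(object@lowFraction < 0) || any(object@lowFraction > 1))
      msg <- c(msg, "lowFraction must lie in [0, 1]")
    if (any(object@rmsf < 0)) msg <- c(msg, "rmsf must be non-negative")
    if (length(msg)) msg else TRUE
  }
)
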