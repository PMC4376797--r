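#' Construct a Trajectory
#'
#' @param coords an `nAtoms x 3 x nFrames` array, a single `nAtoms x 3`
#'   matrix, or a list of such matrices (one per frame), Angstrom.
#' @param atoms either a character vector of unique atom ids or a data.frame
#'   with columns `id`, `name`, `resname`, `chain`, `resno`, `icode`.  When a
#'   bare id vector (or nothing) is given, a pseudo C-alpha roster is built
#'   (name `CA`, residue `ALA`, chain `A`, residue numbers 1..N).
#' @param frameLabels numeric labels, default `1:nFrames`.
#'
#' @return a [Trajectory-class] object.
#' @examples
#' ref <- matrix(rnorm(30), 10, 3)
#' traj <- Trajectory(list(ref, ref + 0.1))
#' nFrames(traj)
#' @export
Trajectory <- function(coords, atoms = NULL, frameLabels = NULL) {
  if (is.list(coords) && !is.array(coords))
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 3L, length(coords)))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  n <- dim(coords)[1]
  if (is.null(atoms)) atoms <- defaultRoster(n)
  if (is.character(atoms)) atoms <- defaultRoster(n, ids = atoms)
  if (is.null(frameLabels)) frameLabels <- seq_len(dim(coords)[3])
  new("Trajectory", coords = coords, atoms = atoms,
      frameLabels = as.numeric(frameLabels))
}

defaultRoster <- function(n, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("A:%d:CA", seq_len(n))
  data.frame(id = ids, name = "CA", resname = "ALA", chain = "A",
             resno = seq_len(n), icode = "", stringsAsFactors = FALSE)
}

#' @rdname Trajectory-class
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])
#' @rdname Trajectory-class
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])
#' @rdname Trajectory-class
#' @export
setMethod("atomIds", "Trajectory", function(x) x@atoms$id)
#' @rdname Trajectory-class
#' @export
setMethod("atomData", "Trajectory", function(x) x@atoms)
#' @rdname Trajectory-class
#' @export
setMethod("frameLabels", "Trajectory", function(x) x@frameLabels)

#' @rdname Trajectory-class
#' @export
setMethod("frameCoords", "Trajectory", function(x, i = 1L) {
  m <- x@coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  rownames(m) <- x@atoms$id
  m
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nAtoms(object), "atoms x", nFrames(object), "frames\n")
  cat("  atoms:", paste(head(atomIds(object), 3), collapse = ", "),
      if (nAtoms(object) > 3) "..." else "", "\n")
})

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 translation vector, Angstrom.
#' @return a [RigidTransform-class].
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' @rdname RigidTransform-class
#' @export
setMethod("rotation", "RigidTransform", function(x) x@rotation)
#' @rdname RigidTransform-class
#' @export
setMethod("translation", "RigidTransform", function(x) x@translation)
#' @rdname RigidTransform-class
#' @export
setMethod("rotation", "Superposition", function(x) x@transform@rotation)
#' @rdname RigidTransform-class
#' @export
setMethod("translation", "Superposition", function(x) x@transform@translation)
#' @rdname RigidTransform-class
#' @export
setMethod("rotation", "FrameAlignment", function(x) x@transform@rotation)
#' @rdname RigidTransform-class
#' @export
setMethod("translation", "FrameAlignment", function(x) x@transform@translation)

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation:", paste(round(object@translation, 6), collapse = " "),
      "\n")
})

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return the inverse transform (`x -> R' (x - t)`).
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  RigidTransform(Rt, -Rt %*% transform@translation)
}

#' Apply a rigid transform to coordinates
#'
#' Maps every atom as \eqn{x \to R x + t}; atom identifiers (rownames) are
#' preserved.
#'
#' @param transform a [RigidTransform-class].
#' @param frame numeric `N x 3` coordinate matrix (or 1-frame Trajectory).
#' @return transformed `N x 3` matrix.
#' @export
applyTransform <- function(transform, frame) {
  x <- asCoordMatrix(frame)
  out <- x %*% t(transform@rotation)
  out <- sweep(out, 2, transform@translation, "+")
  rownames(out) <- rownames(x)
  out
}

#' Per-atom squared displacement
#'
#' Squared Euclidean displacement of each atom between a frame and the
#' reference, in the current relative orientation (no superposition is
#' performed).
#'
#' @param frame,reference `N x 3` coordinate matrices with the same atom
#'   roster and order (rownames, when present on both, must agree).
#' @return numeric vector of N squared displacements, Angstrom^2.
#' @examples
#' msdPerAtom(matrix(c(1, 2, 2), 1, 3), matrix(0, 1, 3))  # 9
#' @export
msdPerAtom <- function(frame, reference) {
  x <- asCoordMatrix(frame, "frame")
  y <- asCoordMatrix(reference, "reference")
  checkCorrespondence(x, y)
  rowSums((x - y)^2)
}

#' Root-mean-square deviation
#'
#' RMSD between a frame and a reference in the current orientation, optionally
#' restricted to a subset of atoms:
#' \eqn{\mathrm{RMSD} = \sqrt{\frac{1}{|S|}\sum_{i \in S} \|x_i - x_i^{ref}\|^2}}.
#'
#' @inheritParams msdPerAtom
#' @param subset integer atom indices (default: all atoms).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(frame, reference, subset = NULL) {
  msd <- msdPerAtom(frame, reference)
  if (is.null(subset)) subset <- seq_along(msd)
  subset <- as.integer(subset)
  if (length(subset) == 0L)
    stop("subset must be non-empty", call. = FALSE)
  if (any(subset < 1L) || any(subset > length(msd)))
    stop("subset indices out of range", call. = FALSE)
  sqrt(mean(msd[subset]))
}

checkFitSubset <- function(reference, subset) {
  n <- nrow(reference)
  subset <- as.integer(subset)
  if (anyDuplicated(subset) || any(subset < 1L) || any(subset > n))
    stop("subset must be distinct indices in 1..", n, call. = FALSE)
  if (length(subset) < 3L)
    stop("degenerate fit: subset has fewer than 3 atoms", call. = FALSE)
  # collinear/coincident when the two smallest principal variances vanish
  ev <- eigen(stats::cov(reference[subset, , drop = FALSE]),
              symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] < 1e-12 && ev[3] < 1e-12)
    stop("degenerate fit: reference subset is collinear or coincident",
         call. = FALSE)
  subset
}

#' Kearsley quaternion superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between the
#' `subset` atoms of `mobile` and the corresponding atoms of `reference`
#' (exact global minimum of the rigid-body problem, via the eigenvector of the
#' smallest eigenvalue of Kearsley's 4x4 quaternion matrix).  The per-atom
#' squared deviations are then recomputed over *all* atoms of the transformed
#' frame, which is what the LOVO iteration re-sorts.
#'
#' @param mobile,reference `N x 3` coordinate matrices, identical rosters.
#' @param subset integer indices of the atoms to fit (default all); at least 3
#'   non-collinear atoms.
#' @return a [Superposition-class].
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(30), 10, 3)
#' x <- sweep(y, 2, c(1, 2, 3), "+")
#' kearsleySuperpose(x, y)@rmsdFit  # 0: pure translation is removed
#' @export
kearsleySuperpose <- function(mobile, reference, subset = NULL) {
  x <- asCoordMatrix(mobile, "mobile")
  y <- asCoordMatrix(reference, "reference")
  checkCorrespondence(x, y)
  if (is.null(subset)) subset <- seq_len(nrow(x))
  subset <- checkFitSubset(y, subset)
  fit <- .cpp_kearsley(x, y, subset)
  new("Superposition",
      transform = RigidTransform(fit$rotation, fit$translation),
      rmsdFit = fit$rmsdFit, msdAll = as.numeric(fit$msdAll),
      subset = subset)
}

setMethod("show", "Superposition", function(object) {
  cat("Superposition: rmsd_fit =", fmtNum(object@rmsdFit), "A over",
      length(object@subset), "of", length(object@msdAll), "atoms\n")
})

#' @rdname FrameAlignment-class
#' @export
setMethod("msdAll", "Superposition", function(x) x@msdAll)
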