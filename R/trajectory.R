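#' Robust LOVO alignment of a whole trajectory
#'
#' Aligns every frame independently to the reference with multistart LOVO
#' ([lovoAlign()]), collecting the RMSD_L / RMSD_H / RMSD_T time series, the
#' transformed coordinates, per-frame low-set membership and per-atom RMSF.
#' The low set is re-identified on every frame, so membership may differ
#' across frames; the per-atom `lowFraction` records how often each atom was
#' classified as least-mobile.
#'
#' Frames are independent: each frame uses its own RNG stream seeded with
#' `bitwXor(options@seed, frameIndex)`, so results do not depend on
#' processing order.
#'
#' @param traj a [Trajectory-class].
#' @param reference `N x 3` matrix sharing the trajectory's roster; default
#'   is the first frame.
#' @param phi fraction of atoms to align, in (0, 1].
#' @param options a [LovoOptions-class].
#' @return a [MobilityReport-class].
#' @examples
#' syn <- syntheticTrajectory(nCore = 30, nMobile = 10, nFrames = 3,
#'                            coreNoiseSigma = 0.05, mobileOffset = 4, seed = 1)
#' rep <- alignTrajectory(syn$trajectory, phi = 0.75,
#'                        options = lovoOptions(nStarts = 10, seed = 1))
#' frameStats(rep)
#' @export
alignTrajectory <- function(traj, reference = NULL, phi,
                            options = lovoOptions()) {
  stopifnot(is(traj, "Trajectory"))
  if (is.null(reference)) reference <- frameCoords(traj, 1L)
  y <- asCoordMatrix(reference, "reference")
  if (nrow(y) != nAtoms(traj))
    stop("correspondence error: reference has ", nrow(y),
         " atoms but trajectory has ", nAtoms(traj), call. = FALSE)
  if (!is.null(rownames(y)) && !identical(rownames(y), atomIds(traj)))
    stop("correspondence error: reference roster differs from trajectory",
         call. = FALSE)
  n <- nAtoms(traj)
  nf <- nFrames(traj)
  nLow <- nLowFor(phi, n)

  aligned <- array(NA_real_, dim = c(n, 3L, nf))
  rots <- array(NA_real_, dim = c(3L, 3L, nf))
  trans <- matrix(NA_real_, 3L, nf)
  member <- matrix(FALSE, n, nf)
  stats <- data.frame(frame = frameLabels(traj), rmsd_L = NA_real_,
                      rmsd_H = NA_real_, rmsd_T = NA_real_,
                      iters = NA_integer_, converged = NA)
  for (f in seq_len(nf)) {
    opt <- options
    opt@seed <- frameSeed(options@seed, f)
    fit <- lovoAlign(frameCoords(traj, f), y, phi, opt)
    aligned[, , f] <- applyTransform(fit@transform, frameCoords(traj, f))
    rots[, , f] <- rotation(fit)
    trans[, f] <- translation(fit)
    member[fit@lowSet, f] <- TRUE
    stats$rmsd_L[f] <- fit@rmsdLow
    stats$rmsd_H[f] <- fit@rmsdHigh
    stats$rmsd_T[f] <- fit@rmsdTotal
    stats$iters[f] <- fit@nIterations
    stats$converged[f] <- fit@converged
  }
  rep <- new("MobilityReport", phi = phi, nLow = nLow, frameStats = stats,
             rmsf = numeric(n), lowFraction = rowMeans(member),
             lowMembership = member, alignedCoords = aligned,
             rotations = rots, translations = trans,
             atoms = atomData(traj), frameLabels = frameLabels(traj),
             referenceCoords = unname(y), options = options)
  rep@rmsf <- computeRMSF(rep, mode = "reference")
  rep
}

#' Scan the aligned fraction phi
#'
#' Runs [alignTrajectory()] over a grid of phi values and summarizes each run,
#' mapping how the RMSD of the least-mobile subset grows as more atoms are
#' required to fit: a sharp rise localizes the boundary of a rigid core.
#'
#' @inheritParams alignTrajectory
#' @param phiGrid increasing vector of fractions in (0, 1]; default
#'   `seq(0.01, 0.99, by = 0.01)`.
#' @param mode `"trajectory"` (default) summarizes over all frames;
#'   `"endpoints"` aligns only the last frame to the first (useful when the
#'   structure diverges steadily and the first/last comparison is the
#'   quantity of interest).
#' @return data.frame with columns `phi`, `n_L`, `mean_rmsd_L`, `max_rmsd_L`,
#'   `mean_rmsd_H`, `mean_rmsd_T`, one row per phi, ascending.
#' @export
phiScan <- function(traj, reference = NULL, phiGrid = seq(0.01, 0.99, 0.01),
                    options = lovoOptions(),
                    mode = c("trajectory", "endpoints")) {
  mode <- match.arg(mode)
  stopifnot(is(traj, "Trajectory"))
  if (is.unsorted(phiGrid, strictly = TRUE) ||
      any(phiGrid <= 0) || any(phiGrid > 1))
    stop("phiGrid must be strictly increasing, in (0, 1]", call. = FALSE)
  if (mode == "endpoints") {
    if (is.null(reference)) reference <- frameCoords(traj, 1L)
    traj <- Trajectory(frameCoords(traj, nFrames(traj)), atomData(traj),
                       frameLabels(traj)[nFrames(traj)])
  }
  rows <- lapply(phiGrid, function(phi) {
    rep <- alignTrajectory(traj, reference, phi, options)
    st <- frameStats(rep)
    data.frame(phi = phi, n_L = rep@nLow,
               mean_rmsd_L = mean(st$rmsd_L), max_rmsd_L = max(st$rmsd_L),
               mean_rmsd_H = mean(st$rmsd_H), mean_rmsd_T = mean(st$rmsd_T))
  })
  do.call(rbind, rows)
}

#' Per-atom root-mean-square fluctuation
#'
#' RMSF of each atom over the aligned trajectory:
#' \eqn{\mathrm{RMSF}_i = \sqrt{\langle \|x_i(t) - r_i\|^2 \rangle_t}} where
#' `r_i` is the reference coordinate (`mode = "reference"`, the default,
#' measuring displacement from the reference structure) or the
#' trajectory-average coordinate (`mode = "average"`, the classical
#' fluctuation about the mean).
#'
#' @param report a [MobilityReport-class].
#' @param mode `"reference"` or `"average"`.
#' @return numeric vector of per-atom RMSF values, Angstrom.
#' @export
computeRMSF <- function(report, mode = c("reference", "average")) {
  mode <- match.arg(mode)
  ac <- report@alignedCoords
  nf <- dim(ac)[3]
  if (mode == "average" && nf == 1L)
    warning("single-frame trajectory: RMSF about the average is identically 0")
  r <- if (mode == "reference") report@referenceCoords
       else apply(ac, c(1, 2), mean)
  sq <- vapply(seq_len(nf),
               function(f) rowSums((ac[, , f] - r)^2), numeric(dim(ac)[1]))
  sqrt(rowMeans(matrix(sq, nrow = dim(ac)[1])))
}

#' Per-frame, per-atom deviation series
#'
#' The displacement (Angstrom) of every atom from its reference position in
#' every aligned frame, i.e. `sqrt(MSD_i(t))`.  This is the quantity painted
#' into the b-factor field of the annotated PDB output, and its root mean
#' square over frames equals the reference-mode RMSF.
#'
#' @param report a [MobilityReport-class].
#' @return numeric `nAtoms x nFrames` matrix.
#' @export
deviationSeries <- function(report) {
  ac <- report@alignedCoords
  out <- vapply(seq_len(dim(ac)[3]),
                function(f) sqrt(rowSums((ac[, , f] - report@referenceCoords)^2)),
                numeric(dim(ac)[1]))
  out <- matrix(out, nrow = dim(ac)[1])
  rownames(out) <- report@atoms$id
  out
}

#' @rdname MobilityReport-class
#' @param x a `MobilityReport`.
#' @export
setMethod("frameStats", "MobilityReport", function(x) x@frameStats)
#' @rdname MobilityReport-class
#' @export
setMethod("rmsf", "MobilityReport", function(x) setNames(x@rmsf, x@atoms$id))
#' @rdname MobilityReport-class
#' @export
setMethod("lowFraction", "MobilityReport",
          function(x) setNames(x@lowFraction, x@atoms$id))
#' @rdname MobilityReport-class
#' @export
setMethod("lowMembership", "MobilityReport", function(x) x@lowMembership)
#' @rdname MobilityReport-class
#' @export
setMethod("alignedTrajectory", "MobilityReport", function(x)
  Trajectory(x@alignedCoords, x@atoms, x@frameLabels))
#' @rdname MobilityReport-class
#' @export
setMethod("nAtoms", "MobilityReport", function(x) dim(x@alignedCoords)[1])
#' @rdname MobilityReport-class
#' @export
setMethod("nFrames", "MobilityReport", function(x) dim(x@alignedCoords)[3])
#' @rdname MobilityReport-class
#' @export
setMethod("atomIds", "MobilityReport", function(x) x@atoms$id)

#' Rigid motion applied to one frame
#'
#' @param report a [MobilityReport-class].
#' @param f frame index.
#' @return the [RigidTransform-class] that aligned frame `f`.
#' @export
frameTransform <- function(report, f) {
  RigidTransform(report@rotations[, , f], report@translations[, f])
}

#' Consensus low-mobility core
#'
#' Atoms classified as least-mobile in at least `threshold` of the frames
#' (default half), the committed aggregation used for structure coloring.
#'
#' @param report a [MobilityReport-class].
#' @param threshold membership fraction cut-off in [0, 1].
#' @return logical vector, one entry per atom.
#' @export
consensusCore <- function(report, threshold = 0.5) {
  setNames(report@lowFraction >= threshold, report@atoms$id)
}

#' @rdname MobilityReport-class
#' @param object a `MobilityReport`.
#' @export
setMethod("show", "MobilityReport", function(object) {
  st <- object@frameStats
  cat("MobilityReport: phi =", object@phi,
      sprintf("(nLow = %d/%d), %d frames\n", object@nLow, nAtoms(object),
              nFrames(object)))
  cat(sprintf("  mean rmsd_L = %s  rmsd_H = %s  rmsd_T = %s A\n",
              fmtNum(mean(st$rmsd_L)), fmtNum(mean(st$rmsd_H)),
              fmtNum(mean(st$rmsd_T))))
  cat("  consensus core:", sum(object@lowFraction >= 0.5), "atoms;",
      sum(!st$converged), "frame(s) not converged\n")
})

#' Write report tables as TSV
#'
#' Three tab-separated outputs: the per-frame time series
#' (`frame rmsd_L rmsd_H rmsd_T iters converged`), the per-atom summary
#' (`atom_id rmsf low_fraction`), and — from [phiScan()] output — the scan
#' table (`phi n_L mean_rmsd_L max_rmsd_L mean_rmsd_H mean_rmsd_T`).  Floats
#' are written with 6 decimals.
#'
#' @param report a [MobilityReport-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeFrameTable <- function(report, path) {
  st <- report@frameStats
  out <- data.frame(frame = st$frame, rmsd_L = fmtNum(st$rmsd_L),
                    rmsd_H = fmtNum(st$rmsd_H), rmsd_T = fmtNum(st$rmsd_T),
                    iters = st$iters, converged = st$converged)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFrameTable
#' @export
writeAtomTable <- function(report, path) {
  out <- data.frame(atom_id = report@atoms$id, rmsf = fmtNum(report@rmsf),
                    low_fraction = fmtNum(report@lowFraction))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFrameTable
#' @param scan data.frame returned by [phiScan()].
#' @export
writePhiScanTable <- function(scan, path) {
  out <- data.frame(phi = fmtNum(scan$phi), n_L = scan$n_L,
                    mean_rmsd_L = fmtNum(scan$mean_rmsd_L),
                    max_rmsd_L = fmtNum(scan$max_rmsd_L),
                    mean_rmsd_H = fmtNum(scan$mean_rmsd_H),
                    mean_rmsd_T = fmtNum(scan$mean_rmsd_T))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
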