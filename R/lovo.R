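#' LOVO alignment options
#'
#' @param nStarts number of multistart initial subsets (default 100).
#' @param maxIterations per-start iteration cap (default 200).
#' @param convergenceTol tolerance on the change of the LOVO objective MSD_L
#'   between iterations, Angstrom^2 (default 1e-9).
#' @param seed integer seed controlling the random initial subsets.
#' @return a [LovoOptions-class].
#' @export
lovoOptions <- function(nStarts = 100L, maxIterations = 200L,
                        convergenceTol = 1e-9, seed = 1L) {
  new("LovoOptions", nStarts = as.integer(nStarts),
      maxIterations = as.integer(maxIterations),
      convergenceTol = as.numeric(convergenceTol), seed = as.integer(seed))
}

setMethod("show", "LovoOptions", function(object) {
  cat("LovoOptions: nStarts =", object@nStarts,
      "maxIterations =", object@maxIterations,
      "convergenceTol =", object@convergenceTol,
      "seed =", object@seed, "\n")
})

#' Indices of the smallest per-atom deviations
#'
#' Returns the atom indices of the `nLow` smallest values.  Ties are broken
#' deterministically by original atom index (stable selection), so results do
#' not depend on the sorting library.
#'
#' @param msd numeric vector of per-atom squared deviations.
#' @param nLow number of indices to select, `1 <= nLow <= length(msd)`.
#' @return sorted integer vector of `nLow` indices.
#' @examples
#' selectLowest(c(4, 1, 3, 2), 2)  # 2 4
#' @export
selectLowest <- function(msd, nLow) {
  nLow <- as.integer(nLow)
  if (nLow < 1L || nLow > length(msd))
    stop("nLow must be in 1..", length(msd), call. = FALSE)
  sort(head(order(msd, seq_along(msd)), nLow))
}

makeFrameAlignment <- function(fit, phi, nLow) {
  n <- length(fit$msdAll)
  msd <- as.numeric(fit$msdAll)
  low <- as.integer(fit$lowSet)
  rmsdLow <- sqrt(fit$msdLowSum / nLow)
  rmsdHigh <- if (nLow < n) sqrt(sum(msd[-low]) / (n - nLow)) else 0
  new("FrameAlignment",
      transform = RigidTransform(fit$rotation, as.numeric(fit$translation)),
      lowSet = low, msdAll = msd, msdLowSum = fit$msdLowSum,
      rmsdLow = rmsdLow, rmsdHigh = rmsdHigh, rmsdTotal = sqrt(mean(msd)),
      nIterations = as.integer(fit$nIterations),
      converged = as.logical(fit$converged),
      msdLowPath = as.numeric(fit$msdLowPath),
      phi = phi, nLow = as.integer(nLow))
}

# deterministic start: bottom-nLow deviations after whole-structure alignment
deterministicStart <- function(x, y, nLow) {
  whole <- .cpp_kearsley(x, y, seq_len(nrow(x)))
  selectLowest(as.numeric(whole$msdAll), nLow)
}

#' LOVO alignment of one frame from a single start
#'
#' Runs the iterative LOVO loop for one frame: superpose on the current
#' subset, transform the whole frame, re-sort the per-atom squared deviations,
#' re-select the bottom `nLow`, until the objective change falls below the
#' tolerance *and* the selected subset is stable (subsets that differ only
#' among numerically tied deviations count as stable).  The objective MSD_L (sum of
#' the `nLow` smallest squared deviations) is non-increasing across
#' iterations, which guarantees convergence to a local minimizer.
#'
#' @param frame,reference `N x 3` coordinate matrices, identical rosters.
#' @param phi fraction of atoms to align, in (0, 1]; the subset size is
#'   `nLow = max(3, round(phi * N))` (round half away from zero).
#' @param initialSet integer vector of `nLow` starting indices; default is the
#'   deterministic start (bottom `nLow` after whole-structure superposition).
#' @param options a [LovoOptions-class] (only `maxIterations` and
#'   `convergenceTol` are used here).
#' @return a [FrameAlignment-class]; non-convergence within the iteration cap
#'   is reported via `converged(x) == FALSE`, not as an error.
#' @seealso [lovoAlign()] for the multistart (globalized) version.
#' @export
lovoAlignFrame <- function(frame, reference, phi, initialSet = NULL,
                           options = lovoOptions()) {
  x <- asCoordMatrix(frame, "frame")
  y <- asCoordMatrix(reference, "reference")
  checkCorrespondence(x, y)
  nLow <- nLowFor(phi, nrow(x))
  if (is.null(initialSet)) initialSet <- deterministicStart(x, y, nLow)
  if (length(initialSet) != nLow)
    stop("initialSet must have nLow = ", nLow, " indices", call. = FALSE)
  checkFitSubset(y, initialSet)
  fit <- .cpp_lovo(x, y, matrix(as.integer(initialSet), ncol = 1),
                   options@convergenceTol, options@maxIterations)
  makeFrameAlignment(fit, phi, nLow)
}

#' Multistart LOVO alignment of one frame
#'
#' Globalizes [lovoAlignFrame()] by running it from `nStarts` initial subsets:
#' the deterministic bottom-`nLow`-after-whole-structure-alignment start plus
#' `nStarts - 1` uniformly random `nLow`-subsets drawn from a generator seeded
#' with `options@seed`.  The result with the smallest MSD_L is returned (first
#' found on ties), so the output is deterministic given the seed.
#'
#' @inheritParams lovoAlignFrame
#' @param options a [LovoOptions-class].
#' @return a [FrameAlignment-class].
#' @examples
#' set.seed(7)
#' ref <- matrix(rnorm(30), 10, 3)
#' frm <- ref + matrix(rnorm(30, sd = 0.2), 10, 3)
#' fit <- lovoAlign(frm, ref, phi = 0.5, options = lovoOptions(seed = 2))
#' lowSet(fit)
#' @export
lovoAlign <- function(frame, reference, phi, options = lovoOptions()) {
  x <- asCoordMatrix(frame, "frame")
  y <- asCoordMatrix(reference, "reference")
  checkCorrespondence(x, y)
  n <- nrow(x)
  nLow <- nLowFor(phi, n)
  checkFitSubset(y, seq_len(n))
  starts <- matrix(0L, nrow = nLow, ncol = options@nStarts)
  starts[, 1] <- deterministicStart(x, y, nLow)
  if (options@nStarts > 1L)
    starts[, -1] <- withSeed(options@seed,
      vapply(seq_len(options@nStarts - 1L),
             function(k) sort(sample.int(n, nLow)), integer(nLow)))
  fit <- .cpp_lovo(x, y, starts, options@convergenceTol,
                   options@maxIterations)
  if (!isTRUE(fit$monotone))
    warning("LOVO objective increased beyond tolerance during iteration")
  makeFrameAlignment(fit, phi, nLow)
}

#' @rdname FrameAlignment-class
#' @param x a `FrameAlignment`.
#' @export
setMethod("lowSet", "FrameAlignment", function(x) x@lowSet)
#' @rdname FrameAlignment-class
#' @export
setMethod("msdAll", "FrameAlignment", function(x) x@msdAll)

#' @rdname FrameAlignment-class
#' @param object a `FrameAlignment`.
#' @export
setMethod("show", "FrameAlignment", function(object) {
  n <- length(object@msdAll)
  cat("FrameAlignment: phi =", object@phi,
      sprintf("(nLow = %d/%d, realized %.3f)\n", object@nLow, n,
              object@nLow / n))
  cat("  rmsd_L =", fmtNum(object@rmsdLow),
      " rmsd_H =", fmtNum(object@rmsdHigh),
      " rmsd_T =", fmtNum(object@rmsdTotal), "A\n")
  cat("  iterations:", object@nIterations,
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
})
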