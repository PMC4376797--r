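# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# round-half-away-from-zero (base round() rounds half to even)
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# committed rounding of phi * N, floored at 3 (a rigid fit needs >= 3 atoms)
nLowFor <- function(phi, n) {
  if (!is.numeric(phi) || length(phi) != 1L || is.na(phi) ||
      phi <= 0 || phi > 1)
    stop("phi must be a single value in (0, 1]", call. = FALSE)
  if (n < 3L) stop("need at least 3 atoms", call. = FALSE)
  as.integer(max(3, min(n, roundHalfAway(phi * n))))
}

# per-frame seed derivation, documented contract: seed XOR frame index
frameSeed <- function(seed, frame) bitwXor(as.integer(seed), as.integer(frame))

asCoordMatrix <- function(x, arg = "frame") {
  if (is(x, "Trajectory")) {
    if (nFrames(x) != 1L)
      stop(arg, " is a multi-frame Trajectory; pass a single frame", call. = FALSE)
    return(frameCoords(x, 1L))
  }
  if (!is.matrix(x) || ncol(x) != 3L || !is.numeric(x))
    stop(arg, " must be a numeric N x 3 coordinate matrix", call. = FALSE)
  if (!all(is.finite(x)))
    stop(arg, " contains non-finite coordinates", call. = FALSE)
  x
}

checkCorrespondence <- function(frame, reference) {
  if (nrow(frame) != nrow(reference))
    stop("correspondence error: frame has ", nrow(frame),
         " atoms but reference has ", nrow(reference), call. = FALSE)
  rf <- rownames(frame)
  rr <- rownames(reference)
  if (!is.null(rf) && !is.null(rr) && !identical(rf, rr))
    stop("correspondence error: atom rosters differ (first mismatch: ",
         rf[which(rf != rr)[1]], " vs ", rr[which(rf != rr)[1]], ")",
         call. = FALSE)
  invisible(TRUE)
}

fmtNum <- function(x) sprintf("%.6f", x)
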