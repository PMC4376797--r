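# Shared fixtures and independent oracles for the test suite.
# The oracle code here deliberately avoids the package's own superposition
# and LOVO routines wherever it checks them.

# independent quaternion -> rotation (textbook formula, written separately
# from the compiled implementation)
quatRot <- function(q) {
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
           2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
           2 * (b * d + a * c), 2 * (c * d - a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

randomRotation <- function() quatRot(rnorm(4))

randomRigid <- function(x, tmax = 10) {
  applyTransform(RigidTransform(randomRotation(), runif(3, -tmax, tmax)), x)
}

# Brute-force rigid-fit oracle: best RMSD over random proper rotations with
# the closed-form optimal translation (centroid matching).  Vectorized via
# residual = ||xc||^2 + ||yc||^2 - 2 tr(R A), A = sum_i xc_i yc_i^T.
# With refine = TRUE, shrinking-radius random search around the incumbent
# quaternion polishes the sampled optimum to ~1e-6 without any use of the
# package's solver.
bruteForceFitRmsd <- function(mobile, reference, subset = NULL,
                              nRot = 10000, refine = FALSE) {
  if (is.null(subset)) subset <- seq_len(nrow(mobile))
  xs <- mobile[subset, , drop = FALSE]
  ys <- reference[subset, , drop = FALSE]
  xc <- sweep(xs, 2, colMeans(xs))
  yc <- sweep(ys, 2, colMeans(ys))
  c0 <- sum(xc^2) + sum(yc^2)
  A <- t(xc) %*% yc
  vecA <- as.vector(t(A))  # A[k,j] laid out to match row-major R entries
  residFor <- function(Q) {
    a <- Q[, 1]; b <- Q[, 2]; cc <- Q[, 3]; d <- Q[, 4]
    R <- cbind(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc + a * d),
               2 * (b * d - a * cc),
               2 * (b * cc - a * d), a^2 - b^2 + cc^2 - d^2,
               2 * (cc * d + a * b),
               2 * (b * d + a * cc), 2 * (cc * d - a * b),
               a^2 - b^2 - cc^2 + d^2)
    c0 - 2 * drop(R %*% vecA)  # tr(R A) = sum_{j,k} R[j,k] A[k,j]
  }
  Q <- matrix(rnorm(4 * nRot), nRot, 4)
  Q <- Q / sqrt(rowSums(Q^2))
  resid <- residFor(Q)
  best <- min(resid)
  qBest <- Q[which.min(resid), ]
  if (refine) {
    scale <- 0.2
    for (stage in 1:14) {
      P <- matrix(rnorm(4 * 400, sd = scale), 400, 4)
      P <- sweep(P, 2, qBest, "+")
      P <- P / sqrt(rowSums(P^2))
      r <- residFor(P)
      if (min(r) < best) {
        best <- min(r)
        qBest <- P[which.min(r), ]
      }
      scale <- scale * 0.45
    }
  }
  sqrt(max(0, best) / length(subset))
}

# Exhaustive LOVO oracle: minimum over all nLow-subsets of the within-subset
# mean-square-deviation sum after optimally superposing on that subset.
enumerateLovoOptimum <- function(frame, reference, nLow) {
  subs <- utils::combn(nrow(frame), nLow)
  best <- Inf
  for (k in seq_len(ncol(subs))) {
    s <- subs[, k]
    fit <- kearsleySuperpose(frame, reference, s)
    best <- min(best, nLow * fit@rmsdFit^2)
  }
  best
}

# reference + frame pair where a known core matches exactly after a rigid
# motion and the rest is displaced far away
coreLoopFrame <- function(n = 20, coreFrac = 0.7, displacement = 8) {
  ref <- matrix(rnorm(3 * n, sd = 3), n, 3)
  nCore <- round(coreFrac * n)
  frm <- ref
  frm[(nCore + 1):n, ] <- frm[(nCore + 1):n, ] + displacement
  frm <- randomRigid(frm)
  list(ref = ref, frame = frm, core = seq_len(nCore))
}

# tiny in-code PDB trajectory text, hand-built at fixed widths
pdbLine <- function(record = "ATOM", serial, name, altloc = " ",
                    resname = "ALA", chain = "A", resno, icode = " ",
                    x, y, z, occ = 1, b = 0, element = " C") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, if (nchar(name) >= 4) name else paste0(" ", name),
          altloc, resname, chain, resno, icode, x, y, z, occ, b, element)
}
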