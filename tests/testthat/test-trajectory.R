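smallOptions <- function(seed = 1) lovoOptions(nStarts = 10, seed = seed)

staticTrajectory <- function(n = 15, nf = 4) {
  set.seed(32)
  ref <- matrix(rnorm(3 * n, sd = 3), n, 3)
  Trajectory(replicate(nf, ref, simplify = FALSE))
}

test_that("a static trajectory reports zero everywhere", {
  traj <- staticTrajectory()
  rep <- alignTrajectory(traj, phi = 0.6, options = smallOptions())
  st <- frameStats(rep)
  expect_equal(max(st$rmsd_L, st$rmsd_H, st$rmsd_T), 0, tolerance = 1e-9)
  expect_true(all(st$converged))
  expect_equal(unname(rmsf(rep)), rep(0, 15), tolerance = 1e-9)
  expect_true(all(lowFraction(rep) %in% c(0, 1)))
  expect_equal(colSums(lowMembership(rep)), rep(rep@nLow, 4))
})

test_that("a growing mobile loop drives rmsd_H up while rmsd_L stays flat", {
  syn <- syntheticTrajectory(nCore = 40, nMobile = 15, nFrames = 6,
                             coreNoiseSigma = 0.02, mobileOffset = 6,
                             schedule = "ramp", seed = 5)
  rep <- alignTrajectory(syn$trajectory, reference = syn$reference,
                         phi = 40 / 55, options = smallOptions())
  st <- frameStats(rep)
  expect_true(all(diff(st$rmsd_H) > 0))
  expect_lt(max(st$rmsd_L), 0.1)
})

test_that("a global rigid motion of all input frames changes nothing", {
  syn <- syntheticTrajectory(nCore = 25, nMobile = 10, nFrames = 3,
                             coreNoiseSigma = 0.1, mobileOffset = 4, seed = 6)
  ref <- syn$reference
  base <- alignTrajectory(syn$trajectory, ref, phi = 0.7,
                          options = smallOptions())
  set.seed(33)
  tr <- RigidTransform(randomRotation(), runif(3, -8, 8))
  moved <- Trajectory(lapply(seq_len(nFrames(syn$trajectory)), function(f)
    applyTransform(tr, frameCoords(syn$trajectory, f))))
  after <- alignTrajectory(moved, ref, phi = 0.7, options = smallOptions())
  for (col in c("rmsd_L", "rmsd_H", "rmsd_T"))
    expect_equal(frameStats(after)[[col]], frameStats(base)[[col]],
                 tolerance = 1e-8)
  expect_equal(unname(rmsf(after)), unname(rmsf(base)), tolerance = 1e-8)
  expect_identical(lowMembership(after), lowMembership(base))
})

test_that("frames are independent: permuting them permutes the report", {
  syn <- syntheticTrajectory(nCore = 20, nMobile = 8, nFrames = 5,
                             coreNoiseSigma = 0.15, mobileOffset = 4,
                             seed = 7)
  traj <- syn$trajectory
  ref <- syn$reference
  base <- alignTrajectory(traj, ref, phi = 0.7, options = smallOptions())
  p <- c(3, 5, 1, 2, 4)
  # per-frame seeds follow the original frame label, so reuse them explicitly
  rows <- lapply(p, function(f) {
    opt <- smallOptions()
    opt@seed <- bitwXor(opt@seed, f)
    fit <- lovoAlign(frameCoords(traj, f), ref, 0.7, opt)
    c(fit@rmsdLow, fit@rmsdHigh, fit@rmsdTotal)
  })
  got <- do.call(rbind, rows)
  st <- frameStats(base)
  expect_equal(got[, 1], st$rmsd_L[p], tolerance = 1e-12)
  expect_equal(got[, 2], st$rmsd_H[p], tolerance = 1e-12)
})

test_that("each frame contributes exactly nLow memberships", {
  syn <- syntheticTrajectory(nCore = 20, nMobile = 10, nFrames = 4,
                             coreNoiseSigma = 0.2, mobileOffset = 3, seed = 8)
  rep <- alignTrajectory(syn$trajectory, phi = 0.55, options = smallOptions())
  expect_equal(colSums(lowMembership(rep)),
               rep(rep@nLow, nFrames(rep)))
  expect_equal(mean(lowFraction(rep)), rep@nLow / nAtoms(rep),
               tolerance = 1e-12)
})

test_that("scaling all coordinates scales every statistic linearly", {
  syn <- syntheticTrajectory(nCore = 18, nMobile = 6, nFrames = 3,
                             coreNoiseSigma = 0.2, mobileOffset = 4, seed = 9)
  k <- 2.5
  scaled <- Trajectory(syn$trajectory@coords * k, atomData(syn$trajectory))
  a <- alignTrajectory(syn$trajectory, syn$reference, phi = 0.7,
                       options = smallOptions())
  b <- alignTrajectory(scaled, syn$reference * k, phi = 0.7,
                       options = smallOptions())
  for (col in c("rmsd_L", "rmsd_H", "rmsd_T"))
    expect_equal(frameStats(b)[[col]], k * frameStats(a)[[col]],
                 tolerance = 1e-10)
  expect_equal(unname(rmsf(b)), k * unname(rmsf(a)), tolerance = 1e-10)
})

test_that("phi scan: phi = 1 row matches whole-structure alignment", {
  syn <- syntheticTrajectory(nCore = 15, nMobile = 6, nFrames = 3,
                             coreNoiseSigma = 0.1, mobileOffset = 4, seed = 10)
  traj <- syn$trajectory
  sc <- phiScan(traj, phiGrid = c(0.5, 1), options = smallOptions())
  expect_equal(sc$phi, c(0.5, 1))
  expect_true(all(diff(sc$n_L) >= 0))
  whole <- vapply(seq_len(nFrames(traj)), function(f)
    kearsleySuperpose(frameCoords(traj, f), frameCoords(traj, 1))@rmsdFit,
    numeric(1))
  expect_equal(sc$mean_rmsd_L[2], mean(whole), tolerance = 1e-9)
  expect_equal(sc$mean_rmsd_T[2], mean(whole), tolerance = 1e-9)
})

test_that("phi scan localizes the core fraction and is monotone in phi", {
  syn <- syntheticTrajectory(nCore = 35, nMobile = 15, nFrames = 4,
                             coreNoiseSigma = 0.05, mobileOffset = 6,
                             seed = 11)
  grid <- seq(0.5, 0.9, by = 0.05)  # core fraction is 0.7
  sc <- phiScan(syn$trajectory, syn$reference, grid,
                options = smallOptions())
  expect_true(all(diff(sc$mean_rmsd_L) >= -1e-6))
  below <- sc$mean_rmsd_L[sc$phi <= 0.7]
  above <- sc$mean_rmsd_L[sc$phi >= 0.75]
  expect_lt(max(below), 0.12)     # noise level while within the true core
  expect_gt(min(above), 3 * max(below))  # sharp rise one step past the core
})

test_that("the endpoints scan mode uses only the first and last frames", {
  syn <- syntheticTrajectory(nCore = 15, nMobile = 5, nFrames = 4,
                             coreNoiseSigma = 0.1, mobileOffset = 5,
                             schedule = "ramp", seed = 12)
  traj <- syn$trajectory
  sc <- phiScan(traj, phiGrid = c(0.7), options = smallOptions(),
                mode = "endpoints")
  opt <- smallOptions()
  opt@seed <- bitwXor(opt@seed, 1L)
  fit <- lovoAlign(frameCoords(traj, 4), frameCoords(traj, 1), 0.7, opt)
  expect_equal(sc$mean_rmsd_L, fit@rmsdLow, tolerance = 1e-12)
  expect_equal(sc$max_rmsd_L, fit@rmsdLow, tolerance = 1e-12)
})

test_that("RMSF conventions: reference vs trajectory-average position", {
  set.seed(34)
  core <- matrix(rnorm(60, sd = 4), 20, 3)
  ref <- rbind(core, c(0, 0, 20))
  d <- 0.8
  up <- ref; up[21, 3] <- up[21, 3] + d
  dn <- ref; dn[21, 3] <- dn[21, 3] - d
  # alternating atom: both conventions see displacement d
  alt <- Trajectory(list(up, dn, up, dn))
  repAlt <- alignTrajectory(alt, ref, phi = 20 / 21,
                            options = smallOptions())
  expect_equal(unname(rmsf(repAlt))[21], d, tolerance = 1e-6)
  expect_equal(unname(computeRMSF(repAlt, "average"))[21], d,
               tolerance = 1e-6)
  # persistent offset: reference convention sees d, average sees 0
  per <- Trajectory(list(up, up, up, up))
  repPer <- alignTrajectory(per, ref, phi = 20 / 21,
                            options = smallOptions())
  expect_equal(unname(rmsf(repPer))[21], d, tolerance = 1e-6)
  expect_equal(unname(computeRMSF(repPer, "average"))[21], 0,
               tolerance = 1e-6)
  expect_warning(
    computeRMSF(alignTrajectory(Trajectory(up), ref, phi = 0.9,
                                options = smallOptions()), "average"),
    "single-frame")
})

test_that("deviation series is the per-frame sqrt-MSD and averages to RMSF", {
  syn <- syntheticTrajectory(nCore = 12, nMobile = 6, nFrames = 5,
                             coreNoiseSigma = 0.2, mobileOffset = 3,
                             seed = 13)
  rep <- alignTrajectory(syn$trajectory, syn$reference, phi = 0.7,
                         options = smallOptions())
  dev <- deviationSeries(rep)
  expect_equal(dim(dev), c(18, 5))
  byHand <- sqrt(rowSums((rep@alignedCoords[, , 3] -
                            rep@referenceCoords)^2))
  expect_equal(unname(dev[, 3]), byHand, tolerance = 1e-12)
  expect_equal(unname(sqrt(rowMeans(dev^2))), unname(rmsf(rep)),
               tolerance = 1e-12)
  static <- alignTrajectory(staticTrajectory(), phi = 0.5,
                            options = smallOptions())
  expect_equal(max(deviationSeries(static)), 0, tolerance = 1e-9)
})

test_that("report tables carry the exact column contracts", {
  syn <- syntheticTrajectory(nCore = 10, nMobile = 4, nFrames = 2,
                             coreNoiseSigma = 0.1, mobileOffset = 3,
                             seed = 14)
  rep <- alignTrajectory(syn$trajectory, phi = 0.7, options = smallOptions())
  fframes <- tempfile(fileext = ".tsv")
  fatoms <- tempfile(fileext = ".tsv")
  fscan <- tempfile(fileext = ".tsv")
  writeFrameTable(rep, fframes)
  writeAtomTable(rep, fatoms)
  writePhiScanTable(phiScan(syn$trajectory, phiGrid = c(0.5, 0.8),
                            options = smallOptions()), fscan)
  expect_identical(strsplit(readLines(fframes, n = 1), "\t")[[1]],
                   c("frame", "rmsd_L", "rmsd_H", "rmsd_T", "iters",
                     "converged"))
  expect_identical(strsplit(readLines(fatoms, n = 1), "\t")[[1]],
                   c("atom_id", "rmsf", "low_fraction"))
  expect_identical(strsplit(readLines(fscan, n = 1), "\t")[[1]],
                   c("phi", "n_L", "mean_rmsd_L", "max_rmsd_L",
                     "mean_rmsd_H", "mean_rmsd_T"))
  # floats with 6 decimals
  expect_match(readLines(fframes)[2], "\t\\d+\\.\\d{6}\t")
})

test_that("roster mismatches between trajectory and reference are caught", {
  traj <- staticTrajectory(n = 10)
  expect_error(alignTrajectory(traj, reference = matrix(0, 4, 3), phi = 0.5,
                               options = smallOptions()),
               "correspondence")
  bad <- frameCoords(traj, 1)
  rownames(bad) <- paste0("x", 1:10)
  expect_error(alignTrajectory(traj, bad, phi = 0.5,
                               options = smallOptions()),
               "correspondence")
})
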