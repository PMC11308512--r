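test_that("atom-free frames give G identically zero", {
  ens <- emptyEnsemble(box = c(12, 12, 12), nFrames = 3)
  m <- computeIlsMap(ens, config = ilsConfig(gridSpacing = 3))
  expect_true(all(mapValues(m) == 0))
  expect_false(any(occludedMask(m)))
})

test_that("one frame, one orientation, one atom is the log-exp identity", {
  at <- makeAtoms(1, rminHalf = 2.0, epsilon = 0.11)
  ens <- FrameEnsemble(at, matrix(c(5, 5, 5), 1, 3), box = c(10, 10, 10))
  cfg <- ilsConfig(gridSpacing = 1, cutoff = 5, orientationCount = 1,
                   region = list(min = c(3, 3, 3), max = c(7, 7, 7)))
  m <- computeIlsMap(ens, singleSiteProbe(1.7, 0.12), config = cfg)
  cen <- voxelCenters(m, seq_len(prod(mapDims(m))))
  p <- singleSiteProbe(1.7, 0.12)
  for (v in seq_len(nrow(cen))) {
    dE <- probeInsertionEnergy(ens, p, cen[v, ], c(0, 0, 1), 5)
    if (is.finite(dE) && dE <= cfg$energyCap) {
      expect_equal(as.numeric(mapValues(m))[v], dE, tolerance = 1e-10)
      expect_false(as.logical(occludedMask(m))[v])
    } else {
      expect_true(as.logical(occludedMask(m))[v])
      expect_equal(as.numeric(mapValues(m))[v], cfg$displayCap)
    }
  }
})

test_that("the map equals a naive Widom oracle on LJ-fluid frames", {
  fl <- genLJFluid(nParticles = 25, boxLength = 12, nFrames = 6,
                   equilibrationSweeps = 60, samplingInterval = 2,
                   cutoff = 5.5, seed = 14)
  cfg <- ilsConfig(gridSpacing = 2, cutoff = 5.5, orientationCount = 5,
                   region = list(min = c(2, 2, 2), max = c(10, 10, 10)))
  m <- computeIlsMap(fl, o2Probe(), config = cfg)
  axes <- orientationAxes(generateOrientations(5))
  cen <- voxelCenters(m, seq_len(prod(mapDims(m))))
  ref <- refIlsValues(fl, o2Probe(), axes, cen, 300, 5.5, cfg$energyCap)
  got <- as.numeric(mapValues(m))
  occ <- as.logical(occludedMask(m))
  expect_identical(occ, ref$occluded)
  expect_lt(max(abs(got[!occ] - ref$G[!occ])), 1e-10)
})

test_that("frame duplication leaves G unchanged exactly", {
  fl <- genLJFluid(nParticles = 15, boxLength = 12, nFrames = 2,
                   equilibrationSweeps = 40, cutoff = 5, seed = 3)
  dup <- FrameEnsemble(atoms(fl), coords(fl)[, , c(1, 2, 1, 2)],
                       box = boxLengths(fl)[c(1, 2, 1, 2), ])
  cfg <- ilsConfig(gridSpacing = 3, cutoff = 5, orientationCount = 3)
  m1 <- computeIlsMap(fl, config = cfg)
  m2 <- computeIlsMap(dup, config = cfg)
  expect_equal(mapValues(m2), mapValues(m1), tolerance = 1e-13)
})

test_that("in the high-temperature limit G approaches the mean energy", {
  at <- makeAtoms(1, rminHalf = 2.0, epsilon = 0.1)
  co <- array(0, c(1, 3, 2))
  co[, , 1] <- c(5, 5, 5); co[, , 2] <- c(5.6, 5, 5)
  ens <- FrameEnsemble(at, co, box = c(10, 10, 10))
  p <- singleSiteProbe(1.7, 0.12)
  cfg <- ilsConfig(temperature = 1e9, gridSpacing = 1, cutoff = 5,
                   orientationCount = 1,
                   region = list(min = c(7, 5, 5), max = c(7, 5, 5)))
  m <- computeIlsMap(ens, p, config = cfg)
  e1 <- probeInsertionEnergy(ens, p, c(7, 5, 5), c(0, 0, 1), 5, frameIndex = 1)
  e2 <- probeInsertionEnergy(ens, p, c(7, 5, 5), c(0, 0, 1), 5, frameIndex = 2)
  expect_equal(as.numeric(mapValues(m)), mean(c(e1, e2)), tolerance = 1e-2)
})

test_that("region outside any box errors and zero frames error", {
  ens <- emptyEnsemble(box = c(0, 0, 0))
  expect_error(computeIlsMap(ens), "region")
})

test_that("bulk reference: pure solvent qualifies everywhere, uniform G = c", {
  wat <- FrameEnsemble(makeAtoms(2, resname = "HOH"),
                       matrix(c(1, 1, 1, 2, 2, 2), 2, 3, byrow = TRUE),
                       box = c(6, 6, 6))
  G <- array(1.75, c(3, 3, 3))
  pm <- asPmf(G)
  br <- bulkReference(pm, wat, minDistanceFromSolute = 12)
  expect_equal(br$voxelCount, 27)
  expect_equal(br$meanG, 1.75, tolerance = 1e-12)
  expect_equal(br$sd, 0, tolerance = 1e-12)
})

test_that("bulk reference excludes voxels near solute and can be empty", {
  at <- makeAtoms(1, resname = "LIG")
  sol <- FrameEnsemble(at, matrix(c(1, 1, 1), 1, 3), box = c(6, 6, 6))
  pm <- asPmf(array(0.5, c(3, 3, 3)))
  expect_error(bulkReference(pm, sol, minDistanceFromSolute = 12),
               "empty bulk region")
  # with a tiny exclusion all but the solute-adjacent voxels qualify
  br <- bulkReference(pm, sol, minDistanceFromSolute = 1.1)
  expect_lt(br$voxelCount, 27)
  expect_gt(br$voxelCount, 0)
})

test_that("bulk reference agrees with a direct Widom estimate", {
  wb <- genWaterBox(nMolecules = 64, nFrames = 30, equilibrationSweeps = 400,
                    samplingInterval = 5, cutoff = 5.5, seed = 21)
  L <- boxLengths(wb)[1, 1]
  cfg <- ilsConfig(cutoff = 5.5,
                   region = list(min = rep(4, 3), max = rep(round(L) - 4, 3)))
  m <- computeIlsMap(wb, config = cfg)
  br <- bulkReference(m, wb)
  # independent Widom insertion at random positions on the same frames
  set.seed(77)
  kT <- kBoltzmann * 300
  axes <- orientationAxes(generateOrientations(21))
  w <- 0; n <- 0
  for (f in seq_len(nFrames(wb))) {
    for (r in 1:20) {
      pos <- runif(3, 0, L)
      ax <- axes[sample(nrow(axes), 1), ]
      E <- probeInsertionEnergy(wb, o2Probe(), pos, ax, 5.5, frameIndex = f)
      n <- n + 1
      if (is.finite(E) && E <= cfg$energyCap) w <- w + exp(-E / kT)
    }
  }
  direct <- -kT * log(w / n)
  expect_lt(abs(br$meanG - direct), 2 * max(br$sd, 0.3))
})

test_that("occupancy map marks a fixed atom's voxel and rejects empties", {
  at <- makeAtoms(1)
  co <- array(rep(c(2, 2, 2), 4), c(1, 3, 4))
  ens <- FrameEnsemble(at, co, box = c(6, 6, 6))
  occ <- computeOccupancyMap(ens, "all", spacing = 2)
  v <- nearestVoxel(occ, c(2, 2, 2))
  vals <- as.numeric(mapValues(occ))
  expect_equal(vals[v], 1)
  expect_true(all(vals[-v] == 0))
  expect_error(computeOccupancyMap(ens, "resname HOH"), "empty selection")
})

test_that("ideal-gas occupancy matches the binomial expectation", {
  fl <- genLJFluid(nParticles = 40, boxLength = 10, epsilon = 0,
                   nFrames = 150, equilibrationSweeps = 20,
                   samplingInterval = 2, maxTranslation = 4, cutoff = 4,
                   seed = 30)
  occ <- computeOccupancyMap(fl, "all", spacing = 2)
  # interior voxels only: edge voxels have their capture volume clipped by
  # the box boundary, so the binomial expectation holds away from the edges
  vals <- array(mapValues(occ), mapDims(occ))
  inner <- as.numeric(vals[2:(dim(vals)[1] - 1), 2:(dim(vals)[2] - 1),
                           2:(dim(vals)[3] - 1)])
  pVox <- (2 / 10)^3
  expected <- 1 - (1 - pVox)^40
  mu <- mean(inner)
  se <- sd(inner) / sqrt(length(inner))
  expect_lt(abs(mu - expected), 3 * max(se, 0.01))
})
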