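# independent R implementation of the rigid-water molecule pair energy:
# molecule-based O-O minimum-image cutoff, O-O Lennard-Jones, site-site
# reaction-field Coulomb
refWaterPair <- function(I, J, L, rc) {
  qs <- c(-0.834, 0.417, 0.417)
  krf <- 1 / (2 * rc^3); crf <- 3 / (2 * rc)
  doo <- J[1, ] - I[1, ]
  shift <- -L * round(doo / L)
  oo <- doo + shift
  r2 <- sum(oo^2)
  if (r2 >= rc^2) return(0)
  e <- refLj(1.7682, 0.1521, 1.7682, 0.1521, sqrt(r2))
  for (a in 1:3) for (b in 1:3) {
    d <- J[b, ] + shift - I[a, ]
    rr2 <- sum(d^2)
    e <- e + 332.0636 * qs[a] * qs[b] * (1 / sqrt(rr2) + krf * rr2 - crf)
  }
  e
}

# rigid TIP3P-geometry water with O at `o`, arbitrary orientation
rigidWater <- function(o, seed) {
  set.seed(seed)
  rOH <- 0.9572; half <- 104.52 / 2 * pi / 180
  h1 <- c(rOH * sin(half), rOH * cos(half), 0)
  h2 <- c(-rOH * sin(half), rOH * cos(half), 0)
  q <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(rbind(c(0, 0, 0), h1, h2) %*% q, 2, o, "+")
}

test_that("the exposed water pair energy matches an independent R sum", {
  L <- 12; rc <- 5.5
  for (k in 1:10) {
    I <- rigidWater(runif(3, 0, L), seed = k)
    J <- rigidWater(runif(3, 0, L), seed = 100 + k)
    expect_equal(waterPairEnergy(I, J, L, rc), refWaterPair(I, J, L, rc),
                 tolerance = 1e-8)
  }
  # beyond the molecule cutoff the interaction is exactly zero
  I <- rigidWater(c(1, 1, 1), seed = 3)
  J <- rigidWater(c(1 + 5.6, 1, 1), seed = 4)
  expect_equal(waterPairEnergy(I, J, 40, 5.5), 0)
})

test_that("water sampling is seeded, rigid and reasonably accepted", {
  wb1 <- genWaterBox(nMolecules = 32, nFrames = 5, equilibrationSweeps = 100,
                     samplingInterval = 2, cutoff = 4.5, seed = 42)
  wb2 <- genWaterBox(nMolecules = 32, nFrames = 5, equilibrationSweeps = 100,
                     samplingInterval = 2, cutoff = 4.5, seed = 42)
  expect_identical(coords(wb1), coords(wb2))            # bit-identical
  acc <- attr(wb1, "acceptance")
  expect_gt(acc, 0.2); expect_lt(acc, 0.8)
  # rigid geometry in every frame
  for (f in c(1, 5)) {
    X <- coords(wb1, f)
    o <- X[seq(1, 96, 3), ]; h1 <- X[seq(2, 96, 3), ]; h2 <- X[seq(3, 96, 3), ]
    d1 <- sqrt(rowSums((h1 - o)^2)); d2 <- sqrt(rowSums((h2 - o)^2))
    expect_lt(max(abs(c(d1, d2) - 0.9572)), 1e-8)
    cosA <- rowSums((h1 - o) * (h2 - o)) / (d1 * d2)
    expect_lt(max(abs(acos(cosA) * 180 / pi - 104.52)), 1e-6)
  }
  expect_error(genWaterBox(nMolecules = 8, cutoff = 9), "half the box")
})

test_that("the ideal-gas limit of the LJ fluid is spatially uniform", {
  fl <- genLJFluid(nParticles = 30, boxLength = 10, epsilon = 0, nFrames = 200,
                   equilibrationSweeps = 10, samplingInterval = 1,
                   maxTranslation = 5, cutoff = 4, seed = 99)
  x <- as.numeric(coords(fl)[, 1, ])
  ct <- table(cut(x %% 10, seq(0, 10, 2.5)))
  p <- chisq.test(ct)$p.value
  expect_gt(p, 0.01)
  expect_identical(coords(fl),
                   coords(genLJFluid(nParticles = 30, boxLength = 10,
                                     epsilon = 0, nFrames = 200,
                                     equilibrationSweeps = 10,
                                     samplingInterval = 1, maxTranslation = 5,
                                     cutoff = 4, seed = 99)))
  expect_error(genLJFluid(nParticles = 2000, boxLength = 10), "density")
})

test_that("the cavity is empty at its center and the channel is open", {
  cav <- genCavityChannel(cavityRadius = 6, channelRadius = 3.5,
                          boxLength = 20, wallSpacing = 1.6)
  expect_true(all(atoms(cav)$resname == "WAL"))
  ctr <- rep(10, 3)
  # no wall atom inside the cavity sphere
  d <- sqrt(rowSums(sweep(coords(cav, 1), 2, ctr)^2))
  expect_true(all(d > 6))
  # probe at the center: beyond the cutoff from every wall atom -> G ~ 0
  cfg <- ilsConfig(gridSpacing = 1, cutoff = 5,
                   region = list(min = ctr, max = ctr))
  m <- computeIlsMap(cav, config = cfg)
  expect_lt(abs(as.numeric(mapValues(m))), 1e-12)
  expect_error(genCavityChannel(wallSpacing = 4), "watertight")
})

test_that("a channel connects the cavity to the boundary; sealed does not", {
  open <- genCavityChannel(cavityRadius = 6, channelRadius = 4.7,
                           boxLength = 20, wallSpacing = 1.6)
  sealed <- genCavityChannel(cavityRadius = 6, channelRadius = 4.7,
                             boxLength = 20, wallSpacing = 1.6,
                             channelAxes = list())
  cfg <- ilsConfig(gridSpacing = 1.5, cutoff = 6,
                   region = list(min = c(0, 0, 0), max = c(20, 20, 20)))
  site <- rep(10, 3)
  mo <- computeIlsMap(open, config = cfg)
  gpo <- minimaxBarrier(mo, nearestVoxel(mo, site), "boundary")
  expect_true(gpo$connected)
  expect_lt(gpo$bottleneck, 1)                          # low-barrier channel
  ms <- computeIlsMap(sealed, config = cfg)
  gps <- minimaxBarrier(ms, nearestVoxel(ms, site), "boundary")
  expect_false(gps$connected)
  # exactly one channel at a modest isovalue
  ch <- enumeratePathways(mo, 1, nearestVoxel(mo, site))
  expect_length(ch, 1)
})

test_that("a frozen latent series pins every frame to endpoint A", {
  lt <- genLoopTrajectory(nFrames = 4, noiseSd = 0, latent = rep(0, 4),
                          seed = 2, includeCore = FALSE)
  co <- coords(lt$ensemble)
  for (f in 2:4) expect_identical(co[, , f], co[, , 1])
  expect_equal(lt$groundTruth$s, rep(0, 4))
  expect_true(all(lt$groundTruth$basin == "A"))
  # latent = 1 gives endpoint B, at interEndpointRmsd from A
  ltB <- genLoopTrajectory(nFrames = 2, noiseSd = 0, latent = rep(1, 2),
                           seed = 2, includeCore = FALSE)
  rmsd <- sqrt(mean(rowSums((coords(ltB$ensemble, 1) -
                               coords(lt$ensemble, 1))^2)))
  expect_equal(rmsd, lt$groundTruth$interEndpointRmsd, tolerance = 1e-10)
})

test_that("loop trajectories carry core plus loop with stable core", {
  lt <- genLoopTrajectory(nFrames = 6, tauTrue = 2, noiseSd = 0, seed = 5)
  a <- atoms(lt$ensemble)
  expect_equal(sum(a$resname == "COR"), 40)
  expect_equal(sum(a$resname == "GLY"), 20)
  expect_equal(sort(unique(a$resid[a$resname == "GLY"])), 342:361)
  core <- which(a$resname == "COR")
  for (f in 2:6)
    expect_identical(coords(lt$ensemble, f)[core, ],
                     coords(lt$ensemble, 1)[core, ])
})

test_that("the ideal helix has the canonical rise; extended chains stretch", {
  h <- genIdealHelix(15)
  ca <- match(selectAtoms(h, "name CA"), atoms(h)$index)
  X <- coords(h, 1)[ca, ]
  axisLen <- sqrt(sum((X[15, ] - X[1, ])^2))
  rise <- axisLen / 14
  expect_gt(rise, 1.4); expect_lt(rise, 1.7)
  ext <- genIdealHelix(15, phi = 180, psi = 180)
  Xe <- coords(ext, 1)[match(selectAtoms(ext, "name CA"), atoms(ext)$index), ]
  endToEnd <- sqrt(sum((Xe[15, ] - Xe[1, ])^2))
  expect_gt(endToEnd, 3.2 * 14)                         # ~3.5 A per residue
  one <- genIdealHelix(1)
  expect_equal(nAtoms(one), 4)
  expect_error(genIdealHelix(0), "nResidues")
})
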