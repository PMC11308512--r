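test_that("a one-atom PDB parses to its exact coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPdb(f, 1.0, 2.0, 3.0)
  ens <- loadStructure(f)
  expect_equal(nFrames(ens), 1)
  expect_equal(nAtoms(ens), 1)
  expect_equal(as.numeric(coords(ens, 1)), c(1, 2, 3))
  expect_equal(atoms(ens)$name, "CA")
  expect_equal(atoms(ens)$resid, 1)
})

test_that("write then load round trips coordinates to PDB precision", {
  wb <- genWaterBox(nMolecules = 34, nFrames = 2, equilibrationSweeps = 30,
                    samplingInterval = 2, cutoff = 4.5, seed = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(wb, f)
  back <- loadTrajectory(f, f, zeroFallback = TRUE)
  expect_equal(nAtoms(back), nAtoms(wb))
  expect_equal(nFrames(back), nFrames(wb))
  expect_lt(max(abs(coords(back) - coords(wb))), 1e-3 + 1e-12)
  expect_equal(boxLengths(back)[1, ], boxLengths(wb)[1, ], tolerance = 1e-3)
})

test_that("unmapped atoms error without fallback and zero-fill with it", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPdb(f)
  tabf <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(residue_name = "HOH", atom_name = "O",
                       rmin_half = 1.7682, epsilon = 0.1521, charge = -0.834),
            tabf, row.names = FALSE)
  tab <- readParameterTable(tabf)
  expect_error(loadStructure(f, tab), "missing from parameter table")
  ens <- loadStructure(f, tab, zeroFallback = TRUE)
  expect_equal(atoms(ens)$epsilon, 0)
})

test_that("parameter wildcard rows match any residue", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPdb(f)
  tabf <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(residue_name = "*", atom_name = "CA",
                       rmin_half = 2.275, epsilon = 0.02, charge = 0.1),
            tabf, row.names = FALSE)
  ens <- loadStructure(f, readParameterTable(tabf))
  expect_equal(atoms(ens)$rminHalf, 2.275)
  expect_equal(atoms(ens)$epsilon, 0.02)
})

test_that("trajectory stride selects every stride-th frame in order", {
  wb <- genWaterBox(nMolecules = 8, nFrames = 10, equilibrationSweeps = 20,
                    samplingInterval = 1, cutoff = 2.5, seed = 6)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(wb, f)
  all10 <- loadTrajectory(f, f, stride = 1, zeroFallback = TRUE)
  expect_equal(nFrames(all10), 10)
  s3 <- loadTrajectory(f, f, stride = 3, zeroFallback = TRUE)
  expect_equal(nFrames(s3), 4)                    # frames 1, 4, 7, 10
  expect_equal(coords(s3, 2), coords(all10, 4))
  expect_equal(coords(s3, 4), coords(all10, 10))
  expect_equal(frameInterval(s3), frameInterval(all10) * 3)
})

test_that("atom-count mismatch between topology and trajectory errors", {
  wb5 <- genWaterBox(nMolecules = 5, nFrames = 2, equilibrationSweeps = 10,
                     samplingInterval = 1, cutoff = 2.2, seed = 1)
  wb6 <- genWaterBox(nMolecules = 6, nFrames = 2, equilibrationSweeps = 10,
                     samplingInterval = 1, cutoff = 2.3, seed = 1)
  f5 <- withr::local_tempfile(fileext = ".pdb")
  f6 <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(wb5, f5); writeEnsemblePDB(wb6, f6)
  expect_error(loadTrajectory(f5, f6, zeroFallback = TRUE),
               "atom-count mismatch")
})

test_that("XTC trajectories are rejected with a clear message", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPdb(f)
  expect_error(loadTrajectory(f, "anything.xtc"), "XTC")
})

test_that("selection language finds the loop C-alphas per chain", {
  prot <- twoChainProtein()
  sel <- selectAtoms(prot, "name CA and resid 342-361")
  expect_length(sel, 40)                               # 20 per chain
  a <- atoms(prot)
  expect_true(all(a$resid[match(sel, a$index)] %in% 342:361))
  selA <- selectAtoms(prot, "name CA and resid 342-361 and chain A")
  expect_length(selA, 20)
})

test_that("selection trivial cases and operator laws hold", {
  prot <- twoChainProtein()
  expect_length(selectAtoms(prot, "resname HOH"), 0)
  expect_equal(selectAtoms(prot, "name CA or name CA"),
               selectAtoms(prot, "name CA"))
  expect_equal(selectAtoms(prot, "chain A and resid 350"),
               selectAtoms(prot, "resid 350 and chain A"))
  expect_equal(selectAtoms(prot, "not (chain A or chain B)"), integer(0))
  expect_equal(selectAtoms(prot, "all"), atoms(prot)$index)
})

test_that("malformed selections raise errors", {
  prot <- twoChainProtein()
  expect_error(selectAtoms(prot, "name"), "malformed")
  expect_error(selectAtoms(prot, "bogus CA"), "malformed")
  expect_error(selectAtoms(prot, "(name CA"), "malformed")
  expect_error(selectAtoms(prot, "resid x-y"), "malformed")
})

test_that("a 2x2x2 zero map round trips identically through OpenDX", {
  m <- VolumetricMap(c(0, 0, 0), 1, c(2, 2, 2), array(0, c(2, 2, 2)))
  f <- withr::local_tempfile(fileext = ".dx")
  writeVolumetricMap(m, f)
  back <- readVolumetricMap(f)
  expect_equal(mapValues(back), mapValues(m))
  expect_equal(mapOrigin(back), mapOrigin(m))
  expect_equal(mapDims(back), mapDims(m))
})

test_that("DX round trip preserves metadata exactly and values to 1e-6", {
  set.seed(31)
  v <- array(rnorm(3 * 4 * 5, sd = 3), c(3, 4, 5))
  m <- VolumetricMap(c(-5, -5, -5), 1.0, c(3, 4, 5), v)
  f <- withr::local_tempfile(fileext = ".dx")
  writeVolumetricMap(m, f)
  back <- readVolumetricMap(f)
  expect_identical(mapOrigin(back), c(-5, -5, -5))
  expect_identical(mapSpacing(back), 1.0)
  expect_identical(mapDims(back), as.integer(c(3, 4, 5)))
  expect_lt(max(abs(mapValues(back) - v)), 1e-6)
})

test_that("malformed DX files raise errors", {
  f <- withr::local_tempfile(fileext = ".dx")
  writeLines("not a dx file", f)
  expect_error(readVolumetricMap(f), "malformed DX header")
  m <- VolumetricMap(c(0, 0, 0), 1, c(2, 2, 2), array(1, c(2, 2, 2)))
  writeVolumetricMap(m, f)
  lines <- readLines(f)
  writeLines(lines[-length(lines) + 1], f)  # drop a data line
  truncated <- sub("counts 2 2 2", "counts 2 2 2", lines)
  dataStart <- grep("data follows", lines)
  writeLines(c(lines[1:dataStart], lines[dataStart + 1]), f)  # 3 of 8 values
  expect_error(readVolumetricMap(f), "mismatch")
})
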