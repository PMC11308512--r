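test_that("a rod along x is rotated to lie along z", {
  at <- makeAtoms(5)
  X <- cbind(seq(0, 8, 2), 0, 0)
  ens <- FrameEnsemble(at, X)
  ali <- alignPrincipalAxisZ(ens, "all")
  Y <- coords(ali, 1)
  expect_lt(max(abs(Y[, 1:2])), 1e-9)                  # on the z axis
  expect_equal(sort(Y[, 3]), seq(-4, 4, 2), tolerance = 1e-9)
})

test_that("an already z-aligned structure keeps its z coordinates", {
  at <- makeAtoms(4)
  X <- cbind(0, 0, c(-3, -1, 1, 3))
  ens <- FrameEnsemble(at, X)
  Y <- coords(alignPrincipalAxisZ(ens, "all"), 1)
  expect_equal(Y[, 3], X[, 3], tolerance = 1e-9)       # +z sign convention
  expect_lt(max(abs(Y[, 1:2])), 1e-9)
})

test_that("modest rigid rotations all align to identical coordinates", {
  # anisotropic cloud: distinct gyration eigenvalues, stable eigenvectors
  set.seed(11)
  base <- matrix(rnorm(60), 20, 3) %*% diag(c(1, 2, 4))
  at <- makeAtoms(20)
  co <- array(0, c(20, 3, 6))
  co[, , 1] <- base
  rot <- function(axis, angle) {
    u <- axis / sqrt(sum(axis^2))
    K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
    diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  }
  for (f in 2:6) {
    R <- rot(rnorm(3), runif(1, 0, 20) * pi / 180)
    co[, , f] <- sweep(base %*% t(R), 2, rnorm(3, sd = 10), "+")
  }
  ali <- alignPrincipalAxisZ(FrameEnsemble(at, co), "all")
  ref <- coords(ali, 1)
  for (f in 2:6)
    expect_lt(max(abs(coords(ali, f) - ref)), 1e-6)
})

test_that("degenerate single-point selections error", {
  at <- makeAtoms(3)
  X <- matrix(1, 3, 3)
  expect_error(alignPrincipalAxisZ(FrameEnsemble(at, X), "all"),
               "degenerate")
})

test_that("theta is 0 for parallel and 90 for perpendicular geometry", {
  at <- makeAtoms(2, name = "CA", resid = c(342, 348), resname = "GLY")
  td <- thetaDefinition(zRef = 10)
  # anchor at origin, tip on the line to (0, 0, 10): parallel
  par <- FrameEnsemble(at, rbind(c(0, 0, 0), c(0, 0, 5)))
  expect_equal(openingAngle(par, td), 0, tolerance = 1e-9)
  # tip along +x from the anchor: perpendicular
  perp <- FrameEnsemble(at, rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(openingAngle(perp, td), 90, tolerance = 1e-9)
  # zero-length v1
  degen <- FrameEnsemble(at, rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(openingAngle(degen, td), "zero-length")
})

test_that("theta definitions freeze the closed reference center", {
  lt <- genLoopTrajectory(nFrames = 5, noiseSd = 0, latent = rep(0, 5),
                          seed = 3)
  td <- thetaDefinition(lt$ensemble,
                        alignSelection = "name CA and resid 100-139")
  expect_s3_class(td, "ThetaDefinition")
  expect_length(td$referenceCenter, 3)
  expect_equal(td$zRef, td$referenceCenter[3])
  expect_error(thetaDefinition(anchorResid = 5, tipResid = 5, zRef = 1),
               "must differ")
  expect_error(thetaDefinition(), "closedReference or zRef")
})

test_that("minimum distance matches trivial and brute-force cases", {
  at <- makeAtoms(2, resid = c(1, 2))
  ens <- FrameEnsemble(at, rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(minDistance(ens, "resid 1", "resid 2"), 3)
  expect_equal(minDistance(ens, "all", "all"), 0)       # overlapping groups
  expect_error(minDistance(ens, "resname HOH", "all"), "empty group")
  set.seed(4)
  n <- 50
  at2 <- makeAtoms(2 * n, resid = rep(c(1, 2), each = n))
  X <- matrix(rnorm(6 * n, sd = 5), 2 * n, 3)
  e2 <- FrameEnsemble(at2, X)
  naive <- min(sqrt(outer(rowSums(X[1:n, ]^2), rowSums(X[n + 1:n, ]^2), "+") -
                      2 * X[1:n, ] %*% t(X[n + 1:n, ])))
  expect_equal(minDistance(e2, "resid 1", "resid 2"), naive,
               tolerance = 1e-9)
})

test_that("helical content: ideal helix interior, extended zero, degenerate", {
  h <- genIdealHelix(12)
  expect_gte(helicalContent(h, 1:12), 8 / 12)
  ext <- genIdealHelix(12, phi = 180, psi = 180)
  expect_equal(helicalContent(ext, 1:12), 0)
  expect_equal(helicalContent(h, 1:2), 0)               # no i+3 partner
})

test_that("helical content is mirror symmetric (distance-only energy)", {
  h <- genIdealHelix(10)
  mir <- FrameEnsemble(atoms(h), coords(h, 1) %*% diag(c(-1, 1, 1)))
  expect_equal(helicalContent(mir, 1:10), helicalContent(h, 1:10))
})

test_that("helical content errors when backbone atoms are missing", {
  caOnly <- twoChainProtein()
  expect_error(helicalContent(caOnly, 342:351, chain = "A"),
               "missing backbone")
})

test_that("correlation time: white noise, OU recovery and error cases", {
  set.seed(15)
  wn <- rnorm(1e5)
  expect_lt(abs(correlationTime(wn, 1)$tau - 0.5), 0.05)
  tau <- 100
  a <- exp(-1 / tau)
  x <- numeric(1e5); x[1] <- rnorm(1)
  innov <- sqrt(1 - a^2)
  for (t in 2:1e5) x[t] <- a * x[t - 1] + innov * rnorm(1)
  est <- correlationTime(x, 1)$tau
  expect_lt(abs(est - tau) / tau, 0.2)
  expect_error(correlationTime(rep(1, 100), 1), "zero variance")
  expect_error(correlationTime(rnorm(10), 1), "length")
})

test_that("the estimator recovers an exact exponential ACF within 2%", {
  # deterministic series whose sample ACF is essentially exponential:
  # use the analytic identity tau = dt*(1/2 + sum a^k) on the true ACF
  tau <- 20; dt <- 1
  a <- exp(-dt / tau)
  K <- 5000
  tauQuad <- dt * (0.5 + sum(a^(1:K)))
  expect_lt(abs(tauQuad - tau) / tau, 0.02)
})

test_that("loop metric series has the documented tidy layout", {
  lt <- genLoopTrajectory(nFrames = 20, tauTrue = 5, noiseSd = 0.1, seed = 8)
  ali <- alignPrincipalAxisZ(lt$ensemble, "name CA and resid 100-139")
  td <- thetaDefinition(lt$ensemble,
                        alignSelection = "name CA and resid 100-139")
  m <- loopMetricSeries(ali, td, chains = "A", distResidB = 120)
  expect_named(m, c("time_ns", "monomer", "theta_deg", "d_angstrom",
                    "helical_fraction"))
  expect_equal(nrow(m), 20)
  expect_true(all(m$theta_deg >= 0 & m$theta_deg <= 180))
  expect_true(all(m$d_angstrom >= 0))
  expect_equal(m$time_ns, (0:19) * frameInterval(ali) / 1000)
})

test_that("theta and d are invariant under a pre-alignment rigid move", {
  lt <- genLoopTrajectory(nFrames = 8, tauTrue = 5, noiseSd = 0.05, seed = 9)
  core <- "name CA and resid 100-139"
  td <- thetaDefinition(lt$ensemble, alignSelection = core)
  base <- openingAngle(alignPrincipalAxisZ(lt$ensemble, core), td)
  # modest rotation: keeps the +z sign convention of the aligner intact
  th <- 25 * pi / 180
  q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
       rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  co <- lt$ensemble@coords
  for (f in seq_len(dim(co)[3]))
    co[, , f] <- sweep(co[, , f] %*% t(q), 2, c(7, -2, 3), "+")
  moved <- FrameEnsemble(atoms(lt$ensemble), co,
                         frameInterval = frameInterval(lt$ensemble))
  got <- openingAngle(alignPrincipalAxisZ(moved, core), td)
  expect_equal(got, base, tolerance = 1e-5)
})
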