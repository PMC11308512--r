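# Seeded generators producing inputs with the statistical structure each
# pipeline stage assumes: rigid-water boxes, Lennard-Jones fluids,
# cavity-channel wall systems, two-basin loop trajectories and ideal
# backbone helices. Every generator is a pure function of its arguments
# (seed included).

# TIP3P-style rigid three-site water
.WATER <- list(qO = -0.834, qH = 0.417, rminHalfO = 1.7682, epsO = 0.1521,
               rOH = 0.9572, angHOH = 104.52, massMol = 18.0153)

#' Rigid-water box sampled by Metropolis Monte Carlo
#'
#' Three-site rigid water (charges -0.834/+0.417 e, O-site LJ
#' Rmin/2 = 1.7682 A, eps = 0.1521 kcal/mol, r(OH) = 0.9572 A,
#' HOH = 104.52 deg) at fixed density in a cubic periodic box, sampled by
#' rigid translations and rotations. Electrostatics use a molecule-based
#' cutoff on the O-O distance with an infinite-dielectric reaction-field
#' correction; O-O Lennard-Jones is truncated at the same cutoff. Frames are
#' emitted every \code{samplingInterval} sweeps after equilibration and the
#' whole run is reproducible from \code{seed}.
#'
#' @param nMolecules number of waters (>= 2; default 216, an ~18.6 A cube at
#'   0.997 g/cm3, large enough for a 9 A probe cutoff under minimum image).
#' @param temperature Kelvin.
#' @param density g/cm3 (fixed; no barostat).
#' @param nFrames production frames to emit.
#' @param equilibrationSweeps sweeps (1 sweep = nMolecules single-molecule
#'   moves) discarded before sampling.
#' @param samplingInterval sweeps between emitted frames.
#' @param maxTranslation,maxRotation move sizes (A, degrees); defaults give
#'   acceptance in the 0.2-0.7 band.
#' @param cutoff molecule-based interaction cutoff, A (must be < half box).
#' @param seed RNG seed.
#' @return A \linkS4class{FrameEnsemble} (resname HOH, atoms O/H1/H2 per
#'   molecule) with attribute \code{"acceptance"}.
#' @export
genWaterBox <- function(nMolecules = 216, temperature = 300, density = 0.997,
                        nFrames = 100, equilibrationSweeps = 5000,
                        samplingInterval = 10, maxTranslation = 0.18,
                        maxRotation = 18, cutoff = 9, seed = 1) {
  stopifnot(nMolecules >= 2, density > 0, nFrames >= 1)
  w <- .WATER
  L <- (nMolecules * w$massMol / (density * 0.6022140857))^(1 / 3)
  if (cutoff >= L / 2)
    stop(sprintf("cutoff %.1f A must be below half the box length (%.2f A)",
                 cutoff, L / 2))
  set.seed(seed)
  res <- .waterBoxMCCpp(nMolecules, L, temperature, equilibrationSweeps,
                        nFrames, samplingInterval, maxTranslation,
                        maxRotation, cutoff, w$rminHalfO, w$epsO,
                        c(w$qO, w$qH, w$qH), w$rOH, w$angHOH)
  nAt <- 3L * nMolecules
  co <- array(res$frames, c(nAt, 3, nFrames))
  atoms <- data.frame(
    index = seq_len(nAt) - 1L,
    name = rep(c("O", "H1", "H2"), nMolecules),
    resname = "HOH",
    resid = rep(seq_len(nMolecules), each = 3),
    chain = "W",
    element = rep(c("O", "H", "H"), nMolecules),
    rminHalf = rep(c(w$rminHalfO, NA_real_, NA_real_), nMolecules),
    epsilon = rep(c(w$epsO, 0, 0), nMolecules),
    charge = rep(c(w$qO, w$qH, w$qH), nMolecules),
    stringsAsFactors = FALSE)
  ens <- FrameEnsemble(atoms, co, box = c(L, L, L),
                       frameInterval = samplingInterval)
  attr(ens, "acceptance") <- res$acceptance
  ens
}

#' Total pair energy of two rigid waters (oracle hook)
#'
#' The exact molecule-pair energy used by the water sampler (LJ + reaction-
#' field Coulomb, molecule-based cutoff), exposed so tests can compare it to
#' an independent site-site sum.
#'
#' @param sitesI,sitesJ 3x3 matrices (rows O, H1, H2), Angstrom.
#' @param boxL cubic box length.
#' @param cutoff molecule cutoff, A.
#' @return Energy, kcal/mol.
#' @export
waterPairEnergy <- function(sitesI, sitesJ, boxL, cutoff = 9) {
  w <- .WATER
  .waterPairEnergyCpp(sitesI, sitesJ, boxL, cutoff, w$rminHalfO, w$epsO,
                      c(w$qO, w$qH, w$qH))
}

#' Lennard-Jones fluid sampled by Metropolis Monte Carlo
#'
#' Single-site LJ particles in a cubic periodic box; the oracle substrate for
#' checking the map engine against naive Widom insertion. With epsilon = 0
#' the dynamics reduce to an ideal gas and positions are uniform.
#'
#' @param nParticles particle count.
#' @param boxLength cubic box length, A.
#' @param rminHalf,epsilon LJ parameters (CHARMM convention).
#' @param temperature Kelvin.
#' @param nFrames,equilibrationSweeps,samplingInterval sampling schedule.
#' @param maxTranslation move size, A.
#' @param cutoff pair cutoff, A.
#' @param seed RNG seed.
#' @return A \linkS4class{FrameEnsemble} (resname LJP) with attribute
#'   \code{"acceptance"}.
#' @export
genLJFluid <- function(nParticles = 50, boxLength = 15, rminHalf = 1.7682,
                       epsilon = 0.1521, temperature = 300, nFrames = 100,
                       equilibrationSweeps = 500, samplingInterval = 5,
                       maxTranslation = 1.0, cutoff = 7, seed = 1) {
  sigma <- 2 * rminHalf / 2^(1 / 6)
  rho <- nParticles * sigma^3 / boxLength^3
  # the density guard only applies to interacting particles; an ideal gas
  # (epsilon = 0) samples uniformly at any density
  if (abs(epsilon) > 0 && rho >= 0.9)
    stop(sprintf("reduced density %.2f must be < 0.9", rho))
  set.seed(seed)
  res <- .ljFluidMCCpp(nParticles, boxLength, rminHalf, abs(epsilon),
                       temperature, equilibrationSweeps, nFrames,
                       samplingInterval, maxTranslation, cutoff)
  co <- array(res$frames, c(nParticles, 3, nFrames))
  atoms <- data.frame(index = seq_len(nParticles) - 1L, name = "AR",
                      resname = "LJP", resid = seq_len(nParticles),
                      chain = "X", element = "AR", rminHalf = rminHalf,
                      epsilon = abs(epsilon), charge = 0,
                      stringsAsFactors = FALSE)
  ens <- FrameEnsemble(atoms, co, box = rep(boxLength, 3),
                       frameInterval = samplingInterval)
  attr(ens, "acceptance") <- res$acceptance
  ens
}

#' Cavity-plus-channel wall system
#'
#' A static frame of wall pseudo-atoms filling the box except for a central
#' spherical cavity and one (or more) cylindrical channels bored from the
#' cavity to the box boundary -- a geometric stand-in for an active-site
#' pocket with gas entrance pathways. Wall atoms sit on a cubic lattice of
#' pitch \code{wallSpacing}, which must be below the probe contact distance
#' so the walls are watertight. Pseudo-residue labels partition the wall
#' into ~4 A patches so pathway-lining analysis has residues to report.
#'
#' @param cavityRadius A (cavity carved around the box center).
#' @param channelRadius A (< cavityRadius).
#' @param channelAxes list of direction vectors, one channel each, bored from
#'   the center toward the boundary.
#' @param boxLength cubic box length, A.
#' @param wallSpacing lattice pitch, A.
#' @param wallRminHalf,wallEps wall-site LJ parameters.
#' @param probeContact probe-wall contact distance used for the
#'   watertightness check (default the O2 site against the default wall).
#' @return A single-frame \linkS4class{FrameEnsemble} (resname WAL).
#' @export
genCavityChannel <- function(cavityRadius = 7, channelRadius = 4.7,
                             channelAxes = list(c(1, 0, 0)), boxLength = 26,
                             wallSpacing = 1.5, wallRminHalf = 2.0,
                             wallEps = 0.1,
                             probeContact = wallRminHalf + 1.7) {
  stopifnot(channelRadius < cavityRadius, wallSpacing > 0)
  if (wallSpacing >= probeContact)
    stop("wall spacing must be below the probe contact distance (watertight)")
  n1 <- floor(boxLength / wallSpacing)
  g <- seq(0.5, n1 - 0.5) * wallSpacing
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  ctr <- rep(boxLength / 2, 3)
  rel <- sweep(pts, 2, ctr)
  keep <- rowSums(rel^2) > cavityRadius^2
  for (ax in channelAxes) {
    u <- ax / sqrt(sum(ax^2))
    t <- rel %*% u
    radial2 <- rowSums(rel^2) - as.numeric(t)^2
    keep <- keep & !(t > 0 & radial2 < channelRadius^2)
  }
  pts <- pts[keep, , drop = FALSE]
  # ~4 A patches as pseudo-residues
  patch <- floor(pts / 4)
  resid <- as.integer(factor(paste(patch[, 1], patch[, 2], patch[, 3])))
  n <- nrow(pts)
  atoms <- data.frame(index = seq_len(n) - 1L, name = "WA", resname = "WAL",
                      resid = resid, chain = "X", element = "C",
                      rminHalf = wallRminHalf, epsilon = wallEps, charge = 0,
                      stringsAsFactors = FALSE)
  # non-periodic: a periodic image of the wall would seal the channel exit
  FrameEnsemble(atoms, pts, box = c(0, 0, 0), frameInterval = 0)
}

# latent coordinate dynamics: exact OU step (wellDepth = 0, no boundaries,
# so the ACF is exactly exponential) or overdamped double-well Langevin
# reflected into [0, 1]
.simulateLatent <- function(nFrames, tau, stationarySd, mean = 0.5,
                            wellDepth = 0, start = mean) {
  x <- numeric(nFrames)
  x[1] <- start
  a <- exp(-1 / tau)
  innov <- stationarySd * sqrt(1 - a^2)
  reflect <- function(v) {
    while (v < 0 || v > 1) {
      if (v < 0) v <- -v
      if (v > 1) v <- 2 - v
    }
    v
  }
  for (t in 2:nFrames) {
    if (wellDepth == 0) {
      x[t] <- mean + (x[t - 1] - mean) * a + innov * stats::rnorm(1)
    } else {
      u <- 2 * x[t - 1] - 1
      drift <- (-(x[t - 1] - mean) + wellDepth * u * (1 - u^2)) / tau
      x[t] <- reflect(x[t - 1] + drift +
                        stationarySd * sqrt(2 / tau) * stats::rnorm(1))
    }
  }
  x
}

#' Two-basin loop trajectory with prescribed relaxation time
#'
#' Frames combine a rigid core scaffold (a 40-residue C-alpha helix oriented
#' along z, resid 100-139, the stand-in for the stable enzyme core that
#' alignment and RMSD fitting should use) with a mobile 20-residue C-alpha
#' loop (resid 342-361) interpolating between two endpoint conformations,
#' \code{A + s_t (B - A)}, plus per-atom Gaussian thermal noise on every
#' atom. The latent coordinate s_t follows an Ornstein-Uhlenbeck process of
#' relaxation time \code{tauTrue} (in frames); with \code{wellDepth = 0} it
#' is unbounded and its ACF is exactly exponential, so tau is recoverable. A
#' positive \code{wellDepth} switches to a double-well Langevin reflected
#' into [0, 1], concentrating occupancy in two basins near the endpoints
#' (the open/closed gating picture) at the cost of the analytic ACF.
#'
#' Because the core is rigid, selections on resid 100-139 give a stable
#' reference frame: use them for \code{\link{alignPrincipalAxisZ}} and as
#' \code{fitSelection} in PCA/clustering, exactly as one fits on the enzyme
#' core before measuring loop motion.
#'
#' @param endpointA,endpointB loop-only \code{[nAtoms, 3]} conformations
#'   (same atom count); NULL builds the default loop helix attached near the
#'   core top and a 70-degree rigid swing of it about its anchor.
#' @param tauTrue OU relaxation time in frames (>= 1).
#' @param noiseSd per-atom thermal noise sd, A.
#' @param nFrames frames to generate.
#' @param dt ns per frame (metadata).
#' @param stationarySd,wellDepth latent-process shape (see above).
#' @param latent optional explicit latent series (length \code{nFrames},
#'   overrides the simulated process; e.g. a two-component mixture for
#'   cluster-recovery tests).
#' @param includeCore set FALSE for a loop-only ensemble.
#' @param seed RNG seed.
#' @return list: \code{ensemble} (a \linkS4class{FrameEnsemble}),
#'   \code{groundTruth} (list: \code{s}, \code{tauTrue}, \code{basin}
#'   with labels "A"/"B" split at s = 0.5, \code{interEndpointRmsd} over
#'   the loop atoms).
#' @export
genLoopTrajectory <- function(endpointA = NULL, endpointB = NULL,
                              tauTrue = 20, noiseSd = 0.3, nFrames = 2000,
                              dt = 0.01, stationarySd = 0.3, wellDepth = 0,
                              latent = NULL, includeCore = TRUE, seed = 1) {
  stopifnot(tauTrue >= 1, nFrames >= 2)
  core <- NULL
  if (includeCore) {
    ch <- genIdealHelix(40, startResid = 100)
    ca <- match(selectAtoms(ch, "name CA"), atoms(ch)$index)
    core <- coords(ch, 1)[ca, , drop = FALSE]
    # orient the core helix axis along +z, center at the origin
    cen <- colMeans(core)
    core <- sweep(core, 2, cen)
    ax <- core[nrow(core), ] - core[1, ]
    ax <- ax / sqrt(sum(ax^2))
    v <- .cross3(ax, c(0, 0, 1)); s2 <- sqrt(sum(v^2)); cth <- ax[3]
    if (s2 > 1e-12) {
      K <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
      R <- diag(3) + K + K %*% K * ((1 - cth) / s2^2)
      core <- core %*% t(R)
    }
  }
  if (is.null(endpointA)) {
    helix <- genIdealHelix(20, startResid = 342)
    ca <- match(selectAtoms(helix, "name CA"), atoms(helix)$index)
    endpointA <- coords(helix, 1)[ca, , drop = FALSE]
    if (includeCore) {
      # anchor the loop just outside the core top
      shift <- c(6, 0, max(core[, 3])) - endpointA[1, ]
      endpointA <- sweep(endpointA, 2, shift, "+")
    }
  }
  if (is.null(endpointB)) {
    anchor <- endpointA[1, ]
    th <- 70 * pi / 180
    R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
    endpointB <- sweep(sweep(endpointA, 2, anchor) %*% t(R), 2, anchor, "+")
  }
  stopifnot(nrow(endpointA) == nrow(endpointB))
  set.seed(seed)
  s <- if (!is.null(latent)) {
    stopifnot(length(latent) == nFrames)
    as.numeric(latent)
  } else {
    .simulateLatent(nFrames, tauTrue, stationarySd, wellDepth = wellDepth)
  }
  nLoop <- nrow(endpointA)
  nCore <- if (includeCore) nrow(core) else 0L
  nAt <- nCore + nLoop
  co <- array(0, c(nAt, 3, nFrames))
  D <- endpointB - endpointA
  for (f in seq_len(nFrames)) {
    X <- endpointA + s[f] * D
    if (nCore) X <- rbind(core, X)
    co[, , f] <- X + matrix(stats::rnorm(3 * nAt, sd = noiseSd), nAt, 3)
  }
  resid <- c(if (nCore) 99L + seq_len(nCore), 341L + seq_len(nLoop))
  atoms <- data.frame(index = seq_len(nAt) - 1L, name = "CA",
                      resname = c(rep("COR", nCore), rep("GLY", nLoop)),
                      resid = resid, chain = "A", element = "C",
                      rminHalf = NA_real_, epsilon = 0, charge = 0,
                      stringsAsFactors = FALSE)
  ens <- FrameEnsemble(atoms, co, box = c(0, 0, 0),
                       frameInterval = dt * 1000)
  list(ensemble = ens,
       groundTruth = list(s = s, tauTrue = tauTrue,
                          basin = ifelse(s < 0.5, "A", "B"),
                          interEndpointRmsd = sqrt(mean(rowSums(D^2)))))
}

# place atom D given A, B, C with bond |CD|, angle BCD (deg), torsion ABCD (deg)
.nerfPlace <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Ideal polypeptide backbone at fixed dihedrals
#'
#' Builds backbone N, CA, C, O for \code{nResidues} residues from ideal bond
#' geometry (N-CA 1.458, CA-C 1.525, C-N 1.329, C-O 1.231 A; trans peptide
#' bond) at the given phi/psi. (-57, -47) gives a canonical alpha-helix with
#' ~1.5 A rise per residue; (180, 180) a fully extended chain.
#'
#' @param nResidues chain length (>= 1).
#' @param phi,psi backbone dihedrals, degrees.
#' @param startResid first residue number.
#' @param chain chain id.
#' @return A single-frame \linkS4class{FrameEnsemble} (resname ALA).
#' @export
genIdealHelix <- function(nResidues, phi = -57, psi = -47, startResid = 1,
                          chain = "A") {
  stopifnot(nResidues >= 1)
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329; bCO <- 1.231
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7; aCACO <- 120.8
  N <- CA <- C <- O <- matrix(0, nResidues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bNCA, 0, 0)
  ang <- aNCAC * pi / 180
  C[1, ] <- CA[1, ] + bCAC * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in seq_len(nResidues)) {
    if (i > 1) {
      N[i, ] <- .nerfPlace(N[i - 1, ], CA[i - 1, ], C[i - 1, ], bCN, aCACN, psi)
      CA[i, ] <- .nerfPlace(CA[i - 1, ], C[i - 1, ], N[i, ], bNCA, aCNCA, 180)
      C[i, ] <- .nerfPlace(C[i - 1, ], N[i, ], CA[i, ], bCAC, aNCAC, phi)
    }
    O[i, ] <- .nerfPlace(N[i, ], CA[i, ], C[i, ], bCO, aCACO, psi + 180)
  }
  xyz <- matrix(0, 4 * nResidues, 3)
  nm <- character(4 * nResidues); rid <- integer(4 * nResidues)
  el <- character(4 * nResidues)
  for (i in seq_len(nResidues)) {
    r <- 4 * (i - 1)
    xyz[r + 1, ] <- N[i, ]; xyz[r + 2, ] <- CA[i, ]
    xyz[r + 3, ] <- C[i, ]; xyz[r + 4, ] <- O[i, ]
    nm[r + 1:4] <- c("N", "CA", "C", "O")
    el[r + 1:4] <- c("N", "C", "C", "O")
    rid[r + 1:4] <- startResid + i - 1L
  }
  atoms <- data.frame(index = seq_len(4 * nResidues) - 1L, name = nm,
                      resname = "ALA", resid = rid, chain = chain,
                      element = el, rminHalf = NA_real_, epsilon = 0,
                      charge = 0, stringsAsFactors = FALSE)
  FrameEnsemble(atoms, xyz, box = c(0, 0, 0), frameInterval = 0)
}
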