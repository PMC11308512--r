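# The diatomic O2 probe, its orientation set, and single-insertion
# interaction energies.

#' Rigid diatomic O2 probe
#'
#' Two identical Lennard-Jones sites at +/- half the O-O bond length along the
#' local z axis; symmetry order 2 (homonuclear). Per-site parameters default
#' to sigma = 1.7 A and |epsilon| = 0.12 kcal/mol. By default sigma is read
#' as the CHARMM Rmin/2 (consistent with the value's magnitude in the CHARMM
#' ecosystem); set \code{sigmaIs = "lj"} to read it as the 12-6 zero-crossing
#' instead, in which case Rmin/2 = 2^(1/6) sigma / 2. The probe is apolar:
#' no charges, LJ only.
#'
#' @param sigma per-site size parameter, Angstrom.
#' @param epsilon per-site well depth magnitude, kcal/mol.
#' @param bondLength O-O bond length, Angstrom (default 1.21).
#' @param sigmaIs "rmin2" (default) or "lj".
#' @return A \linkS4class{ProbeModel}.
#' @export
o2Probe <- function(sigma = 1.7, epsilon = 0.12, bondLength = 1.21,
                    sigmaIs = c("rmin2", "lj")) {
  sigmaIs <- match.arg(sigmaIs)
  rminHalf <- if (sigmaIs == "rmin2") sigma else 2^(1 / 6) * sigma / 2
  h <- bondLength / 2
  new("ProbeModel",
      siteOffsets = rbind(c(0, 0, h), c(0, 0, -h)),
      siteRminHalf = rep(rminHalf, 2), siteEps = rep(abs(epsilon), 2),
      symmetryOrder = 2L)
}

#' Single-site probe (for oracle and degenerate-case work)
#'
#' @param rminHalf,epsilon LJ parameters of the single site.
#' @return A \linkS4class{ProbeModel} with one site at the probe center.
#' @export
singleSiteProbe <- function(rminHalf, epsilon) {
  new("ProbeModel", siteOffsets = matrix(0, 1, 3),
      siteRminHalf = rminHalf, siteEps = abs(epsilon), symmetryOrder = 1L)
}

#' Deterministic hemispherical orientation set
#'
#' Spherical-Fibonacci axes on the upper hemisphere: quasi-uniform coverage
#' of orientation space once the C2 symmetry of a homonuclear diatomic has
#' been exploited (antipodal axes are equivalent, so only a hemisphere is
#' needed). Deterministic and reproducible across runs. \code{count = 1}
#' degenerates to the +z axis.
#'
#' @param count number of orientations C (>= 1); 21 reproduces the
#'   orientation count used for the enzyme maps.
#' @return An \linkS4class{OrientationSet}.
#' @export
generateOrientations <- function(count) {
  if (!is.numeric(count) || count < 1) stop("count must be >= 1")
  count <- as.integer(count)
  if (count == 1L)
    return(new("OrientationSet", axes = matrix(c(0, 0, 1), 1)))
  i <- seq_len(count) - 1
  z <- (i + 0.5) / count          # cos(polar angle) in (0, 1): hemisphere
  phi <- i * pi * (3 - sqrt(5))   # golden angle
  r <- sqrt(pmax(0, 1 - z^2))
  ax <- cbind(r * cos(phi), r * sin(phi), z)
  ax <- ax / sqrt(rowSums(ax^2))
  new("OrientationSet", axes = ax)
}

#' CHARMM-convention 12-6 pair energy
#'
#' \code{Rmin_ij = rminHalfI + rminHalfJ}, \code{eps_ij = sqrt(epsI * epsJ)},
#' \code{E = eps_ij * ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6)} so the minimum is
#' exactly \code{-eps_ij} at \code{r = Rmin_ij}.
#'
#' @param rminHalfI,epsI,rminHalfJ,epsJ per-atom Rmin/2 (Angstrom) and well
#'   depth magnitudes (kcal/mol).
#' @param r separation(s), Angstrom (> 0).
#' @return Energy in kcal/mol (vectorised over \code{r}).
#' @export
ljPairEnergy <- function(rminHalfI, epsI, rminHalfJ, epsJ, r) {
  .ljPairEnergyCpp(rminHalfI, abs(epsI), rminHalfJ, abs(epsJ), as.numeric(r))
}

#' Interaction energy of inserting the probe into one frame
#'
#' Sum of \code{\link{ljPairEnergy}} over probe sites x LJ-active system atoms
#' within \code{cutoff} of each site, under the minimum-image convention
#' (orthorhombic box; zero box length disables imaging on that axis).
#' Truncated, unshifted. Overlaps produce large positive values (capped
#' downstream by the map engine); exact coincidence returns \code{Inf}.
#'
#' @param frame \code{[nAtoms, 3]} coordinate matrix or a
#'   \linkS4class{FrameEnsemble} (first frame used unless \code{frameIndex}).
#' @param probe a \linkS4class{ProbeModel}.
#' @param position probe center, length-3.
#' @param axis unit orientation axis (local +z maps onto it).
#' @param cutoff Angstrom (> 0).
#' @param box length-3 box lengths; taken from the ensemble when one is given.
#' @param rminHalf,epsilon per-atom LJ vectors when \code{frame} is a bare
#'   matrix.
#' @param frameIndex which frame of an ensemble to use.
#' @return Insertion energy Delta E, kcal/mol.
#' @export
probeInsertionEnergy <- function(frame, probe, position, axis, cutoff,
                                 box = NULL, rminHalf = NULL, epsilon = NULL,
                                 frameIndex = 1L) {
  stopifnot(cutoff > 0)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9) stop("axis must be unit-norm")
  if (is(frame, "FrameEnsemble")) {
    if (is.null(box)) box <- boxLengths(frame)[frameIndex, ]
    a <- atoms(frame)
    rminHalf <- ifelse(is.na(a$rminHalf), 0, a$rminHalf)
    epsilon <- ifelse(is.na(a$epsilon), 0, a$epsilon)
    frame <- coords(frame, frameIndex)
    if (is.null(dim(frame))) frame <- matrix(frame, ncol = 3)
  }
  if (is.null(box)) box <- c(0, 0, 0)
  if (nrow(frame) == 0) return(0)
  .insertionEnergyCpp(frame, as.numeric(rminHalf), as.numeric(epsilon),
                      as.numeric(position), as.numeric(axis),
                      probe@siteOffsets, probe@siteRminHalf, probe@siteEps,
                      as.numeric(box), cutoff)
}
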