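# The implicit-ligand-sampling engine: 3D gas free-energy maps via
# orientation-averaged Widom test-particle insertion over trajectory frames,
# bulk-solvent reference extraction, and solvent occupancy maps.

#' ILS run configuration
#'
#' Bundles the estimator settings. The per-voxel free energy is
#' \deqn{G(r) = -k_B T \ln\Big[\frac{1}{NC}\sum_{m=1}^{N}\sum_{k=1}^{C}
#'   e^{-\Delta E_{m,k}(r)/k_B T}\Big]}
#' with N frames and C probe orientations; insertion energies above
#' \code{energyCap} get zero Boltzmann weight, and a voxel where every sample
#' is capped is flagged occluded (displayed at \code{displayCap}).
#'
#' @param temperature Kelvin (> 0); default 300.
#' @param gridSpacing voxel spacing, Angstrom; default 1.
#' @param cutoff LJ cutoff, Angstrom; default 10 (truncated, unshifted).
#' @param energyCap kcal/mol; default 87 kB T, the point where the Boltzmann
#'   factor reaches ~exp(-87).
#' @param orientationCount number of probe orientations C; default 21.
#' @param frameStride analyse every stride-th stored frame.
#' @param region list with \code{min} and \code{max} (length-3, Angstrom)
#'   bounding the grid, or NULL for the full first-frame box.
#' @param displayCap value written into occluded voxels, kcal/mol.
#' @param seed retained for provenance of any subsampling.
#' @return A list of class \code{IlsConfig}.
#' @export
ilsConfig <- function(temperature = 300, gridSpacing = 1, cutoff = 10,
                      energyCap = 87 * kBoltzmann * temperature,
                      orientationCount = 21, frameStride = 1, region = NULL,
                      displayCap = 30, seed = NULL) {
  stopifnot(temperature > 0, gridSpacing > 0, energyCap > 0, cutoff > 0,
            orientationCount >= 1, frameStride >= 1)
  structure(list(temperature = temperature, gridSpacing = gridSpacing,
                 cutoff = cutoff, energyCap = energyCap,
                 orientationCount = as.integer(orientationCount),
                 frameStride = as.integer(frameStride), region = region,
                 displayCap = displayCap, seed = seed),
            class = "IlsConfig")
}

.gridFromRegion <- function(region, spacing) {
  origin <- as.numeric(region$min)
  dims <- pmax(1L, as.integer(floor((region$max - region$min) / spacing + 1e-9)) + 1L)
  list(origin = origin, dims = dims)
}

#' Compute a 3D gas free-energy map (implicit ligand sampling)
#'
#' Orientation-averaged Widom insertion of \code{probe} on a regular grid
#' over every frame of \code{ensemble}; see \code{\link{ilsConfig}} for the
#' estimator. Vacuum defines the zero of G, so atom-free frames give G = 0
#' everywhere.
#'
#' @param ensemble a \linkS4class{FrameEnsemble}; the grid region must lie
#'   within the periodic box of every frame.
#' @param probe a \linkS4class{ProbeModel} (default the O2 probe).
#' @param orientations an \linkS4class{OrientationSet}, or NULL to generate
#'   \code{config$orientationCount} axes.
#' @param config an \code{\link{ilsConfig}}.
#' @return A \linkS4class{PmfMap}.
#' @export
computeIlsMap <- function(ensemble, probe = o2Probe(), orientations = NULL,
                          config = ilsConfig()) {
  if (nFrames(ensemble) < 1) stop("zero frames")
  if (is.null(orientations))
    orientations <- generateOrientations(config$orientationCount)
  axes <- orientationAxes(orientations)
  if (nrow(axes) < 1) stop("zero orientations")
  keep <- seq(1, nFrames(ensemble), by = config$frameStride)
  region <- config$region
  if (is.null(region)) {
    L <- boxLengths(ensemble)[1, ]
    if (any(L <= 0))
      stop("ensemble has no periodic box; supply config$region explicitly")
    region <- list(min = c(0, 0, 0), max = L)
  }
  g <- .gridFromRegion(region, config$gridSpacing)
  a <- atoms(ensemble)
  rmin <- ifelse(is.na(a$rminHalf), 0, a$rminHalf)
  eps <- ifelse(is.na(a$epsilon), 0, a$epsilon)
  co <- ensemble@coords[, , keep, drop = FALSE]
  res <- .ilsMapCpp(as.numeric(co), nAtoms(ensemble), length(keep),
                    rmin, eps, boxLengths(ensemble)[keep, , drop = FALSE],
                    orientationAxes(orientations), probe@siteOffsets,
                    probe@siteRminHalf, probe@siteEps,
                    g$origin, config$gridSpacing, g$dims,
                    config$temperature, config$cutoff, config$energyCap)
  G <- array(res$G, g$dims)
  occ <- array(res$occluded, g$dims)
  G[occ] <- config$displayCap
  new("PmfMap", VolumetricMap(g$origin, config$gridSpacing, g$dims, G),
      occluded = occ,
      metadata = list(nFrames = length(keep),
                      orientationCount = nrow(axes),
                      temperature = config$temperature,
                      cutoff = config$cutoff, energyCap = config$energyCap,
                      displayCap = config$displayCap))
}

#' Bulk-solvent reference free energy
#'
#' Pools the Boltzmann weights of all map voxels farther than
#' \code{minDistanceFromSolute} from every non-solvent atom in every frame
#' (all voxels qualify in a pure-solvent system):
#' \code{meanG = -kT log(mean(exp(-G/kT)))}. The quoted sd is a
#' block-averaging error from 5 voxel sub-blocks. The result corresponds to
#' the solvation free energy of the gas molecule and is the reference
#' subtracted from cavity barriers.
#'
#' @param pmf a \linkS4class{PmfMap}.
#' @param ensemble the frames the map was computed from.
#' @param minDistanceFromSolute Angstrom; default 12 (beyond the nonbonded
#'   cutoff heritage of the source simulations).
#' @param solventResnames residue names treated as solvent.
#' @return A list of class \code{BulkReference}: \code{meanG}, \code{sd},
#'   \code{voxelCount}, \code{region}.
#' @export
bulkReference <- function(pmf, ensemble, minDistanceFromSolute = 12,
                          solventResnames = c("HOH", "WAT", "TIP3", "SOL")) {
  a <- atoms(ensemble)
  solute <- which(!(a$resname %in% solventResnames))
  nvox <- prod(mapDims(pmf))
  ok <- !as.logical(occludedMask(pmf))
  qual <- rep(TRUE, nvox)
  if (length(solute)) {
    centers <- voxelCenters(pmf, seq_len(nvox))
    box <- boxLengths(ensemble)
    d2min <- rep(Inf, nvox)
    for (f in seq_len(nFrames(ensemble))) {
      xyz <- coords(ensemble, f)
      if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
      xyz <- xyz[solute, , drop = FALSE]
      L <- box[f, ]
      for (s in seq_len(nrow(xyz))) {
        d <- sweep(centers, 2, xyz[s, ], "-")
        for (ax in 1:3) if (L[ax] > 0) d[, ax] <- d[, ax] - L[ax] * round(d[, ax] / L[ax])
        d2min <- pmin(d2min, rowSums(d^2))
      }
    }
    qual <- d2min > minDistanceFromSolute^2
  }
  idx <- which(qual & ok)
  if (!length(idx)) stop("empty bulk region")
  kT <- kBoltzmann * pmf@metadata$temperature
  G <- mapValues(pmf)[idx]
  pooled <- function(g) -kT * log(mean(exp(-g / kT)))
  meanG <- pooled(G)
  nb <- 5L
  sdv <- 0
  if (length(idx) >= nb) {
    blocks <- split(G, cut(seq_along(G), nb, labels = FALSE))
    bm <- vapply(blocks, pooled, numeric(1))
    sdv <- stats::sd(bm) / sqrt(nb)
  }
  structure(list(meanG = meanG, sd = sdv, voxelCount = length(idx),
                 region = sprintf("%d voxels > %.1f A from solute",
                                  length(idx), minDistanceFromSolute)),
            class = "BulkReference")
}

#' @export
print.BulkReference <- function(x, ...) {
  cat(sprintf("BulkReference: G = %.3f +/- %.3f kcal/mol over %d voxels (%s)\n",
              x$meanG, x$sd, x$voxelCount, x$region))
  invisible(x)
}

#' Solvent occupancy map
#'
#' Per voxel, the fraction of frames in which at least one selected atom lies
#' inside the voxel; values in [0, 1].
#'
#' @param ensemble a \linkS4class{FrameEnsemble}.
#' @param selection selection expression (see \code{\link{selectAtoms}}) or an
#'   integer vector of 0-based atom indices.
#' @param spacing voxel spacing, Angstrom (> 0).
#' @param region optional list(min, max); default the first-frame box.
#' @return A \linkS4class{VolumetricMap} with units label "occupancy".
#' @export
computeOccupancyMap <- function(ensemble, selection, spacing = 1,
                                region = NULL) {
  stopifnot(spacing > 0)
  idx <- if (is.character(selection)) selectAtoms(ensemble, selection)
         else as.integer(selection)
  if (!length(idx)) stop("empty selection")
  rows <- match(idx, atoms(ensemble)$index)
  if (is.null(region)) {
    L <- boxLengths(ensemble)[1, ]
    if (any(L <= 0)) stop("ensemble has no box; supply region")
    region <- list(min = c(0, 0, 0), max = L)
  }
  g <- .gridFromRegion(region, spacing)
  counts <- array(0L, g$dims)
  nf <- nFrames(ensemble)
  for (f in seq_len(nf)) {
    xyz <- coords(ensemble, f)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    xyz <- xyz[rows, , drop = FALSE]
    ijk <- round(sweep(xyz, 2, g$origin, "-") / spacing)
    keep <- ijk[, 1] >= 0 & ijk[, 1] < g$dims[1] &
            ijk[, 2] >= 0 & ijk[, 2] < g$dims[2] &
            ijk[, 3] >= 0 & ijk[, 3] < g$dims[3]
    ijk <- ijk[keep, , drop = FALSE]
    if (nrow(ijk)) {
      lin <- unique(1L + ijk[, 1] + g$dims[1] * (ijk[, 2] + g$dims[2] * ijk[, 3]))
      counts[lin] <- counts[lin] + 1L
    }
  }
  VolumetricMap(g$origin, spacing, g$dims, counts / nf,
                unitsLabel = "occupancy")
}
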