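#' FrameEnsemble: a topology plus ordered coordinate frames
#'
#' The central container of the package: an atom table with per-atom
#' Lennard-Jones parameters, a stack of coordinate frames (Angstrom) and the
#' per-frame orthorhombic box lengths. Corresponds to the N simulation frames
#' averaged over by the implicit-ligand-sampling estimator.
#'
#' @slot atoms data.frame with columns \code{index} (0-based), \code{name},
#'   \code{resname}, \code{resid}, \code{chain}, \code{element},
#'   \code{rminHalf} (Angstrom), \code{epsilon} (kcal/mol, stored as a
#'   magnitude), \code{charge} (e, may be NA).
#' @slot coords numeric array \code{[nAtoms, 3, nFrames]}, Angstrom.
#' @slot box numeric matrix \code{[nFrames, 3]} of orthorhombic box lengths
#'   (Angstrom); a row of zeros means "no periodicity".
#' @slot frameInterval time between stored frames, picoseconds.
#' @export
setClass("FrameEnsemble",
  representation(atoms = "data.frame", coords = "array",
                 box = "matrix", frameInterval = "numeric"))

setValidity("FrameEnsemble", function(object) {
  msg <- NULL
  a <- object@atoms
  need <- c("index", "name", "resname", "resid", "chain", "element",
            "rminHalf", "epsilon", "charge")
  if (!all(need %in% names(a)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an [nAtoms, 3, nFrames] array")
  else {
    if (d[1] != nrow(a))
      msg <- c(msg, "every frame must have exactly nrow(atoms) positions")
    if (d[3] < 1L) msg <- c(msg, "number of frames must be >= 1")
    if (nrow(object@box) != d[3] || ncol(object@box) != 3L)
      msg <- c(msg, "box must be an [nFrames, 3] matrix")
    else if (any(object@box < 0))
      msg <- c(msg, "box lengths must be >= 0")
  }
  if (all(need %in% names(a)) && anyDuplicated(a$index))
    msg <- c(msg, "atom indices must be unique")
  if (all(need %in% names(a))) {
    ljActive <- !is.na(a$epsilon) & a$epsilon > 0
    if (any(ljActive & (is.na(a$rminHalf) | a$rminHalf <= 0)))
      msg <- c(msg, "rminHalf must be > 0 for LJ-active atoms")
    if (any(!is.na(a$epsilon) & a$epsilon < 0))
      msg <- c(msg, "epsilon is stored as a magnitude and must be >= 0")
  }
  if (length(object@frameInterval) != 1L || object@frameInterval < 0)
    msg <- c(msg, "frameInterval must be a single non-negative number")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FrameEnsemble
#'
#' @param atoms atom table (see the class slots). Missing LJ/charge columns
#'   are added as NA/0.
#' @param coords \code{[nAtoms, 3, nFrames]} array, or an \code{[nAtoms, 3]}
#'   matrix for a single frame.
#' @param box per-frame box lengths: a length-3 vector (recycled) or an
#'   \code{[nFrames, 3]} matrix. Defaults to no periodicity.
#' @param frameInterval picoseconds between frames (default 10, the
#'   trajectory-writing interval assumed throughout).
#' @return A validated \linkS4class{FrameEnsemble}.
#' @export
FrameEnsemble <- function(atoms, coords, box = c(0, 0, 0), frameInterval = 10) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  for (col in c("rminHalf", "epsilon", "charge"))
    if (is.null(atoms[[col]])) atoms[[col]] <- rep(NA_real_, nrow(atoms))
  for (col in c("element"))
    if (is.null(atoms[[col]])) atoms[[col]] <- rep(NA_character_, nrow(atoms))
  if (is.null(atoms$index)) atoms$index <- seq_len(nrow(atoms)) - 1L
  new("FrameEnsemble", atoms = atoms, coords = coords,
      box = box, frameInterval = as.numeric(frameInterval))
}

#' VolumetricMap: a scalar field on a regular 3D grid
#'
#' Voxel center (i, j, k) (0-based) sits at \code{origin + spacing * (i,j,k)}.
#'
#' @slot origin grid origin, Angstrom.
#' @slot spacing isotropic voxel spacing, Angstrom (> 0).
#' @slot dims integer (nx, ny, nz), all >= 1.
#' @slot values numeric array of dim \code{dims}.
#' @slot unitsLabel free-text unit label (e.g. "kcal/mol").
#' @export
setClass("VolumetricMap",
  representation(origin = "numeric", spacing = "numeric", dims = "integer",
                 values = "array", unitsLabel = "character"))

setValidity("VolumetricMap", function(object) {
  msg <- NULL
  if (length(object@origin) != 3L) msg <- c(msg, "origin must have length 3")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number")
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be three integers >= 1")
  if (!identical(dim(object@values), as.integer(object@dims)))
    msg <- c(msg, "values must be an array of dim dims")
  if (is.null(msg)) TRUE else msg
})

#' Construct a VolumetricMap
#'
#' @param origin,spacing,dims,values,unitsLabel see the class slots;
#'   \code{values} may be a vector of length \code{prod(dims)} in
#'   x-fastest order.
#' @return A validated \linkS4class{VolumetricMap}.
#' @export
VolumetricMap <- function(origin, spacing, dims, values,
                          unitsLabel = "kcal/mol") {
  dims <- as.integer(dims)
  if (is.null(dim(values))) {
    if (length(values) != prod(dims))
      stop("values length does not match prod(dims)")
    values <- array(values, dims)
  }
  new("VolumetricMap", origin = as.numeric(origin),
      spacing = as.numeric(spacing), dims = dims,
      values = values, unitsLabel = unitsLabel)
}

#' PmfMap: a 3D gas free-energy map (kcal/mol, vacuum = 0)
#'
#' A \linkS4class{VolumetricMap} of insertion free energies G(r) with an
#' occlusion mask. Where the mask is TRUE every insertion sample exceeded the
#' energy cap; those voxels carry the display cap value but the mask is
#' authoritative.
#'
#' @slot occluded logical array, same dim as the values.
#' @slot metadata list: nFrames, orientationCount, temperature, cutoff,
#'   energyCap, displayCap.
#' @export
setClass("PmfMap", contains = "VolumetricMap",
  representation(occluded = "array", metadata = "list"))

setValidity("PmfMap", function(object) {
  msg <- NULL
  if (!identical(dim(object@occluded), dim(object@values)))
    msg <- c(msg, "occluded mask must have the same dim as values")
  if (any(!is.finite(object@values[!object@occluded])))
    msg <- c(msg, "G must be finite where not occluded")
  if (is.null(msg)) TRUE else msg
})

#' ProbeModel: a rigid multi-site Lennard-Jones gas probe
#'
#' @slot siteOffsets matrix \code{[nSites, 3]} of offsets from the probe
#'   center in the local frame (local +z is the orientation axis), Angstrom.
#' @slot siteRminHalf per-site CHARMM Rmin/2, Angstrom.
#' @slot siteEps per-site well depth magnitude, kcal/mol.
#' @slot symmetryOrder rotational symmetry about site exchange (2 for a
#'   homonuclear diatomic).
#' @export
setClass("ProbeModel",
  representation(siteOffsets = "matrix", siteRminHalf = "numeric",
                 siteEps = "numeric", symmetryOrder = "integer"))

setValidity("ProbeModel", function(object) {
  msg <- NULL
  ns <- nrow(object@siteOffsets)
  if (ncol(object@siteOffsets) != 3L) msg <- c(msg, "siteOffsets must be [nSites, 3]")
  if (length(object@siteRminHalf) != ns || length(object@siteEps) != ns)
    msg <- c(msg, "per-site LJ vectors must match the number of sites")
  if (any(object@siteEps < 0)) msg <- c(msg, "site epsilon stored as magnitude (>= 0)")
  if (is.null(msg)) TRUE else msg
})

#' OrientationSet: unit orientation axes of the probe
#'
#' The C probe orientations averaged over by the estimator. Axes are unit
#' vectors; for a homonuclear diatomic the C2 symmetry is already reduced, so
#' no two axes are equal or antipodal.
#'
#' @slot axes matrix \code{[C, 3]} of unit vectors.
#' @export
setClass("OrientationSet", representation(axes = "matrix"))

setValidity("OrientationSet", function(object) {
  msg <- NULL
  ax <- object@axes
  if (ncol(ax) != 3L) msg <- c(msg, "axes must be [C, 3]")
  nrm <- sqrt(rowSums(ax^2))
  if (any(abs(nrm - 1) > 1e-9)) msg <- c(msg, "axes must be unit vectors (1e-9)")
  if (nrow(ax) > 1) {
    dots <- tcrossprod(ax)
    diag(dots) <- 0
    if (any(abs(dots) > 1 - 1e-9))
      msg <- c(msg, "no two axes may be equal or antipodal")
  }
  if (is.null(msg)) TRUE else msg
})

# ---- generics and accessors -------------------------------------------------

#' @describeIn FrameEnsemble number of frames
#' @param x object
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @describeIn FrameEnsemble number of atoms
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @describeIn FrameEnsemble atom table
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @describeIn FrameEnsemble coordinates of one frame (\code{[nAtoms, 3]}) or
#'   the full array
#' @param frame frame number (1-based) or NULL for the full array
#' @export
setGeneric("coords", function(x, frame = NULL) standardGeneric("coords"))
#' @describeIn FrameEnsemble per-frame box lengths
#' @export
setGeneric("boxLengths", function(x) standardGeneric("boxLengths"))
#' @describeIn FrameEnsemble time between frames (ps)
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @export
setMethod("nFrames", "FrameEnsemble", function(x) dim(x@coords)[3])
#' @export
setMethod("nAtoms", "FrameEnsemble", function(x) dim(x@coords)[1])
#' @export
setMethod("atoms", "FrameEnsemble", function(x) x@atoms)
#' @export
setMethod("coords", "FrameEnsemble", function(x, frame = NULL) {
  if (is.null(frame)) x@coords else x@coords[, , frame, drop = TRUE]
})
#' @export
setMethod("boxLengths", "FrameEnsemble", function(x) x@box)
#' @export
setMethod("frameInterval", "FrameEnsemble", function(x) x@frameInterval)

setMethod("show", "FrameEnsemble", function(object) {
  cat("FrameEnsemble:", nAtoms(object), "atoms,", nFrames(object),
      "frame(s), dt =", object@frameInterval, "ps\n")
  b <- object@box[1, ]
  cat("  box[1]:", paste(sprintf("%.2f", b), collapse = " x "), "A\n")
  cat("  residues:", length(unique(paste(object@atoms$chain,
                                         object@atoms$resid))), "\n")
})

#' @describeIn VolumetricMap grid values array
#' @param x object
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @export
setMethod("mapValues", "VolumetricMap", function(x) x@values)
#' @describeIn VolumetricMap grid origin
#' @export
setGeneric("mapOrigin", function(x) standardGeneric("mapOrigin"))
#' @export
setMethod("mapOrigin", "VolumetricMap", function(x) x@origin)
#' @describeIn VolumetricMap voxel spacing
#' @export
setGeneric("mapSpacing", function(x) standardGeneric("mapSpacing"))
#' @export
setMethod("mapSpacing", "VolumetricMap", function(x) x@spacing)
#' @describeIn VolumetricMap grid dimensions
#' @export
setGeneric("mapDims", function(x) standardGeneric("mapDims"))
#' @export
setMethod("mapDims", "VolumetricMap", function(x) x@dims)

setMethod("show", "VolumetricMap", function(object) {
  cat("VolumetricMap:", paste(object@dims, collapse = " x "),
      "voxels, spacing", object@spacing, "A [", object@unitsLabel, "]\n")
  cat("  origin:", paste(sprintf("%.2f", object@origin), collapse = ", "), "\n")
  v <- object@values[is.finite(object@values)]
  if (length(v)) cat("  range:", sprintf("%.3f .. %.3f", min(v), max(v)), "\n")
})

#' @describeIn PmfMap occlusion mask (TRUE where all samples were capped)
#' @param x object
#' @export
setGeneric("occludedMask", function(x) standardGeneric("occludedMask"))
#' @export
setMethod("occludedMask", "PmfMap", function(x) x@occluded)

setMethod("show", "PmfMap", function(object) {
  callNextMethod()
  cat("  occluded voxels:", sum(object@occluded), "/",
      length(object@occluded), "\n")
  md <- object@metadata
  cat("  N =", md$nFrames, ", C =", md$orientationCount,
      ", T =", md$temperature, "K, cutoff =", md$cutoff, "A\n")
})

setMethod("show", "ProbeModel", function(object) {
  cat("ProbeModel:", nrow(object@siteOffsets), "site(s), symmetry order",
      object@symmetryOrder, "\n")
  for (s in seq_len(nrow(object@siteOffsets)))
    cat(sprintf("  site %d: offset (%.3f, %.3f, %.3f) A, Rmin/2 %.3f A, eps %.3f kcal/mol\n",
                s, object@siteOffsets[s, 1], object@siteOffsets[s, 2],
                object@siteOffsets[s, 3], object@siteRminHalf[s],
                object@siteEps[s]))
})

#' @describeIn OrientationSet orientation axes matrix
#' @param x object
#' @export
setGeneric("orientationAxes", function(x) standardGeneric("orientationAxes"))
#' @export
setMethod("orientationAxes", "OrientationSet", function(x) x@axes)

setMethod("show", "OrientationSet", function(object) {
  cat("OrientationSet:", nrow(object@axes),
      "hemispherical unit axes (C2-reduced)\n")
})

# ---- voxel index helpers ----------------------------------------------------

#' Voxel index arithmetic
#'
#' Linear voxel indices are 1-based and x-fastest, matching R array order.
#'
#' @param map a \linkS4class{VolumetricMap}
#' @param ijk integer matrix \code{[n, 3]} of 0-based grid indices
#' @return \code{ijkToVoxel}: 1-based linear indices. \code{voxelToIjk}: 0-based
#'   \code{[n, 3]} index matrix. \code{voxelCenters}: \code{[n, 3]} Cartesian
#'   centers (Angstrom).
#' @export
ijkToVoxel <- function(map, ijk) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  d <- mapDims(map)
  as.integer(1L + ijk[, 1] + d[1] * (ijk[, 2] + d[2] * ijk[, 3]))
}

#' @rdname ijkToVoxel
#' @param voxel 1-based linear voxel indices
#' @export
voxelToIjk <- function(map, voxel) {
  d <- mapDims(map)
  v <- as.integer(voxel) - 1L
  cbind(i = v %% d[1], j = (v %/% d[1]) %% d[2], k = v %/% (d[1] * d[2]))
}

#' @rdname ijkToVoxel
#' @export
voxelCenters <- function(map, voxel) {
  ijk <- voxelToIjk(map, voxel)
  sweep(ijk * mapSpacing(map), 2, mapOrigin(map), "+")
}

#' Voxel index nearest to a Cartesian point
#'
#' @param map a \linkS4class{VolumetricMap}
#' @param point length-3 Cartesian coordinates (Angstrom)
#' @return 1-based linear voxel index (clamped to the grid).
#' @export
nearestVoxel <- function(map, point) {
  ijk <- round((point - mapOrigin(map)) / mapSpacing(map))
  ijk <- pmin(pmax(ijk, 0), mapDims(map) - 1L)
  ijkToVoxel(map, matrix(ijk, ncol = 3))
}
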