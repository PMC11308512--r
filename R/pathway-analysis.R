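# Entrance pathways, minimax (bottleneck) barriers and pathway-lining
# residues extracted from a 3D gas free-energy map.

.neighborOffsets26 <- local({
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  as.matrix(g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ])
})

# vectorised 26-neighbourhood of a set of linear voxel indices
.neighbors26 <- function(voxels, dims) {
  ijk <- cbind((voxels - 1L) %% dims[1],
               ((voxels - 1L) %/% dims[1]) %% dims[2],
               (voxels - 1L) %/% (dims[1] * dims[2]))
  out <- integer(0)
  for (r in seq_len(nrow(.neighborOffsets26))) {
    n <- sweep(ijk, 2, .neighborOffsets26[r, ], "+")
    keep <- n[, 1] >= 0 & n[, 1] < dims[1] & n[, 2] >= 0 & n[, 2] < dims[2] &
            n[, 3] >= 0 & n[, 3] < dims[3]
    if (any(keep))
      out <- c(out, 1L + n[keep, 1] + dims[1] * (n[keep, 2] + dims[2] * n[keep, 3]))
  }
  unique(out)
}

#' Minimax (bottleneck) path through a free-energy map
#'
#' Among all 26-connected voxel paths from \code{startVoxel} to the goal
#' region, finds one whose maximum G (start included) is smallest -- the
#' minimum free-energy barrier a gas molecule must overcome. Exact
#' widest-path variant of best-first search; ties broken by shorter path,
#' then lexicographic voxel order. Occluded voxels are impassable.
#'
#' @param pmf a \linkS4class{PmfMap}.
#' @param startVoxel 1-based linear voxel index, or a length-3 Cartesian
#'   point (Angstrom) mapped to its nearest voxel.
#' @param goalRegion vector of 1-based voxel indices, a length-3 Cartesian
#'   point, or \code{"boundary"} for all voxels on the grid faces.
#' @return A list of class \code{GridPath}: \code{connected}, \code{path}
#'   (voxel indices), \code{bottleneck} (kcal/mol), \code{centers}
#'   (\code{[n, 3]} Cartesian voxel centers), \code{exit} (last voxel).
#'   When no path exists, \code{connected = FALSE} and the rest is absent.
#' @export
minimaxBarrier <- function(pmf, startVoxel, goalRegion) {
  d <- mapDims(pmf)
  if (length(startVoxel) == 3 && !is.integer(startVoxel))
    startVoxel <- nearestVoxel(pmf, startVoxel)
  if (is.character(goalRegion) && identical(goalRegion, "boundary")) {
    goalRegion <- .boundaryVoxels(d)
  } else if (length(goalRegion) == 3 && !is.integer(goalRegion)) {
    goalRegion <- nearestVoxel(pmf, goalRegion)
  }
  G <- mapValues(pmf)
  res <- .minimaxPathCpp(as.numeric(G), d, as.logical(occludedMask(pmf)),
                         as.integer(startVoxel) - 1L,
                         as.integer(goalRegion) - 1L)
  if (!res$connected)
    return(structure(list(connected = FALSE), class = "GridPath"))
  structure(list(connected = TRUE, path = res$path,
                 bottleneck = res$bottleneck,
                 centers = voxelCenters(pmf, res$path),
                 exit = res$path[length(res$path)]),
            class = "GridPath")
}

#' @export
print.GridPath <- function(x, ...) {
  if (!x$connected) cat("GridPath: disconnected\n")
  else cat(sprintf("GridPath: %d voxels, bottleneck %.3f kcal/mol\n",
                   length(x$path), x$bottleneck))
  invisible(x)
}

.boundaryVoxels <- function(d) {
  v <- seq_len(prod(d))
  ijk <- cbind((v - 1L) %% d[1], ((v - 1L) %/% d[1]) %% d[2],
               (v - 1L) %/% (d[1] * d[2]))
  v[ijk[, 1] == 0 | ijk[, 1] == d[1] - 1 | ijk[, 2] == 0 |
    ijk[, 2] == d[2] - 1 | ijk[, 3] == 0 | ijk[, 3] == d[3] - 1]
}

.floodFill <- function(passable, dims, seed) {
  visited <- logical(length(passable))
  if (!passable[seed]) return(integer(0))
  visited[seed] <- TRUE
  frontier <- seed
  while (length(frontier)) {
    nb <- .neighbors26(frontier, dims)
    nb <- nb[passable[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  which(visited)
}

# connected components (26-conn) of an arbitrary voxel set
.components <- function(voxels, dims) {
  passable <- logical(prod(dims))
  passable[voxels] <- TRUE
  comps <- list()
  remaining <- passable
  while (any(remaining)) {
    seed <- which(remaining)[1]
    comp <- .floodFill(remaining, dims, seed)
    comps[[length(comps) + 1L]] <- comp
    remaining[comp] <- FALSE
  }
  comps
}

#' Enumerate entrance channels below an isovalue
#'
#' Flood-fills the voxels with \code{G <= isovalue} (26-connectivity,
#' occluded voxels excluded) from \code{siteVoxel}. The connected region is
#' partitioned into channels, one per connected patch of map-boundary voxels
#' it reaches (its exits), by grid-geodesic proximity (multi-source breadth
#' first search; ties to the lower channel id). Channels are disjoint and
#' their union is the sub-isovalue voxel set connected to the site. A region
#' that never reaches the boundary yields no channels.
#'
#' @param pmf a \linkS4class{PmfMap}.
#' @param isovalue finite free-energy threshold, kcal/mol.
#' @param siteVoxel active-site voxel (1-based index or Cartesian point);
#'   user-specified, e.g. a cofactor or substrate atom position.
#' @return A list of channels, each \code{list(voxels, exitVoxels)}, ordered
#'   by channel size (largest first). Empty when \code{siteVoxel} is above
#'   the isovalue or the region is landlocked.
#' @export
enumeratePathways <- function(pmf, isovalue, siteVoxel) {
  stopifnot(is.finite(isovalue))
  d <- mapDims(pmf)
  if (length(siteVoxel) == 3 && !is.integer(siteVoxel))
    siteVoxel <- nearestVoxel(pmf, siteVoxel)
  siteVoxel <- as.integer(siteVoxel)
  passable <- as.numeric(mapValues(pmf)) <= isovalue & !as.logical(occludedMask(pmf))
  if (!passable[siteVoxel]) return(list())
  region <- .floodFill(passable, d, siteVoxel)
  inRegion <- logical(prod(d)); inRegion[region] <- TRUE
  exits <- intersect(region, .boundaryVoxels(d))
  if (!length(exits)) return(list())
  exitGroups <- .components(exits, d)
  # multi-source BFS over the region, label = first-reaching exit group
  label <- integer(prod(d))
  dist <- rep(NA_integer_, prod(d))
  frontier <- integer(0)
  for (gi in seq_along(exitGroups)) {
    label[exitGroups[[gi]]] <- gi
    dist[exitGroups[[gi]]] <- 0L
    frontier <- c(frontier, exitGroups[[gi]])
  }
  step <- 0L
  while (length(frontier)) {
    step <- step + 1L
    nxt <- integer(0)
    for (gi in sort(unique(label[frontier]))) {
      f <- frontier[label[frontier] == gi]
      nb <- .neighbors26(f, d)
      nb <- nb[inRegion[nb] & is.na(dist[nb])]
      if (length(nb)) {
        dist[nb] <- step
        label[nb] <- gi
        nxt <- c(nxt, nb)
      }
    }
    frontier <- nxt
  }
  channels <- lapply(seq_along(exitGroups), function(gi)
    list(voxels = region[label[region] == gi],
         exitVoxels = exitGroups[[gi]]))
  channels[order(-vapply(channels, function(ch) length(ch$voxels), numeric(1)))]
}

#' Residues lining a pathway
#'
#' Residues with any heavy atom within \code{radius} of any path voxel
#' center in at least half of the frames, sorted by their minimum observed
#' distance to the path.
#'
#' @param path a \code{GridPath} from \code{\link{minimaxBarrier}} (or any
#'   list with a \code{centers} matrix).
#' @param ensemble a \linkS4class{FrameEnsemble}.
#' @param radius Angstrom (> 0); default 4.5.
#' @param frameFraction fraction of frames required (default 0.5).
#' @return data.frame: \code{resid}, \code{resname}, \code{chain},
#'   \code{minDistance} (Angstrom).
#' @export
liningResidues <- function(path, ensemble, radius = 4.5, frameFraction = 0.5) {
  stopifnot(radius > 0)
  centers <- path$centers
  if (is.null(centers) || !nrow(centers)) stop("empty path")
  a <- atoms(ensemble)
  heavy <- which(!(toupper(substr(gsub("^[0-9]+", "", a$name), 1, 1)) == "H" |
                   (!is.na(a$element) & toupper(a$element) == "H")))
  if (!length(heavy))
    return(data.frame(resid = integer(0), resname = character(0),
                      chain = character(0), minDistance = numeric(0)))
  key <- paste(a$chain[heavy], a$resid[heavy], a$resname[heavy], sep = "|")
  ukey <- unique(key)
  nf <- nFrames(ensemble)
  within <- matrix(FALSE, length(ukey), nf)
  minD <- rep(Inf, length(ukey))
  for (f in seq_len(nf)) {
    xyz <- coords(ensemble, f)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    xyz <- xyz[heavy, , drop = FALSE]
    # per-atom min distance to any path center
    d2 <- rep(Inf, nrow(xyz))
    for (c in seq_len(nrow(centers))) {
      dd <- sweep(xyz, 2, centers[c, ], "-")
      d2 <- pmin(d2, rowSums(dd^2))
    }
    dres <- vapply(split(sqrt(d2), key)[ukey], min, numeric(1))
    within[, f] <- dres <= radius
    minD <- pmin(minD, dres)
  }
  hit <- rowMeans(within) >= frameFraction
  parts <- strsplit(ukey[hit], "|", fixed = TRUE)
  out <- data.frame(
    resid = vapply(parts, function(p) as.integer(p[2]), integer(1)),
    resname = vapply(parts, function(p) p[3], character(1)),
    chain = vapply(parts, function(p) p[1], character(1)),
    minDistance = minD[hit], stringsAsFactors = FALSE)
  out[order(out$minDistance), , drop = FALSE]
}
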