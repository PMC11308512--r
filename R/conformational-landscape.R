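# PCA of loop C-alpha coordinates, 2D free-energy surfaces over the leading
# components, and GROMOS RMSD clustering with central members.

# [nFrames, 3N] coordinate matrix of an ensemble
.xyzMatrix <- function(ensemble) {
  nf <- nFrames(ensemble)
  out <- matrix(0, nf, 3 * nAtoms(ensemble))
  for (f in seq_len(nf)) {
    X <- coords(ensemble, f)
    if (is.null(dim(X))) X <- matrix(X, ncol = 3)
    out[f, ] <- as.numeric(t(X))
  }
  out
}

.xyzInds <- function(rows) as.numeric(t(outer(3 * (rows - 1), 1:3, "+")))

#' Principal component analysis of loop C-alpha coordinates
#'
#' Frames are least-squares superposed on \code{fitSelection} (so loop motion
#' is measured in the enzyme frame), then the 3n x 3n covariance of the loop
#' C-alpha coordinates is eigendecomposed. Projections are the centered
#' coordinates dotted onto the eigenvectors. To analyse combined runs, pool
#' their frames into one ensemble first: the eigenvectors then come from the
#' pooled covariance.
#'
#' @param ensemble a \linkS4class{FrameEnsemble} with >= 2 frames.
#' @param caSelection loop C-alpha selection (expression or 0-based indices).
#' @param fitSelection superposition selection; defaults to the non-loop
#'   C-alpha set complementing \code{caSelection} when that is an expression,
#'   else to \code{caSelection} itself.
#' @return A list of class \code{ProjectionResult}: \code{mean} (3n),
#'   \code{eigenvectors} (3n x 3n), \code{eigenvalues} (Angstrom^2,
#'   descending), \code{explained}, \code{projections} (frames x components),
#'   \code{totalVariance}.
#' @export
pcaLoop <- function(ensemble, caSelection, fitSelection = NULL) {
  if (nFrames(ensemble) < 2) stop("need at least 2 frames for PCA")
  a <- atoms(ensemble)
  caIdx <- if (is.character(caSelection)) selectAtoms(ensemble, caSelection)
           else as.integer(caSelection)
  caRows <- match(caIdx, a$index)
  if (length(caRows) < 1) stop("degenerate C-alpha selection")
  if (is.null(fitSelection)) {
    if (is.character(caSelection)) {
      fitIdx <- selectAtoms(ensemble, sprintf("name CA and not (%s)", caSelection))
      if (!length(fitIdx)) fitIdx <- caIdx
    } else fitIdx <- caIdx
  } else {
    fitIdx <- if (is.character(fitSelection)) selectAtoms(ensemble, fitSelection)
              else as.integer(fitSelection)
  }
  fitRows <- match(fitIdx, a$index)
  xyz <- .xyzMatrix(ensemble)
  fi <- .xyzInds(fitRows)
  fitted <- bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                           fixed.inds = fi, mobile.inds = fi)
  loop <- fitted[, .xyzInds(caRows), drop = FALSE]
  mu <- colMeans(loop)
  centered <- sweep(loop, 2, mu)
  C <- stats::cov(centered)
  ev <- eigen(C, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  structure(list(mean = mu, eigenvectors = ev$vectors, eigenvalues = vals,
                 explained = vals / sum(vals),
                 projections = centered %*% ev$vectors,
                 totalVariance = sum(diag(C))),
            class = "ProjectionResult")
}

#' @export
print.ProjectionResult <- function(x, ...) {
  cat(sprintf("ProjectionResult: %d frames, %d coordinates\n",
              nrow(x$projections), length(x$mean)))
  e <- utils::head(x$explained, 3) * 100
  cat(sprintf("  explained: PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%%\n",
              e[1], e[2], e[3]))
  invisible(x)
}

#' 2D free-energy surface over two projection coordinates
#'
#' Histogram of the points, then \code{F = -kT log(count / max(count))}
#' kcal/mol so the modal bin sits at F = 0. Empty bins carry \code{NA} (the
#' sentinel) together with an explicit mask; for plotting they are
#' conventionally rendered at the map maximum + 1 kT, never as numbers.
#'
#' @param projections two-column matrix (e.g. PC1 and PC2 per frame).
#' @param bins bins per axis (>= 2); a single number or length-2.
#' @param temperature Kelvin.
#' @return A list of class \code{FreeEnergySurface}: \code{F} (bins x bins),
#'   \code{empty} mask, \code{xEdges}, \code{yEdges}, \code{temperature}.
#' @export
fes2d <- function(projections, bins = 40, temperature = 300) {
  projections <- as.matrix(projections)
  if (nrow(projections) < 1) stop("empty projection set")
  if (ncol(projections) < 2) stop("need two projection columns")
  bins <- rep(as.integer(bins), length.out = 2)
  if (any(bins < 2)) stop("bins must be >= 2 per axis")
  x <- projections[, 1]; y <- projections[, 2]
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  rx <- pad(range(x)); ry <- pad(range(y))
  xe <- seq(rx[1], rx[2], length.out = bins[1] + 1)
  ye <- seq(ry[1], ry[2], length.out = bins[2] + 1)
  ix <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1), bins[1])
  iy <- pmin(pmax(findInterval(y, ye, rightmost.closed = TRUE), 1), bins[2])
  counts <- matrix(0, bins[1], bins[2])
  for (i in seq_along(ix)) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1
  kT <- kBoltzmann * temperature
  FF <- -kT * log(counts / max(counts))
  FF[counts == 0] <- NA_real_
  structure(list(F = FF, empty = counts == 0, xEdges = xe, yEdges = ye,
                 temperature = temperature),
            class = "FreeEnergySurface")
}

.pairRMSD <- function(xyz, fitInds, rmsdInds) {
  nf <- nrow(xyz)
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    fitted <- bio3d::fit.xyz(fixed = xyz[i, ],
                             mobile = xyz[(i + 1):nf, , drop = FALSE],
                             fixed.inds = fitInds, mobile.inds = fitInds)
    ref <- xyz[i, rmsdInds]
    for (jj in seq_len(nrow(fitted))) {
      dv <- fitted[jj, rmsdInds] - ref
      D[i, i + jj] <- D[i + jj, i] <- sqrt(mean(matrix(dv^2, ncol = 3,
                                                       byrow = TRUE) |>
                                                  rowSums()))
    }
  }
  D
}

#' GROMOS RMSD clustering
#'
#' The greedy neighbour-counting algorithm: pairwise RMSD of all frames
#' (least-squares fit on \code{fitSelection}, RMSD over \code{selection});
#' repeatedly, the unassigned frame with the most unassigned neighbours
#' within \code{cutoff} becomes a cluster center and it plus its neighbours
#' are assigned and removed. Ties go to the lowest frame index, making the
#' result deterministic. Cluster populations are non-increasing by
#' construction.
#'
#' @param ensemble a \linkS4class{FrameEnsemble}.
#' @param selection atoms whose RMSD is clustered.
#' @param cutoff RMSD cutoff, Angstrom (6.2 reproduces the loop analysis).
#' @param fitSelection superposition atoms (default: \code{selection}).
#' @return A list of class \code{ClusterSet}: \code{membership} (per-frame
#'   cluster id), \code{centers} (central member frame index per cluster),
#'   \code{populations} (fractions), \code{cutoff}, \code{rmsd} (the pairwise
#'   matrix).
#' @export
gromosCluster <- function(ensemble, selection, cutoff = 6.2,
                          fitSelection = NULL) {
  nf <- nFrames(ensemble)
  if (nf < 1) stop("empty ensemble")
  a <- atoms(ensemble)
  selIdx <- if (is.character(selection)) selectAtoms(ensemble, selection)
            else as.integer(selection)
  selRows <- match(selIdx, a$index)
  fitRows <- if (is.null(fitSelection)) selRows else
    match(if (is.character(fitSelection)) selectAtoms(ensemble, fitSelection)
          else as.integer(fitSelection), a$index)
  xyz <- .xyzMatrix(ensemble)
  D <- .pairRMSD(xyz, .xyzInds(fitRows), .xyzInds(selRows))
  membership <- rep(NA_integer_, nf)
  centers <- integer(0)
  cl <- 0L
  while (anyNA(membership)) {
    un <- which(is.na(membership))
    counts <- vapply(un, function(i) sum(D[i, un] <= cutoff), integer(1))
    center <- un[which.max(counts)]       # which.max: lowest index on ties
    cl <- cl + 1L
    members <- un[D[center, un] <= cutoff]
    membership[members] <- cl
    centers <- c(centers, center)
  }
  structure(list(membership = membership, centers = centers,
                 populations = as.numeric(table(membership)) / nf,
                 cutoff = cutoff, rmsd = D),
            class = "ClusterSet")
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat(sprintf("ClusterSet: %d cluster(s) at cutoff %.2f A\n",
              length(x$centers), x$cutoff))
  for (i in seq_along(x$centers))
    cat(sprintf("  cluster %d: %.1f%% (center frame %d)\n",
                i, 100 * x$populations[i], x$centers[i]))
  invisible(x)
}
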