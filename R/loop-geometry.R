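# Per-frame catalytic-loop metrics: principal-axis alignment of the dimer,
# loop opening angle, minimum contact distance, backbone helical content and
# the correlation time of a metric series.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Align the longest principal axis of a selection with +z
#'
#' Per frame: the centroid of the selection is moved to the origin and the
#' frame is rotated so the largest-eigenvalue axis of the selection's
#' gyration tensor lies along +z (second axis along +y, third = y x z, a
#' proper rotation). Axis signs are fixed by continuity: dot product with the
#' previous frame's axes, and with +z/+y for the first frame. All atoms are
#' transformed, not just the selection.
#'
#' @param ensemble a \linkS4class{FrameEnsemble}.
#' @param selection selection expression or 0-based atom indices (>= 3
#'   atoms), typically the dimer C-alpha set. For a collinear selection the
#'   longest axis is still well defined; the perpendicular orientation is
#'   then an arbitrary but deterministic choice.
#' @return A new, aligned \linkS4class{FrameEnsemble} (box metadata kept;
#'   periodicity is meaningless after rotation and should not be relied on).
#' @export
alignPrincipalAxisZ <- function(ensemble, selection = "name CA") {
  idx <- if (is.character(selection)) selectAtoms(ensemble, selection)
         else as.integer(selection)
  rows <- match(idx, atoms(ensemble)$index)
  if (length(rows) < 3) stop("selection must contain at least 3 atoms")
  co <- ensemble@coords
  prev <- NULL
  for (f in seq_len(dim(co)[3])) {
    X <- co[, , f]
    sel <- X[rows, , drop = FALSE]
    cen <- colMeans(sel)
    Xc <- sweep(X, 2, cen)
    S <- sweep(sel, 2, cen)
    gyr <- crossprod(S) / nrow(S)
    ev <- eigen(gyr, symmetric = TRUE)
    if (ev$values[1] < 1e-12)
      stop("degenerate selection: all atoms coincide, principal axes undefined")
    e1 <- ev$vectors[, 1]; e2 <- ev$vectors[, 2]
    ref1 <- if (is.null(prev)) c(0, 0, 1) else prev[[1]]
    ref2 <- if (is.null(prev)) c(0, 1, 0) else prev[[2]]
    if (sum(e1 * ref1) < 0) e1 <- -e1
    if (sum(e2 * ref2) < 0) e2 <- -e2
    e3 <- .cross3(e2, e1)             # x = y cross z: proper rotation
    prev <- list(e1, e2)
    co[, , f] <- Xc %*% cbind(e3, e2, e1)
  }
  new("FrameEnsemble", atoms = ensemble@atoms, coords = co,
      box = ensemble@box, frameInterval = ensemble@frameInterval)
}

#' Loop opening-angle definition
#'
#' The opening angle theta is measured at the anchor residue's C-alpha:
#' between the vector to the tip residue's C-alpha and the vector to the
#' z-axis projection (x = y = 0) of the loop C-alpha centroid of a designated
#' closed-reference structure. The reference is aligned once with
#' \code{\link{alignPrincipalAxisZ}} and its projected center is frozen into
#' the definition; all analysed frames must be aligned with the same
#' convention. Defaults follow the enzyme's numbering: anchor Leu342, tip
#' Tyr348, loop 342-361.
#'
#' @param closedReference a \linkS4class{FrameEnsemble} holding the
#'   closed-reference structure (first frame used), or NULL to supply
#'   \code{zRef} directly.
#' @param anchorResid,tipResid residue numbers of anchor and tip (C-alpha
#'   atoms are used).
#' @param loopResids residue numbers of the loop.
#' @param chain chain of the monomer the reference center is computed from;
#'   NULL uses all chains.
#' @param alignSelection selection used to align the reference.
#' @param zRef directly supplied reference-center z (Angstrom) when
#'   \code{closedReference} is NULL.
#' @return A list of class \code{ThetaDefinition}.
#' @export
thetaDefinition <- function(closedReference = NULL, anchorResid = 342,
                            tipResid = 348, loopResids = 342:361,
                            chain = NULL, alignSelection = "name CA",
                            zRef = NULL) {
  if (anchorResid == tipResid) stop("anchor and tip residues must differ")
  if (!length(loopResids)) stop("loop range must be non-empty")
  refCenter <- NULL
  if (!is.null(closedReference)) {
    ali <- alignPrincipalAxisZ(closedReference, alignSelection)
    sel <- sprintf("name CA and resid %d-%d", min(loopResids), max(loopResids))
    if (!is.null(chain)) sel <- sprintf("(%s) and chain %s", sel, chain)
    rows <- match(selectAtoms(ali, sel), atoms(ali)$index)
    if (!length(rows)) stop("no loop C-alpha atoms found in the reference")
    refCenter <- colMeans(coords(ali, 1)[rows, , drop = FALSE])
    zRef <- refCenter[3]
  }
  if (is.null(zRef)) stop("supply either closedReference or zRef")
  structure(list(anchorResid = anchorResid, tipResid = tipResid,
                 loopResids = loopResids, chain = chain,
                 referenceCenter = refCenter, zRef = zRef),
            class = "ThetaDefinition")
}

#' Loop opening angle theta
#'
#' Angle (degrees) at the anchor C-alpha between \code{v1 = tip - anchor}
#' and \code{v2 = (0, 0, zRef) - anchor}. Frames must already be aligned with
#' \code{\link{alignPrincipalAxisZ}} under the same convention used for the
#' \code{\link{thetaDefinition}} reference.
#'
#' @param ensemble an aligned \linkS4class{FrameEnsemble}.
#' @param thetaDef a \code{ThetaDefinition}.
#' @param chain monomer chain to measure (default: the definition's chain,
#'   else all chains pooled into one anchor/tip lookup).
#' @return Numeric vector of theta per frame, degrees in [0, 180].
#' @export
openingAngle <- function(ensemble, thetaDef, chain = thetaDef$chain) {
  selFor <- function(resid) {
    s <- sprintf("name CA and resid %d", resid)
    if (!is.null(chain)) s <- sprintf("(%s) and chain %s", s, chain)
    rows <- match(selectAtoms(ensemble, s), atoms(ensemble)$index)
    if (length(rows) != 1)
      stop("expected exactly one C-alpha for residue ", resid,
           " (found ", length(rows), ")")
    rows
  }
  ra <- selFor(thetaDef$anchorResid)
  rt <- selFor(thetaDef$tipResid)
  nf <- nFrames(ensemble)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    X <- coords(ensemble, f)
    if (is.null(dim(X))) X <- matrix(X, ncol = 3)
    v1 <- X[rt, ] - X[ra, ]
    v2 <- c(0, 0, thetaDef$zRef) - X[ra, ]
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 == 0 || n2 == 0) stop("zero-length theta vector in frame ", f)
    out[f] <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
  }
  out
}

#' Minimum cross-group atom distance
#'
#' Minimum over all pairs (a in groupA, b in groupB) of the Euclidean
#' distance, without periodic imaging (intra-protein contacts).
#'
#' @param ensemble a \linkS4class{FrameEnsemble}.
#' @param groupA,groupB selection expressions or 0-based atom index vectors
#'   (both non-empty).
#' @return Numeric vector: the minimum distance per frame, Angstrom.
#' @export
minDistance <- function(ensemble, groupA, groupB) {
  toRows <- function(g) {
    idx <- if (is.character(g)) selectAtoms(ensemble, g) else as.integer(g)
    rows <- match(idx, atoms(ensemble)$index)
    if (!length(rows)) stop("empty group")
    rows
  }
  ra <- toRows(groupA); rb <- toRows(groupB)
  nf <- nFrames(ensemble)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    X <- coords(ensemble, f)
    if (is.null(dim(X))) X <- matrix(X, ncol = 3)
    A <- X[ra, , drop = FALSE]; B <- X[rb, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    out[f] <- sqrt(max(0, min(d2)))
  }
  out
}

# Kabsch-Sander backbone H-bond energy and helix assignment for one frame.
# Returns per-residue class: "H" (alpha), "G" (3-helix) or "" over `resids`.
.helixAssign <- function(X, a, resids, chain) {
  inRange <- a$resid %in% resids
  if (!is.null(chain)) inRange <- inRange & a$chain == chain
  getAtom <- function(resid, nm) {
    r <- which(inRange & a$resid == resid & a$name == nm)
    if (length(r) != 1) return(NULL)
    X[r, ]
  }
  n <- length(resids)
  Npos <- Cpos <- Opos <- CApos <- Hpos <- vector("list", n)
  for (i in seq_len(n)) {
    Npos[i] <- list(getAtom(resids[i], "N"))
    CApos[i] <- list(getAtom(resids[i], "CA"))
    Cpos[i] <- list(getAtom(resids[i], "C"))
    Opos[i] <- list(getAtom(resids[i], "O"))
    if (is.null(Npos[[i]]) || is.null(CApos[[i]]) || is.null(Cpos[[i]]) ||
        is.null(Opos[[i]]))
      stop("missing backbone atoms for residue ", resids[i])
    Hpos[i] <- list(getAtom(resids[i], "H"))  # may be NULL; keep the slot
  }
  # rebuild amide H at 1.01 A opposing the bisector of C(prev)-N and CA-N
  for (i in 2:n) {
    if (is.null(Hpos[[i]])) {
      u1 <- Npos[[i]] - Cpos[[i - 1]]; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- Npos[[i]] - CApos[[i]];   u2 <- u2 / sqrt(sum(u2^2))
      b <- u1 + u2; b <- b / sqrt(sum(b^2))
      Hpos[[i]] <- Npos[[i]] + 1.01 * b
    }
  }
  hbond <- function(i, j) {          # CO(i) accepts from NH(j)
    if (j < 2 || j > n || is.null(Hpos[[j]])) return(FALSE)
    rON <- sqrt(sum((Opos[[i]] - Npos[[j]])^2))
    rCH <- sqrt(sum((Cpos[[i]] - Hpos[[j]])^2))
    rOH <- sqrt(sum((Opos[[i]] - Hpos[[j]])^2))
    rCN <- sqrt(sum((Cpos[[i]] - Npos[[j]])^2))
    E <- 27.888 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    E < -0.5
  }
  turn4 <- vapply(seq_len(n), function(i) i + 4 <= n && hbond(i, i + 4), logical(1))
  turn3 <- vapply(seq_len(n), function(i) i + 3 <= n && hbond(i, i + 3), logical(1))
  cls <- rep("", n)
  for (i in 2:n) if (turn4[i - 1] && turn4[i])
    cls[i:min(n, i + 3)] <- "H"
  for (i in 2:n) if (turn3[i - 1] && turn3[i]) {
    j <- i:min(n, i + 2)
    cls[j][cls[j] == ""] <- "G"
  }
  cls
}

#' Backbone helical content of a residue range
#'
#' Kabsch-Sander electrostatic H-bond assignment
#' (\code{E = 27.888 (1/rON + 1/rCH - 1/rOH - 1/rCN)} kcal/mol, H-bond when
#' \code{E < -0.5}), alpha-helix from two consecutive i to i+4 turns and
#' 3-helix from two consecutive i to i+3 turns. The amide hydrogen is rebuilt
#' from geometry when absent. The returned fraction counts residues assigned
#' to either helix class over the range length. Note the energy uses
#' distances only, so a mirror image scores identically.
#'
#' @param ensemble a \linkS4class{FrameEnsemble} with backbone N, CA, C, O.
#' @param resids residue-number range to assess.
#' @param chain restrict to one chain (NULL: all, residue numbers must then
#'   be unique).
#' @return Numeric vector: helical fraction in [0, 1] per frame.
#' @export
helicalContent <- function(ensemble, resids, chain = NULL) {
  a <- atoms(ensemble)
  if (length(resids) < 3)
    return(rep(0, nFrames(ensemble)))  # no i+3/i+4 partner possible
  nf <- nFrames(ensemble)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    X <- coords(ensemble, f)
    if (is.null(dim(X))) X <- matrix(X, ncol = 3)
    cls <- .helixAssign(X, a, sort(resids), chain)
    out[f] <- mean(cls != "")
  }
  out
}

#' Correlation time by truncated autocorrelation integration
#'
#' Normalised autocorrelation rho_k of the series; the integrated estimate
#' \code{tau = dt * (1/2 + sum(rho_k, k = 1..K))} with K the first lag at
#' which rho_k drops below zero (initial-positive-sequence truncation). For
#' white noise tau approaches dt/2; for an exponential ACF with tau >= 10 dt
#' the quadrature error is below 2 percent.
#'
#' @param series numeric vector, length >= 50, nonzero variance.
#' @param dt time per sample (any unit; tau is returned in the same unit).
#' @return A list of class \code{TauEstimate}: \code{tau},
#'   \code{truncationLag}, \code{method}.
#' @export
correlationTime <- function(series, dt) {
  if (length(series) < 50) stop("series length must be >= 50")
  if (stats::var(series) == 0) stop("zero variance series")
  lagMax <- length(series) - 1L
  rho <- as.numeric(stats::acf(series, lag.max = lagMax, plot = FALSE,
                               demean = TRUE)$acf)[-1]
  neg <- which(rho < 0)
  K <- if (length(neg)) neg[1] else lagMax
  tau <- dt * (0.5 + sum(rho[seq_len(K)]))
  structure(list(tau = tau, truncationLag = K, method = "integrated-acf"),
            class = "TauEstimate")
}

#' @export
print.TauEstimate <- function(x, ...) {
  cat(sprintf("TauEstimate: tau = %.4g (lag %d, %s)\n",
              x$tau, x$truncationLag, x$method))
  invisible(x)
}

#' Per-frame loop metric series
#'
#' Computes theta, the Tyr-His style minimum contact distance and helical
#' content for each frame and monomer of an aligned ensemble, as a tidy
#' table matching the package's CSV output layout.
#'
#' @param ensemble an aligned \linkS4class{FrameEnsemble}.
#' @param thetaDef a \code{\link{thetaDefinition}}.
#' @param chains monomer chains to analyse.
#' @param distResidA,distResidB residue numbers whose atoms define the
#'   minimum contact distance (e.g. tip tyrosine and its histidine partner).
#' @param helixResids residue range for helical content (default the loop).
#' @return data.frame: \code{time_ns}, \code{monomer}, \code{theta_deg},
#'   \code{d_angstrom}, \code{helical_fraction}.
#' @export
loopMetricSeries <- function(ensemble, thetaDef, chains = "A",
                             distResidA = thetaDef$tipResid,
                             distResidB = NULL,
                             helixResids = thetaDef$loopResids) {
  res <- list()
  tns <- (seq_len(nFrames(ensemble)) - 1) * frameInterval(ensemble) / 1000
  for (ch in chains) {
    theta <- openingAngle(ensemble, thetaDef, chain = ch)
    d <- rep(NA_real_, nFrames(ensemble))
    if (!is.null(distResidB)) {
      selA <- sprintf("resid %d and chain %s", distResidA, ch)
      selB <- sprintf("resid %d and chain %s", distResidB, ch)
      d <- minDistance(ensemble, selA, selB)
    }
    hel <- tryCatch(helicalContent(ensemble, helixResids, chain = ch),
                    error = function(e) rep(NA_real_, nFrames(ensemble)))
    res[[ch]] <- data.frame(time_ns = tns, monomer = ch, theta_deg = theta,
                            d_angstrom = d, helical_fraction = hel,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}
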