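# Independent reference implementations (deliberately naive) and small
# fixture builders shared across the test files.

# minimal atom table
makeAtoms <- function(n, name = "C", resname = "LIG", resid = seq_len(n),
                      chain = "A", element = "C", rminHalf = 2.0,
                      epsilon = 0.1, charge = 0) {
  data.frame(index = seq_len(n) - 1L, name = rep(name, length.out = n),
             resname = rep(resname, length.out = n),
             resid = rep(resid, length.out = n),
             chain = rep(chain, length.out = n),
             element = rep(element, length.out = n),
             rminHalf = rep(rminHalf, length.out = n),
             epsilon = rep(epsilon, length.out = n),
             charge = rep(charge, length.out = n),
             stringsAsFactors = FALSE)
}

# an ensemble with no atoms at all
emptyEnsemble <- function(box = c(20, 20, 20), nFrames = 1) {
  FrameEnsemble(makeAtoms(0), array(0, c(0, 3, nFrames)),
                box = box)
}

# a two-chain C-alpha "protein" with a 342-361 loop per chain
twoChainProtein <- function() {
  resid <- c(300:400, 300:400)
  chain <- rep(c("A", "B"), each = 101)
  n <- length(resid)
  at <- data.frame(index = seq_len(n) - 1L, name = "CA", resname = "GLY",
                   resid = resid, chain = chain, element = "C",
                   rminHalf = NA_real_, epsilon = 0, charge = 0,
                   stringsAsFactors = FALSE)
  FrameEnsemble(at, matrix(seq_len(3 * n) / 10, n, 3), box = c(0, 0, 0))
}

# naive CHARMM 12-6 pair energy
refLj <- function(rh1, e1, rh2, e2, r) {
  rm <- rh1 + rh2
  eps <- sqrt(e1 * e2)
  eps * ((rm / r)^12 - 2 * (rm / r)^6)
}

# naive double-loop insertion energy: probe sites x atoms, minimum image
refInsertion <- function(X, rminHalf, eps, pos, axis, probe, cutoff, box) {
  # rotate local +z onto axis (Rodrigues)
  a <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * a[3] - z[3] * a[2], z[3] * a[1] - z[1] * a[3],
         z[1] * a[2] - z[2] * a[1])
  s <- sqrt(sum(v^2)); cth <- sum(z * a)
  R <- if (s < 1e-14) {
    if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    K <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
    diag(3) + K + K %*% K * ((1 - cth) / s^2)
  }
  sites <- sweep(probe@siteOffsets %*% t(R), 2, pos, "+")
  E <- 0
  for (k in seq_len(nrow(sites))) {
    for (i in seq_len(nrow(X))) {
      if (eps[i] == 0) next
      d <- X[i, ] - sites[k, ]
      for (ax in 1:3) if (box[ax] > 0) d[ax] <- d[ax] - box[ax] * round(d[ax] / box[ax])
      r <- sqrt(sum(d^2))
      if (r >= cutoff) next
      if (r == 0) return(Inf)
      E <- E + refLj(probe@siteRminHalf[k], probe@siteEps[k],
                     rminHalf[i], eps[i], r)
    }
  }
  E
}

# naive Widom/ILS estimator over an ensemble at given voxel centers
refIlsValues <- function(ensemble, probe, axes, centers, temperature, cutoff,
                         cap) {
  kT <- kBoltzmann * temperature
  a <- atoms(ensemble)
  rh <- ifelse(is.na(a$rminHalf), 0, a$rminHalf)
  ep <- ifelse(is.na(a$epsilon), 0, a$epsilon)
  nf <- nFrames(ensemble)
  G <- numeric(nrow(centers))
  occ <- logical(nrow(centers))
  for (v in seq_len(nrow(centers))) {
    w <- 0
    for (f in seq_len(nf)) {
      X <- coords(ensemble, f)
      if (is.null(dim(X))) X <- matrix(X, ncol = 3)
      for (k in seq_len(nrow(axes))) {
        E <- refInsertion(X, rh, ep, centers[v, ], axes[k, ], probe, cutoff,
                          boxLengths(ensemble)[f, ])
        if (is.finite(E) && E <= cap) w <- w + exp(-E / kT)
      }
    }
    if (w == 0) occ[v] <- TRUE else G[v] <- -kT * log(w / (nf * nrow(axes)))
  }
  list(G = G, occluded = occ)
}

# exact minimax bottleneck by threshold connectivity (26-connected)
refMinimax <- function(G, start, goals, occluded = NULL) {
  d <- dim(G); n <- length(G)
  if (is.null(occluded)) occluded <- array(FALSE, d)
  nb26 <- function(v) {
    ij <- arrayInd(v, d)
    out <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      p <- ij + c(dx, dy, dz)
      if (all(p >= 1 & p <= d))
        out <- c(out, (p[3] - 1) * d[1] * d[2] + (p[2] - 1) * d[1] + p[1])
    }
    out
  }
  if (occluded[start] || all(occluded[goals])) return(Inf)
  for (t in sort(unique(pmax(as.numeric(G)[!occluded], G[start])))) {
    ok <- G <= t & !occluded
    if (!ok[start]) next
    seen <- rep(FALSE, n); seen[start] <- TRUE; q <- start
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in nb26(v)) if (ok[w] && !seen[w]) { seen[w] <- TRUE; q <- c(q, w) }
    }
    if (any(seen[goals])) return(t)
  }
  Inf
}

# a PmfMap wrapper around a plain value array
asPmf <- function(G, occluded = NULL, origin = c(0, 0, 0), spacing = 1,
                  temperature = 300) {
  d <- dim(G)
  if (is.null(occluded)) occluded <- array(FALSE, d)
  new("PmfMap", VolumetricMap(origin, spacing, d, G), occluded = occluded,
      metadata = list(temperature = temperature, nFrames = 1L,
                      orientationCount = 1L, cutoff = 10,
                      energyCap = 87 * kBoltzmann * temperature,
                      displayCap = 30))
}

# naive GROMOS reference clustering given a precomputed distance matrix
refGromos <- function(D, cutoff) {
  n <- nrow(D)
  membership <- rep(NA_integer_, n)
  centers <- integer(0)
  cl <- 0L
  while (anyNA(membership)) {
    un <- which(is.na(membership))
    best <- un[1]; bestCount <- -1L
    for (i in un) {
      cnt <- sum(D[i, un] <= cutoff)
      if (cnt > bestCount) { best <- i; bestCount <- cnt }
    }
    cl <- cl + 1L
    members <- un[D[best, un] <= cutoff]
    membership[members] <- cl
    centers <- c(centers, best)
  }
  list(membership = membership, centers = centers)
}

# Welch statistic from the textbook formula
refWelch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

writeTinyPdb <- function(path, x = 1.0, y = 2.0, z = 3.0) {
  writeLines(c(
    sprintf("ATOM      1  CA  GLY A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
            x, y, z),
    "END"), path)
}
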