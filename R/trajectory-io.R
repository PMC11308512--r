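# Structure / trajectory / parameter-table / volumetric-map I/O, built on
# bio3d for the PDB and DCD formats. Coordinates are Angstrom throughout;
# atom indices are 0-based internally, residue numbers stay as authored.

#' Read a Lennard-Jones parameter table
#'
#' CSV with columns \code{residue_name, atom_name, rmin_half, epsilon, charge}.
#' A row with \code{residue_name == "*"} matches any residue (wildcard).
#' Epsilon may be given with either sign; its magnitude is stored (the well
#' depth sign convention lives in the energy function).
#'
#' @param path CSV file path.
#' @return data.frame with normalised column names.
#' @export
readParameterTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("residue_name", "atom_name", "rmin_half", "epsilon")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  if (is.null(tab$charge)) tab$charge <- 0
  tab$epsilon <- abs(tab$epsilon)
  tab
}

.applyParameters <- function(atoms, parameterTable, zeroFallback = FALSE) {
  if (is.null(parameterTable)) {
    atoms$rminHalf <- NA_real_; atoms$epsilon <- 0; atoms$charge <- 0
    return(atoms)
  }
  key <- paste(parameterTable$residue_name, parameterTable$atom_name)
  hit <- match(paste(atoms$resname, atoms$name), key)
  wild <- match(paste("*", atoms$name), key)
  hit[is.na(hit)] <- wild[is.na(hit)]
  if (anyNA(hit) && !zeroFallback) {
    bad <- unique(paste(atoms$resname, atoms$name)[is.na(hit)])
    stop("atoms missing from parameter table (no zero-parameter fallback): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  atoms$rminHalf <- parameterTable$rmin_half[hit]
  atoms$epsilon <- parameterTable$epsilon[hit]
  atoms$charge <- parameterTable$charge[hit]
  atoms$rminHalf[is.na(hit)] <- NA_real_
  atoms$epsilon[is.na(hit)] <- 0
  atoms$charge[is.na(hit)] <- 0
  atoms
}

.readCryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, n = 500L, warn = FALSE), value = TRUE)
  if (!length(ln)) return(NULL)
  a <- as.numeric(substr(ln[1], 7, 15))
  b <- as.numeric(substr(ln[1], 16, 24))
  c <- as.numeric(substr(ln[1], 25, 33))
  ang <- c(as.numeric(substr(ln[1], 34, 40)), as.numeric(substr(ln[1], 41, 47)),
           as.numeric(substr(ln[1], 48, 54)))
  if (any(abs(ang - 90) > 1e-3))
    stop("only orthorhombic boxes are supported (CRYST1 angles must be 90)")
  c(a, b, c)
}

.atomsFromPdb <- function(pdb) {
  a <- pdb$atom
  elesy <- a$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(elesy == ""))
    elesy <- toupper(substr(gsub("[0-9]", "", a$elety), 1, 1))
  data.frame(index = seq_len(nrow(a)) - 1L, name = a$elety,
             resname = a$resid, resid = a$resno,
             chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
             element = elesy, rminHalf = NA_real_, epsilon = 0, charge = 0,
             stringsAsFactors = FALSE)
}

#' Load a single-frame structure from PDB
#'
#' Reads atoms and coordinates, attaches per-atom LJ parameters from a
#' parameter table, and picks up an orthorhombic box from CRYST1 when present.
#'
#' @param path PDB file.
#' @param parameterTable output of \code{\link{readParameterTable}}, or NULL
#'   for a parameter-free ensemble (all epsilon 0).
#' @param zeroFallback if TRUE, atoms absent from the table get zero LJ
#'   parameters instead of raising an error.
#' @param box length-3 orthorhombic box lengths used when the PDB has no
#'   CRYST1 record; default none (non-periodic).
#' @param frameInterval picoseconds (metadata only for a single frame).
#' @return A \linkS4class{FrameEnsemble} with one frame.
#' @export
loadStructure <- function(path, parameterTable = NULL, zeroFallback = FALSE,
                          box = NULL, frameInterval = 10) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- .applyParameters(.atomsFromPdb(pdb), parameterTable, zeroFallback)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  bx <- .readCryst1(path)
  if (is.null(bx)) bx <- if (is.null(box)) c(0, 0, 0) else box
  FrameEnsemble(atoms, xyz, box = bx, frameInterval = frameInterval)
}

#' Load a multi-frame trajectory
#'
#' Topology comes from a PDB; frames from a DCD file or a multi-model PDB,
#' taken in file order, every \code{stride}-th frame. XTC is not supported
#' (no installed reader); convert to DCD or multi-model PDB upstream.
#'
#' @param topologyPath PDB with the atom records.
#' @param trajectoryPath DCD (`.dcd`) or multi-model PDB.
#' @param stride keep every stride-th frame (>= 1).
#' @param parameterTable,zeroFallback,box as in \code{\link{loadStructure}}.
#' @param frameInterval ps between frames as written in the file; the stored
#'   interval is \code{frameInterval * stride}.
#' @return A \linkS4class{FrameEnsemble}.
#' @export
loadTrajectory <- function(topologyPath, trajectoryPath, stride = 1,
                           parameterTable = NULL, zeroFallback = FALSE,
                           box = NULL, frameInterval = 10) {
  stopifnot(stride >= 1)
  top <- loadStructure(topologyPath, parameterTable, zeroFallback, box)
  ext <- tolower(tools::file_ext(trajectoryPath))
  if (ext == "xtc")
    stop("XTC trajectories are not supported; supply DCD or multi-model PDB")
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(trajectoryPath, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(trajectoryPath, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (nrow(xyz) < 1) stop("empty trajectory: ", trajectoryPath)
  if (ncol(xyz) != 3 * nAtoms(top))
    stop("atom-count mismatch: topology has ", nAtoms(top), " atoms, ",
         "trajectory has ", ncol(xyz) / 3)
  keep <- seq(1, nrow(xyz), by = stride)
  co <- array(0, c(nAtoms(top), 3, length(keep)))
  for (f in seq_along(keep))
    co[, , f] <- matrix(xyz[keep[f], ], ncol = 3, byrow = TRUE)
  FrameEnsemble(atoms(top), co, box = boxLengths(top)[1, ],
                frameInterval = frameInterval * stride)
}

#' Write a FrameEnsemble as a (multi-model) PDB
#'
#' Emits a CRYST1 record when the first frame has a periodic box, then one
#' MODEL per frame via bio3d.
#'
#' @param ensemble a \linkS4class{FrameEnsemble}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEnsemblePDB <- function(ensemble, path) {
  a <- atoms(ensemble)
  nf <- nFrames(ensemble)
  xyz <- t(apply(ensemble@coords, 3, function(m) as.numeric(t(m))))
  if (nf == 1) xyz <- matrix(xyz, nrow = 1)
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resid, resid = a$resname,
                   eleno = a$index + 1L, elety = a$name, chain = a$chain,
                   elesy = a$element, verbose = FALSE)
  b <- boxLengths(ensemble)[1, ]
  if (all(b > 0)) {
    lines <- readLines(path, warn = FALSE)
    cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     b[1], b[2], b[3], 90, 90, 90)
    writeLines(c(cryst, lines), path)
  }
  invisible(path)
}

# ---- atom selection ---------------------------------------------------------

.tokenizeSelection <- function(selection) {
  s <- gsub("([()])", " \\1 ", selection)
  tok <- strsplit(trimws(s), "\\s+")[[1]]
  tok[nzchar(tok)]
}

# recursive-descent parser over tokens; returns a logical mask over atoms
.parseSelection <- function(tokens, atoms) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { t <- tokens[pos]; pos <<- pos + 1L; t }
  keywords <- c("name", "resname", "resid", "chain", "element", "all",
                "and", "or", "not", "(", ")")

  parseValues <- function() {
    vals <- character(0)
    while (!is.na(peek()) && !(peek() %in% keywords)) vals <- c(vals, advance())
    if (!length(vals)) stop("malformed selection: keyword without values")
    vals
  }
  parsePrimary <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed selection: unexpected end of expression")
    if (t == "(") {
      advance()
      m <- parseOr()
      if (!identical(peek(), ")")) stop("malformed selection: missing ')'")
      advance()
      return(m)
    }
    if (t == "all") { advance(); return(rep(TRUE, nrow(atoms))) }
    if (t %in% c("name", "resname", "chain", "element")) {
      advance()
      vals <- parseValues()
      col <- c(name = "name", resname = "resname", chain = "chain",
               element = "element")[t]
      return(atoms[[col]] %in% vals)
    }
    if (t == "resid") {
      advance()
      vals <- parseValues()
      ids <- integer(0)
      for (v in vals) {
        if (grepl("^-?[0-9]+[-:]-?[0-9]+$", v) && grepl("[-:]", substring(v, 2))) {
          sp <- regmatches(v, regexec("^(-?[0-9]+)[-:](-?[0-9]+)$", v))[[1]]
          ids <- c(ids, seq(as.integer(sp[2]), as.integer(sp[3])))
        } else if (grepl("^-?[0-9]+$", v)) {
          ids <- c(ids, as.integer(v))
        } else stop("malformed resid value: ", v)
      }
      return(atoms$resid %in% ids)
    }
    stop("malformed selection near '", t, "'")
  }
  parseNot <- function() {
    if (identical(peek(), "not")) { advance(); return(!parseNot()) }
    parsePrimary()
  }
  parseAnd <- function() {
    m <- parseNot()
    while (identical(peek(), "and")) { advance(); m <- m & parseNot() }
    m
  }
  parseOr <- function() {
    m <- parseAnd()
    while (identical(peek(), "or")) { advance(); m <- m | parseAnd() }
    m
  }
  m <- parseOr()
  if (pos <= length(tokens))
    stop("malformed selection: trailing tokens from '", tokens[pos], "'")
  m
}

#' Select atoms with a small expression language
#'
#' Supported terms: \code{name}, \code{resname}, \code{resid} (values or
#' \code{a-b} ranges), \code{chain}, \code{element}, \code{all}; combined
#' with \code{and}, \code{or}, \code{not} and parentheses
#' (e.g. \code{"name CA and resid 342-361"}).
#'
#' @param ensemble a \linkS4class{FrameEnsemble}.
#' @param selection expression string.
#' @return Sorted unique 0-based atom indices.
#' @export
selectAtoms <- function(ensemble, selection) {
  a <- atoms(ensemble)
  mask <- .parseSelection(.tokenizeSelection(selection), a)
  sort(unique(a$index[mask]))
}

# ---- OpenDX volumetric maps -------------------------------------------------

#' Write / read a VolumetricMap in OpenDX scalar format
#'
#' The standard "gridpositions / gridconnections / array" layout with the
#' z index varying fastest, as written by common molecular visualisation
#' tools. A write/read round trip preserves origin, spacing and dims exactly
#' and values to 1e-6.
#'
#' @param map a \linkS4class{VolumetricMap}.
#' @param path file path.
#' @return \code{writeVolumetricMap}: \code{path}, invisibly.
#' @export
writeVolumetricMap <- function(map, path) {
  d <- mapDims(map); o <- mapOrigin(map); s <- mapSpacing(map)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# %s written by ilsmap", map@unitsLabel),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", o[1], o[2], o[3]),
    sprintf("delta %.6f 0.000000 0.000000", s),
    sprintf("delta 0.000000 %.6f 0.000000", s),
    sprintf("delta 0.000000 0.000000 %.6f", s),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # z fastest
  v <- aperm(mapValues(map), c(3, 2, 1))
  v <- as.numeric(v)
  n <- length(v)
  full <- n %/% 3L
  if (full > 0) {
    m <- matrix(sprintf("%.6e", v[seq_len(full * 3L)]), ncol = 3, byrow = TRUE)
    writeLines(paste(m[, 1], m[, 2], m[, 3]), con)
  }
  if (n %% 3L)
    writeLines(paste(sprintf("%.6e", v[(full * 3L + 1L):n]), collapse = " "), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' @rdname writeVolumetricMap
#' @param unitsLabel label attached to the map on reading.
#' @export
readVolumetricMap <- function(path, unitsLabel = "kcal/mol") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  gp <- grep("class gridpositions", lines, value = TRUE)
  if (!length(gp)) stop("malformed DX header: no gridpositions object")
  d <- as.integer(strsplit(sub(".*counts", "", gp[1]), "\\s+")[[1]][-1])
  if (length(d) != 3 || anyNA(d)) stop("malformed DX header: bad counts")
  ol <- grep("^origin", lines, value = TRUE)
  if (!length(ol)) stop("malformed DX header: no origin")
  o <- as.numeric(strsplit(trimws(sub("^origin", "", ol[1])), "\\s+")[[1]])
  dl <- grep("^delta", lines, value = TRUE)
  if (length(dl) != 3) stop("malformed DX header: need three delta rows")
  dm <- t(vapply(dl, function(x)
    as.numeric(strsplit(trimws(sub("^delta", "", x)), "\\s+")[[1]]),
    numeric(3)))
  sp <- c(dm[1, 1], dm[2, 2], dm[3, 3])
  if (any(abs(dm - diag(sp)) > 1e-9) || length(unique(round(sp, 9))) != 1)
    stop("only isotropic axis-aligned grids are supported")
  di <- grep("data follows", lines)
  if (!length(di)) stop("malformed DX header: no data section")
  dataLines <- lines[(di[1] + 1):length(lines)]
  dataLines <- dataLines[!grepl("^(attribute|object)", dataLines)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(dataLines), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) < prod(d))
    stop("dims/values length mismatch: expected ", prod(d), " got ", length(vals))
  vals <- vals[seq_len(prod(d))]
  arr <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))  # back to x fastest
  VolumetricMap(o, sp[1], d, arr, unitsLabel = unitsLabel)
}
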