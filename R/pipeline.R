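# Orchestration of the two end-to-end analyses from a single configuration,
# with provenance capture. The exported functions are the package's
# entry points; scripts can wrap them trivially.

#' Read a run configuration from YAML
#'
#' @param path YAML file. Top-level keys mirror the arguments of
#'   \code{\link{runO2Accessibility}} and \code{\link{runLoopDynamics}}.
#' @return A named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}

.provenance <- function(outputDir, config, seed = NULL) {
  man <- list(
    package = "ilsmap",
    version = as.character(utils::packageVersion("ilsmap")),
    rVersion = R.version.string,
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = seed,
    config = config)
  path <- file.path(outputDir, "provenance.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

.resolveEnsemble <- function(input) {
  if (is(input, "FrameEnsemble")) return(input)
  if (is.list(input) && !is.null(input$topology)) {
    tab <- if (!is.null(input$parameterTable))
      readParameterTable(input$parameterTable) else NULL
    if (!is.null(input$trajectory))
      return(loadTrajectory(input$topology, input$trajectory,
                            stride = input$stride %||% 1,
                            parameterTable = tab,
                            zeroFallback = isTRUE(input$zeroFallback),
                            box = input$box))
    return(loadStructure(input$topology, tab,
                         zeroFallback = isTRUE(input$zeroFallback),
                         box = input$box))
  }
  stop("input must be a FrameEnsemble or a list with $topology")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gas accessibility analysis: map, bulk reference, channels, barriers
#'
#' Runs the full accessibility workflow on one ensemble: the 3D gas
#' free-energy map, the bulk-solvent reference (when solvent is present),
#' sub-isovalue entrance channels from each active site, the minimax barrier
#' from each site to the map boundary, and (when several barrier samples are
#' supplied or produced) a group summary table with Welch tests. Artifacts
#' (OpenDX map, CSV reports, JSON provenance) are written to
#' \code{outputDir} when given.
#'
#' @param config list (or YAML via \code{\link{readRunConfig}}) with:
#'   \code{input} (a \linkS4class{FrameEnsemble} or \code{topology} /
#'   \code{trajectory} / \code{parameterTable} paths), \code{ils} (arguments
#'   to \code{\link{ilsConfig}}), \code{sites} (named list of active-site
#'   Cartesian points), \code{isovalue} (kcal/mol, for channel enumeration),
#'   \code{bulk} (\code{minDistance}, or \code{skip = TRUE}),
#'   \code{liningRadius}, \code{outputDir}, \code{seed}.
#' @return list: \code{map} (\linkS4class{PmfMap}), \code{bulk},
#'   \code{pathways} (per site: channels, \code{GridPath}, barrier report
#'   row), \code{report} (data.frame).
#' @export
runO2Accessibility <- function(config) {
  ens <- .resolveEnsemble(config$input)
  ilsArgs <- config$ils %||% list()
  cfg <- do.call(ilsConfig, ilsArgs)
  message("[ils] computing free-energy map (", nFrames(ens), " frames)")
  map <- computeIlsMap(ens, config$probe %||% o2Probe(), config = cfg)

  bulk <- NULL
  if (!isTRUE(config$bulk$skip)) {
    bulk <- tryCatch(
      bulkReference(map, ens,
                    minDistanceFromSolute = config$bulk$minDistance %||% 12),
      error = function(e) {
        message("[bulk] no bulk region: ", conditionMessage(e))
        NULL
      })
  }

  pathways <- list()
  rows <- list()
  for (nm in names(config$sites)) {
    site <- as.numeric(config$sites[[nm]])
    message("[paths] site ", nm)
    gp <- minimaxBarrier(map, site, "boundary")
    channels <- if (!is.null(config$isovalue))
      enumeratePathways(map, config$isovalue, site) else list()
    lining <- NULL
    if (gp$connected && !is.null(config$liningRadius))
      lining <- liningResidues(gp, ens, radius = config$liningRadius)
    barrierAbs <- if (gp$connected) gp$bottleneck else NA_real_
    rows[[nm]] <- data.frame(
      site = nm, connected = gp$connected,
      barrier_abs = barrierAbs,
      barrier_rel = if (!is.null(bulk)) barrierAbs - bulk$meanG else NA_real_,
      n_channels = length(channels), stringsAsFactors = FALSE)
    pathways[[nm]] <- list(path = gp, channels = channels, lining = lining)
  }
  report <- if (length(rows)) do.call(rbind, rows) else NULL

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    writeVolumetricMap(map, file.path(config$outputDir, "pmf.dx"))
    if (!is.null(report))
      utils::write.csv(report, file.path(config$outputDir, "pathways.csv"),
                       row.names = FALSE)
    if (!is.null(bulk))
      jsonlite::write_json(bulk[c("meanG", "sd", "voxelCount", "region")],
                           file.path(config$outputDir, "bulk.json"),
                           auto_unbox = TRUE, digits = NA)
    serializableCfg <- config[setdiff(names(config), c("input", "probe"))]
    .provenance(config$outputDir, serializableCfg, config$seed)
  }
  list(map = map, bulk = bulk, pathways = pathways, report = report)
}

#' Loop dynamics analysis: metrics, correlation times, PCA, FES, clusters
#'
#' Aligns each input ensemble on the principal axis, computes the per-frame
#' loop metrics (theta, contact distance, helical content) per monomer,
#' estimates the correlation time of theta, pools all frames for PCA of the
#' loop C-alpha coordinates, builds the free-energy surface over PC1/PC2 and
#' clusters the loop conformations with the GROMOS algorithm. Single-frame
#' input yields metrics only, with tau and clustering skipped (with notice).
#'
#' @param config list with: \code{inputs} (list of ensembles or input specs),
#'   \code{align} (selection, default "name CA"), \code{theta} (arguments to
#'   \code{\link{thetaDefinition}}; \code{reference} may be an ensemble),
#'   \code{chains}, \code{distResidB} (contact partner residue),
#'   \code{loopSelection} (PCA/cluster selection), \code{fitSelection},
#'   \code{clusterCutoff} (default 6.2), \code{fesBins}, \code{temperature},
#'   \code{outputDir}, \code{seed}.
#' @return list: \code{metrics} (data.frame), \code{tau} (per monomer),
#'   \code{pca}, \code{fes}, \code{clusters}, \code{pooled} (the pooled
#'   aligned ensemble).
#' @export
runLoopDynamics <- function(config) {
  inputs <- lapply(config$inputs, .resolveEnsemble)
  alignSel <- config$align %||% "name CA"
  aligned <- lapply(inputs, alignPrincipalAxisZ, selection = alignSel)

  thetaArgs <- config$theta %||% list()
  ref <- thetaArgs$reference %||% aligned[[1]]
  if (!is(ref, "FrameEnsemble")) ref <- .resolveEnsemble(ref)
  td <- thetaDefinition(
    closedReference = ref,
    anchorResid = thetaArgs$anchorResid %||% 342,
    tipResid = thetaArgs$tipResid %||% 348,
    loopResids = thetaArgs$loopResids %||% (342:361),
    chain = thetaArgs$chain, alignSelection = alignSel)

  chains <- config$chains %||% "A"
  metrics <- do.call(rbind, lapply(seq_along(aligned), function(i) {
    m <- loopMetricSeries(aligned[[i]], td, chains = chains,
                          distResidB = config$distResidB)
    m$run <- i
    m
  }))

  tau <- list()
  for (ch in chains) {
    th <- metrics$theta_deg[metrics$monomer == ch]
    dtns <- frameInterval(aligned[[1]]) / 1000
    tau[[ch]] <- tryCatch(correlationTime(th, dtns), error = function(e) {
      message("[tau] skipped for monomer ", ch, ": ", conditionMessage(e))
      NULL
    })
  }

  # pool frames of all runs (same topology required)
  pooled <- inputs[[1]]
  if (length(aligned) > 1) {
    co <- do.call(abind3, lapply(aligned, function(e) e@coords))
    pooled <- new("FrameEnsemble", atoms = aligned[[1]]@atoms, coords = co,
                  box = do.call(rbind, lapply(aligned, boxLengths)),
                  frameInterval = aligned[[1]]@frameInterval)
  } else pooled <- aligned[[1]]

  loopSel <- config$loopSelection %||%
    sprintf("name CA and resid %d-%d", min(td$loopResids), max(td$loopResids))
  pca <- fes <- clusters <- NULL
  if (nFrames(pooled) >= 2) {
    pca <- pcaLoop(pooled, loopSel, config$fitSelection)
    fes <- fes2d(pca$projections[, 1:2], bins = config$fesBins %||% 40,
                 temperature = config$temperature %||% 300)
    clusters <- gromosCluster(pooled, loopSel,
                              cutoff = config$clusterCutoff %||% 6.2,
                              fitSelection = config$fitSelection)
  } else {
    message("[loop] single frame: tau, PCA and clustering skipped")
  }

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(config$outputDir, "loop_metrics.csv"),
                     row.names = FALSE)
    if (!is.null(pca)) {
      proj <- data.frame(frame = seq_len(nrow(pca$projections)),
                         PC1 = pca$projections[, 1],
                         PC2 = pca$projections[, 2])
      utils::write.csv(proj, file.path(config$outputDir, "projections.csv"),
                       row.names = FALSE)
    }
    if (!is.null(clusters)) {
      utils::write.csv(
        data.frame(cluster = seq_along(clusters$centers),
                   center_frame = clusters$centers,
                   population = clusters$populations),
        file.path(config$outputDir, "clusters.csv"), row.names = FALSE)
      for (i in seq_along(clusters$centers)) {
        cen <- clusters$centers[i]
        single <- new("FrameEnsemble", atoms = pooled@atoms,
                      coords = pooled@coords[, , cen, drop = FALSE],
                      box = pooled@box[cen, , drop = FALSE],
                      frameInterval = pooled@frameInterval)
        writeEnsemblePDB(single, file.path(config$outputDir,
                                           sprintf("centroid_%02d.pdb", i)))
      }
    }
    serializableCfg <- config[setdiff(names(config),
                                      c("inputs", "theta"))]
    .provenance(config$outputDir, serializableCfg, config$seed)
  }
  list(metrics = metrics, tau = tau, pca = pca, fes = fes,
       clusters = clusters, pooled = pooled, thetaDefinition = td)
}

# bind 3D arrays along the third dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n3 <- sum(vapply(arrs, function(a) dim(a)[3], numeric(1)))
  out <- array(0, c(d[1], d[2], n3))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[3]
    out[, , at + seq_len(k)] <- a
    at <- at + k
  }
  out
}
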