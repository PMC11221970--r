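#' Run the full community -> network -> cohesion pipeline
#'
#' Executes, per dietary group and with one seeded generator threaded
#' through every stochastic stage: relative abundance and genus
#' aggregation, Simpson dominance with group ANOVA, Bray-Curtis PCoA,
#' pairwise Welch differential abundance, per-group co-occurrence networks
#' (log transform, Spearman matrix, RMT cutoff, topology, degree-preserving
#' random baselines), cohesion with taxon-shuffle calibration, the
#' cohesion group contrast, and focal-taxon/cohesion correlations.
#' Cohesion connectedness is calibrated once on all samples pooled (the
#' cohesion metric's convention); group structure enters through the
#' abundance weighting and the downstream contrast.
#' Writes per-stage TSVs, GraphML/edge-list exports and one JSON summary
#' recording the configuration and seed; identical config and seed give
#' byte-identical numeric outputs.
#'
#' @param x an \linkS4class{OtuExperiment} with group labels, or the path
#'   to an OTU table TSV.
#' @param config a \code{\link{runConfig}} list.
#' @param groups,taxonomy optional paths forwarded to
#'   \code{\link{readOtuTable}} when \code{x} is a path; \code{groups} is
#'   required in that case.
#' @param focalOtus OTU ids whose abundance/positive-cohesion correlation
#'   is reported; defaults to the two most abundant OTUs overall.
#' @return invisibly, the summary list (also written as
#'   \code{summary.json} under \code{config$outDir}).
#' @export
runPipeline <- function(x, config = runConfig(), groups = NULL,
                        taxonomy = NULL, focalOtus = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.character(x)) {
    if (is.null(groups))
      stop("stage 'input': a sample-to-group metadata file is required")
    if (!file.exists(x)) stop("stage 'input': OTU table not found: ", x)
    x <- readOtuTable(x, orientation = "samples", groups = groups,
                      taxonomy = taxonomy, quiet = TRUE)
  }
  stopifnot(is(x, "OtuExperiment"))
  g <- sampleGroups(x)
  if (is.null(g)) stop("stage 'input': OtuExperiment carries no group labels")
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  partialFlag <- file.path(config$outDir, "PARTIAL")
  file.create(partialFlag)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- list(package = "miconet",
              version = as.character(utils::packageVersion("miconet")),
              seed = config$seed,
              config = unclass(config))
  lev <- levels(g)

  ## community stage
  rel <- stage("community", relativeAbundance(x))
  tax <- taxonomyMap(x)
  genus <- stage("community", aggregateGenus(rel, tax))
  simp <- stage("community", simpsonByGroup(rel, g))
  pcoa <- stage("community", brayCurtisPcoa(rel, k = 2))
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  diff <- stage("community", lapply(pairs, function(p)
    welchDifferential(rel, g, p, fdr = config$fdr)))
  names(diff) <- vapply(pairs, paste, "", collapse = "_vs_")
  utils::write.table(
    data.frame(sample = names(simp$perSample), group = as.character(g),
               simpson = simp$perSample),
    file.path(config$outDir, "diversity.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = rownames(pcoa$points), pcoa$points),
    file.path(config$outDir, "ordination.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(diff))
    utils::write.table(diff[[nm]],
                       file.path(config$outDir,
                                 paste0("differential_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  out$community <- list(
    simpson = simp$summary, simpson_anova_p = simp$anova_p,
    pcoa_proportion = pcoa$proportion,
    genus_mean = lapply(lev, function(l)
      rowMeans(genus[, g == l, drop = FALSE])))
  names(out$community$genus_mean) <- lev

  ## network stage, per group
  out$network <- list()
  for (l in lev) {
    xg <- x[, g == l]
    m <- otuCounts(xg)
    if (config$minPrevalence > 0)
      m <- m[rowSums(m > 0) >= config$minPrevalence, , drop = FALSE]
    net <- stage(paste0("network:", l), {
      corr <- spearmanMatrix(logTransform(m, config$pseudocount))
      scan <- tryCatch(
        rmtThreshold(corr, config$scanMin, config$scanMax, config$scanStep),
        error = function(e) NULL)
      cutoff <- if (!is.null(scan) && !is.na(chosenCutoff(scan)))
        chosenCutoff(scan) else config$fallbackCutoff
      if (!is.null(scan))
        utils::write.table(scanTable(scan),
                           file.path(config$outDir,
                                     paste0("rmt_scan_", l, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      list(net = suppressWarnings(buildNetwork(corr, cutoff, tax)),
           cutoff = cutoff,
           rmtFound = !is.null(scan) && !is.na(chosenCutoff(scan)))
    })
    topo <- NULL; null <- NULL
    if (igraph::ecount(networkGraph(net$net)) >= 2) {
      topo <- stage(paste0("network:", l), networkTopology(net$net))
      null <- stage(paste0("network:", l), randomBaseline(
        net$net, R = config$nRandom,
        seed = stageSeed(config$seed, paste0("null_", l))))
      suppressWarnings(writeNetwork(
        net$net, file.path(config$outDir, paste0("network_", l))))
    }
    out$network[[l]] <- list(
      cutoff = net$cutoff, rmt_found = net$rmtFound,
      N = if (is.null(topo)) 0L else topo$N,
      E = if (is.null(topo)) 0L else topo$E,
      avgK = if (is.null(topo)) 0 else topo$avgK,
      clustering = if (is.null(topo)) NA else topo$clustering,
      pathLength = if (is.null(topo)) NA else topo$pathLength,
      modularity = if (is.null(topo)) NA else topo$modularity,
      null_z = if (is.null(null)) NULL else null$summary)
  }

  ## cohesion stage: one connectedness vector calibrated on all samples
  coh <- stage("cohesion", {
    corrected <- nullCorrectedCorrelations(
      rel, method = config$cohesionMethod, rNull = config$rNull,
      seed = stageSeed(config$seed, "cohesion"))
    cohesionIndex(rel, connectedness(corrected),
                  method = config$cohesionMethod, rNull = config$rNull,
                  seed = stageSeed(config$seed, "cohesion"))
  })
  contrast <- stage("cohesion", cohesionContrast(coh, g))
  utils::write.table(
    data.frame(sample = sampleIds(x), group = as.character(g),
               positive = positiveCohesion(coh),
               negative = negativeCohesion(coh)),
    file.path(config$outDir, "cohesion.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(connectednessTable(coh),
                     file.path(config$outDir, "connectedness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(focalOtus))
    focalOtus <- names(sort(rowSums(otuCounts(x)), decreasing = TRUE))[1:2]
  focal <- stage("cohesion", lapply(focalOtus, function(o)
    abundanceCohesionCorrelation(x, coh, o)))
  names(focal) <- focalOtus
  out$cohesion <- list(
    summary = contrast$positive$summary,
    anova_p = contrast$positive$anova_p,
    ratios = contrast$ratios,
    focal = lapply(focal, function(f) f[c("rho", "p.value")]))

  jsonlite::write_json(out, file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  unlink(partialFlag)
  invisible(out)
}
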