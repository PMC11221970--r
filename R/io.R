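#' Read an OTU count table from a tab-separated file
#'
#' The file must be a classic flat table: first row sample (or OTU)
#' identifiers, first column the other axis. Orientation is never guessed;
#' silent transposition is a classic microbiome bug, so the caller states it.
#'
#' @param path path to a TSV file.
#' @param orientation \code{"samples"} if rows are samples,
#'   \code{"otus"} if rows are OTUs.
#' @param groups optional named group vector or path to a two-column
#'   (sample, group) TSV.
#' @param taxonomy optional taxonomy data.frame or path to a two-column
#'   (otu, lineage) TSV.
#' @param quiet suppress the parse report message.
#' @return A validated \linkS4class{OtuExperiment}.
#' @export
readOtuTable <- function(path, orientation = c("samples", "otus"),
                         groups = NULL, taxonomy = NULL, quiet = FALSE) {
  orientation <- match.arg(orientation)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate row identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(raw)[-1]))
    stop("duplicate column identifiers: ",
         paste(unique(colnames(raw)[-1][duplicated(colnames(raw)[-1])]),
               collapse = ", "))
  m <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = list(ids, colnames(m))))
  bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row '%s', column '%s': \"%s\"",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]], m[bad[1, ]]))
  frac <- which(num != round(num), arr.ind = TRUE)
  if (length(frac) && nrow(frac))
    stop(sprintf("non-integer count at row '%s', column '%s': %s",
                 ids[frac[1, 1]], colnames(m)[frac[1, 2]], num[frac[1, ]]))
  if (orientation == "samples") num <- t(num)   # normalise to OTU x sample
  if (is.character(groups) && length(groups) == 1L)
    groups <- readSampleGroups(groups)
  if (is.character(taxonomy) && length(taxonomy) == 1L)
    taxonomy <- readTaxonomy(taxonomy)
  oe <- OtuExperiment(num, groups = groups, taxonomy = taxonomy)
  if (!quiet)
    message(sprintf("read OTU table: %d samples, %d OTUs, %s total counts",
                    ncol(num), nrow(num), format(sum(num), big.mark = ",")))
  oe
}

#' Write an OTU table to TSV (samples in rows)
#'
#' Inverse of \code{\link{readOtuTable}} with \code{orientation="samples"};
#' a write/read round trip is cell-identical.
#'
#' @param x an OtuExperiment.
#' @param path output file.
#' @export
writeOtuTable <- function(x, path) {
  m <- t(otuCounts(x))
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample-to-group mapping
#' @param path TSV with columns sample, group.
#' @return named factor.
#' @export
readSampleGroups <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  stats::setNames(factor(df[[2]]), df[[1]])
}

#' Read a taxonomy table (OTU, semicolon-delimited lineage)
#' @param path TSV with columns otu, lineage.
#' @return data.frame with columns otu, lineage.
#' @export
readTaxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  data.frame(otu = df[[1]], lineage = df[[2]])
}

#' Export a co-occurrence network as GraphML plus a plain edge list
#'
#' Writes \code{<prefix>.graphml} (node attributes otu_id and genus, edge
#' attributes correlation and sign) and \code{<prefix>.edges.tsv}
#' (source, target, correlation). Re-reading the edge list with
#' \code{\link{readEdgeList}} reproduces the edge set exactly.
#'
#' @param net a \linkS4class{CoNetwork}.
#' @param pathPrefix output path without extension.
#' @return invisibly, the two file paths.
#' @export
writeNetwork <- function(net, pathPrefix) {
  g <- networkGraph(net)
  if (igraph::ecount(g) == 0)
    warning("writing an empty network")
  graphml <- paste0(pathPrefix, ".graphml")
  edges <- paste0(pathPrefix, ".edges.tsv")
  igraph::write_graph(g, graphml, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  if (nrow(el) == 0)
    el <- data.frame(from = character(), to = character(),
                     correlation = numeric(), sign = character())
  utils::write.table(
    data.frame(source = el$from, target = el$to,
               correlation = el$correlation),
    edges, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graphml = graphml, edges = edges))
}

#' Read an edge-list TSV written by \code{writeNetwork}
#' @param path the .edges.tsv file.
#' @return data.frame (source, target, correlation).
#' @export
readEdgeList <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "numeric"))
}

#' Assemble and validate a pipeline run configuration
#'
#' @param pseudocount added before the log transform (> 0).
#' @param cohesionMethod correlation method for cohesion,
#'   "pearson" (default of the cohesion metric) or "spearman".
#' @param scanMin,scanMax,scanStep RMT cutoff scan grid over (0, 1).
#' @param rNull taxon-shuffle iterations for cohesion calibration (>= 1).
#' @param nRandom degree-preserving randomizations for network baselines.
#' @param fdr multiple-testing method passed to \code{p.adjust}.
#' @param seed integer seed; all stochastic stages derive substreams from it.
#' @param minPrevalence minimum number of samples an OTU must be present in
#'   to enter network construction (0 disables the filter).
#' @param fallbackCutoff correlation cutoff used when the RMT scan flags no
#'   cutoff.
#' @param outDir output directory for \code{\link{runPipeline}}.
#' @return a validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(pseudocount = 1, cohesionMethod = c("pearson", "spearman"),
                      scanMin = 0.30, scanMax = 0.99, scanStep = 0.01,
                      rNull = 200L, nRandom = 100L, fdr = "BH", seed = 1L,
                      minPrevalence = 0L, fallbackCutoff = 0.8,
                      outDir = tempfile("miconet_run_")) {
  cohesionMethod <- match.arg(cohesionMethod)
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (scanMin <= 0 || scanMax >= 1 || scanMin >= scanMax)
    stop("scan bounds must satisfy 0 < scanMin < scanMax < 1")
  if (scanStep <= 0) stop("scanStep must be > 0")
  if (rNull < 1 || nRandom < 1) stop("iteration counts must be >= 1")
  structure(list(pseudocount = pseudocount, cohesionMethod = cohesionMethod,
                 scanMin = scanMin, scanMax = scanMax, scanStep = scanStep,
                 rNull = as.integer(rNull), nRandom = as.integer(nRandom),
                 fdr = fdr, seed = as.integer(seed),
                 minPrevalence = as.integer(minPrevalence),
                 fallbackCutoff = fallbackCutoff, outDir = outDir),
            class = "RunConfig")
}

# deterministic per-stage substream so stage order never perturbs results;
# kept below 2^31
stageSeed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 2047L + sum(utf8ToInt(stage)) %% 2047L
}
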