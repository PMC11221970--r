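#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' OtuExperiment: an OTU count table with sample groups and taxonomy
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding one integer
#' assay \code{"counts"} with OTUs in rows and samples in columns.
#' \code{colData$group} carries the dietary (or other) group label,
#' \code{rowData$lineage} the semicolon-delimited ranked lineage and
#' \code{rowData$genus} its genus field (\code{"unclassified"} when unknown).
#'
#' Validity requires non-negative integral counts, unique sample and OTU
#' identifiers, at least 2 samples and 2 OTUs, and a positive total count in
#' every sample.
#'
#' @export
setClass("OtuExperiment", contains = "SummarizedExperiment")

setValidity("OtuExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is missing")
  m <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must carry OTU rownames and sample colnames")
  if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate OTU identifiers")
  if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate sample identifiers")
  if (nrow(m) < 2L || ncol(m) < 2L)
    msg <- c(msg, "need at least 2 OTUs and 2 samples")
  if (any(m < 0) || any(m != round(m)))
    msg <- c(msg, "counts must be non-negative integers")
  empty <- colnames(m)[colSums(m) == 0]
  if (length(empty))
    msg <- c(msg, paste0("samples with zero total count: ",
                         paste(empty, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an OtuExperiment
#'
#' @param counts integer matrix, OTUs in rows, samples in columns, with
#'   dimnames.
#' @param groups optional named vector/factor mapping sample id to group
#'   label; names must cover all samples.
#' @param taxonomy optional data.frame with columns \code{otu} and
#'   \code{lineage} (semicolon-delimited ranks down to genus). OTUs absent
#'   from it receive an explicit \code{"unclassified"} lineage.
#' @return A validated \linkS4class{OtuExperiment}.
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("OTU_", 1:3), paste0("S", 1:4)))
#' oe <- OtuExperiment(m, groups = setNames(rep(c("A", "B"), 2), colnames(m)))
#' sampleGroups(oe)
#' @export
OtuExperiment <- function(counts, groups = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(groups)) {
    if (is.null(names(groups)))
      stop("'groups' must be named by sample id")
    missing <- setdiff(colnames(counts), names(groups))
    if (length(missing))
      stop("samples without a group: ", paste(missing, collapse = ", "))
    cd$group <- factor(as.character(groups[colnames(counts)]))
  }
  lineage <- rep("unclassified", nrow(counts))
  names(lineage) <- rownames(counts)
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    hit <- intersect(taxonomy$otu, rownames(counts))
    lineage[hit] <- taxonomy$lineage[match(hit, taxonomy$otu)]
  }
  rd <- S4Vectors::DataFrame(lineage = unname(lineage),
                             genus = genusFromLineage(lineage),
                             row.names = rownames(counts))
  new("OtuExperiment",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowData = rd, colData = cd))
}

# last informative rank of a semicolon-delimited lineage
genusFromLineage <- function(lineage) {
  vapply(strsplit(lineage, ";"), function(p) {
    p <- trimws(p)
    p <- p[nzchar(p) & p != "unclassified"]
    # strip rank prefixes such as "g__"
    p <- sub("^[a-z]__", "", p)
    p <- p[nzchar(p)]
    if (length(p)) p[length(p)] else "unclassified"
  }, character(1))
}

#' @describeIn OtuExperiment OTU-by-sample count matrix
#' @param x an OtuExperiment
#' @export
otuCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn OtuExperiment named factor of sample group labels (or NULL)
#' @export
sampleGroups <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"group" %in% colnames(cd)) return(NULL)
  stats::setNames(cd$group, rownames(cd))
}

#' @describeIn OtuExperiment taxonomy as a data.frame (otu, lineage, genus)
#' @export
taxonomyMap <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(otu = rownames(rd), lineage = rd$lineage, genus = rd$genus,
             row.names = NULL)
}

#' @describeIn OtuExperiment OTU identifiers
#' @export
otuIds <- function(x) rownames(x)

#' @describeIn OtuExperiment sample identifiers
#' @export
sampleIds <- function(x) colnames(x)

setMethod("show", "OtuExperiment", function(object) {
  m <- otuCounts(object)
  cat("OtuExperiment:", nrow(m), "OTUs x", ncol(m), "samples,",
      format(sum(m), big.mark = ","), "total counts\n")
  g <- sampleGroups(object)
  if (!is.null(g)) {
    tab <- table(g)
    cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab),
                         collapse = ", "), "\n")
  }
})

#' Pairwise correlation matrix over OTUs with p-values
#'
#' @slot rho symmetric matrix of correlation coefficients, unit diagonal.
#' @slot p matching matrix of two-sided p-values from the t approximation.
#' @slot method "spearman" or "pearson".
#' @slot nSamples number of samples the correlations were computed from.
#' @export
setClass("CorrelationResult",
         representation(rho = "matrix", p = "matrix", method = "character",
                        nSamples = "integer"))

setValidity("CorrelationResult", function(object) {
  r <- object@rho
  if (nrow(r) != ncol(r)) return("rho must be square")
  if (max(abs(r - t(r))) > 1e-12) return("rho must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-12) return("rho must have unit diagonal")
  if (any(abs(r) > 1 + 1e-12)) return("correlations outside [-1, 1]")
  TRUE
})

setMethod("show", "CorrelationResult", function(object) {
  cat("CorrelationResult:", nrow(object@rho), "x", ncol(object@rho),
      object@method, "matrix over", object@nSamples, "samples\n")
})

#' Record of an RMT threshold scan
#'
#' One row per candidate cutoff: matrix order after pruning, chi-square
#' statistics and p-values of the unfolded nearest-neighbour spacing
#' distribution against the Poisson law and the Wigner surmise, and the
#' decision flag (Poisson accepted AND Wigner rejected at 0.05).
#'
#' @slot scan data.frame with columns cutoff, order, chi2_poisson,
#'   p_poisson, chi2_wigner, p_wigner, flagged.
#' @slot chosen the smallest sustained flagged cutoff, or NA if none was
#'   found.
#' @slot unfolding label of the unfolding recipe used.
#' @export
setClass("ThresholdScan",
         representation(scan = "data.frame", chosen = "numeric",
                        unfolding = "character"))

setValidity("ThresholdScan", function(object) {
  s <- object@scan$cutoff
  if (is.unsorted(s, strictly = TRUE)) return("cutoffs must strictly increase")
  ch <- object@chosen
  if (!is.na(ch)) {
    fl <- object@scan$cutoff[which(object@scan$flagged)]
    if (!length(fl) || min(abs(ch - fl)) > 1e-12)
      return("chosen cutoff must be a flagged cutoff")
  }
  TRUE
})

#' @describeIn ThresholdScan the selected cutoff (NA when none was flagged)
#' @param x a ThresholdScan
#' @export
chosenCutoff <- function(x) x@chosen

#' @describeIn ThresholdScan the full per-cutoff scan table
#' @export
scanTable <- function(x) x@scan

setMethod("show", "ThresholdScan", function(object) {
  cat("ThresholdScan:", nrow(object@scan), "cutoffs in [",
      min(object@scan$cutoff), ",", max(object@scan$cutoff), "], chosen =",
      if (is.na(object@chosen)) "none found" else object@chosen,
      sprintf("(unfolding: %s)\n", object@unfolding))
})

#' Signed, thresholded co-occurrence network
#'
#' @slot graph an undirected \pkg{igraph} graph; vertices carry
#'   \code{otu_id} and \code{genus}, edges carry \code{correlation} and
#'   categorical \code{sign} ("positive"/"negative").
#' @slot cutoff the correlation threshold that produced the edge set.
#' @export
setClass("CoNetwork", representation(graph = "ANY", cutoff = "numeric"))

setValidity("CoNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::ecount(g) > 0) {
    w <- igraph::E(g)$correlation
    if (any(abs(w) < object@cutoff - 1e-12))
      return("edge |correlation| below cutoff")
  }
  if (igraph::vcount(g) > 0 && any(igraph::degree(g) == 0))
    return("isolated nodes are not allowed")
  TRUE
})

#' @describeIn CoNetwork underlying igraph graph
#' @param x a CoNetwork
#' @export
networkGraph <- function(x) x@graph

#' @describeIn CoNetwork correlation threshold of the network
#' @export
networkCutoff <- function(x) x@cutoff

setMethod("show", "CoNetwork", function(object) {
  n <- igraph::vcount(object@graph); e <- igraph::ecount(object@graph)
  pos <- if (e) sum(igraph::E(object@graph)$correlation > 0) else 0L
  cat(sprintf(
    "CoNetwork: N = %d, E = %d (%d positive, %d negative), cutoff = %.2f\n",
    n, e, pos, e - pos, object@cutoff))
})

#' Per-sample cohesion with its connectedness calibration
#'
#' @slot positive named numeric, per-sample positive cohesion (>= 0).
#' @slot negative named numeric, per-sample negative cohesion (<= 0).
#' @slot connectedness data.frame (otu, positive, negative) of per-taxon
#'   null-corrected connectedness values.
#' @slot method correlation method used ("pearson" or "spearman").
#' @slot rNull number of taxon-shuffle null iterations.
#' @slot seed seed used for the null model.
#' @export
setClass("CohesionResult",
         representation(positive = "numeric", negative = "numeric",
                        connectedness = "data.frame", method = "character",
                        rNull = "integer", seed = "integer"))

setValidity("CohesionResult", function(object) {
  if (any(object@positive < -1e-12)) return("positive cohesion must be >= 0")
  if (any(object@negative > 1e-12)) return("negative cohesion must be <= 0")
  if (!all(c("otu", "positive", "negative") %in%
           colnames(object@connectedness)))
    return("connectedness needs columns otu, positive, negative")
  TRUE
})

#' @describeIn CohesionResult named vector of per-sample positive cohesion
#' @param x a CohesionResult
#' @export
positiveCohesion <- function(x) x@positive

#' @describeIn CohesionResult named vector of per-sample negative cohesion
#' @export
negativeCohesion <- function(x) x@negative

#' @describeIn CohesionResult per-taxon connectedness table
#' @export
connectednessTable <- function(x) x@connectedness

setMethod("show", "CohesionResult", function(object) {
  cat(sprintf(
    "CohesionResult: %d samples, %d taxa (%s, Rnull = %d)\n",
    length(object@positive), nrow(object@connectedness), object@method,
    object@rNull))
  cat(sprintf("  positive cohesion: mean %.4f;  negative: mean %.4f\n",
              mean(object@positive), mean(object@negative)))
})
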