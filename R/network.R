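#' Log-transform counts before correlation
#'
#' Entrywise ln(count + pseudocount). Because the map is strictly monotone,
#' Spearman correlations are unchanged by it; it is kept for parity with the
#' conventional network-construction recipe and for Pearson-based variants.
#'
#' @param x an \linkS4class{OtuExperiment} or count matrix (OTUs x samples).
#' @param pseudocount positive value added before taking logs.
#' @return matrix of the same shape.
#' @export
logTransform <- function(x, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  m <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
  log(m + pseudocount)
}

#' Pairwise Spearman correlations over OTUs
#'
#' Average-rank tie handling (as in \code{cor(method = "spearman")});
#' two-sided p-values from the t approximation
#' t = rho * sqrt((n-2)/(1-rho^2)). Constant rows get rho = 0, p = 1 by
#' convention.
#'
#' @param m matrix with OTUs in rows and samples in columns (>= 4 samples),
#'   e.g. from \code{\link{logTransform}}.
#' @return a \linkS4class{CorrelationResult}.
#' @export
spearmanMatrix <- function(m) {
  m <- as.matrix(m)
  n <- ncol(m)
  if (n < 4) stop("need at least 4 samples for rank correlations")
  const <- apply(m, 1, function(v) length(unique(v)) == 1L)
  rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  rho[const, ] <- 0; rho[, const] <- 0
  diag(rho) <- 1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-15] <- 0
  p[const, ] <- 1; p[, const] <- 1
  diag(p) <- 0
  rho <- (rho + t(rho)) / 2
  new("CorrelationResult", rho = rho, p = (p + t(p)) / 2,
      method = "spearman", nSamples = as.integer(n))
}

#' Build a signed co-occurrence network at a correlation cutoff
#'
#' An undirected edge connects every OTU pair with |rho| >= cutoff; the edge
#' keeps the signed correlation and a categorical sign attribute. Only OTUs
#' with at least one supra-threshold edge become nodes, so N depends on the
#' cutoff.
#'
#' @param corr a \linkS4class{CorrelationResult}.
#' @param cutoff correlation threshold in (0, 1].
#' @param taxonomy optional data.frame (otu, genus) used to annotate nodes.
#' @return a \linkS4class{CoNetwork} (possibly empty, with a warning).
#' @export
buildNetwork <- function(corr, cutoff, taxonomy = NULL) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  rho <- corr@rho
  adj <- abs(rho) >= cutoff
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("no edges survive cutoff ", cutoff, "; empty network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(new("CoNetwork", graph = g, cutoff = cutoff))
  }
  ids <- rownames(rho)
  el <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                   correlation = rho[idx])
  el$sign <- ifelse(el$correlation >= 0, "positive", "negative")
  nodes <- sort(unique(c(el$from, el$to)))
  vdf <- data.frame(name = nodes, otu_id = nodes)
  vdf$genus <- if (!is.null(taxonomy))
    as.character(taxonomy$genus[match(nodes, taxonomy$otu)])
  else NA_character_
  vdf$genus[is.na(vdf$genus)] <- "unclassified"
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = vdf)
  new("CoNetwork", graph = g, cutoff = cutoff)
}

#' Topology indices of a co-occurrence network
#'
#' N, E, average connectivity avgK = 2E/N, average clustering coefficient
#' (per-node transitivity averaged, zero for degree-1 nodes), average
#' geodesic distance over the giant component, and modularity of a greedy
#' agglomerative partition (deterministic for a given graph).
#'
#' @param net a non-empty \linkS4class{CoNetwork} or igraph graph.
#' @return list: N, E, avgK, clustering, pathLength, modularity, membership.
#' @export
networkTopology <- function(net) {
  g <- if (is(net, "CoNetwork")) networkGraph(net) else net
  if (igraph::vcount(g) == 0)
    stop("empty network: no edges survived buildNetwork")
  N <- igraph::vcount(g); E <- igraph::ecount(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  pl <- igraph::mean_distance(giant, directed = FALSE)
  fg <- igraph::cluster_fast_greedy(g, weights = NULL)
  list(N = N, E = E, avgK = 2 * E / N, clustering = mean(cc),
       pathLength = pl, modularity = igraph::modularity(fg),
       membership = igraph::membership(fg))
}

#' Random-network baselines for topology indices
#'
#' Generates R degree-preserving randomizations of the network by double
#' edge swaps (10 x E attempted swaps each), recomputes modularity, average
#' clustering and average path length per replicate, and reports the null
#' mean, sd and the z-score of the observed value.
#'
#' @param net a \linkS4class{CoNetwork} with >= 2 edges.
#' @param R number of randomized replicates.
#' @param seed integer seed (R's RNG drives the swaps).
#' @return list with \code{summary} (data.frame index, observed, null_mean,
#'   null_sd, z) and \code{values} (R x 3 matrix of null index values).
#' @export
randomBaseline <- function(net, R = 100, seed = 1) {
  g <- networkGraph(net)
  if (igraph::ecount(g) < 2) stop("need at least 2 edges to randomize")
  obs <- networkTopology(net)
  set.seed(as.integer(seed))
  vals <- matrix(NA_real_, R, 3,
                 dimnames = list(NULL, c("modularity", "clustering",
                                         "pathLength")))
  for (r in seq_len(R)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(
      niter = 10 * igraph::ecount(g)))
    stopifnot(identical(sort(igraph::degree(gr)), sort(igraph::degree(g))))
    cc <- igraph::transitivity(gr, type = "local", isolates = "zero")
    comp <- igraph::components(gr)
    giant <- igraph::induced_subgraph(
      gr, which(comp$membership == which.max(comp$csize)))
    vals[r, ] <- c(igraph::modularity(igraph::cluster_fast_greedy(gr)),
                   mean(cc),
                   igraph::mean_distance(giant, directed = FALSE))
  }
  obsv <- c(obs$modularity, obs$clustering, obs$pathLength)
  mu <- colMeans(vals); sdv <- apply(vals, 2, stats::sd)
  list(summary = data.frame(index = colnames(vals), observed = obsv,
                            null_mean = mu, null_sd = sdv,
                            z = (obsv - mu) / sdv, row.names = NULL),
       values = vals)
}

#' Neighbourhood of a focal taxon with association signs
#'
#' Lists the direct neighbours of an OTU in the network with their signed
#' correlations, and counts positive vs negative associations. An absent
#' OTU yields zero neighbours, not an error, so focal taxa can be queried
#' uniformly across group networks of different node sets.
#'
#' @param net a \linkS4class{CoNetwork}.
#' @param otuId focal OTU identifier.
#' @return list: \code{neighbours} (data.frame otu, correlation, sign),
#'   \code{nPositive}, \code{nNegative}.
#' @export
focalNeighborhood <- function(net, otuId) {
  g <- networkGraph(net)
  empty <- data.frame(otu = character(), correlation = numeric(),
                      sign = character())
  if (igraph::vcount(g) == 0 ||
      !otuId %in% igraph::V(g)$name)
    return(list(neighbours = empty, nPositive = 0L, nNegative = 0L))
  inc <- igraph::incident(g, otuId)
  if (length(inc) == 0)
    return(list(neighbours = empty, nPositive = 0L, nNegative = 0L))
  ends <- igraph::ends(g, inc)
  nb <- ifelse(ends[, 1] == otuId, ends[, 2], ends[, 1])
  rho <- igraph::edge_attr(g, "correlation", inc)
  df <- data.frame(otu = nb, correlation = rho,
                   sign = ifelse(rho >= 0, "positive", "negative"))
  list(neighbours = df[order(-abs(df$correlation)), ],
       nPositive = sum(rho >= 0), nNegative = sum(rho < 0))
}
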