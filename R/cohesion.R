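#' Null-corrected pairwise correlations (taxon-shuffle calibration)
#'
#' Computes the observed correlation matrix over taxa, then subtracts, for
#' every pair, the correlation expected in the absence of true association.
#' The null is the taxon-shuffle model: the focal taxon's abundances are
#' permuted across samples while all partners stay fixed, its correlations
#' with every partner are recomputed, and the procedure is repeated
#' \code{rNull} times and averaged. The corrected matrix is symmetrized by
#' averaging the two focal choices of each pair. Taxa constant across
#' samples get zero corrected correlation by convention.
#'
#' @param rel taxa-by-sample proportion matrix (>= 4 samples).
#' @param method "pearson" (the cohesion metric's default) or "spearman".
#' @param rNull number of shuffle iterations (a warning is issued below 50).
#' @param seed integer seed for the permutations.
#' @return symmetric corrected correlation matrix with zero diagonal.
#' @export
nullCorrectedCorrelations <- function(rel, method = c("pearson", "spearman"),
                                      rNull = 200, seed = 1) {
  method <- match.arg(method)
  m <- t(as.matrix(rel))                 # samples x taxa for cor()
  n <- nrow(m); p <- ncol(m)
  if (n < 4) stop("need at least 4 samples")
  if (rNull < 50) warning("rNull below 50; null means will be noisy")
  const <- apply(m, 2, function(v) length(unique(v)) == 1L)
  obs <- suppressWarnings(stats::cor(m, method = method))
  obs[is.na(obs)] <- 0
  obs[const, ] <- 0; obs[, const] <- 0
  set.seed(as.integer(seed))
  nullM <- matrix(0, p, p, dimnames = dimnames(obs))
  for (i in seq_len(p)) {
    if (const[i]) next
    perms <- replicate(rNull, sample(m[, i]))
    nc <- suppressWarnings(stats::cor(perms, m, method = method))
    nc[is.na(nc)] <- 0
    nullM[i, ] <- colMeans(nc)
  }
  corrected <- obs - nullM
  corrected <- (corrected + t(corrected)) / 2
  corrected[const, ] <- 0; corrected[, const] <- 0
  diag(corrected) <- 0
  corrected
}

#' Per-taxon positive and negative connectedness
#'
#' For taxon i, positive connectedness is the mean of its positive
#' null-corrected correlations with all other taxa (0 if it has none);
#' negative connectedness is the mean of the negative ones (0 if none).
#' The diagonal is excluded.
#'
#' @param corrected symmetric null-corrected correlation matrix from
#'   \code{\link{nullCorrectedCorrelations}}.
#' @return data.frame: otu, positive (>= 0), negative (<= 0).
#' @export
connectedness <- function(corrected) {
  corrected <- as.matrix(corrected)
  if (nrow(corrected) != ncol(corrected)) stop("matrix must be square")
  if (max(abs(corrected - t(corrected))) > 1e-8)
    stop("matrix must be symmetric")
  m <- nrow(corrected)
  pos <- neg <- numeric(m)
  for (i in seq_len(m)) {
    v <- corrected[i, -i]
    vp <- v[v > 0]; vn <- v[v < 0]
    pos[i] <- if (length(vp)) mean(vp) else 0
    neg[i] <- if (length(vn)) mean(vn) else 0
  }
  ids <- rownames(corrected)
  if (is.null(ids)) ids <- paste0("taxon_", seq_len(m))
  data.frame(otu = ids, positive = pos, negative = neg)
}

#' Abundance-weighted cohesion per sample
#'
#' The cohesion index of a sample is the sum over taxa of relative
#' abundance times connectedness, applied separately to the positive and
#' negative connectedness vectors: positive cohesion quantifies the
#' cooperative association a sample carries, negative cohesion the
#' competitive one. Because abundances sum to 1, each cohesion value is
#' bounded by the largest connectedness in magnitude.
#'
#' @param rel taxa-by-sample proportion matrix.
#' @param conn connectedness data.frame from \code{\link{connectedness}},
#'   aligned with the rows of \code{rel}.
#' @param method,rNull,seed metadata echoed into the result.
#' @return a \linkS4class{CohesionResult}.
#' @export
cohesionIndex <- function(rel, conn, method = "pearson", rNull = NA_integer_,
                          seed = NA_integer_) {
  if (nrow(rel) != nrow(conn))
    stop(sprintf("axis mismatch: %d taxa in abundances vs %d in connectedness",
                 nrow(rel), nrow(conn)))
  if (!is.null(rownames(rel)) && !all(rownames(rel) == conn$otu)) {
    if (!setequal(rownames(rel), conn$otu))
      stop("taxon identifiers differ between abundances and connectedness")
    conn <- conn[match(rownames(rel), conn$otu), ]
  }
  pos <- as.numeric(crossprod(rel, conn$positive))
  neg <- as.numeric(crossprod(rel, conn$negative))
  names(pos) <- names(neg) <- colnames(rel)
  new("CohesionResult", positive = pos, negative = pmin(neg, 0),
      connectedness = conn, method = method,
      rNull = as.integer(rNull), seed = as.integer(seed))
}

#' One-call cohesion from a count or proportion table
#'
#' Chains \code{\link{relativeAbundance}} (when given counts),
#' \code{\link{nullCorrectedCorrelations}}, \code{\link{connectedness}} and
#' \code{\link{cohesionIndex}}.
#'
#' @param x an \linkS4class{OtuExperiment}, count matrix or proportion
#'   matrix (taxa x samples; treated as proportions when columns already
#'   sum to 1).
#' @inheritParams nullCorrectedCorrelations
#' @return a \linkS4class{CohesionResult}.
#' @export
cohesion <- function(x, method = c("pearson", "spearman"), rNull = 200,
                     seed = 1) {
  method <- match.arg(method)
  m <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
  rel <- if (max(abs(colSums(m) - 1)) < 1e-6) m else relativeAbundance(m)
  corrected <- nullCorrectedCorrelations(rel, method = method,
                                         rNull = rNull, seed = seed)
  cohesionIndex(rel, connectedness(corrected), method = method,
                rNull = rNull, seed = seed)
}

#' Group contrast of cohesion values
#'
#' ANOVA with Tukey letters on per-sample positive (and negative) cohesion,
#' plus the ratio of every ordered pair of group means of positive
#' cohesion - the "times higher" comparison used when contrasting dietary
#' groups.
#'
#' @param coh a \linkS4class{CohesionResult}.
#' @param groups named group vector covering the samples.
#' @return list: positive and negative \code{\link{anovaTukey}} outputs and
#'   \code{ratios} (data.frame group1, group2, ratio of positive-cohesion
#'   means).
#' @export
cohesionContrast <- function(coh, groups) {
  pos <- positiveCohesion(coh); neg <- negativeCohesion(coh)
  g <- groups[names(pos)]
  atPos <- anovaTukey(pos, g)
  atNeg <- anovaTukey(neg, g)
  mu <- stats::setNames(atPos$summary$mean, atPos$summary$group)
  pairs <- expand.grid(group1 = names(mu), group2 = names(mu),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$group1 != pairs$group2, ]
  pairs$ratio <- mu[pairs$group1] / mu[pairs$group2]
  rownames(pairs) <- NULL
  list(positive = atPos, negative = atNeg, ratios = pairs)
}

#' Association between a focal OTU's abundance and positive cohesion
#'
#' Spearman correlation (with p-value) between an OTU's per-sample counts
#' and the per-sample positive cohesion, as used to relate dominant taxa to
#' community cooperation.
#'
#' @param x an \linkS4class{OtuExperiment} or count matrix (OTUs x samples).
#' @param coh a \linkS4class{CohesionResult} over the same samples.
#' @param otuId focal OTU.
#' @return list: rho, p.value, n.
#' @export
abundanceCohesionCorrelation <- function(x, coh, otuId) {
  m <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
  if (!otuId %in% rownames(m)) stop("OTU not found: ", otuId)
  pos <- positiveCohesion(coh)
  common <- intersect(colnames(m), names(pos))
  if (length(common) < 4) stop("need at least 4 shared samples")
  ct <- suppressWarnings(
    stats::cor.test(m[otuId, common], pos[common], method = "spearman"))
  list(rho = unname(ct$estimate), p.value = ct$p.value,
       n = length(common))
}
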