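#' Relative abundance of an OTU table
#'
#' Converts counts to per-sample proportions (each column of the result
#' sums to 1). Matrix orientation follows the container: OTUs in rows,
#' samples in columns.
#'
#' @param x an \linkS4class{OtuExperiment} or an OTU-by-sample count matrix.
#' @return numeric matrix of proportions, same dimnames.
#' @export
relativeAbundance <- function(x) {
  m <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
  tot <- colSums(m)
  zero <- colnames(m)[tot == 0]
  if (length(zero))
    stop("samples with zero total count: ", paste(zero, collapse = ", "))
  sweep(m, 2, tot, "/")
}

#' Aggregate a relative-abundance table to genus level
#'
#' Genus proportion is the sum of its member OTU proportions; compositional
#' closure is preserved. OTUs missing from the taxonomy are kept under an
#' explicit \code{"unclassified"} genus, never dropped.
#'
#' @param rel OTU-by-sample proportion matrix from
#'   \code{\link{relativeAbundance}}.
#' @param taxonomy data.frame with columns \code{otu} and \code{genus}
#'   (as from \code{\link{taxonomyMap}}), or with \code{lineage} from which
#'   genus is derived.
#' @return genus-by-sample proportion matrix.
#' @export
aggregateGenus <- function(rel, taxonomy) {
  taxonomy <- as.data.frame(taxonomy)
  if (!"genus" %in% colnames(taxonomy)) {
    if (!"lineage" %in% colnames(taxonomy))
      stop("taxonomy needs a 'genus' or 'lineage' column")
    taxonomy$genus <- genusFromLineage(taxonomy$lineage)
  }
  gen <- taxonomy$genus[match(rownames(rel), taxonomy$otu)]
  gen[is.na(gen)] <- "unclassified"
  out <- rowsum(rel, group = gen)
  out[order(-rowMeans(out)), , drop = FALSE]
}

#' Simpson dominance index per sample
#'
#' Reports the dominance form D = sum(p_i^2): lower D means higher
#' diversity. A single-taxon sample has D = 1; the uniform composition over
#' S taxa attains the minimum 1/S. Set \code{complement = TRUE} for 1 - D
#' (Gini-Simpson) when comparing with tools that report that variant.
#'
#' @param rel OTU-by-sample proportion matrix.
#' @param complement return 1 - D instead of D.
#' @return named numeric vector, one value per sample.
#' @export
simpsonIndex <- function(rel, complement = FALSE) {
  d <- colSums(rel^2)
  if (complement) 1 - d else d
}

#' Bray-Curtis principal coordinates analysis
#'
#' Computes the Bray-Curtis dissimilarity on per-sample compositions, then
#' classical metric scaling (Gower double-centering and eigendecomposition,
#' coordinates scaled by the square root of the eigenvalue). Negative
#' eigenvalues are reported, not dropped; proportion explained is computed
#' over positive eigenvalues only. No Lingoes/Cailliez correction is applied
#' unless requested, keeping axes comparable with common vegan-style
#' defaults.
#'
#' @param rel OTU-by-sample proportion matrix (>= 3 samples).
#' @param k number of axes requested.
#' @param correction "none" (default) or "cailliez".
#' @return list with \code{points} (samples x k coordinate matrix),
#'   \code{eig} (all eigenvalues, non-increasing) and
#'   \code{proportion} (variance explained per returned axis).
#' @export
brayCurtisPcoa <- function(rel, k = 2, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  if (ncol(rel) < 3) stop("PCoA needs at least 3 samples")
  d <- vegan::vegdist(t(rel), method = "bray")
  fit <- suppressWarnings(   # re-warned below with the axis count
    stats::cmdscale(d, k = min(k, ncol(rel) - 1), eig = TRUE,
                    add = correction == "cailliez"))
  eig <- sort(fit$eig, decreasing = TRUE)
  npos <- sum(eig > sqrt(.Machine$double.eps))
  if (k > npos) {
    warning(sprintf("k = %d exceeds the %d positive eigenvalues; truncated",
                    k, npos))
    k <- npos
  }
  pts <- fit$points[, seq_len(min(k, ncol(fit$points))), drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  list(points = pts, eig = eig,
       proportion = eig[seq_len(ncol(pts))] / sum(eig[eig > 0]))
}

#' Pairwise differential abundance by Welch's t-test
#'
#' STAMP-style two-group comparison: a two-sided Welch (unequal-variance)
#' t-test per OTU on relative abundances, with Benjamini-Hochberg q-values
#' by default. An OTU constant at the same value in both groups gets p = 1
#' by convention; constant at different values (zero variance, nonzero
#' difference) gets p = 0.
#'
#' @param rel OTU-by-sample proportion matrix.
#' @param groups named group vector covering the samples.
#' @param pair character vector of the two group labels to compare.
#' @param fdr method for \code{p.adjust} (default "BH").
#' @return data.frame: otu, mean proportions per group, difference
#'   (group1 - group2), t statistic, p, q; ordered by q.
#' @export
welchDifferential <- function(rel, groups, pair, fdr = "BH") {
  if (length(pair) != 2) stop("'pair' must name exactly two groups")
  groups <- groups[colnames(rel)]
  miss <- setdiff(pair, unique(as.character(groups)))
  if (length(miss))
    stop("group absent from metadata: ", paste(miss, collapse = ", "))
  a <- rel[, groups == pair[1], drop = FALSE]
  b <- rel[, groups == pair[2], drop = FALSE]
  if (ncol(a) < 3 || ncol(b) < 3)
    stop("each group needs at least 3 samples")
  res <- t(vapply(seq_len(nrow(rel)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      d <- mean(x) - mean(y)
      return(c(mean(x), mean(y), d, if (d == 0) 0 else sign(d) * Inf,
               if (d == 0) 1 else 0))
    }
    tt <- stats::t.test(x, y)
    c(mean(x), mean(y), mean(x) - mean(y), unname(tt$statistic), tt$p.value)
  }, numeric(5)))
  out <- data.frame(otu = rownames(rel), mean1 = res[, 1], mean2 = res[, 2],
                    difference = res[, 3], t = res[, 4], p = res[, 5])
  names(out)[2:3] <- paste0("mean_", pair)
  out$q <- stats::p.adjust(out$p, method = fdr)
  out[order(out$q, out$p), ]
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Group means and standard errors (sd/sqrt(n)), the one-way ANOVA p-value,
#' Tukey honest-significant-difference pairwise comparisons, and letters
#' where groups sharing a letter are not significantly different at the
#' given level.
#'
#' @param values numeric vector of per-sample (or per-replicate) values.
#' @param groups group labels aligned with \code{values} (or named vector
#'   matched by names of \code{values}).
#' @param alpha significance level for the letter display.
#' @return list with \code{summary} (group, n, mean, se, letter),
#'   \code{anova_p}, and \code{tukey} (pairwise table from TukeyHSD).
#' @export
anovaTukey <- function(values, groups, alpha = 0.05) {
  if (!is.null(names(values)) && !is.null(names(groups)))
    groups <- groups[names(values)]
  g <- factor(as.character(groups))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  n <- table(g)
  if (any(n < 2))
    stop("groups with fewer than 2 values: ",
         paste(names(n)[n < 2], collapse = ", "))
  df <- data.frame(y = as.numeric(values), g = g)
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  p <- an[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$g
  letters <- cldFromTukey(fit, levels(g), alpha)
  agg <- vapply(levels(g), function(l) {
    v <- df$y[df$g == l]
    c(n = length(v), mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  }, numeric(3))
  list(summary = data.frame(group = levels(g), n = agg["n", ],
                            mean = agg["mean", ], se = agg["se", ],
                            letter = letters[levels(g)], row.names = NULL),
       anova_p = p,
       tukey = data.frame(comparison = rownames(tk), tk, row.names = NULL))
}

# compact letter display from Tukey contrasts via multcomp
cldFromTukey <- function(fit, levs, alpha) {
  res <- try({
    glht <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
    multcomp::cld(glht, level = alpha)$mcletters$Letters
  }, silent = TRUE)
  if (!inherits(res, "try-error") && !any(is.na(res))) return(res)
  # degenerate fits (e.g. zero residual variance): letters from TukeyHSD p
  tk <- stats::TukeyHSD(fit)$g
  pmat <- matrix(1, length(levs), length(levs), dimnames = list(levs, levs))
  for (r in rownames(tk)) {
    ab <- strsplit(r, "-", fixed = TRUE)[[1]]
    pv <- tk[r, "p adj"]
    if (is.nan(pv)) pv <- if (abs(tk[r, "diff"]) > 0) 0 else 1
    pmat[ab[1], ab[2]] <- pmat[ab[2], ab[1]] <- pv
  }
  insertAbsorbLetters(pmat, alpha)
}

# insert-and-absorb letter assignment from a pairwise p-value matrix
insertAbsorbLetters <- function(pmat, alpha) {
  levs <- rownames(pmat)
  groupsets <- list(levs)          # start with one letter covering all
  for (i in seq_along(levs)) for (j in seq_along(levs)) {
    if (j <= i || pmat[i, j] >= alpha) next
    for (k in seq_along(groupsets)) {
      s <- groupsets[[k]]
      if (all(c(levs[i], levs[j]) %in% s)) {
        groupsets[[k]] <- setdiff(s, levs[i])
        groupsets <- c(groupsets, list(setdiff(s, levs[j])))
      }
    }
    # absorb subsets
    keep <- rep(TRUE, length(groupsets))
    for (k in seq_along(groupsets)) for (l in seq_along(groupsets))
      if (k != l && keep[l] &&
          all(groupsets[[k]] %in% groupsets[[l]])) keep[k] <- FALSE
    groupsets <- groupsets[keep & lengths(groupsets) > 0]
  }
  # order letter groups by the mean rank of their members
  ord <- order(vapply(groupsets, function(s) mean(match(s, levs)), 0))
  groupsets <- groupsets[ord]
  out <- stats::setNames(rep("", length(levs)), levs)
  for (k in seq_along(groupsets))
    out[groupsets[[k]]] <- paste0(out[groupsets[[k]]], letters[k])
  out
}

#' Simpson diversity with group comparison
#'
#' Convenience wrapper: per-sample Simpson dominance, then
#' \code{\link{anovaTukey}} across groups.
#'
#' @inheritParams simpsonIndex
#' @param groups named group vector covering the samples.
#' @return list with \code{perSample} and the \code{anovaTukey} output.
#' @export
simpsonByGroup <- function(rel, groups, complement = FALSE) {
  d <- simpsonIndex(rel, complement = complement)
  c(list(perSample = d), anovaTukey(d, groups[names(d)]))
}
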