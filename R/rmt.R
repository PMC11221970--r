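#' Unfold an eigenvalue spectrum to unit mean spacing
#'
#' Rescales eigenvalues so the local mean spacing is 1, making
#' nearest-neighbour spacing distributions comparable with the universal
#' Poisson and Wigner laws. The default recipe fits a smooth monotone curve
#' (Hyman-filtered cubic spline on 10 knots) to the empirical cumulative
#' spectral density; \code{method = "mean"} instead divides raw spacings by
#' their mean, the simple normalization used as an independent oracle for
#' small matrices.
#'
#' @param ev numeric vector of eigenvalues.
#' @param method "spline" (default) or "mean".
#' @param nKnots number of spline knots.
#' @return vector of nearest-neighbour spacings of the unfolded spectrum.
#' @export
unfoldSpacings <- function(ev, method = c("spline", "mean"), nKnots = 10) {
  method <- match.arg(method)
  ev <- sort(ev)
  if (length(ev) < 3) stop("need at least 3 eigenvalues")
  if (method == "mean") {
    d <- diff(ev)
    return(d / mean(d))
  }
  u <- unique(ev)
  if (length(u) < 4) {           # too degenerate for a spline
    d <- diff(ev)
    return(d / mean(d))
  }
  cc <- cumsum(tabulate(match(ev, u)))
  k <- max(4, min(nKnots, length(u)))
  idx <- unique(round(seq(1, length(u), length.out = k)))
  f <- stats::splinefun(u[idx], cc[idx], method = "hyman")
  diff(f(ev))
}

#' Chi-square goodness of fit of spacings to the Poisson or Wigner law
#'
#' Spacings are normalized to unit mean, binned into equal-probability bins
#' of the reference law (20 bins, merged so every expected count is >= 5),
#' and compared by Pearson's chi-square. Reference densities: Poisson
#' exp(-d); Wigner surmise (pi d / 2) exp(-pi d^2 / 4).
#'
#' @param spacings nearest-neighbour spacings (unfolded).
#' @param law "poisson" or "wigner".
#' @param nBins maximum number of equal-probability bins.
#' @return list: statistic, df, p.value, law.
#' @export
nnsdTest <- function(spacings, law = c("poisson", "wigner"), nBins = 20) {
  law <- match.arg(law)
  d <- spacings[is.finite(spacings)]
  d <- d[d >= 0]
  if (length(d) < 10) stop("need at least 10 spacings")
  d <- d / mean(d)
  n <- length(d)
  qf <- if (law == "poisson") function(p) stats::qexp(p, 1)
        else function(p) sqrt(-4 * log(1 - p) / pi)
  cf <- if (law == "poisson") function(x) stats::pexp(x, 1)
        else function(x) 1 - exp(-pi * x^2 / 4)
  nb <- min(nBins, max(2, floor(n / 5)))   # expected count >= 5 per bin
  br <- qf(seq(0, 1, length.out = nb + 1))
  br[1] <- 0; br[nb + 1] <- Inf
  obs <- as.vector(table(cut(d, breaks = br, include.lowest = TRUE)))
  expd <- n * diff(c(cf(br[-(nb + 1)]), 1))
  stat <- sum((obs - expd)^2 / expd)
  df <- nb - 1
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE), law = law)
}

#' RMT screening of the optimal correlation cutoff
#'
#' For each candidate cutoff s on the grid: entries with |rho| < s are
#' zeroed, rows/columns left without any off-diagonal entry are dropped,
#' the pruned matrix is eigendecomposed, the spectrum unfolded, and the
#' nearest-neighbour spacing distribution tested against the Poisson law
#' and the Wigner surmise. A cutoff is flagged when Poisson fits
#' (p > alpha) and Wigner does not (p <= alpha) - the transition from
#' correlated (GOE-like) to uncorrelated (Poisson-like) spectral
#' statistics. Because per-cutoff chi-square p-values fluctuate on small
#' matrices, a transition only counts when it is sustained: the chosen
#' cutoff is the smallest one opening a run of \code{persistence}
#' consecutive flagged grid points (falling back to the smallest flagged
#' cutoff when no run is long enough). The full scan table is always
#' returned, so callers can widen the bounds when no cutoff is flagged.
#'
#' @param corr a \linkS4class{CorrelationResult} (matrix order >= 20 after
#'   pruning at \code{sMin}).
#' @param sMin,sMax,sStep scan grid (defaults 0.30-0.99 by 0.01, the
#'   molecular-ecological-network convention).
#' @param alpha significance level for both spacing tests.
#' @param minOrder smallest pruned-matrix order still scanned; also the
#'   minimum number of distinct eigenvalues required for the spacing tests.
#' @param degeneracyTol eigenvalues closer than this are treated as one
#'   degenerate level and collapsed before unfolding.
#' @param persistence number of consecutive flagged cutoffs required for a
#'   sustained transition.
#' @param unfolding passed to \code{\link{unfoldSpacings}}.
#' @return a \linkS4class{ThresholdScan}.
#' @export
rmtThreshold <- function(corr, sMin = 0.30, sMax = 0.99, sStep = 0.01,
                         alpha = 0.05, minOrder = 20,
                         degeneracyTol = 1e-8, persistence = 3,
                         unfolding = c("spline", "mean")) {
  unfolding <- match.arg(unfolding)
  rho <- corr@rho
  grid <- seq(sMin, sMax, by = sStep)
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    s <- grid[i]
    M <- rho
    M[abs(M) < s] <- 0
    diag(M) <- 1
    keep <- colSums(M != 0) > 1          # >= 1 off-diagonal entry
    M <- M[keep, keep, drop = FALSE]
    ord <- nrow(M)
    if (ord < minOrder) {
      rows[[i]] <- data.frame(cutoff = s, order = ord,
                              chi2_poisson = NA_real_, p_poisson = NA_real_,
                              chi2_wigner = NA_real_, p_wigner = NA_real_,
                              flagged = FALSE)
      next
    }
    ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    # collapse spectral degeneracies: rank-deficient correlation matrices
    # (few samples) carry large eigenvalue multiplicities whose zero
    # spacings mimic the Poisson law's excess at zero
    ev <- ev[c(TRUE, diff(ev) > degeneracyTol)]
    if (length(ev) < minOrder) {
      rows[[i]] <- data.frame(cutoff = s, order = ord,
                              chi2_poisson = NA_real_, p_poisson = NA_real_,
                              chi2_wigner = NA_real_, p_wigner = NA_real_,
                              flagged = FALSE)
      next
    }
    d <- unfoldSpacings(ev, method = unfolding)
    tp <- nnsdTest(d, "poisson")
    tw <- nnsdTest(d, "wigner")
    rows[[i]] <- data.frame(cutoff = s, order = ord,
                            chi2_poisson = tp$statistic,
                            p_poisson = tp$p.value,
                            chi2_wigner = tw$statistic,
                            p_wigner = tw$p.value,
                            flagged = tp$p.value > alpha &
                              tw$p.value <= alpha)
  }
  scan <- do.call(rbind, rows)
  if (all(scan$order < minOrder))
    stop("matrix order below ", minOrder, " over the whole scan grid; ",
         "widen the bounds or lower sMin")
  chosen <- NA_real_
  if (any(scan$flagged)) {
    runs <- rle(scan$flagged)
    starts <- cumsum(c(1, runs$lengths))[seq_along(runs$lengths)]
    sustained <- starts[runs$values & runs$lengths >= persistence]
    chosen <- if (length(sustained)) scan$cutoff[min(sustained)]
              else min(scan$cutoff[scan$flagged])
  }
  new("ThresholdScan", scan = scan, chosen = chosen, unfolding = unfolding)
}
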