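#' Growth-performance metrics of one trial replicate
#'
#' Computes the eight standard aquaculture indices from a cage record:
#' \itemize{
#'   \item WGR (\%) = 100 (FBW - IBW) / IBW
#'   \item SGR (\%/d) = 100 (ln FBW - ln IBW) / days
#'   \item FCR = feed / (final total weight - initial total weight)
#'   \item FI (g/100 g/d) = 100 feed / ((final + initial total)/2) / days
#'   \item SR (\%) = 100 final count / initial count
#'   \item CF (g/cm^3) = 100 body weight / body length^3
#'   \item HSI (\%) = 100 liver weight / body weight
#'   \item VSI (\%) = 100 visceral weight / body weight
#' }
#' Cage totals are mean weight times fish count. Metrics whose fields are
#' missing come back NA; the others are still computed. FCR is NA with a
#' warning when no weight was gained.
#'
#' @param rec one replicate: a list or single-row data.frame with fields
#'   \code{ibw}, \code{fbw} (mean weights, g), \code{days}, and optionally
#'   \code{feed}, \code{initialCount}, \code{finalCount},
#'   \code{bodyLength}, \code{bodyWeight}, \code{liverWeight},
#'   \code{visceralWeight}.
#' @return named numeric vector: WGR, SGR, FCR, FI, SR, CF, HSI, VSI.
#' @export
computeGrowth <- function(rec) {
  rec <- as.list(rec)
  get0n <- function(f) if (!is.null(rec[[f]]) && !is.na(rec[[f]]))
    as.numeric(rec[[f]]) else NA_real_
  ibw <- get0n("ibw"); fbw <- get0n("fbw"); days <- get0n("days")
  if (is.na(ibw) || is.na(fbw) || ibw <= 0 || fbw <= 0)
    stop("ibw and fbw must be present and positive")
  if (is.na(days) || days <= 0) stop("days must be present and positive")
  n0 <- get0n("initialCount"); n1 <- get0n("finalCount")
  feed <- get0n("feed")
  wgr <- 100 * (fbw - ibw) / ibw
  sgr <- 100 * (log(fbw) - log(ibw)) / days
  sr <- if (!is.na(n0) && !is.na(n1)) 100 * n1 / n0 else NA_real_
  fcr <- fi <- NA_real_
  if (!is.na(feed) && !is.na(n0) && !is.na(n1)) {
    gain <- fbw * n1 - ibw * n0
    if (gain <= 0) {
      warning("no positive weight gain; FCR undefined")
    } else {
      fcr <- feed / gain
    }
    fi <- 100 * feed / ((fbw * n1 + ibw * n0) / 2) / days
  }
  bw <- get0n("bodyWeight"); len <- get0n("bodyLength")
  cf <- if (!is.na(bw) && !is.na(len)) 100 * bw / len^3 else NA_real_
  liv <- get0n("liverWeight"); vis <- get0n("visceralWeight")
  hsi <- if (!is.na(liv) && !is.na(bw)) 100 * liv / bw else NA_real_
  vsi <- if (!is.na(vis) && !is.na(bw)) 100 * vis / bw else NA_real_
  c(WGR = wgr, SGR = sgr, FCR = fcr, FI = fi, SR = sr, CF = cf,
    HSI = hsi, VSI = vsi)
}

#' Group summary of growth metrics (trial-table layout)
#'
#' Applies \code{\link{computeGrowth}} to every replicate, then for IBW,
#' FBW and each derived metric reports group mean, standard error and Tukey
#' compact letters from \code{\link{anovaTukey}}. Metrics are computed per
#' replicate and then averaged, so the group SGR is the mean of cage SGRs
#' (which differs slightly from an SGR recomputed on group-mean weights).
#'
#' @param records data.frame of replicate records as produced by
#'   \code{\link{simulateGrowthRecords}} (must contain \code{group}).
#' @return list with \code{table} (metric, then per group "mean±se letter")
#'   and \code{metrics} (per-replicate metric data.frame).
#' @export
summarizeGrowth <- function(records) {
  stopifnot(is.data.frame(records), "group" %in% colnames(records))
  met <- t(apply(records, 1, function(r) computeGrowth(as.list(r))))
  met <- data.frame(replicate = records$replicate, group = records$group,
                    IBW = as.numeric(records$ibw),
                    FBW = as.numeric(records$fbw), met,
                    check.names = FALSE, row.names = NULL)
  metricNames <- c("IBW", "FBW", "WGR", "SGR", "FCR", "FI", "SR", "HSI",
                   "VSI", "CF")
  groupsv <- stats::setNames(records$group, records$replicate)
  rows <- list()
  for (mname in metricNames) {
    v <- stats::setNames(met[[mname]], met$replicate)
    if (all(is.na(v))) next
    at <- anovaTukey(v[!is.na(v)], groupsv[!is.na(v)])
    cells <- sprintf("%.2f ± %.2f %s", at$summary$mean,
                     at$summary$se, at$summary$letter)
    rows[[mname]] <- stats::setNames(
      data.frame(metric = mname, t(cells), anova_p = at$anova_p),
      c("metric", at$summary$group, "anova_p"))
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       metrics = met)
}
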