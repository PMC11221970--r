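#' Configuration for the synthetic community generator
#'
#' Defines the statistical structure of a simulated feeding-trial
#' microbiome: per-group dominant taxa, planted correlation blocks, and the
#' count-noise model. Defaults emulate a three-diet trial in which the
#' control group is dominated by a single genus at 97.6% relative abundance
#' while the two substituted groups are dominated by a different genus at
#' 76.7%, with the middle group carrying the densest planted co-occurrence
#' structure.
#'
#' Counts are generated by a Gaussian copula: within-block taxa share a
#' latent correlation rho, latents are mapped through log-normal abundance
#' multipliers onto a fixed weight skeleton, compositions are closed, and
#' counts are drawn multinomially at a log-normally distributed depth.
#' A plain Dirichlet-multinomial cannot plant specific pairwise
#' correlations, which the network and cohesion stages need.
#'
#' @param groups data.frame with columns \code{name},
#'   \code{dominantOtu} (integer index), \code{dominance} (target
#'   proportion in (0,1)).
#' @param nOtus number of OTUs.
#' @param samplesPerGroup samples simulated per group.
#' @param blocks named list (one entry per group name) of lists of
#'   \code{list(size =, rho =)} correlation blocks planted in that group.
#' @param blockWeight multiplier applied to the weight skeleton of a
#'   group's block OTUs within that group (raises the abundance of the
#'   interacting taxa).
#' @param sigma log-normal latent scale.
#' @param baseShape gamma shape of the fixed weight skeleton.
#' @param depthMean,depthCV sequencing depth scale (log-normal).
#' @param domJitter logit-scale sd of the dominant taxon's proportion.
#' @param seed integer seed.
#' @return validated list of class \code{"SynthConfig"}.
#' @export
synthConfig <- function(
    groups = data.frame(name = c("D1", "D2", "D3"),
                        dominantOtu = c(1L, 2L, 2L),
                        dominance = c(0.976, 0.767, 0.767)),
    nOtus = 60, samplesPerGroup = 9,
    blocks = list(D1 = list(list(size = 6, rho = 0.6)),
                  D2 = list(list(size = 10, rho = 0.85),
                            list(size = 10, rho = 0.85)),
                  D3 = list(list(size = 5, rho = 0.7))),
    blockWeight = 3, sigma = 1, baseShape = 0.8,
    depthMean = 2e4, depthCV = 0.3, domJitter = 0.05, seed = 1) {
  stopifnot(is.data.frame(groups),
            all(c("name", "dominantOtu", "dominance") %in% colnames(groups)))
  if (any(groups$dominance <= 0 | groups$dominance >= 1))
    stop("dominance must lie in (0, 1)")
  if (depthMean <= 0) stop("depth must be > 0")
  if (!all(names(blocks) %in% groups$name))
    stop("blocks named for unknown groups: ",
         paste(setdiff(names(blocks), groups$name), collapse = ", "))
  rhos <- unlist(lapply(blocks, vapply, function(b) b$rho, 0))
  if (length(rhos) && any(rhos <= -1 | rhos >= 1))
    stop("block rho must lie in (-1, 1)")
  need <- sum(unlist(lapply(blocks, vapply, function(b) b$size, 0)))
  nDom <- length(unique(groups$dominantOtu))
  if (need > nOtus - nDom)
    stop(sprintf("block sizes sum to %d but only %d non-dominant OTUs exist",
                 need, nOtus - nDom))
  structure(list(groups = groups, nOtus = as.integer(nOtus),
                 samplesPerGroup = as.integer(samplesPerGroup),
                 blocks = blocks, blockWeight = blockWeight, sigma = sigma,
                 baseShape = baseShape, depthMean = depthMean,
                 depthCV = depthCV, domJitter = domJitter,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

# genus pool used to label non-dominant OTUs
.genusPool <- c("Lactobacillus", "Bacillus", "Turicibacter", "Aeromonas",
                "Shewanella", "Pseudomonas", "Clostridium", "Vibrio",
                "Enterococcus", "Streptococcus", "unclassified")

#' Simulate a grouped OTU table with planted structure
#'
#' Draws counts per the copula -> log-normal -> multinomial model of
#' \code{\link{synthConfig}}. Dominant taxa are excluded from correlation
#' blocks, so dominance and network structure are separately tunable; each
#' dominant taxon receives a distinct genus in the taxonomy.
#'
#' @param cfg a \code{"SynthConfig"}.
#' @return an \linkS4class{OtuExperiment} with group labels and taxonomy.
#' @export
simulateCommunity <- function(cfg = synthConfig()) {
  stopifnot(inherits(cfg, "SynthConfig"))
  set.seed(cfg$seed)
  nOtu <- cfg$nOtus
  otuIds <- paste0("OTU_", seq_len(nOtu))
  domIdx <- unique(cfg$groups$dominantOtu)
  baseW <- stats::rgamma(nOtu, cfg$baseShape) + 1e-6
  # deterministic block layout over non-dominant OTUs, in group order
  avail <- setdiff(seq_len(nOtu), domIdx)
  layout <- list()
  for (gname in cfg$groups$name) {
    gl <- list()
    for (b in cfg$blocks[[gname]] %||% list()) {
      idx <- avail[seq_len(b$size)]
      avail <- setdiff(avail, idx)
      gl[[length(gl) + 1]] <- list(idx = idx, rho = b$rho)
    }
    layout[[gname]] <- gl
  }
  counts <- NULL; sampleGroup <- character()
  n <- cfg$samplesPerGroup
  sdlog <- sqrt(log(1 + cfg$depthCV^2))
  for (gi in seq_len(nrow(cfg$groups))) {
    gname <- cfg$groups$name[gi]
    dom <- cfg$groups$dominantOtu[gi]
    domP <- cfg$groups$dominance[gi]
    nd <- setdiff(seq_len(nOtu), dom)
    Z <- matrix(stats::rnorm(n * nOtu), n, nOtu)
    blkIdx <- integer()
    for (b in layout[[gname]]) {
      S <- matrix(b$rho, length(b$idx), length(b$idx)); diag(S) <- 1
      Z[, b$idx] <- MASS::mvrnorm(n, rep(0, length(b$idx)), S)
      blkIdx <- c(blkIdx, b$idx)
    }
    w <- baseW
    w[blkIdx] <- w[blkIdx] * cfg$blockWeight
    W <- sweep(exp(cfg$sigma * Z), 2, w, "*")
    P <- matrix(0, n, nOtu)
    dp <- stats::plogis(stats::qlogis(domP) +
                          stats::rnorm(n, 0, cfg$domJitter))
    P[, nd] <- W[, nd] / rowSums(W[, nd, drop = FALSE]) * (1 - dp)
    P[, dom] <- dp
    depth <- pmax(100, round(stats::rlnorm(
      n, log(cfg$depthMean) - sdlog^2 / 2, sdlog)))
    X <- vapply(seq_len(n), function(i) stats::rmultinom(1, depth[i], P[i, ]),
                integer(nOtu))
    colnames(X) <- sprintf("%s_S%02d", gname, seq_len(n))
    counts <- cbind(counts, X)
    sampleGroup <- c(sampleGroup,
                     stats::setNames(rep(gname, n), colnames(X)))
  }
  rownames(counts) <- otuIds
  domGenera <- c("Mycoplasma", "Cetobacterium", "Plesiomonas",
                 "Acinetobacter")
  genus <- rep(.genusPool, length.out = nOtu)
  genus[domIdx] <- domGenera[seq_along(domIdx)]
  lineage <- ifelse(
    genus == "unclassified", "unclassified",
    paste0("Bacteria;unclassified;unclassified;unclassified;unclassified;",
           genus))
  OtuExperiment(counts, groups = sampleGroup,
                taxonomy = data.frame(otu = otuIds, lineage = lineage))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate per-cage growth-trial records
#'
#' Draws replicate (cage) records around group means with a common
#' coefficient of variation. Defaults emulate a 56-day trial with three
#' cages of 30 fish per diet, initial body weight near 46 g and final body
#' weights separated across diets; feed consumed is derived from a target
#' feed conversion ratio per group.
#'
#' @param nReplicates cages per group (>= 2).
#' @param groupMeans data.frame with columns name, ibw, fbw, fcr, survival
#'   (fraction), length (cm), hsi, vsi (percent targets for sampled fish).
#' @param days trial length in days.
#' @param initialCount fish stocked per cage.
#' @param cv coefficient of variation applied to the drawn quantities
#'   (0 gives identical replicates).
#' @param seed integer seed.
#' @return data.frame of \code{GrowthRecord} rows (one per cage).
#' @export
simulateGrowthRecords <- function(
    nReplicates = 3,
    groupMeans = data.frame(
      name = c("D1", "D2", "D3"),
      ibw = c(46.33, 45.67, 46.33),
      fbw = c(102.12, 96.64, 85.48),
      fcr = c(1.21, 1.31, 1.61),
      survival = c(0.956, 0.944, 0.933),
      length = c(14.8, 14.7, 14.2),
      hsi = c(1.57, 1.46, 1.38),
      vsi = c(9.16, 8.91, 8.51)),
    days = 56, initialCount = 30, cv = 0.05, seed = 1) {
  if (nReplicates < 2) stop("need at least 2 replicates per group")
  if (any(groupMeans$ibw <= 0 | groupMeans$fbw <= 0 | groupMeans$fcr <= 0))
    stop("group means must be positive")
  set.seed(as.integer(seed))
  jitter <- function(mu) mu * (1 + stats::rnorm(1, 0, cv))
  rows <- list()
  for (gi in seq_len(nrow(groupMeans))) {
    gm <- groupMeans[gi, ]
    for (r in seq_len(nReplicates)) {
      ibw <- jitter(gm$ibw); fbw <- jitter(gm$fbw)
      finalCount <- min(initialCount,
                        round(jitter(gm$survival) * initialCount))
      gain <- fbw * finalCount - ibw * initialCount
      feed <- jitter(gm$fcr) * max(gain, 1)
      len <- jitter(gm$length)
      bw <- fbw
      rows[[length(rows) + 1]] <- data.frame(
        replicate = sprintf("%s_r%d", gm$name, r), group = gm$name,
        days = days, ibw = ibw, fbw = fbw,
        initialCount = initialCount, finalCount = finalCount,
        feed = feed, bodyLength = len, bodyWeight = bw,
        liverWeight = jitter(gm$hsi) / 100 * bw,
        visceralWeight = jitter(gm$vsi) / 100 * bw)
    }
  }
  do.call(rbind, rows)
}
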