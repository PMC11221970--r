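test_that("relative abundance closes each sample to 1", {
  m <- matrix(c(1, 1, 1, 1), 4, 1, dimnames = list(paste0("o", 1:4), "s1"))
  expect_equal(unname(relativeAbundance(cbind(m, m))[, 1]), rep(0.25, 4))

  m2 <- matrix(c(97600, 2400, 1, 1), 2, 2,
               dimnames = list(c("dom", "rest"), c("s1", "s2")))
  expect_equal(unname(relativeAbundance(m2)[, "s1"]), c(0.976, 0.024))

  set.seed(3)
  r <- relativeAbundance(matrix(rpois(60, 20) + 1, 10, 6,
                                dimnames = list(paste0("o", 1:10),
                                                paste0("s", 1:6))))
  expect_equal(unname(colSums(r)), rep(1, 6), tolerance = 1e-12)
  expect_true(all(r >= 0 & r <= 1))

  bad <- matrix(c(1, 2, 0, 0), 2, 2,
                dimnames = list(c("a", "b"), c("ok", "empty")))
  expect_error(relativeAbundance(bad), "empty")
})

test_that("genus aggregation is additive and preserves closure", {
  rel <- matrix(c(0.3, 0.4, 0.3), 3, 1,
                dimnames = list(c("o1", "o2", "o3"), "s1"))
  tax <- data.frame(otu = c("o1", "o2", "o3"),
                    genus = c("Bacillus", "Bacillus", "Vibrio"))
  g <- aggregateGenus(rel, tax)
  expect_equal(g["Bacillus", "s1"], 0.7)
  expect_equal(unname(colSums(g)), 1)

  gAll <- aggregateGenus(rel, data.frame(otu = "none", genus = "x"))
  expect_equal(rownames(gAll), "unclassified")
  expect_equal(unname(gAll[1, 1]), 1)
})

test_that("Simpson dominance hits its closed-form values and bounds", {
  relu <- matrix(0.25, 4, 1, dimnames = list(paste0("o", 1:4), "s"))
  expect_equal(unname(simpsonIndex(relu)), 0.25)
  relp <- matrix(c(1, 0, 0, 0), 4, 1, dimnames = dimnames(relu))
  expect_equal(unname(simpsonIndex(relp)), 1)
  reld <- matrix(c(0.976, 0.024), 2, 1,
                 dimnames = list(c("a", "b"), "s"))
  expect_equal(unname(simpsonIndex(reld)), 0.953152)  # 0.976^2 + 0.024^2
  expect_equal(unname(simpsonIndex(reld, complement = TRUE)),
               1 - 0.953152)

  # uniform minimises (1/S), point mass maximises (1)
  set.seed(4)
  for (S in c(3, 7, 12)) {
    p <- matrix(rgamma(S, 1), S, 1); p <- p / sum(p)
    rownames(p) <- paste0("o", 1:S); colnames(p) <- "s"
    expect_gte(simpsonIndex(p)[1], 1 / S)
    expect_lte(simpsonIndex(p)[1], 1)
  }
})

test_that("aggregating one-OTU-per-genus leaves Simpson unchanged", {
  set.seed(5)
  rel <- relativeAbundance(matrix(rpois(40, 30) + 1, 8, 5,
                                  dimnames = list(paste0("o", 1:8),
                                                  paste0("s", 1:5))))
  tax <- data.frame(otu = paste0("o", 1:8), genus = paste0("G", 1:8))
  expect_equal(unname(sort(simpsonIndex(aggregateGenus(rel, tax)))),
               unname(sort(simpsonIndex(rel))))
})

test_that("Bray-Curtis PCoA embeds compositions faithfully", {
  # identical samples: distance 0
  rel <- matrix(rep(c(0.5, 0.5), 4), 2, 4,
                dimnames = list(c("a", "b"), paste0("s", 1:4)))
  d <- vegan::vegdist(t(rel), "bray")
  expect_equal(max(d), 0)

  # disjoint supports: distance 1
  rel2 <- matrix(c(1, 0, 0, 1, 1, 0), 2, 3,
                 dimnames = list(c("a", "b"), paste0("s", 1:3)))
  expect_equal(as.numeric(vegan::vegdist(t(rel2), "bray"))[1], 1)

  # 5 two-taxon compositions on a line: BC is euclidean-embeddable and
  # axis 1 must recover the line ordering and pairwise distances
  t5 <- c(0.1, 0.25, 0.4, 0.6, 0.9)
  rel3 <- rbind(a = t5, b = 1 - t5)
  colnames(rel3) <- paste0("s", 1:5)
  fit <- suppressWarnings(brayCurtisPcoa(rel3, k = 2))  # axis 2 is degenerate
  ax1 <- fit$points[, 1]
  expect_true(all(diff(order(ax1)) == 1) || all(diff(order(-ax1)) == 1))
  emb <- as.matrix(dist(fit$points))
  bc <- as.matrix(vegan::vegdist(t(rel3), "bray"))
  expect_lt(max(abs(emb - bc)), 1e-8)
  expect_true(all(diff(fit$eig) <= 1e-12))

  expect_warning(brayCurtisPcoa(rel3, k = 4), "truncated")
  expect_error(brayCurtisPcoa(rel3[, 1:2]), "3 samples")
})

test_that("Welch differential flags a planted shift and respects the null", {
  set.seed(6)
  n <- 9
  rel <- rbind(
    shifted = c(rnorm(n, 0.5, 0.02), rnorm(n, 0.05, 0.02)),
    flat1 = rnorm(2 * n, 0.2, 0.05),
    flat2 = rnorm(2 * n, 0.25, 0.05))
  colnames(rel) <- paste0("s", 1:(2 * n))
  g <- setNames(rep(c("A", "B"), each = n), colnames(rel))
  res <- welchDifferential(rel, g, c("A", "B"))
  # hand Welch t: |0.45| / (0.02 sqrt(2/9)) > 30
  expect_lt(res$q[res$otu == "shifted"], 0.05)
  expect_gt(abs(res$t[res$otu == "shifted"]), 10)
  expect_true(all(res$q >= res$p - 1e-12))

  # identical compositions in both groups: zero-variance convention p = 1
  relc <- matrix(rep(c(0.6, 0.4), 2 * n), 2, 2 * n,
                 dimnames = list(c("a", "b"), names(g)))
  resc <- welchDifferential(relc, g, c("A", "B"))
  expect_true(all(resc$p == 1))

  expect_error(welchDifferential(rel, g, c("A", "C")), "absent")
  expect_error(welchDifferential(rel, g, "A"), "two groups")
})

test_that("BH q-values are monotone in p and never smaller", {
  set.seed(7)
  p <- runif(50)
  q <- p.adjust(p, "BH")
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  rel <- matrix(rnorm(50 * 12, 0.3, 0.05), 50, 12,
                dimnames = list(paste0("o", 1:50), paste0("s", 1:12)))
  g <- setNames(rep(c("A", "B"), each = 6), colnames(rel))
  res <- welchDifferential(rel, g, c("A", "B"))
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("ANOVA/Tukey summaries separate what should be separated", {
  set.seed(8)
  g <- rep(c("A", "B", "C"), each = 3)
  same <- rep(c(4, 5, 6), times = 3)   # identical groups, equal means
  at <- anovaTukey(same, g)
  expect_gt(at$anova_p, 0.9)
  expect_equal(length(unique(at$summary$letter)), 1)

  sep <- c(0, 0, 0, 10, 10, 10, 20, 20, 20) + rnorm(9, 0, 1e-3)
  at2 <- anovaTukey(sep, g)
  expect_lt(at2$anova_p, 1e-6)
  expect_equal(length(unique(at2$summary$letter)), 3)
  # SE = sd/sqrt(n)
  expect_equal(at2$summary$se[1],
               sd(sep[g == "A"]) / sqrt(3), tolerance = 1e-9)

  expect_error(anovaTukey(c(1, 2, 3), c("A", "A", "B")), "fewer than 2")
})
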