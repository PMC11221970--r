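test_that("connectedness splits signed means exactly", {
  m <- matrix(0, 4, 4, dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  m["t1", 2:4] <- m[2:4, "t1"] <- c(0.4, 0.2, -0.3)
  cv <- connectedness(m)
  expect_equal(cv$positive[1], 0.3)     # mean(0.4, 0.2)
  expect_equal(cv$negative[1], -0.3)

  z <- connectedness(matrix(0, 3, 3))
  expect_true(all(z$positive == 0) && all(z$negative == 0))

  # hand-built symmetric 4x4 vs an independent loop oracle
  set.seed(41)
  h <- matrix(rnorm(16, 0, 0.3), 4, 4); h <- (h + t(h)) / 2; diag(h) <- 0
  dimnames(h) <- list(paste0("t", 1:4), paste0("t", 1:4))
  cv2 <- connectedness(h)
  for (i in 1:4) {
    v <- h[i, -i]
    expect_identical(cv2$positive[i],
                     if (any(v > 0)) sum(v[v > 0]) / sum(v > 0) else 0)
    expect_identical(cv2$negative[i],
                     if (any(v < 0)) sum(v[v < 0]) / sum(v < 0) else 0)
  }
  expect_error(connectedness(matrix(rnorm(12), 3, 4)), "square")
})

test_that("cohesion is the abundance-weighted connectedness sum", {
  rel <- matrix(c(0.6, 0.4, 1, 0), 2, 2,
                dimnames = list(c("t1", "t2"), c("s1", "s2")))
  conn <- data.frame(otu = c("t1", "t2"), positive = c(0.5, 0.25),
                     negative = c(-0.1, -0.2))
  ch <- cohesionIndex(rel, conn)
  expect_equal(unname(positiveCohesion(ch)["s1"]), 0.40) # 0.6*0.5+0.4*0.25
  expect_equal(unname(positiveCohesion(ch)["s2"]), 0.5)  # point mass
  expect_equal(unname(negativeCohesion(ch)["s2"]), -0.1)

  conn0 <- data.frame(otu = c("t1", "t2"), positive = c(0, 0),
                      negative = c(0, 0))
  expect_true(all(positiveCohesion(cohesionIndex(rel, conn0)) == 0))

  connBad <- data.frame(otu = c("x", "y"), positive = 1:2, negative = 0)
  expect_error(cohesionIndex(rel, connBad), "identifiers differ")
})

test_that("Eq-style linearity: a 50/50 sample mixture averages cohesion", {
  set.seed(42)
  rel <- relativeAbundance(matrix(rpois(8 * 6, 40) + 1, 8, 6,
                                  dimnames = list(paste0("t", 1:8),
                                                  paste0("s", 1:6))))
  conn <- connectedness(nullCorrectedCorrelations(rel, rNull = 60,
                                                  seed = 9))
  mix <- cbind(rel, mixed = (rel[, 1] + rel[, 2]) / 2)
  ch <- cohesionIndex(mix, conn)
  pos <- positiveCohesion(ch)
  expect_equal(unname(pos["mixed"]), unname((pos["s1"] + pos["s2"]) / 2),
               tolerance = 1e-12)
})

test_that("cohesion depends on proportions, not sequencing depth", {
  set.seed(43)
  counts <- matrix(rpois(10 * 8, 50) + 1, 10, 8,
                   dimnames = list(paste0("t", 1:10), paste0("s", 1:8)))
  ch1 <- cohesion(counts, rNull = 60, seed = 7)
  ch2 <- cohesion(counts * 10L, rNull = 60, seed = 7)
  expect_equal(positiveCohesion(ch1), positiveCohesion(ch2),
               tolerance = 1e-12)
  # sign partition holds on any input
  expect_true(all(positiveCohesion(ch1) >= 0))
  expect_true(all(negativeCohesion(ch1) <= 0))
})

test_that("the taxon-shuffle null centres corrected correlations at zero", {
  set.seed(44)
  # identical columns: observed rho 1, null near 0, corrected stays > 0
  base <- rlnorm(20)
  m <- cbind(t1 = base, t2 = base, t3 = rlnorm(20), t4 = rlnorm(20))
  rel <- t(m / rowSums(m))
  cc <- nullCorrectedCorrelations(rel, rNull = 100, seed = 1)
  expect_gt(cc["t1", "t2"], 0.5)

  # convergence: corrected matrices at small vs large Rnull agree within
  # Monte-Carlo error shrinking as 1/sqrt(Rnull)
  set.seed(45)
  rel2 <- relativeAbundance(matrix(rpois(12 * 16, 60) + 1, 12, 16,
                                   dimnames = list(paste0("t", 1:12),
                                                   paste0("s", 1:16))))
  c1 <- nullCorrectedCorrelations(rel2, rNull = 50, seed = 2)
  c2 <- nullCorrectedCorrelations(rel2, rNull = 800, seed = 3)
  dev <- max(abs(c1 - c2))
  expect_lt(dev, 6 / sqrt(50))   # generous MC bound
  expect_warning(nullCorrectedCorrelations(rel2, rNull = 10, seed = 1),
                 "noisy")
  expect_error(
    nullCorrectedCorrelations(rel2[, 1:3], rNull = 60, seed = 1),
    "4 samples")
})

test_that("group contrasts report reciprocal-consistent ratios", {
  set.seed(46)
  pos <- c(rnorm(6, 0.30, 0.01), rnorm(6, 0.45, 0.01))
  names(pos) <- paste0("s", 1:12)
  ch <- new("CohesionResult", positive = pos, negative = -pos / 2,
            connectedness = data.frame(otu = "t1", positive = 0.3,
                                       negative = -0.1),
            method = "pearson", rNull = 100L, seed = 1L)
  g <- setNames(rep(c("A", "B"), each = 6), names(pos))
  ct <- cohesionContrast(ch, g)
  r <- ct$ratios
  ab <- r$ratio[r$group1 == "A" & r$group2 == "B"]
  ba <- r$ratio[r$group1 == "B" & r$group2 == "A"]
  expect_equal(ab * ba, 1, tolerance = 1e-12)
  expect_gt(ba, 1)
  expect_lt(ct$positive$anova_p, 0.01)

  # identical groups: all ratios 1
  pos2 <- rep(0.4, 12) + rnorm(12, 0, 1e-9); names(pos2) <- names(pos)
  ch2 <- new("CohesionResult", positive = pos2, negative = -pos2,
             connectedness = ch@connectedness, method = "pearson",
             rNull = 100L, seed = 1L)
  expect_equal(cohesionContrast(ch2, g)$ratios$ratio, rep(1, 2),
               tolerance = 1e-6)
})

test_that("abundance/cohesion association recovers rank agreement", {
  pos <- setNames(c(0.1, 0.2, 0.3, 0.4, 0.5), paste0("s", 1:5))
  ch <- new("CohesionResult", positive = pos, negative = -pos,
            connectedness = data.frame(otu = "t1", positive = 1,
                                       negative = -1),
            method = "pearson", rNull = 1L, seed = 1L)
  counts <- rbind(up = c(10, 20, 30, 40, 50), down = c(50, 40, 30, 20, 10))
  colnames(counts) <- names(pos)
  expect_equal(abundanceCohesionCorrelation(counts, ch, "up")$rho, 1)
  expect_equal(abundanceCohesionCorrelation(counts, ch, "down")$rho, -1)
  expect_error(abundanceCohesionCorrelation(counts, ch, "zz"), "not found")
})
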