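test_that("log transform hits ln values and never changes Spearman", {
  m <- matrix(c(0, exp(1) - 1, 3, 9, 27, 81), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  lt <- logTransform(m, 1)
  expect_equal(lt["a", "s1"], 0)        # ln 1
  expect_equal(lt["a", "s2"], 1)        # ln e
  expect_error(logTransform(m, 0), "pseudocount")

  set.seed(21)
  counts <- matrix(rpois(8 * 10, 30), 8, 10,
                   dimnames = list(paste0("o", 1:8), paste0("s", 1:10)))
  r1 <- spearmanMatrix(counts)
  r2 <- spearmanMatrix(logTransform(counts, 1))
  expect_equal(r1@rho, r2@rho, tolerance = 1e-12)
})

test_that("Spearman matrix matches rank-then-Pearson with ties", {
  x <- c(1, 2, 2, 3, 4, 5)   # one tie: average ranks 1, 2.5, 2.5, 4, 5, 6
  y <- c(2, 1, 4, 3, 6, 5)
  m <- rbind(x = x, y = y)
  colnames(m) <- paste0("s", 1:6)
  res <- spearmanMatrix(m)
  oracle <- cor(c(1, 2.5, 2.5, 4, 5, 6), rank(y), method = "pearson")
  expect_equal(res@rho["x", "y"], oracle, tolerance = 1e-10)

  inc <- rbind(a = 1:6, b = (1:6)^2); colnames(inc) <- paste0("s", 1:6)
  expect_equal(spearmanMatrix(inc)@rho["a", "b"], 1)
  anti <- rbind(a = 1:6, b = -(1:6)); colnames(anti) <- paste0("s", 1:6)
  expect_equal(spearmanMatrix(anti)@rho["a", "b"], -1)

  cst <- rbind(a = 1:6, b = rep(2, 6)); colnames(cst) <- paste0("s", 1:6)
  rc <- spearmanMatrix(cst)
  expect_equal(rc@rho["a", "b"], 0)
  expect_equal(rc@p["a", "b"], 1)

  expect_error(spearmanMatrix(m[, 1:3]), "4 samples")
})

test_that("network construction thresholds on |rho| and keeps signs", {
  rho <- matrix(0.1, 3, 3,
                dimnames = list(paste0("o", 1:3), paste0("o", 1:3)))
  rho["o1", "o2"] <- rho["o2", "o1"] <- 0.95
  net <- buildNetwork(corrFromMatrix(rho), 0.9)
  g <- networkGraph(net)
  expect_equal(igraph::vcount(g), 2)    # o3 isolated, excluded
  expect_equal(igraph::ecount(g), 1)

  expect_warning(net0 <- buildNetwork(corrFromMatrix(rho), 1.0), "empty")
  expect_equal(igraph::vcount(networkGraph(net0)), 0)

  rho["o1", "o3"] <- rho["o3", "o1"] <- -0.92
  net2 <- buildNetwork(corrFromMatrix(rho), 0.9)
  e <- igraph::as_data_frame(networkGraph(net2))
  expect_setequal(e$sign, c("positive", "negative"))
})

test_that("raising the cutoff never grows the network", {
  set.seed(22)
  m <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(paste0("o", 1:30), paste0("s", 1:10)))
  corr <- spearmanMatrix(m)
  prev <- c(Inf, Inf)
  for (s in c(0.3, 0.5, 0.7, 0.9)) {
    net <- suppressWarnings(buildNetwork(corr, s))
    g <- networkGraph(net)
    now <- c(igraph::vcount(g), igraph::ecount(g))
    expect_true(all(now <= prev))
    if (igraph::ecount(g) > 0) {
      topo <- networkTopology(net)
      expect_equal(topo$avgK, 2 * topo$E / topo$N)
    }
    prev <- now
  }
})

test_that("topology indices match closed forms on canonical graphs", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- paste0("o", 1:3)
  t1 <- networkTopology(tri)
  expect_equal(t1$avgK, 2)
  expect_equal(t1$clustering, 1)
  expect_equal(t1$pathLength, 1)

  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- paste0("o", 1:6)
  t2 <- networkTopology(star)
  expect_equal(t2$avgK, 2 * 5 / 6, tolerance = 1e-12)
  expect_equal(t2$clustering, 0)

  # two disjoint 5-cliques: modularity of the 2-block partition is 0.5
  cliq <- igraph::disjoint_union(igraph::make_full_graph(5),
                                 igraph::make_full_graph(5))
  igraph::V(cliq)$name <- paste0("o", 1:10)
  t3 <- networkTopology(cliq)
  expect_equal(t3$modularity, 0.5, tolerance = 1e-12)

  expect_error(
    networkTopology(igraph::make_empty_graph(0, directed = FALSE)),
    "empty")
})

test_that("degree-preserving baselines keep the degree sequence", {
  set.seed(23)
  # planted two-block graph: dense blocks, sparse between
  g <- igraph::sample_sbm(30, pref.matrix = rbind(c(0.7, 0.02),
                                                  c(0.02, 0.7)),
                          block.sizes = c(15, 15))
  igraph::V(g)$name <- paste0("o", 1:30)
  igraph::E(g)$correlation <- 0.9
  igraph::E(g)$sign <- "positive"
  net <- new("CoNetwork", graph = g, cutoff = 0.8)
  nb <- randomBaseline(net, R = 30, seed = 5)
  expect_equal(nrow(nb$values), 30)
  zmod <- nb$summary$z[nb$summary$index == "modularity"]
  expect_gt(zmod, 2)

  nb2 <- randomBaseline(net, R = 30, seed = 5)
  expect_equal(nb$summary$null_mean, nb2$summary$null_mean)
})

test_that("focal neighbourhoods report neighbours and signs", {
  rho <- matrix(0, 21, 21,
                dimnames = list(paste0("o", 1:21), paste0("o", 1:21)))
  rho[1, 2:20] <- rho[2:20, 1] <- 0.9           # hub with 19 neighbours
  rho[2, 3] <- rho[3, 2] <- -0.85
  net <- buildNetwork(corrFromMatrix(rho), 0.8)
  hub <- focalNeighborhood(net, "o1")
  expect_equal(nrow(hub$neighbours), 19)
  expect_equal(hub$nPositive, 19)

  expect_equal(focalNeighborhood(net, "o999")$nPositive +
                 focalNeighborhood(net, "o999")$nNegative, 0)

  rhoN <- matrix(0, 4, 4, dimnames = list(paste0("o", 1:4),
                                          paste0("o", 1:4)))
  rhoN[1, 2:4] <- rhoN[2:4, 1] <- -0.9
  netN <- buildNetwork(corrFromMatrix(rhoN), 0.8)
  fn <- focalNeighborhood(netN, "o1")
  expect_equal(fn$nPositive, 0)
  expect_equal(fn$nNegative, 3)
})
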