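fake_adj <- function(A, beta = 10L) {
  structure(list(ids = rownames(A), a = A, beta = beta, mode = "soft"),
            class = "AdjacencyMatrix")
}

test_that("thresholding admits exactly the edges at or above the cutoff", {
  ids <- paste0("p", 1:4)
  A <- matrix(0, 4, 4, dimnames = list(ids, ids))
  A["p1", "p2"] <- A["p2", "p1"] <- 0.5
  A["p1", "p3"] <- A["p3", "p1"] <- 0.2
  A["p3", "p4"] <- A["p4", "p3"] <- 0.15
  g <- threshold_network(fake_adj(A), 0.2)
  el <- igraph::as_data_frame(g)
  expect_setequal(paste(el$from, el$to), c("p1 p2", "p1 p3"))
  expect_equal(igraph::vcount(g), 4)       # isolated p4 retained

  g0 <- threshold_network(fake_adj(A), 0)
  expect_equal(igraph::ecount(g0), 6)      # complete graph minus diagonal
  expect_equal(igraph::ecount(threshold_network(fake_adj(A), 1)), 0)

  # raising the cutoff never increases any degree
  for (s in 1:5) {
    set.seed(s)
    n <- 8
    ids <- paste0("q", 1:n)
    B <- matrix(stats::runif(n * n), n, n, dimnames = list(ids, ids))
    B <- (B + t(B)) / 2; diag(B) <- 0
    cuts <- c(0.2, 0.5, 0.8)
    degs <- sapply(cuts, function(ct)
      igraph::degree(threshold_network(fake_adj(B), ct))[ids])
    expect_true(all(degs[, 2] <= degs[, 1] & degs[, 3] <= degs[, 2]))
  }
})

test_that("MCODE vertex weights equal core-density of the closed neighbourhood", {
  # 4-clique plus pendant: clique nodes score k * density = 3
  adj <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  adj[1:4, 1:4] <- 1; diag(adj) <- 0
  adj["d", "e"] <- adj["e", "d"] <- 1
  g <- adj_to_igraph(adj)
  w <- mcode_vertex_weights(g)
  expect_equal(w[["a"]], 3)
  expect_equal(w[["d"]], 3)   # pendant drops out of d's highest core
  expect_equal(w[["e"]], 1)   # e's neighbourhood is an edge: 1-core, density 1

  # path graph midpoint: neighbourhood P3, highest core k = 1, density 2/3
  p3 <- matrix(0, 3, 3, dimnames = list(c("u", "v", "w"), c("u", "v", "w")))
  p3["u", "v"] <- p3["v", "u"] <- 1; p3["v", "w"] <- p3["w", "v"] <- 1
  expect_equal(mcode_vertex_weights(adj_to_igraph(p3))[["v"]], 2 / 3)

  # isolated node scores zero
  iso <- igraph::make_empty_graph(1, directed = FALSE)
  iso <- igraph::set_vertex_attr(iso, "name", value = "solo")
  expect_equal(mcode_vertex_weights(iso)[["solo"]], 0)

  # random graphs up to 10 nodes match the brute-force oracle
  for (s in 1:8) {
    adj <- random_unweighted_graph(sample(4:10, 1), 0.45, seed = 100 + s)
    g <- adj_to_igraph(adj)
    w <- mcode_vertex_weights(g)
    for (v in rownames(adj))
      expect_equal(w[[v]], oracle_mcode_weight(adj, which(rownames(adj) == v)),
                   tolerance = 1e-10)
  }
})

test_that("MCODE complexes respect haircut, k-core filter and seeding order", {
  # 4-clique with a pendant: haircut trims the pendant, leaving the clique
  adj <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  adj[1:4, 1:4] <- 1; diag(adj) <- 0
  adj["d", "e"] <- adj["e", "d"] <- 1
  res <- mcode_complexes(adj_to_igraph(adj))
  expect_length(res$complexes, 1)
  expect_setequal(res$complexes[[1]], c("a", "b", "c", "d"))
  expect_equal(res$scores[1], 4)  # density 1 x size 4

  # two 4-cliques joined by a bridge: every node has weight 3, so the
  # expansion rule admits the bridge and the complex spans both cliques
  adj2 <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  adj2[1:4, 1:4] <- 1; adj2[5:8, 5:8] <- 1; diag(adj2) <- 0
  adj2["d", "e"] <- adj2["e", "d"] <- 1
  res2 <- mcode_complexes(adj_to_igraph(adj2))
  expect_length(res2$complexes, 1)
  expect_setequal(res2$complexes[[1]], letters[1:8])

  # vertex input order does not change the result
  perm <- c(3, 1, 4, 2, 5, 8, 6, 7)
  res3 <- mcode_complexes(adj_to_igraph(adj2[perm, perm]))
  expect_identical(res3$complexes, res2$complexes)

  expect_warning(mcode_complexes(adj_to_igraph(adj), fluff = TRUE),
                 "not implemented")
})

test_that("hub detection uses within-module degree z-scores", {
  # star K1,9 merged into a 10-node ring: the centre is the unique hub
  n <- 10
  ids <- sprintf("h%02d", 1:n)
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:n) { j <- i %% n + 1; adj[i, j] <- adj[j, i] <- 1 }
  adj[1, ] <- adj[, 1] <- 1; diag(adj) <- 0
  hs <- hub_nodes(adj_to_igraph(adj))
  expect_identical(hs$node[hs$hub], ids[1])
  expect_equal(sum(hs$z), 0, tolerance = 1e-9)
  # hand-computed degrees: centre 9; ring nodes adjacent to the centre in
  # the ring see it once (k = 2); the rest have two ring neighbours plus
  # the centre (k = 3)
  k <- c(9, 2, rep(3, 7), 2)
  expect_equal(hs$z[hs$node == ids[1]], (9 - mean(k)) / stats::sd(k),
               tolerance = 1e-12)

  # degree-regular module has no hubs
  ring <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  for (i in 1:5) { j <- i %% 5 + 1; ring[i, j] <- ring[j, i] <- 1 }
  hr <- hub_nodes(adj_to_igraph(ring))
  expect_false(any(hr$hub))
  expect_true(all(hr$z == 0))

  expect_error(hub_nodes(adj_to_igraph(ring[1:2, 1:2])), "fewer than 3")
})

test_that("neighbourhood extraction returns the closed neighbourhood", {
  star <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  star[1, 2:5] <- star[2:5, 1] <- 1
  g <- adj_to_igraph(star)
  nb <- neighbourhood(g, "a")
  expect_setequal(igraph::V(nb)$name, letters[1:5])
  nb2 <- neighbourhood(g, "b")
  expect_setequal(igraph::V(nb2)$name, c("a", "b"))
  iso <- igraph::make_empty_graph(1, directed = FALSE)
  iso <- igraph::set_vertex_attr(iso, "name", value = "solo")
  expect_equal(igraph::vcount(neighbourhood(iso, "solo")), 1)
  expect_error(neighbourhood(g, "zz"), "unknown node")
})

test_that("Ward sub-clustering recovers separated blocks and matches the oracle", {
  # two well-separated expression blocks
  set.seed(12)
  b1 <- matrix(stats::rnorm(60, 0, 0.1), 10, 6) +
    matrix(rep(c(1, 1, 1, -1, -1, -1), each = 10), 10)
  b2 <- matrix(stats::rnorm(60, 0, 0.1), 10, 6) +
    matrix(rep(c(-1, -1, -1, 1, 1, 1), each = 10), 10)
  m <- rbind(b1, b2)
  dimnames(m) <- list(sprintf("P%02d", 1:20), paste0("S", 1:6))
  x <- expression_matrix(m, transformed = TRUE)
  sc <- ward_subclusters(x, rownames(m), k = 2)
  expect_equal(unname(table(sc$cluster_of)), c(10, 10), ignore_attr = TRUE)
  expect_length(unique(sc$cluster_of[1:10]), 1)
  expect_length(unique(sc$cluster_of[11:20]), 1)
  expect_false(sc$cluster_of[[1]] == sc$cluster_of[[11]])

  # merge heights agree with a naive Lance-Williams Ward implementation
  x8 <- expression_matrix(m[c(1:4, 11:14), ], transformed = TRUE)
  sc8 <- ward_subclusters(x8, rownames(x8$values), k = 2)
  z <- t(scale(t(x8$values)))
  expect_equal(sort(sc8$tree$height),
               oracle_linkage_heights(stats::dist(z), "ward"),
               tolerance = 1e-10)

  expect_equal(length(unique(ward_subclusters(x, rownames(m), 1)$cluster_of)), 1)
  expect_error(ward_subclusters(x, rownames(m), 0), ">= 1")
  expect_error(ward_subclusters(x, rownames(m), 21), "exceeds")
  expect_error(ward_subclusters(x, c("nope"), 1), "unknown")
})
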