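# minimal TOMMatrix constructor for fixtures
fake_tom <- function(tom) {
  structure(list(ids = rownames(tom), tom = tom, dissim = 1 - tom),
            class = "TOMMatrix")
}

test_that("dendrogram construction follows average linkage on 1 - TOM", {
  ids <- paste0("p", 1:5)
  set.seed(4)
  tom <- matrix(stats::runif(25, 0, 0.8), 5, 5, dimnames = list(ids, ids))
  tom <- (tom + t(tom)) / 2; diag(tom) <- 1
  hc <- cluster_dendrogram(fake_tom(tom))
  expect_equal(sort(hc$height),
               oracle_linkage_heights(stats::as.dist(1 - tom), "average"),
               tolerance = 1e-12)

  # identical profiles merge at height ~0
  tom2 <- diag(3) * 0 + 0.1; tom2[1, 2] <- tom2[2, 1] <- 1; diag(tom2) <- 1
  dimnames(tom2) <- list(paste0("q", 1:3), paste0("q", 1:3))
  hc2 <- cluster_dendrogram(fake_tom(tom2))
  expect_equal(min(hc2$height), 0)

  # block-diagonal TOM: the inter-block merge comes last, at max height
  b <- matrix(0.05, 6, 6); b[1:3, 1:3] <- 0.9; b[4:6, 4:6] <- 0.9; diag(b) <- 1
  dimnames(b) <- list(paste0("r", 1:6), paste0("r", 1:6))
  hc3 <- cluster_dendrogram(fake_tom(b))
  expect_equal(max(hc3$height), 0.95)
  expect_equal(sum(hc3$height == max(hc3$height)), 1)
  expect_error(cluster_dendrogram(fake_tom(matrix(1, 1, 1,
    dimnames = list("z", "z")))), "at least 2")
})

test_that("planted modules are recovered from the TOM dendrogram", {
  sim <- simulate_dataset(seed = 21)
  cc <- pairwise_correlation(sim$expression)
  tom <- topological_overlap(soft_adjacency(cc, 10))
  m <- cut_modules(cluster_dendrogram(tom), tom, x = sim$expression)
  expect_gte(ari(m$module_of, sim$truth$module_of), 0.8)
  # conservation: all proteins accounted for
  expect_equal(sum(m$sizes), length(m$ids))
  expect_true(all(m$sizes[setdiff(names(m$sizes), "grey")] >= 30))
})

test_that("a single planted module yields one dominant non-grey module", {
  sim <- simulate_dataset(n_proteins = 400, module_sizes = 40,
                          trait_corrs = 0.5, seed = 11)
  cc <- pairwise_correlation(sim$expression)
  tom <- topological_overlap(soft_adjacency(cc, 10))
  m <- cut_modules(cluster_dendrogram(tom), tom, x = sim$expression)
  planted <- names(sim$truth$module_of)[sim$truth$module_of == "M1"]
  biggest <- names(m$sizes)[names(m$sizes) != "grey"][1]
  recovered <- module_members(m, biggest)
  expect_gte(length(intersect(planted, recovered)) / length(planted), 0.95)
})

test_that("colour labels rank modules by size with deterministic ties", {
  cl <- stats::setNames(c(rep(1L, 3), rep(2L, 5), rep(3L, 3), 0L),
                        sprintf("p%02d", 1:12))
  out <- procoexp:::.colourise(cl, names(cl))
  expect_identical(unname(out[4]), "turquoise")      # size-5 cluster first
  # two size-3 clusters: tie broken by smallest member id (p01 < p09)
  expect_identical(unname(out[1]), "blue")
  expect_identical(unname(out[9]), "brown")
  expect_identical(unname(out[12]), "grey")
})

test_that("module eigengenes behave like a first principal component", {
  # rank-1 module: eigengene proportional to the shared profile
  base <- c(-2, -1, 0, 1, 3, 5)
  m <- rbind(a = 2 * base + 3, b = 5 * base - 1, c = 0.5 * base)
  colnames(m) <- paste0("S", 1:6)
  x <- expression_matrix(m, transformed = TRUE)
  ma <- procoexp:::.module_assignment(
    rownames(m), stats::setNames(rep("turquoise", 3), rownames(m)), 2, 0.25)
  e <- module_eigengenes(x, ma)
  expect_equal(e$explained_variance[["turquoise"]], 1, tolerance = 1e-12)
  expect_equal(abs(stats::cor(e$eigengenes[, 1], base)), 1, tolerance = 1e-12)
  # orientation: positively correlated with members
  expect_gt(stats::cor(e$eigengenes[, 1], base), 0)

  # flipping all member profiles flips the oriented eigengene
  x2 <- expression_matrix(-m, transformed = TRUE)
  e2 <- module_eigengenes(x2, ma)
  expect_equal(e2$eigengenes[, 1], -e$eigengenes[, 1], tolerance = 1e-10)

  # 2-protein module equals a direct SVD of the standardised block
  x3 <- tiny_expression(2, 8, seed = 5)
  ma3 <- procoexp:::.module_assignment(
    rownames(x3$values),
    stats::setNames(rep("turquoise", 2), rownames(x3$values)), 2, 0.25)
  e3 <- module_eigengenes(x3, ma3)
  z <- t(scale(t(x3$values)))
  v1 <- svd(z)$v[, 1]
  expect_equal(abs(stats::cor(e3$eigengenes[, 1], v1)), 1, tolerance = 1e-10)
})

test_that("module-trait correlation reports Pearson r with t-test p-values", {
  sim <- simulate_dataset(seed = 6)
  cc <- pairwise_correlation(sim$expression)
  tom <- topological_overlap(soft_adjacency(cc, 10))
  m <- cut_modules(cluster_dendrogram(tom), tom, x = sim$expression)
  e <- module_eigengenes(sim$expression, m)
  tc <- module_trait_correlation(e, sim$traits)
  expect_true(all(abs(tc$r) <= 1, na.rm = TRUE))
  expect_true(all(tc$p > 0 & tc$p <= 1, na.rm = TRUE))
  expect_equal(tc$n, 12)

  # the strongest planted state correlation is recovered within 0.15
  expect_lt(abs(max(tc$r[, "state"]) - 0.93), 0.15)

  # trait equal to an eigengene correlates perfectly
  t2 <- sim$traits
  t2$echo <- e$eigengenes[, 1]
  tc2 <- module_trait_correlation(e, t2)
  expect_equal(tc2$r[colnames(e$eigengenes)[1], "echo"], 1, tolerance = 1e-12)
  expect_lt(tc2$p[colnames(e$eigengenes)[1], "echo"], 1e-10)

  # constant trait yields NA with a warning
  t2$flat <- 1
  expect_warning(tc3 <- module_trait_correlation(e, t2), "constant")
  expect_true(all(is.na(tc3$r[, "flat"])))
})

test_that("grey proteins are less connected than module members", {
  sim <- simulate_dataset(seed = 13)
  cc <- pairwise_correlation(sim$expression)
  adj <- soft_adjacency(cc, 10)
  tom <- topological_overlap(adj)
  m <- cut_modules(cluster_dendrogram(tom), tom, x = sim$expression)
  grey <- module_members(m, "grey")
  mean_adj <- function(ids) mean(adj$a[ids, ids][upper.tri(adj$a[ids, ids])])
  for (mod in setdiff(names(m$sizes), "grey"))
    expect_lt(mean_adj(grey), mean_adj(module_members(m, mod)))
})
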