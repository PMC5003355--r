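test_that("pairwise correlations match the textbook formula", {
  x <- tiny_expression(3, 4, seed = 11)
  cc <- pairwise_correlation(x)
  expect_equal(cc$r, oracle_pearson(x$values), tolerance = 1e-12)
  expect_equal(diag(cc$r), rep(1, 3), ignore_attr = TRUE)

  # exact anticorrelation on an affine profile
  m <- rbind(a = c(1, 2, 3, 4), b = c(9, 8, 7, 6))
  colnames(m) <- paste0("S", 1:4)
  cc2 <- pairwise_correlation(expression_matrix(m, transformed = TRUE))
  expect_equal(cc2$r["a", "b"], -1)
})

test_that("zero-variance proteins are flagged and excluded", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5))
  colnames(m) <- paste0("S", 1:4)
  expect_warning(cc <- pairwise_correlation(
    expression_matrix(m, transformed = TRUE)), "zero-variance")
  expect_true(cc$zero_variance["b"])
  expect_true(all(is.na(cc$r["b", ])))
})

test_that("soft adjacency follows corr^beta with unsigned folding", {
  r <- matrix(c(1, 0.5, -0.8, 0.5, 1, 0.2, -0.8, 0.2, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  cc <- structure(list(ids = letters[1:3], r = r, method = "pearson",
                       zero_variance = stats::setNames(rep(FALSE, 3), letters[1:3])),
                  class = "CorrelationMatrix")
  a10 <- soft_adjacency(cc, 10)
  expect_equal(a10$a["a", "b"], 0.0009765625)          # 0.5^10
  expect_equal(a10$a["a", "c"], 0.1073741824)          # (-0.8)^10, sign lost
  expect_equal(diag(a10$a), rep(0, 3), ignore_attr = TRUE)
  expect_identical(a10$mode, "soft")

  a1 <- soft_adjacency(cc, 1)
  expect_equal(a1$a["a", "c"], -0.8)                   # signed retention
  expect_identical(a1$mode, "signed")

  # monotone in |r| for fixed even beta
  rs <- seq(0.05, 0.95, by = 0.1)
  a <- abs(rs)^10
  expect_true(all(diff(a) > 0))
})

test_that("a perfect power-law degree sequence scores signed R^2 of 1", {
  # counts 64/16/4/1 at k = 1/2/4/8: freq proportional to k^-2 exactly,
  # and 8 equal-width bins isolate each distinct k
  k <- rep(c(1, 2, 4, 8), times = c(64, 16, 4, 1))
  sf <- procoexp:::.scale_free_r2(k, n_bins = 8)
  expect_equal(unname(sf["r2"]), 1, tolerance = 1e-12)
  expect_equal(unname(sf["slope"]), -2, tolerance = 1e-12)
})

test_that("scale-free fit is invariant to protein relabelling and picks the lowest passing power", {
  sim <- simulate_dataset(n_proteins = 120, module_sizes = c(40, 30),
                          trait_corrs = c(0.6, -0.4), seed = 3)
  cc <- pairwise_correlation(sim$expression)
  sf <- suppressWarnings(scale_free_fit(cc, beta_grid = 1:12))
  perm <- sample(nrow(cc$r))
  cc2 <- cc
  cc2$r <- cc$r[perm, perm]
  cc2$ids <- cc$ids[perm]
  cc2$zero_variance <- cc$zero_variance[perm]
  sf2 <- suppressWarnings(scale_free_fit(cc2, beta_grid = 1:12))
  expect_equal(sf$fit$r2, sf2$fit$r2, tolerance = 1e-10)

  # chosen power is the lowest grid entry at or above the threshold
  thr <- stats::quantile(sf$fit$r2, 0.7, na.rm = TRUE)
  sf3 <- scale_free_fit(cc, beta_grid = 1:12, r2_threshold = thr)
  expect_identical(sf3$chosen_beta, min(sf3$fit$beta[which(sf3$fit$r2 >= thr)]))
  expect_warning(sf4 <- scale_free_fit(cc, beta_grid = 1:3, r2_threshold = 0.999),
                 "no power")
  expect_true(is.na(sf4$chosen_beta))
})

test_that("topological overlap matches its definition", {
  # 3-node graph with all unit adjacency: TOM = 1 everywhere
  ids <- letters[1:3]
  a1 <- matrix(1, 3, 3, dimnames = list(ids, ids)); diag(a1) <- 0
  adj <- structure(list(ids = ids, a = a1, beta = 10L, mode = "soft"),
                   class = "AdjacencyMatrix")
  tom <- topological_overlap(adj)
  expect_equal(tom$tom, matrix(1, 3, 3), ignore_attr = TRUE)

  # two isolated nodes: defined zero limit
  a0 <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  adj0 <- structure(list(ids = c("x", "y"), a = a0, beta = 10L, mode = "soft"),
                    class = "AdjacencyMatrix")
  expect_equal(topological_overlap(adj0)$tom["x", "y"], 0)

  # weighted 4-node toy equals the naive O(n^3) oracle
  set.seed(8)
  ids <- paste0("p", 1:4)
  A <- matrix(stats::runif(16, 0, 0.9), 4, 4, dimnames = list(ids, ids))
  A <- (A + t(A)) / 2; diag(A) <- 0
  adj4 <- structure(list(ids = ids, a = A, beta = 6L, mode = "soft"),
                    class = "AdjacencyMatrix")
  tom4 <- topological_overlap(adj4)
  expect_equal(unname(tom4$tom), unname(oracle_tom(A)), tolerance = 1e-12)
  expect_equal(tom4$dissim, 1 - tom4$tom)
})

test_that("TOM entries stay within [0, 1] on random adjacencies", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(3:10, 1)
    ids <- paste0("p", seq_len(n))
    A <- matrix(stats::runif(n * n), n, n, dimnames = list(ids, ids))
    A <- (A + t(A)) / 2; diag(A) <- 0
    adj <- structure(list(ids = ids, a = A, beta = 2L, mode = "soft"),
                     class = "AdjacencyMatrix")
    tom <- topological_overlap(adj)
    expect_true(all(tom$tom >= 0 & tom$tom <= 1))
    expect_equal(tom$tom, t(tom$tom), tolerance = 1e-12)
  }
})
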