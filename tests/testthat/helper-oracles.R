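# Independent brute-force oracles used to validate the implementation.
# These deliberately use naive textbook algorithms, never the package's
# own code paths.

# Textbook Pearson correlation, elementwise loops.
oracle_pearson <- function(m) {
  n <- nrow(m)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- m[i, ]; y <- m[j, ]
    sx <- sqrt(sum((x - mean(x))^2)); sy <- sqrt(sum((y - mean(y))^2))
    out[i, j] <- sum((x - mean(x)) * (y - mean(y))) / (sx * sy)
  }
  out
}

# Naive O(n^3) topological overlap.
oracle_tom <- function(A) {
  diag(A) <- 0
  n <- nrow(A)
  out <- diag(n)
  k <- rowSums(A)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(A[i, ] * A[, j])
    denom <- min(k[i], k[j]) + 1 - A[i, j]
    out[i, j] <- if (A[i, j] == 0 && l == 0) 0 else (l + A[i, j]) / denom
  }
  dimnames(out) <- dimnames(A)
  out
}

# Naive agglomeration under a Lance-Williams update; method "average"
# (UPGMA) or "ward" (ward.D2 convention: update on squared distances).
oracle_linkage_heights <- function(D, method = c("average", "ward")) {
  method <- match.arg(method)
  D <- as.matrix(D)
  n <- nrow(D)
  active <- seq_len(n)
  size <- rep(1, n)
  d <- D
  if (method == "ward") d <- D^2
  heights <- numeric(0)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      dd <- d[active[a], active[b]]
      if (dd < bd) { bd <- dd; best <- c(active[a], active[b]) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, if (method == "ward") sqrt(bd) else bd)
    # merge j into i
    for (u in setdiff(active, c(i, j))) {
      d[i, u] <- d[u, i] <- if (method == "average")
        (size[i] * d[i, u] + size[j] * d[j, u]) / (size[i] + size[j])
      else
        ((size[i] + size[u]) * d[i, u] + (size[j] + size[u]) * d[j, u] -
           size[u] * d[i, j]) / (size[i] + size[j] + size[u])
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# Brute-force Benjamini-Hochberg: q_i = min over ranks >= rank(i) of p*m/rank.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    cand <- vapply(rank_i:m, function(r) p[o[r]] * m / r, 0)
    q[i] <- min(1, min(cand))
  }
  q
}

# Exhaustive hypergeometric upper tail by enumerating all query draws.
oracle_hyper_enum <- function(universe_pairs, ref_idx, q_draws, observed) {
  draws <- utils::combn(universe_pairs, q_draws)
  hits <- apply(draws, 2, function(d) sum(d %in% ref_idx))
  mean(hits >= observed)
}

# Brute-force k-core numbers: for each k, peel nodes of degree < k until
# stable; survivors have core >= k.
oracle_coreness <- function(adj) {
  n <- nrow(adj)
  core <- rep(0L, n)
  k <- 1L
  repeat {
    alive <- rep(TRUE, n)
    repeat {
      deg <- rowSums(adj[, alive, drop = FALSE])
      low <- which(alive & deg < k)
      if (!length(low)) break
      alive[low] <- FALSE
    }
    if (!any(alive)) break
    core[alive] <- k
    k <- k + 1L
  }
  core
}

# Brute-force MCODE vertex weight: highest k-core of the closed
# neighbourhood times that core's density.
oracle_mcode_weight <- function(adj, v) {
  nb <- which(adj[v, ] > 0)
  nodes <- sort(unique(c(v, nb)))
  sub <- adj[nodes, nodes, drop = FALSE]
  core <- oracle_coreness(sub)
  kmax <- max(core)
  if (kmax == 0) return(0)
  cn <- which(core >= kmax)
  cs <- sub[cn, cn, drop = FALSE]
  nv <- length(cn)
  dens <- if (nv < 2) 0 else sum(cs) / (nv * (nv - 1))
  kmax * dens
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Random undirected adjacency on `n` named nodes with edge prob `p`.
random_unweighted_graph <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1
  adj
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", weighted = TRUE)
}

# Tiny expression fixture with deterministic values.
tiny_expression <- function(nr = 3, nc = 4, seed = 1, transformed = TRUE) {
  set.seed(seed)
  m <- matrix(stats::rnorm(nr * nc, 8, 2), nr, nc,
              dimnames = list(sprintf("P%02d", seq_len(nr)),
                              sprintf("S%02d", seq_len(nc))))
  expression_matrix(m, transformed = transformed)
}

# Synthetic reference interaction network built from planted truth: a
# fraction of within-module pairs plus random cross pairs.
make_reference_network <- function(truth, frac_within = 0.1,
                                   n_noise = 200, seed = 1) {
  set.seed(seed)
  edges <- NULL
  for (mm in setdiff(unique(truth$module_of), "background")) {
    mem <- names(truth$module_of)[truth$module_of == mm]
    pairs <- t(utils::combn(mem, 2))
    take <- sample(nrow(pairs), ceiling(frac_within * nrow(pairs)))
    edges <- rbind(edges, pairs[take, , drop = FALSE])
  }
  ids <- names(truth$module_of)
  noise <- cbind(sample(ids, n_noise, replace = TRUE),
                 sample(ids, n_noise, replace = TRUE))
  noise <- noise[noise[, 1] != noise[, 2], , drop = FALSE]
  edges <- rbind(edges, noise)
  df <- data.frame(from = edges[, 1], to = edges[, 2],
                   weight = stats::runif(nrow(edges), 0.4, 1))
  g <- igraph::graph_from_data_frame(df, directed = FALSE, vertices = ids)
  igraph::simplify(g, edge.attr.comb = list(weight = "max"))
}
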