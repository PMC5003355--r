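# Canonical "a|b" keys for the undirected edges of g restricted to `nodes`.
.edge_keys <- function(g, nodes) {
  el <- igraph::as_edgelist(g)
  if (!nrow(el)) return(character(0))
  keep <- el[, 1] %in% nodes & el[, 2] %in% nodes
  el <- el[keep, , drop = FALSE]
  unique(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
}

#' Overlap statistics between a query and a reference network
#'
#' Restricts both edge sets to the shared node set, then reports the edge
#' intersection, the Jaccard coefficient
#' (`intersection / union` of edge sets) and an upper-tail hypergeometric
#' p-value for the overlap: the probability of drawing at least the
#' observed number of reference edges when the query's edges are drawn
#' uniformly from the universe of unordered node pairs over the shared
#' nodes.
#'
#' @param query An igraph network (e.g. a thresholded co-expression
#'   module network).
#' @param reference An igraph reference interaction network.
#' @param universe `"intersection"` (default) to define the pair universe
#'   over the shared node set, `"union"` to use the union of node sets.
#' @return An object of class `NetworkOverlap`: list with `shared_nodes`,
#'   `universe_edges`, `q_edges`, `r_edges`, `intersection`, `jaccard`,
#'   `p_hyper`.
#' @export
overlap_stats <- function(query, reference,
                          universe = c("intersection", "union")) {
  universe <- match.arg(universe)
  qn <- igraph::V(query)$name
  rn <- igraph::V(reference)$name
  shared <- intersect(qn, rn)
  if (!length(shared)) stop("query and reference share no nodes")
  base <- if (universe == "intersection") shared else union(qn, rn)
  qe <- .edge_keys(query, base)
  re <- .edge_keys(reference, base)
  int <- length(intersect(qe, re))
  uni <- length(union(qe, re))
  U <- choose(length(base), 2)
  p <- if (length(qe) == 0 || length(re) == 0) 1 else
    stats::phyper(int - 1, length(re), U - length(re), length(qe),
                  lower.tail = FALSE)
  structure(list(shared_nodes = length(shared), universe_edges = U,
                 q_edges = length(qe), r_edges = length(re),
                 intersection = int,
                 jaccard = if (uni == 0) 0 else int / uni,
                 p_hyper = p, universe = universe),
            class = "NetworkOverlap")
}

#' @export
print.NetworkOverlap <- function(x, ...) {
  cat(sprintf(paste0("NetworkOverlap: %d shared nodes; query %d / reference ",
                     "%d edges; intersection %d\n"),
              x$shared_nodes, x$q_edges, x$r_edges, x$intersection))
  cat(sprintf("  Jaccard %.4f, hypergeometric p %.3g\n", x$jaccard, x$p_hyper))
  if (!is.null(x$p_empirical))
    cat(sprintf("  empirical p %.3g (%d randomisations)\n",
                x$p_empirical, x$n_randomisations))
  invisible(x)
}

#' Empirical overlap p-value by Erdos-Renyi edge randomisation
#'
#' Repeatedly replaces the query with a uniform random graph on the same
#' (shared) node set and edge count, and counts randomisations whose edge
#' intersection with the reference reaches the observed one. The p-value
#' uses the add-one correction `(1 + hits) / (n + 1)` so it is never zero.
#'
#' @inheritParams overlap_stats
#' @param n Number of randomisations (>= 100 recommended).
#' @param seed Integer seed.
#' @return The input overlap (computed if needed) with `p_empirical`,
#'   `n_randomisations` and `seed` fields added.
#' @export
er_randomisation_p <- function(query, reference, n = 1000, seed = 1) {
  obs <- overlap_stats(query, reference)
  shared <- intersect(igraph::V(query)$name, igraph::V(reference)$name)
  shared <- sort(shared)
  nn <- length(shared)
  U <- choose(nn, 2)
  qm <- min(obs$q_edges, U)
  # mark which pair indices are reference edges
  idx_of <- function(i, j) (i - 1) * nn - i * (i - 1) / 2 + (j - i)
  re <- .edge_keys(reference, shared)
  refmask <- logical(U)
  if (length(re)) {
    parts <- strsplit(re, "|", fixed = TRUE)
    ii <- match(vapply(parts, `[[`, "", 1L), shared)
    jj <- match(vapply(parts, `[[`, "", 2L), shared)
    lo <- pmin(ii, jj); hi <- pmax(ii, jj)
    refmask[idx_of(lo, hi)] <- TRUE
  }
  set.seed(as.integer(seed))
  hits <- 0L
  for (b in seq_len(n)) {
    samp <- sample.int(U, qm)
    if (sum(refmask[samp]) >= obs$intersection) hits <- hits + 1L
  }
  obs$p_empirical <- (1 + hits) / (n + 1)
  obs$n_randomisations <- n
  obs$seed <- as.integer(seed)
  obs
}

#' Sweep query and reference cutoffs and tabulate overlaps
#'
#' Evaluates [overlap_stats()] (optionally with the Erdos-Renyi empirical
#' p-value) over the full cross-product of co-expression adjacency cutoffs
#' and reference confidence cutoffs.
#'
#' @param a An `AdjacencyMatrix`.
#' @param reference An igraph reference network (scores as `weight`), or a
#'   path readable by [read_reference_network()].
#' @param wgcna_cutoffs Adjacency thresholds for the query network.
#' @param ref_cutoffs Confidence thresholds for the reference network.
#' @param ids Optional protein subset (e.g. one module).
#' @param n_rand Number of Erdos-Renyi randomisations (0 = skip).
#' @param seed Seed for the randomisations.
#' @return Data frame with one row per cutoff pair: cutoffs, edge counts,
#'   `jaccard`, `p_hyper` and (when `n_rand > 0`) `p_empirical`.
#' @export
threshold_sweep <- function(a, reference, wgcna_cutoffs, ref_cutoffs,
                            ids = NULL, n_rand = 0, seed = 1) {
  stopifnot(length(wgcna_cutoffs) > 0, length(ref_cutoffs) > 0)
  if (is.character(reference))
    reference <- read_reference_network(reference, score_cutoff = 0,
                                        keep_isolated = TRUE)
  rows <- list()
  for (qc in wgcna_cutoffs) {
    q <- threshold_network(a, qc, ids = ids)
    for (rc in ref_cutoffs) {
      r <- igraph::subgraph_from_edges(
        reference, igraph::E(reference)[igraph::E(reference)$weight >= rc],
        delete.vertices = FALSE)
      ov <- if (n_rand > 0) er_randomisation_p(q, r, n = n_rand, seed = seed)
            else overlap_stats(q, r)
      row <- data.frame(wgcna_cutoff = qc, ref_cutoff = rc,
                        shared_nodes = ov$shared_nodes,
                        q_edges = ov$q_edges, r_edges = ov$r_edges,
                        intersection = ov$intersection,
                        jaccard = ov$jaccard, p_hyper = ov$p_hyper)
      if (n_rand > 0) row$p_empirical <- ov$p_empirical
      rows <- c(rows, list(row))
    }
  }
  do.call(rbind, rows)
}
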