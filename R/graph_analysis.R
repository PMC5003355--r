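#' Threshold an adjacency matrix into a network
#'
#' Builds the co-expression network whose edges are protein pairs with
#' adjacency weight `>= cutoff`. Isolated nodes are retained so module
#' membership is preserved.
#'
#' @param a An `AdjacencyMatrix`.
#' @param cutoff Edge admission threshold in `[0, 1]`.
#' @param ids Optional subset of protein ids (e.g. one module) to restrict
#'   the network to before thresholding.
#' @return An undirected [igraph::graph] with edge attribute `weight` and
#'   graph attribute `threshold`.
#' @export
threshold_network <- function(a, cutoff, ids = NULL) {
  stopifnot(inherits(a, "AdjacencyMatrix"), cutoff >= 0, cutoff <= 1)
  A <- a$a
  if (!is.null(ids)) {
    missing <- setdiff(ids, a$ids)
    if (length(missing))
      stop("unknown protein ids: ", paste(missing, collapse = ", "))
    A <- A[ids, ids, drop = FALSE]
  } else ids <- a$ids
  A[is.na(A)] <- 0
  sel <- which(upper.tri(A) & A >= cutoff, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[sel[, 1]], to = ids[sel[, 2]],
               weight = A[sel]),
    directed = FALSE, vertices = ids)
  g <- igraph::set_graph_attr(g, "threshold", cutoff)
  g
}

#' MCODE vertex weights
#'
#' Scores each node by the density of the highest k-core of its closed
#' neighbourhood times that core's order `k`: the core-clustering
#' coefficient weighting of the molecular-complex-detection algorithm.
#' Nodes embedded in locally dense regions score high; isolated nodes
#' score 0.
#'
#' @param g An igraph graph (edge weights are ignored; MCODE operates on
#'   edge presence).
#' @return Named numeric vector of vertex weights.
#' @export
mcode_vertex_weights <- function(g) {
  nodes <- igraph::V(g)$name
  w <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    nb <- c(v, igraph::neighbors(g, v)$name)
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0) next
    core_nodes <- names(core)[core >= kmax]
    core_sub <- igraph::induced_subgraph(sub, core_nodes)
    nv <- igraph::vcount(core_sub)
    dens <- if (nv < 2) 0 else
      2 * igraph::ecount(core_sub) / (nv * (nv - 1))
    w[v] <- kmax * dens
  }
  w
}

#' Extract dense complexes (MCODE)
#'
#' Seeded dense-cluster extraction: nodes are seeded in decreasing vertex
#' weight; from each unvisited seed, neighbours are included breadth-first
#' while their weight is at least `(1 - node_score_cutoff)` times the seed
#' weight, up to `max_depth` steps from the seed. Complexes not containing
#' a `k_core`-core are discarded; the haircut step removes singly-connected
#' nodes from each complex. Complexes are scored by `density x size` and
#' returned in decreasing score. Seed ties are broken by lexicographic node
#' id, making the output independent of node input order.
#'
#' @param g An igraph graph.
#' @param node_score_cutoff Inclusion slack relative to the seed weight
#'   (default 0.2, the plugin default).
#' @param k_core Minimum core a complex must contain (default 2).
#' @param haircut Remove degree-1 nodes from complexes (default TRUE).
#' @param fluff Not implemented; must stay FALSE (the plugin default).
#' @param max_depth Maximum breadth-first depth from the seed.
#' @return An object of class `MCODEResult`: list with `vertex_weight`,
#'   `complexes` (list of character vectors, decreasing score), `scores`,
#'   `seeds` and `parameters`.
#' @export
mcode_complexes <- function(g, node_score_cutoff = 0.2, k_core = 2,
                            haircut = TRUE, fluff = FALSE, max_depth = 100) {
  if (fluff) warning("fluff post-processing is not implemented; ignored")
  w <- mcode_vertex_weights(g)
  ord <- order(-w, names(w))
  visited <- stats::setNames(rep(FALSE, length(w)), names(w))
  complexes <- list(); seeds <- character(0)
  for (seed in names(w)[ord]) {
    if (visited[seed]) next
    thr <- (1 - node_score_cutoff) * w[seed]
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < max_depth) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in igraph::neighbors(g, v)$name) {
          if (!visited[u] && w[u] >= thr) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < k_core) next
    if (haircut) {
      keep <- names(which(igraph::degree(sub) >= 2))
      if (length(keep) < 2L) next
      sub <- igraph::induced_subgraph(sub, keep)
      members <- keep
    }
    complexes <- c(complexes, list(sort(members)))
    seeds <- c(seeds, seed)
  }
  nv <- vapply(complexes, length, 0L)
  dens <- vapply(complexes, function(m) {
    sub <- igraph::induced_subgraph(g, m)
    n <- igraph::vcount(sub)
    if (n < 2) 0 else 2 * igraph::ecount(sub) / (n * (n - 1))
  }, 0)
  score <- dens * nv
  first_id <- vapply(complexes, `[`, "", 1L)
  ord2 <- order(-score, -nv, first_id)
  structure(list(vertex_weight = w,
                 complexes = complexes[ord2],
                 scores = score[ord2],
                 seeds = seeds[ord2],
                 parameters = list(node_score_cutoff = node_score_cutoff,
                                   k_core = k_core, haircut = haircut,
                                   fluff = fluff, max_depth = max_depth)),
            class = "MCODEResult")
}

#' @export
print.MCODEResult <- function(x, ...) {
  cat("MCODE:", length(x$complexes), "complexes\n")
  for (i in seq_along(x$complexes))
    cat(sprintf("  #%d: %d nodes, score %.3f\n", i,
                length(x$complexes[[i]]), x$scores[i]))
  invisible(x)
}

#' Hub proteins of a module network
#'
#' Computes, within the thresholded module subgraph, each protein's degree
#' `k` and its z-score `(k - mean k) / sd k`; hubs are proteins with
#' `z > 2`, i.e. a number of connections more than two standard deviations
#' above the module average. In a degree-regular subgraph (`sd = 0`) there
#' are no hubs.
#'
#' @param g An igraph network (typically from [threshold_network()]).
#' @param m Optional `ModuleAssignment`; together with `module` restricts
#'   `g` to that module's members.
#' @param module Optional module colour label.
#' @param z_cutoff Hub threshold on the degree z-score (default 2).
#' @return An object of class `HubSet`: data frame with `node`, `k`, `z`,
#'   `hub`, plus attribute `module`.
#' @export
hub_nodes <- function(g, m = NULL, module = NULL, z_cutoff = 2) {
  if (!is.null(m)) {
    stopifnot(inherits(m, "ModuleAssignment"), !is.null(module))
    if (identical(module, "grey")) stop("hubs are defined for non-grey modules")
    members <- intersect(module_members(m, module), igraph::V(g)$name)
    g <- igraph::induced_subgraph(g, members)
  }
  if (igraph::vcount(g) < 3L)
    stop("module subgraph has fewer than 3 nodes")
  k <- igraph::degree(g)
  s <- stats::sd(k)
  z <- if (s <= .Machine$double.eps) rep(0, length(k)) else (k - mean(k)) / s
  out <- data.frame(node = names(k), k = as.integer(k), z = as.numeric(z),
                    hub = if (s <= .Machine$double.eps) FALSE else z > z_cutoff,
                    row.names = NULL)
  out <- out[order(-out$z, out$node), ]
  rownames(out) <- NULL
  structure(out, class = c("HubSet", "data.frame"), module = module)
}

#' Direct co-expression neighbourhood of one protein
#'
#' Induced subgraph on a protein and its direct neighbours.
#'
#' @param g An igraph network.
#' @param node Protein id.
#' @return An igraph subgraph.
#' @export
neighbourhood <- function(g, node) {
  if (!node %in% igraph::V(g)$name) stop("unknown node: ", node)
  igraph::induced_subgraph(g, c(node, igraph::neighbors(g, node)$name))
}

#' Ward sub-clusters of member expression profiles
#'
#' Z-scores each member protein's profile across samples, clusters the
#' profiles with Ward's minimum-variance method on Euclidean distances,
#' and cuts the tree into `k` sub-clusters. Sub-clusters are labelled
#' `a`, `b`, `c`, ... by decreasing size (ties by smallest member id).
#'
#' @param x An `ExpressionMatrix`.
#' @param members Protein ids to cluster (e.g. an MCODE main complex).
#' @param k Number of sub-clusters.
#' @return An object of class `SubclusterResult`: list with `cluster_of`
#'   (named letter labels), `sizes`, `k`, `linkage = "ward"`, `tree`.
#' @export
ward_subclusters <- function(x, members, k) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (k < 1) stop("`k` must be >= 1")
  missing <- setdiff(members, rownames(x$values))
  if (length(missing))
    stop("unknown proteins: ", paste(missing, collapse = ", "))
  if (k > length(members)) stop("`k` exceeds the number of members")
  block <- x$values[members, , drop = FALSE]
  z <- t(scale(t(block)))
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  labs <- sort(unique(cl))
  sz <- vapply(labs, function(l) sum(cl == l), 0L)
  first_id <- vapply(labs, function(l) min(names(cl)[cl == l]), "")
  ord <- order(-sz, first_id)
  letter_of <- stats::setNames(letters[seq_along(labs)], labs[ord])
  cluster_of <- stats::setNames(letter_of[as.character(cl)], names(cl))
  sizes <- sort(table(cluster_of), decreasing = TRUE)
  structure(list(cluster_of = cluster_of, sizes = sizes, k = k,
                 linkage = "ward", tree = hc),
            class = "SubclusterResult")
}
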