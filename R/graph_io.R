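#' Read a reference interaction network from an edge-list file
#'
#' Reads a three-column (nodeA, nodeB, score) delimited edge list in the
#' dialect of a STRING interaction export. Scores on a 0-1000 scale are
#' auto-detected (any score > 1) and rescaled to 0-1. Self-loops are
#' dropped and duplicate/reciprocal edges are collapsed keeping the maximum
#' score, then edges below `score_cutoff` are removed.
#'
#' @param path File path.
#' @param score_cutoff Minimum confidence score on the 0-1 scale (edges with
#'   score >= cutoff are kept).
#' @param keep_isolated Keep nodes that lose all their edges (default FALSE).
#' @return An undirected [igraph::graph] with edge attribute `weight`.
#' @export
read_reference_network <- function(path, score_cutoff = 0.4,
                                   keep_isolated = FALSE) {
  stopifnot(score_cutoff >= 0, score_cutoff <= 1)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty edge-list file: ", path)
  first <- strsplit(lines[[1]], "[\t ,;]+")[[1]]
  has_header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
  body <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  parts <- strsplit(body, "[\t ,;]+")
  n_fields <- lengths(parts)
  bad <- which(n_fields < 3L)
  if (length(bad))
    stop(sprintf("unparsable edge-list line %d: %s",
                 bad[1] + offset, dQuote(body[bad[1]])))
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(s))
  if (length(bad))
    stop(sprintf("unparsable score on edge-list line %d: %s",
                 bad[1] + offset, dQuote(body[bad[1]])))
  if (max(s) > 1) s <- s / 1000
  edge_graph(a, b, s, cutoff = score_cutoff, keep_isolated = keep_isolated)
}

# Build a simple undirected weighted graph from parallel edge vectors,
# collapsing duplicates to the max weight and applying a weight cutoff.
edge_graph <- function(a, b, w, cutoff = 0, keep_isolated = FALSE) {
  keep <- a != b
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  w <- vapply(split(w, key), max, 0)
  pairs <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  nodes <- sort(unique(c(a, b)))
  pass <- w >= cutoff
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[pass, 1], to = pairs[pass, 2],
               weight = unname(w[pass])),
    directed = FALSE,
    vertices = if (keep_isolated) nodes else sort(unique(c(pairs[pass, 1:2])))
  )
  g
}

#' Write a graph as a three-column edge list
#'
#' @param g An igraph graph with a `weight` edge attribute.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_data_frame(g, what = "edges")
  if (is.null(el$weight)) el$weight <- 1
  utils::write.table(el[, c("from", "to", "weight")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a graph as GraphML (Cytoscape-consumable)
#'
#' @inheritParams write_edge_list
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
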