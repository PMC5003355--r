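#' Read a flat annotation map
#'
#' Reads gene/protein -> term annotations from either a 2-3 column
#' delimited file (`protein`, `term`, optional `category`; header
#' optional) or a GMT file (one term per line: id, description, then
#' member genes).
#'
#' @param path File path; GMT is detected by the `.gmt` extension.
#' @return A named list mapping term id to a character vector of proteins,
#'   with attributes `term_names` and `categories` (named character
#'   vectors, possibly empty).
#' @export
read_annotations <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 3L)
    if (length(short))
      stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
    ids <- vapply(parts, `[[`, "", 1L)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- ids
    attr(sets, "term_names") <- stats::setNames(
      vapply(parts, `[[`, "", 2L), ids)
    attr(sets, "categories") <- stats::setNames(rep("", length(ids)), ids)
    return(sets)
  }
  sep <- .dialect_sep(path, "auto")
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"")
  # tolerate a header row
  if (nrow(df) && identical(tolower(as.character(df[1, 1])), "protein"))
    df <- df[-1, , drop = FALSE]
  if (ncol(df) < 2L) stop("annotation file needs >= 2 columns (protein, term)")
  sets <- split(as.character(df[[1]]), as.character(df[[2]]))
  sets <- lapply(sets, unique)
  ids <- names(sets)
  cats <- if (ncol(df) >= 3L)
    vapply(split(as.character(df[[3]]), as.character(df[[2]])),
           function(v) v[1], "")[ids]
  else stats::setNames(rep("", length(ids)), ids)
  attr(sets, "term_names") <- stats::setNames(ids, ids)
  attr(sets, "categories") <- cats
  sets
}

#' Hypergeometric term enrichment of a target set
#'
#' Tests each annotation term for over-representation in `target` against
#' `background` (the two sets must be disjoint; the population is their
#' union, mirroring a module-vs-remaining-modules design). Per term the
#' upper-tail hypergeometric probability of observing at least the actual
#' number of target hits is computed; terms with no target hit are
#' skipped. Benjamini-Hochberg q-values are attached.
#'
#' @param target Character vector of target proteins (e.g. one module).
#' @param background Character vector of background proteins (e.g. the
#'   remaining modules), disjoint from `target`.
#' @param annotations Named list term -> proteins, e.g. from
#'   [read_annotations()].
#' @return A data frame of class `EnrichmentTable`: `term`, `name`,
#'   `category`, `target_hits`, `target_size`, `background_hits`,
#'   `background_size`, `p`, `q`, sorted by `p`.
#' @export
hypergeometric_enrichment <- function(target, background, annotations) {
  if (!length(annotations)) stop("empty annotation map")
  overlap <- intersect(target, background)
  if (length(overlap))
    stop("target and background overlap: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  population <- union(target, background)
  annotated <- unique(unlist(annotations, use.names = FALSE))
  outside <- setdiff(annotated, population)
  if (length(outside))
    message(length(outside), " annotated proteins absent from the population; ignored")
  N <- length(population)
  n_t <- length(target)
  term_names <- attr(annotations, "term_names")
  categories <- attr(annotations, "categories")
  rows <- lapply(names(annotations), function(tm) {
    prots <- intersect(annotations[[tm]], population)
    K <- length(prots)
    k <- length(intersect(prots, target))
    if (k == 0L) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n_t, lower.tail = FALSE)
    data.frame(term = tm,
               name = if (!is.null(term_names)) unname(term_names[tm]) else tm,
               category = if (!is.null(categories)) unname(categories[tm]) else "",
               target_hits = k, target_size = n_t,
               background_hits = K - k, background_size = N - n_t,
               p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- data.frame(term = character(0), name = character(0),
                      category = character(0), target_hits = integer(0),
                      target_size = integer(0), background_hits = integer(0),
                      background_size = integer(0), p = numeric(0),
                      q = numeric(0))
    class(out) <- c("EnrichmentTable", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement;
#' input order is preserved. `q_i >= p_i` always holds.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}
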