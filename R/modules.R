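# Colour ladder for module labels, ordered by module size rank; grey is
# reserved for unassigned proteins.
.module_colours <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

#' Average-linkage dendrogram of the TOM dissimilarity
#'
#' Hierarchically clusters proteins with average linkage on the `1 - TOM`
#' dissimilarity, the standard tree underlying co-expression module
#' detection.
#'
#' @param tom A `TOMMatrix`.
#' @return An [stats::hclust] tree over proteins.
#' @export
cluster_dendrogram <- function(tom) {
  stopifnot(inherits(tom, "TOMMatrix"))
  if (length(tom$ids) < 2L) stop("need at least 2 proteins to cluster")
  d <- stats::as.dist(tom$dissim)
  stats::hclust(d, method = "average")
}

#' Cut the dendrogram into modules
#'
#' Detects modules by cutting the average-linkage TOM dendrogram at a high
#' static height (a quantile of the merge heights, default 0.99, so that
#' only the final background-level joins are undone), sends branches
#' smaller than `min_module_size` to the grey (unassigned) module, and then
#' iteratively merges modules whose eigengenes are closer than
#' `merge_cut_height` on the `1 - cor` scale. Colours are assigned by
#' descending module size (turquoise, blue, brown, yellow, ...); ties are
#' broken by the lexicographically smallest member id. Grey is always the
#' unassigned label.
#'
#' @param d An [stats::hclust] tree from [cluster_dendrogram()].
#' @param tom The `TOMMatrix` the tree was built from.
#' @param x The `ExpressionMatrix`, needed for eigengene-based module
#'   merging; with `x = NULL` the merge step is skipped.
#' @param min_module_size Smallest branch kept as a module (default 30).
#' @param merge_cut_height Eigengene dissimilarity (`1 - cor`) below which
#'   two modules are merged (default 0.25, i.e. eigengene correlation
#'   above 0.75).
#' @param cut_method `"adaptive"` (default) places the branch cut in the
#'   widest gap of the upper merge-height profile — the breakpoint where
#'   tight branches stop forming and background-level joins begin;
#'   `"static"` cuts at the `cut_quantile` quantile of the merge heights.
#' @param cut_quantile Quantile used by the static cut and as fallback
#'   when the height profile is degenerate (default 0.99).
#' @param assign_unclustered After the branch cut, assign each unclustered
#'   protein to the module whose eigengene correlates best (in absolute
#'   value) with its profile, provided that correlation is significant at
#'   `kme_alpha` (default TRUE). Branches merge at different heights, so a
#'   single global cut always strands late-joining members; this
#'   module-membership step recovers them. Requires `x`.
#' @param kme_alpha Two-sided significance level defining the minimum
#'   module-membership correlation for assignment (default 0.05; at 12
#'   samples this is |kME| >= 0.576).
#' @return An object of class `ModuleAssignment`: list with `ids`,
#'   `module_of` (named colour per protein, `"grey"` = unassigned),
#'   `sizes`, `min_module_size`, `merge_cut_height`, `cut_height`.
#' @export
cut_modules <- function(d, tom, x = NULL, min_module_size = 30,
                        merge_cut_height = 0.25,
                        cut_method = c("adaptive", "static"),
                        cut_quantile = 0.99,
                        assign_unclustered = TRUE, kme_alpha = 0.05) {
  stopifnot(inherits(d, "hclust"), inherits(tom, "TOMMatrix"),
            min_module_size >= 1, merge_cut_height >= 0)
  cut_method <- match.arg(cut_method)
  h <- if (cut_method == "adaptive")
    .adaptive_cut_height(d, min_module_size, cut_quantile)
  else stats::quantile(d$height, cut_quantile)
  cl <- stats::cutree(d, h = h)
  ids <- d$labels
  if (is.null(ids)) ids <- tom$ids
  names(cl) <- ids

  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < min_module_size])
  cl[cl %in% small] <- 0L
  if (all(cl == 0L)) {
    warning("no branch reached min_module_size; all proteins are grey")
    module_of <- stats::setNames(rep("grey", length(ids)), ids)
    return(.module_assignment(ids, module_of, min_module_size,
                              merge_cut_height, h))
  }

  if (!is.null(x) && length(unique(cl[cl != 0L])) > 1L)
    cl <- .merge_close_modules(cl, x, merge_cut_height)

  if (!is.null(x) && isTRUE(assign_unclustered) && length(unique(cl[cl != 0L])))
    cl <- .refine_by_kme(cl, x, kme_alpha, min_module_size)

  module_of <- .colourise(cl, ids)
  .module_assignment(ids, module_of, min_module_size, merge_cut_height, h)
}

# Module-membership refinement: starting from the branch-cut cores,
# iteratively (i) compute module eigengenes (sign-oriented towards their
# members), (ii) reassign every protein to the module with its highest
# signed membership correlation kME — provided that kME is significant at
# `alpha` (two-sided Student t, n-2 df) — and (iii) drop modules that fall
# below the minimum size. Signed kME is the conventional membership
# measure and separates anti-correlated modules that unsigned adjacency
# conflates. Stops when labels are stable (at most 10 rounds).
.refine_by_kme <- function(cl, x, alpha, min_module_size) {
  n <- ncol(x$values)
  tcrit <- stats::qt(1 - alpha / 2, df = n - 2)
  r_min <- tcrit / sqrt(tcrit^2 + n - 2)
  for (iter in 1:10) {
    labs <- sort(unique(cl[cl != 0L]))
    if (!length(labs)) return(cl)
    E <- vapply(labs, function(l) {
      .eigengene(x$values[names(cl)[cl == l], , drop = FALSE])$vector
    }, numeric(n))
    kme <- suppressWarnings(stats::cor(t(x$values), E))
    kme[is.na(kme)] <- 0
    best <- max.col(kme, ties.method = "first")
    ok <- kme[cbind(seq_along(best), best)] >= r_min
    new_cl <- ifelse(ok, labs[best], 0L)
    names(new_cl) <- names(cl)
    sz <- table(new_cl[new_cl != 0L])
    drop <- as.integer(names(sz)[sz < min_module_size])
    new_cl[new_cl %in% drop] <- 0L
    if (identical(unname(new_cl), unname(cl))) break
    cl <- new_cl
  }
  cl
}

# Adaptive branch-cut height: candidate heights are the midpoints between
# consecutive merge heights; the chosen cut maximises the number of
# branches reaching min_module_size (ties broken towards the highest cut,
# which strands the fewest proteins below the cut). Degenerate profiles
# fall back to a quantile cut.
.adaptive_cut_height <- function(d, min_module_size, quantile_fallback = 0.99) {
  hs <- sort(unique(d$height))
  if (length(hs) < 2L)
    return(unname(stats::quantile(d$height, quantile_fallback)))
  cand <- (hs[-1] + hs[-length(hs)]) / 2
  if (length(cand) > 400L)
    cand <- cand[unique(round(seq(1, length(cand), length.out = 400L)))]
  labs <- stats::cutree(d, h = cand)
  n_big <- apply(labs, 2L, function(cl) sum(table(cl) >= min_module_size))
  best <- max(n_big)
  if (best == 0L)
    return(unname(stats::quantile(d$height, quantile_fallback)))
  cand[max(which(n_big == best))]
}

.module_assignment <- function(ids, module_of, min_module_size,
                               merge_cut_height, cut_height = NA_real_) {
  sizes <- table(module_of)
  ord <- order(-as.integer(sizes), names(sizes))
  sizes <- sizes[ord]
  structure(list(ids = ids, module_of = module_of,
                 sizes = sizes,
                 min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height,
                 cut_height = unname(cut_height)),
            class = "ModuleAssignment")
}

#' @export
print.ModuleAssignment <- function(x, ...) {
  cat("ModuleAssignment:", length(x$ids), "proteins,",
      sum(names(x$sizes) != "grey"), "modules\n")
  print(x$sizes)
  invisible(x)
}

#' Proteins belonging to a module
#'
#' @param m A `ModuleAssignment`.
#' @param module Colour label.
#' @return Character vector of protein ids.
#' @export
module_members <- function(m, module) {
  stopifnot(inherits(m, "ModuleAssignment"))
  if (!module %in% m$module_of) stop("unknown module: ", module)
  names(m$module_of)[m$module_of == module]
}

# Iteratively merge clusters whose eigengenes are within merge_cut_height
# on the 1 - cor scale, closest pair first.
.merge_close_modules <- function(cl, x, merge_cut_height) {
  repeat {
    labs <- sort(unique(cl[cl != 0L]))
    if (length(labs) < 2L) return(cl)
    E <- vapply(labs, function(l) {
      .eigengene(x$values[names(cl)[cl == l], , drop = FALSE])$vector
    }, numeric(ncol(x$values)))
    D <- 1 - stats::cor(E)
    diag(D) <- Inf
    if (min(D) >= merge_cut_height) return(cl)
    idx <- which(D == min(D), arr.ind = TRUE)[1, ]
    cl[cl == labs[idx[2]]] <- labs[idx[1]]
  }
}

# Size-ranked colour labels; ties broken by smallest member id.
.colourise <- function(cl, ids) {
  labs <- sort(unique(cl[cl != 0L]))
  sz <- vapply(labs, function(l) sum(cl == l), 0L)
  first_id <- vapply(labs, function(l) min(ids[cl == l]), "")
  ord <- order(-sz, first_id)
  colour_of <- stats::setNames(
    c(.module_colours, paste0("module", seq_along(labs)))[seq_along(labs)],
    labs[ord])
  out <- rep("grey", length(cl))
  nz <- cl != 0L
  out[nz] <- colour_of[as.character(cl[nz])]
  stats::setNames(out, ids)
}

# First principal component of a members x samples block: rows are
# standardised, the first right singular vector is the per-sample eigengene,
# sign-oriented so that its mean correlation with member profiles is >= 0.
.eigengene <- function(block) {
  sds <- apply(block, 1L, stats::sd)
  drop <- sds <= .Machine$double.eps
  if (any(drop)) {
    warning("zero-variance proteins dropped from eigengene: ",
            paste(rownames(block)[drop], collapse = ", "))
    block <- block[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  if (nrow(block) < 1L) stop("module has no proteins with variance")
  z <- (block - rowMeans(block)) / sds
  sv <- svd(z)
  e <- sv$v[, 1L]
  orient <- mean(stats::cor(e, t(block)))
  if (!is.na(orient) && orient < 0) e <- -e
  list(vector = e, explained = sv$d[1L]^2 / sum(sv$d^2))
}

#' Module eigengenes
#'
#' Per module (grey excluded), standardises member profiles and extracts
#' the first principal component over samples: the module eigengene, a
#' per-sample summary of the module's expression. Eigengenes are unit
#' vectors sign-oriented so that their mean correlation with member
#' profiles is non-negative.
#'
#' @param x The `ExpressionMatrix`.
#' @param m A `ModuleAssignment`.
#' @return An object of class `EigengeneMatrix`: list with `eigengenes`
#'   (samples x modules matrix), `explained_variance` (per module), and
#'   `samples`.
#' @export
module_eigengenes <- function(x, m) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(m, "ModuleAssignment"))
  mods <- setdiff(names(m$sizes), "grey")
  if (!length(mods)) stop("no non-grey modules")
  res <- lapply(mods, function(mod) {
    members <- module_members(m, mod)
    if (length(members) < 2L)
      stop("module ", mod, " has fewer than 2 proteins")
    .eigengene(x$values[members, , drop = FALSE])
  })
  E <- vapply(res, `[[`, numeric(ncol(x$values)), "vector")
  dimnames(E) <- list(colnames(x$values), mods)
  structure(list(eigengenes = E,
                 explained_variance = stats::setNames(
                   vapply(res, `[[`, 0, "explained"), mods),
                 samples = colnames(x$values)),
            class = "EigengeneMatrix")
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation between each module eigengene and each numeric
#' trait, with a two-sided Student-t p-value on `n - 2` degrees of freedom.
#' Constant traits yield `NA` with a warning.
#'
#' @param e An `EigengeneMatrix`.
#' @param t A `TraitTable` whose samples match the eigengene samples.
#' @return An object of class `TraitCorrelationResult`: list with matrices
#'   `r` and `p` (modules x traits) and `n` (sample count).
#' @export
module_trait_correlation <- function(e, t) {
  stopifnot(inherits(e, "EigengeneMatrix"))
  if (!identical(rownames(t), e$samples))
    stop("trait samples do not match eigengene samples")
  traits <- names(t)
  mods <- colnames(e$eigengenes)
  n <- length(e$samples)
  r <- p <- matrix(NA_real_, length(mods), length(traits),
                   dimnames = list(mods, traits))
  for (tr in traits) {
    tv <- as.numeric(t[[tr]])
    if (stats::sd(tv) <= .Machine$double.eps) {
      warning("trait ", tr, " is constant; correlation undefined")
      next
    }
    for (mod in mods) {
      ct <- stats::cor.test(e$eigengenes[, mod], tv, method = "pearson")
      r[mod, tr] <- unname(ct$estimate)
      p[mod, tr] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n), class = "TraitCorrelationResult")
}

#' @export
print.TraitCorrelationResult <- function(x, ...) {
  cat("Module-trait Pearson correlations (n =", x$n, ")\n")
  out <- matrix(sprintf("%.2f (p=%.3g)", x$r, x$p), nrow(x$r),
                dimnames = dimnames(x$r))
  print(out, quote = FALSE)
  invisible(x)
}
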