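#' Pairwise Pearson correlation of protein profiles
#'
#' Computes the full symmetric proteins x proteins Pearson correlation
#' matrix across samples. Proteins with zero variance across samples are
#' flagged; their correlations are undefined (`NA`) and must be excluded
#' downstream.
#'
#' @param x An `ExpressionMatrix` with `transformed = TRUE` and >= 4
#'   samples.
#' @return An object of class `CorrelationMatrix`: list with `ids`, the
#'   correlation matrix `r`, `method = "pearson"`, and `zero_variance`
#'   (logical per protein).
#' @export
pairwise_correlation <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!x$transformed)
    stop("correlations are computed on the arcsinh scale; call arcsinh_transform() first")
  if (ncol(x$values) < 4L) stop("need >= 4 samples")
  v <- apply(x$values, 1L, stats::var)
  zv <- v <= .Machine$double.eps
  if (any(zv))
    warning("zero-variance proteins excluded from correlations: ",
            paste(rownames(x$values)[zv], collapse = ", "))
  r <- suppressWarnings(stats::cor(t(x$values), method = "pearson"))
  r[zv, ] <- NA_real_
  r[, zv] <- NA_real_
  diag(r) <- ifelse(zv, NA_real_, 1)
  r <- pmin(pmax(r, -1), 1)
  structure(list(ids = rownames(x$values), r = r, method = "pearson",
                 zero_variance = zv),
            class = "CorrelationMatrix")
}

#' Soft-threshold adjacency
#'
#' Raises correlations to the power `beta`: `a_ij = corr(i, j)^beta`. For
#' `beta > 1` this is the unsigned weighted network `|r|^beta` (an even
#' power folds anti-correlation into adjacency; taking `|r|` makes odd
#' powers behave consistently). `beta = 1` is the hard/raw case and keeps
#' the signed correlation itself, for two-tailed threshold analysis. The
#' diagonal is set to 0 so that row sums are connectivities.
#'
#' @param c A `CorrelationMatrix`.
#' @param beta Positive integer thresholding power.
#' @return An object of class `AdjacencyMatrix`: list with `ids`, weight
#'   matrix `a`, `beta` and `mode` (`"soft"` for beta > 1, `"signed"` for
#'   beta = 1).
#' @export
soft_adjacency <- function(c, beta = 10) {
  stopifnot(inherits(c, "CorrelationMatrix"), beta >= 1)
  a <- if (beta == 1) c$r else abs(c$r)^beta
  diag(a) <- 0
  structure(list(ids = c$ids, a = a, beta = as.integer(beta),
                 mode = if (beta == 1) "signed" else "soft"),
            class = "AdjacencyMatrix")
}

#' Scale-free topology fit across candidate soft powers
#'
#' For each power in `beta_grid`, computes the unsigned adjacency
#' `|r|^beta`, the per-protein connectivity `k_i = sum_j a_ij`, bins `k`
#' into `n_bins` equal-count bins, and fits a least-squares line of
#' `log10(frequency)` on `log10(mean k per bin)`. The reported fit index is
#' the signed R^2 (negated when the slope is positive, so only genuinely
#' scale-free decreasing degree distributions score high). The chosen power
#' is the lowest one whose signed R^2 reaches `r2_threshold`.
#'
#' @param c A `CorrelationMatrix`.
#' @param beta_grid Integer powers to evaluate.
#' @param n_bins Number of equal-count connectivity bins.
#' @param r2_threshold Signed R^2 regarded as a good scale-free fit
#'   (default 0.8, the conventional choice).
#' @return An object of class `ScaleFreeFit`: list with `fit` (data frame
#'   of beta, r2, slope, mean_k), `chosen_beta` (NA when no power reaches
#'   the threshold) and `r2_threshold`.
#' @export
scale_free_fit <- function(c, beta_grid = 1:20, n_bins = 10,
                           r2_threshold = 0.8) {
  stopifnot(inherits(c, "CorrelationMatrix"), length(beta_grid) > 0)
  r <- abs(c$r)
  keep <- !c$zero_variance
  r <- r[keep, keep, drop = FALSE]
  rows <- lapply(beta_grid, function(beta) {
    a <- r^beta
    diag(a) <- 0
    k <- rowSums(a)
    sf <- .scale_free_r2(k, n_bins)
    data.frame(beta = beta, r2 = unname(sf["r2"]),
               slope = unname(sf["slope"]), mean_k = mean(k))
  })
  fit <- do.call(rbind, rows)
  rownames(fit) <- NULL
  ok <- which(fit$r2 >= r2_threshold)
  chosen <- if (length(ok)) fit$beta[min(ok)] else NA_integer_
  if (is.na(chosen))
    warning("no power in the grid reaches signed R^2 >= ", r2_threshold)
  structure(list(fit = fit, chosen_beta = chosen,
                 r2_threshold = r2_threshold),
            class = "ScaleFreeFit")
}

#' @export
print.ScaleFreeFit <- function(x, ...) {
  cat("Scale-free topology fit (signed R^2 threshold",
      x$r2_threshold, ")\n")
  print(x$fit, digits = 3)
  cat("chosen beta:", x$chosen_beta, "\n")
  invisible(x)
}

# Signed R^2 of log10 p(k) vs log10 k over equal-width connectivity bins.
.scale_free_r2 <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(c(r2 = NA_real_, slope = NA_real_))
  bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = nlevels(bin)) / length(k)
  kbar <- as.numeric(tapply(k, bin, mean))
  keep <- !is.na(kbar) & freq > 0 & kbar > 0
  if (sum(keep) < 3) return(c(r2 = NA_real_, slope = NA_real_))
  fitlm <- stats::lm(log10(freq[keep]) ~ log10(kbar[keep]))
  slope <- unname(stats::coef(fitlm)[2])
  r2 <- suppressWarnings(summary(fitlm)$r.squared)  # exact fits are fine
  c(r2 = -sign(slope) * r2, slope = slope)
}

#' Topological overlap matrix
#'
#' Computes the unsigned topological overlap
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` and connectivity `k_i = sum_u a_iu` (diagonal
#' treated as 0). TOM combines direct adjacency with shared-neighbour
#' weight: two proteins overlap strongly when they are connected and share
#' the same neighbourhood. The diagonal is 1 and `dissim = 1 - tom` is the
#' clustering dissimilarity. Isolated pairs (both connectivities and the
#' adjacency zero) get the defined limit 0.
#'
#' @param a An `AdjacencyMatrix` with `mode = "soft"`.
#' @return An object of class `TOMMatrix`: list with `ids`, `tom`,
#'   `dissim`.
#' @export
topological_overlap <- function(a) {
  stopifnot(inherits(a, "AdjacencyMatrix"))
  if (a$mode != "soft")
    stop("TOM is defined on the unsigned soft adjacency (beta > 1)")
  A <- a$a
  if (anyNA(A)) {
    bad <- rowSums(is.na(A)) == ncol(A) - 1L
    if (any(bad)) stop("adjacency contains undefined rows; drop zero-variance ",
                       "proteins before computing TOM")
    A[is.na(A)] <- 0
  }
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - A
  tom <- (L + A) / denom
  tom[denom <= 0] <- 0
  tom[A == 0 & L == 0] <- 0   # isolated pairs: defined limit
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  structure(list(ids = a$ids, tom = tom, dissim = 1 - tom),
            class = "TOMMatrix")
}
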