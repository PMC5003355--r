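#' Permute intensities within each protein
#'
#' Builds a permutation null by independently shuffling each protein's
#' intensities across samples. This destroys all inter-protein correlation
#' while preserving every protein's marginal value multiset.
#'
#' @param x An `ExpressionMatrix` with `transformed = TRUE`.
#' @param seed Integer seed; the permutation is reproducible.
#' @return A permuted `ExpressionMatrix`.
#' @export
permute_intensities <- function(x, seed = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!x$transformed)
    stop("permute after the arcsinh transform, where correlations are computed")
  set.seed(as.integer(seed))
  v <- x$values
  n <- ncol(v)
  for (i in seq_len(nrow(v))) v[i, ] <- v[i, sample.int(n)]
  x$values <- v
  x
}

#' Permutation false-discovery curve for correlation thresholds
#'
#' Estimates, for every threshold `t` on a grid, the ratio of null pairs
#' passing `t` to observed pairs passing `t` — an empirical
#' false-discovery ratio for the co-expression threshold. "Passing" means
#' `>= t` for the `positive` and `adjacency` tails and `<= t` for the
#' `negative` tail. Only upper-triangle pairs are counted. When several
#' null replicates are supplied the null count is averaged over them.
#'
#' @param observed A `CorrelationMatrix` or `AdjacencyMatrix` computed on
#'   the real data.
#' @param null A matching object computed on permuted data, or a list of
#'   such objects (one per permutation).
#' @param tail `"positive"`, `"negative"` (signed correlations) or
#'   `"adjacency"` (unsigned soft weights).
#' @param grid Threshold grid; defaults to resolution 5e-4 over `[-1, 1]`
#'   (signed) or `[0, 1]` (adjacency).
#' @return An object of class `FdrCurve`: data frame with `threshold`,
#'   `n_null` (mean over permutations), `n_observed`, `fdr` (`NA` where no
#'   observed pair passes), plus attributes `tail`, `beta`,
#'   `n_permutations`.
#' @export
fdr_curve <- function(observed, null, tail = c("positive", "negative",
                                               "adjacency"), grid = NULL) {
  tail <- match.arg(tail)
  if (!is.list(null) || inherits(null, c("CorrelationMatrix", "AdjacencyMatrix")))
    null <- list(null)
  obs <- .pair_values(observed)
  nulls <- lapply(null, .pair_values)
  if (any(vapply(nulls, length, 0L) != length(obs)))
    stop("observed and null must cover the same protein set")
  if (is.null(grid)) {
    grid <- if (tail == "adjacency") seq(0, 1, by = 5e-4)
            else seq(-1, 1, by = 5e-4)
  }
  if (!length(grid)) stop("empty threshold grid")
  grid <- sort(grid)
  n_obs <- .count_passing(obs, grid, tail)
  n_null <- rowMeans(vapply(nulls, .count_passing, numeric(length(grid)),
                            grid = grid, tail = tail))
  fdr <- ifelse(n_obs > 0, n_null / n_obs, NA_real_)
  out <- data.frame(threshold = grid, n_null = n_null,
                    n_observed = n_obs, fdr = fdr)
  structure(out, class = c("FdrCurve", "data.frame"),
            tail = tail,
            beta = if (inherits(observed, "AdjacencyMatrix")) observed$beta else 1L,
            n_permutations = length(nulls))
}

.pair_values <- function(m) {
  v <- if (inherits(m, "CorrelationMatrix")) m$r
       else if (inherits(m, "AdjacencyMatrix")) m$a
       else stop("need a CorrelationMatrix or AdjacencyMatrix")
  v <- v[upper.tri(v)]
  v[!is.na(v)]
}

# Vector of counts of `values` passing each grid threshold; ties count as
# passing in both tails.
.count_passing <- function(values, grid, tail) {
  s <- sort(values)
  n <- length(s)
  if (tail == "negative") findInterval(grid, s)            # #{v <= t}
  else n - findInterval(grid, s, left.open = TRUE)         # #{v >= t}
}

#' Monotone-enforced false-discovery curve
#'
#' Replaces the raw ratio with its running maximum taken from the stringent
#' end of the grid (high thresholds for the positive/adjacency tails, low
#' thresholds for the negative tail), so the curve is non-increasing toward
#' stringency. Grid points supported by fewer than `min_observed` observed
#' pairs are treated as undefined: a ratio estimated from a handful of
#' pairs is pure Monte-Carlo noise and would otherwise poison the running
#' maximum for every laxer threshold.
#'
#' @param curve An `FdrCurve`.
#' @param min_observed Minimum observed-pair count supporting a grid point
#'   (default 10).
#' @return The curve with an extra `fdr_mono` column.
#' @export
monotone_fdr <- function(curve, min_observed = 10) {
  stopifnot(inherits(curve, "FdrCurve"))
  fdr <- curve$fdr
  fdr[curve$n_observed < min_observed] <- NA_real_
  filled <- ifelse(is.na(fdr), -Inf, fdr)
  mono <- if (attr(curve, "tail") == "negative") cummax(filled)
          else rev(cummax(rev(filled)))
  mono[mono == -Inf] <- NA_real_
  curve$fdr_mono <- ifelse(is.na(fdr), NA_real_, mono)
  curve
}

#' Threshold achieving a target false-discovery ratio
#'
#' Returns the least stringent grid threshold whose monotone-enforced
#' false-discovery ratio is at or below `target` — the smallest `t` for the
#' positive/adjacency tails, the largest for the negative tail.
#'
#' @param curve An `FdrCurve`.
#' @param target Target ratio (default 0.05).
#' @param min_observed Passed to [monotone_fdr()] when the curve has not
#'   been monotone-enforced yet.
#' @return The threshold, or `NA` with a warning when no grid point
#'   achieves the target.
#' @export
threshold_at_fdr <- function(curve, target = 0.05, min_observed = 10) {
  stopifnot(inherits(curve, "FdrCurve"))
  if (is.null(curve$fdr_mono)) curve <- monotone_fdr(curve, min_observed)
  ok <- which(!is.na(curve$fdr_mono) & curve$fdr_mono <= target)
  if (!length(ok)) {
    warning("no threshold achieves a false-discovery ratio of ", target)
    return(NA_real_)
  }
  idx <- if (attr(curve, "tail") == "negative") max(ok) else min(ok)
  curve$threshold[idx]
}

#' Permutation false-discovery calibration of a dataset
#'
#' Convenience wrapper running the whole calibration: computes the observed
#' correlation (and, for `beta > 1`, soft adjacency), generates `n_perm`
#' within-protein permutation nulls, and returns the false-discovery curves
#' and the thresholds at `target`. For `beta = 1` both signed tails are
#' calibrated; for `beta > 1` the single adjacency tail is.
#'
#' @param x A transformed `ExpressionMatrix`.
#' @param beta Soft power (1 = signed correlations).
#' @param n_perm Number of permutation replicates (the numerator is
#'   averaged over them). `n_perm = 1` reproduces a single-randomisation
#'   regime.
#' @param target Target false-discovery ratio.
#' @param seed Integer seed for the permutations.
#' @param grid Optional threshold grid passed to [fdr_curve()].
#' @return A list with `curves` (named list of `FdrCurve`) and
#'   `thresholds` (named numeric).
#' @export
permutation_fdr <- function(x, beta = 1, n_perm = 10, target = 0.05,
                            seed = 1, grid = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"), n_perm >= 1)
  obs_cor <- pairwise_correlation(x)
  null_cor <- lapply(seq_len(n_perm), function(i) {
    suppressWarnings(pairwise_correlation(
      permute_intensities(x, seed = as.integer(seed) + i - 1L)))
  })
  if (beta == 1) {
    curves <- list(
      positive = fdr_curve(obs_cor, null_cor, tail = "positive", grid = grid),
      negative = fdr_curve(obs_cor, null_cor, tail = "negative", grid = grid))
  } else {
    obs_a <- soft_adjacency(obs_cor, beta)
    null_a <- lapply(null_cor, soft_adjacency, beta = beta)
    curves <- list(adjacency = fdr_curve(obs_a, null_a, tail = "adjacency",
                                         grid = grid))
  }
  thresholds <- vapply(curves, threshold_at_fdr, 0, target = target)
  list(curves = curves, thresholds = thresholds)
}
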