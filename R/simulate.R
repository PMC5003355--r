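#' Simulate an expression matrix with planted co-expression modules
#'
#' Generates a proteins x samples matrix on the arcsinh-like (real) scale
#' with a planted module structure: samples split into two equal groups
#' (state 0 = control, 1 = disease); each module has an eigengene whose
#' in-sample Pearson correlation with the state vector equals the requested
#' value exactly (the eigengene is a mix of the standardised state vector
#' and a noise direction orthogonal to it and to every other eigengene);
#' module members are `loading * eigengene + Gaussian noise`; hub proteins
#' receive loadings at the top of the loading range and a reduced noise
#' share (`hub_noise_factor`), giving them near-unit module membership —
#' at 12 samples a loading difference alone is swamped by the sampling
#' noise of the pairwise correlations, so hubness must live in the signal
#' fraction; background proteins are pure noise. Per-protein baseline
#' offsets mimic arcsinh-scale intensity levels without affecting any
#' correlation.
#'
#' The defaults reproduce the geometry of a small two-group label-free
#' proteomics study: 12 samples (6 + 6), ~800 proteins, four planted
#' modules of 272/256/177/76 proteins with trait correlations
#' -0.9/-0.8/+0.93/0, and a background of unassigned proteins.
#'
#' @param n_proteins Total number of proteins.
#' @param n_samples Even number of samples, split half control / half
#'   disease.
#' @param module_sizes Integer vector of planted module sizes (each >= 2,
#'   sum <= `n_proteins`).
#' @param trait_corrs Signed eigengene-state correlations, one per module,
#'   each in \[-1, 1\].
#' @param loading_range Interval in (0, 1] from which member loadings are
#'   drawn uniformly.
#' @param n_hubs Number of hub proteins per module, given loadings in the
#'   top 5% of `loading_range`.
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   transformed scale (eigengenes have unit standard deviation).
#' @param hub_noise_factor Multiplier applied to `noise_sd` for hub
#'   proteins (default 0.3).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with components `expression` ([expression_matrix()],
#'   `transformed = TRUE`), `traits` (a `TraitTable` with `state`, `age`,
#'   `gender`), and `truth` (class `SyntheticTruth`: `module_of`,
#'   `eigengene_trait_corr`, `hub_ids`, `eigengenes`, `loadings`, `seed`).
#' @export
simulate_dataset <- function(n_proteins = 800, n_samples = 12,
                             module_sizes = c(272, 256, 177, 76),
                             trait_corrs = c(-0.9, -0.8, 0.93, 0),
                             loading_range = c(0.6, 0.95),
                             n_hubs = 3, noise_sd = 0.5,
                             hub_noise_factor = 0.3, seed = 1) {
  if (n_samples %% 2L != 0L || n_samples < 4L)
    stop("`n_samples` must be an even count >= 4")
  if (length(trait_corrs) != length(module_sizes))
    stop("`trait_corrs` must have one entry per module")
  if (any(abs(trait_corrs) > 1))
    stop("infeasible trait correlation: |r| must be <= 1")
  if (any(module_sizes < 2))
    stop("module sizes must be >= 2")
  if (sum(module_sizes) > n_proteins)
    stop("sum(module_sizes) exceeds n_proteins")
  if (length(module_sizes) + 1L >= n_samples)
    stop("need n_samples > n_modules + 1 to plant orthogonal eigengenes")
  stopifnot(loading_range[1] > 0, loading_range[2] <= 1,
            loading_range[1] <= loading_range[2], noise_sd >= 0)

  set.seed(as.integer(seed))
  n_modules <- length(module_sizes)
  half <- n_samples %/% 2L
  state <- rep(c(0, 1), each = half)
  samples <- c(sprintf("Ct%02d", seq_len(half)), sprintf("Tu%02d", seq_len(half)))

  # unit-norm centred state direction; eigengene m = r*u_state + sqrt(1-r^2)*u_m
  # with u_m orthogonal to u_state and to all earlier u's, so the in-sample
  # correlations are exact by construction.
  u_state <- .unit_centred(state)
  basis <- list(u_state)
  eigengenes <- matrix(0, n_samples, n_modules,
                       dimnames = list(samples,
                                       if (n_modules) paste0("M", seq_len(n_modules))))
  for (m in seq_len(n_modules)) {
    u <- .orthonormal_draw(basis, n_samples)
    basis <- c(basis, list(u))
    e <- trait_corrs[m] * u_state + sqrt(1 - trait_corrs[m]^2) * u
    eigengenes[, m] <- e / stats::sd(e)   # centred, unit sd
  }

  ids <- sprintf("P%04d", seq_len(n_proteins))
  module_of <- rep("background", n_proteins)
  names(module_of) <- ids
  loadings <- stats::setNames(numeric(n_proteins), ids)
  hub_ids <- character(0)
  values <- matrix(stats::rnorm(n_proteins * n_samples, sd = noise_sd),
                   n_proteins, n_samples, dimnames = list(ids, samples))
  offset <- 1L
  lo <- loading_range[1]; hi <- loading_range[2]
  for (m in seq_len(n_modules)) {
    rows <- seq.int(offset, offset + module_sizes[m] - 1L)
    offset <- offset + module_sizes[m]
    module_of[rows] <- paste0("M", m)
    l <- stats::runif(length(rows), lo, hi)
    nh <- min(n_hubs, length(rows))
    hubs <- sample(seq_along(rows), nh)
    l[hubs] <- stats::runif(nh, hi - 0.05 * (hi - lo), hi)
    hub_ids <- c(hub_ids, ids[rows[hubs]])
    loadings[rows] <- l
    # hubs carry less residual noise: scale their pre-drawn noise rows
    values[rows[hubs], ] <- values[rows[hubs], , drop = FALSE] * hub_noise_factor
    values[rows, ] <- values[rows, ] + outer(l, eigengenes[, m])
  }
  values <- values + stats::runif(n_proteins, 4, 10)  # baseline intensity level

  expr <- expression_matrix(values,
                            group = rep(c("control", "tumour"), each = half),
                            transformed = TRUE)
  traits <- data.frame(state = state,
                       age = round(stats::rnorm(n_samples, 60, 8)),
                       gender = stats::rbinom(n_samples, 1, 0.5),
                       row.names = samples)
  traits <- trait_table(traits, expression = expr)
  truth <- structure(
    list(module_of = module_of,
         eigengene_trait_corr = stats::setNames(trait_corrs,
                                                colnames(eigengenes)),
         hub_ids = hub_ids, eigengenes = eigengenes,
         loadings = loadings, seed = as.integer(seed)),
    class = "SyntheticTruth")
  list(expression = expr, traits = traits, truth = truth)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  sizes <- table(x$module_of)
  cat("SyntheticTruth:", length(x$module_of), "proteins;",
      sum(names(sizes) != "background"), "planted modules\n")
  print(sizes)
  cat("planted eigengene-state correlations:\n")
  print(x$eigengene_trait_corr)
  invisible(x)
}

.unit_centred <- function(v) {
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

# Draw a unit vector orthogonal to every vector in `basis` (all unit,
# centred) and to the constant vector.
.orthonormal_draw <- function(basis, n) {
  for (i in 1:50) {
    z <- stats::rnorm(n)
    z <- z - mean(z)
    for (b in basis) z <- z - sum(z * b) * b
    nrm <- sqrt(sum(z^2))
    if (nrm > 1e-8) return(z / nrm)
  }
  stop("failed to draw an orthogonal direction")
}
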