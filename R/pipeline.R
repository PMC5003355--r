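#' Default pipeline configuration
#'
#' Returns the full set of pipeline parameters with their defaults. Any
#' subset can be overridden via [read_run_config()] or the `cfg` argument
#' of [run_pipeline()]; the effective configuration is always written into
#' the run directory.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    expression = NULL,      # path to intensity table (or ExpressionMatrix)
    traits = NULL,          # path to trait table (or TraitTable)
    reference = NULL,       # optional reference network edge list
    annotations = NULL,     # optional protein -> term annotation file
    transformed = FALSE,    # TRUE when intensities are already arcsinh scale
    beta = 10,              # soft threshold power
    pick_beta = FALSE,      # select beta by scale-free fit instead
    beta_grid = 1:20,
    min_module_size = 30,
    merge_cut_height = 0.25,
    fdr_target = 0.05,
    n_perm = 10,
    network_cutoff = 0.2,   # adjacency cutoff for module networks
    mcode_node_score_cutoff = 0.2,
    mcode_k_core = 2,
    subcluster_k = 4,
    wgcna_cutoffs = c(0.1, 0.2, 0.3),
    ref_cutoffs = c(0.4, 0.7),
    n_rand = 0,             # Erdos-Renyi randomisations in the comparison
    seed = 1,
    out_dir = "procoexp_run"
  )
}

#' Read a flat key = value run configuration
#'
#' Parses a plain-text configuration with one `key = value` per line
#' (`#` comments allowed). Values are coerced: `TRUE`/`FALSE`, numbers,
#' comma-separated numeric lists, `lo:hi` integer ranges; anything else
#' stays a string.
#'
#' @param path Configuration file path.
#' @return Named list merged over [default_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  cfg <- default_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    cfg[[key]] <- .coerce_config_value(val)
  }
  cfg
}

.coerce_config_value <- function(val) {
  if (toupper(val) %in% c("TRUE", "FALSE")) return(as.logical(toupper(val)))
  if (grepl("^-?[0-9]+:[0-9]+$", val)) {
    r <- as.integer(strsplit(val, ":", fixed = TRUE)[[1]])
    return(seq.int(r[1], r[2]))
  }
  parts <- strsplit(val, ",", fixed = TRUE)[[1]]
  nums <- suppressWarnings(as.numeric(trimws(parts)))
  if (!anyNA(nums)) return(nums)
  val
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full co-expression analysis pipeline
#'
#' Orchestrates ingest, soft-power selection, network and TOM
#' construction, module detection, eigengene-trait correlation,
#' permutation-FDR calibration, per-module dense-cluster/hub/sub-cluster
#' analysis, reference-network comparison and enrichment, writing every
#' artefact into the run directory along with the effective configuration
#' and a machine-readable JSON summary. Identical configuration and seed
#' give an identical summary. A failing stage aborts with the stage name;
#' artefacts written before the failure are preserved.
#'
#' @param cfg Named list of parameters (see [default_config()]); may also
#'   carry in-memory `expression`/`traits` objects instead of paths.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(cfg = list()) {
  full <- default_config()
  full[names(cfg)] <- cfg
  cfg <- full
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)

  # effective configuration, dumped verbatim
  dump <- vapply(cfg, function(v) {
    if (is.null(v)) "" else if (is.object(v) || is.list(v)) "<in-memory>"
    else paste(v, collapse = ",")
  }, "")
  writeLines(paste(names(dump), dump, sep = " = "), out("config.txt"))

  x <- .stage("ingest", {
    x <- if (inherits(cfg$expression, "ExpressionMatrix")) cfg$expression
         else read_expression(cfg$expression)
    if (isTRUE(cfg$transformed) && !x$transformed) x$transformed <- TRUE
    if (!x$transformed) x <- arcsinh_transform(x)
    x
  })
  traits <- .stage("ingest", {
    if (is.null(cfg$traits)) NULL
    else if (inherits(cfg$traits, "TraitTable")) cfg$traits
    else read_traits(cfg$traits, expression = x)
  })

  corr <- .stage("correlation", pairwise_correlation(x))

  beta <- cfg$beta
  sf <- .stage("scale_free_fit", scale_free_fit(corr, beta_grid = cfg$beta_grid))
  .write_tsv(sf$fit, out("scale_free_fit.tsv"))
  if (isTRUE(cfg$pick_beta)) {
    if (is.na(sf$chosen_beta))
      stop("pipeline stage `scale_free_fit` failed: no power reached the fit threshold")
    beta <- sf$chosen_beta
  }

  adj <- .stage("adjacency", soft_adjacency(corr, beta))
  tom <- .stage("tom", topological_overlap(adj))
  modules <- .stage("modules", {
    dend <- cluster_dendrogram(tom)
    cut_modules(dend, tom, x = x,
                min_module_size = cfg$min_module_size,
                merge_cut_height = cfg$merge_cut_height)
  })

  eig <- NULL; trait_cor <- NULL
  if (sum(names(modules$sizes) != "grey") > 0) {
    eig <- .stage("eigengenes", module_eigengenes(x, modules))
    .write_tsv(data.frame(sample = eig$samples, eig$eigengenes,
                          check.names = FALSE), out("eigengenes.tsv"))
    if (!is.null(traits)) {
      trait_cor <- .stage("trait_correlation",
                          module_trait_correlation(eig, traits))
      tc <- data.frame(module = rownames(trait_cor$r), trait_cor$r,
                       check.names = FALSE)
      names(tc)[-1] <- paste0("r_", colnames(trait_cor$r))
      tcp <- as.data.frame(trait_cor$p)
      names(tcp) <- paste0("p_", colnames(trait_cor$p))
      .write_tsv(cbind(tc, tcp), out("trait_correlation.tsv"))
    }
  }

  fdr <- .stage("fdr", {
    res <- list(
      beta1 = permutation_fdr(x, beta = 1, n_perm = cfg$n_perm,
                              target = cfg$fdr_target, seed = cfg$seed),
      soft = permutation_fdr(x, beta = beta, n_perm = cfg$n_perm,
                             target = cfg$fdr_target,
                             seed = cfg$seed + 1000L))
    for (nm in names(res$beta1$curves))
      .write_tsv(res$beta1$curves[[nm]], out(sprintf("fdr_beta1_%s.tsv", nm)))
    .write_tsv(res$soft$curves$adjacency, out("fdr_soft_adjacency.tsv"))
    res
  })

  module_stats <- list()
  for (mod in setdiff(names(modules$sizes), "grey")) {
    st <- .stage(paste0("graph_analysis:", mod), {
      members <- module_members(modules, mod)
      g <- threshold_network(adj, cfg$network_cutoff, ids = members)
      write_graphml(g, out(sprintf("%s_network.graphml", mod)))
      write_edge_list(g, out(sprintf("%s_network_edges.tsv", mod)))
      mc <- mcode_complexes(g,
                            node_score_cutoff = cfg$mcode_node_score_cutoff,
                            k_core = cfg$mcode_k_core)
      hubs <- hub_nodes(g)
      k_in <- igraph::degree(g)
      .write_tsv(data.frame(protein = hubs$node, k = hubs$k, z = hubs$z,
                            hub = hubs$hub),
                 out(sprintf("%s_hubs.tsv", mod)))
      main <- if (length(mc$complexes)) mc$complexes[[1]] else character(0)
      if (length(mc$complexes)) {
        comp_df <- do.call(rbind, lapply(seq_along(mc$complexes), function(i)
          data.frame(complex = i, protein = mc$complexes[[i]],
                     score = mc$scores[i])))
        .write_tsv(comp_df, out(sprintf("%s_complexes.tsv", mod)))
      }
      sub <- NULL
      if (length(main) >= max(2, cfg$subcluster_k)) {
        sub <- ward_subclusters(x, main, k = cfg$subcluster_k)
        .write_tsv(data.frame(protein = names(sub$cluster_of),
                              subcluster = unname(sub$cluster_of)),
                   out(sprintf("%s_subclusters.tsv", mod)))
      }
      list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
           main_complex_size = length(main),
           n_hubs = sum(hubs$hub),
           hub_ids = hubs$node[hubs$hub],
           connectivity = k_in,
           subcluster_sizes = if (!is.null(sub)) as.integer(sub$sizes))
    })
    module_stats[[mod]] <- st
  }

  # module table: protein, module, within-module connectivity and z-score
  mt <- .stage("module_table", {
    conn <- z <- stats::setNames(rep(NA_real_, length(modules$ids)), modules$ids)
    for (mod in names(module_stats)) {
      k <- module_stats[[mod]]$connectivity
      conn[names(k)] <- k
      s <- stats::sd(k)
      z[names(k)] <- if (is.na(s) || s <= .Machine$double.eps) 0
                     else (k - mean(k)) / s
    }
    df <- data.frame(protein = modules$ids,
                     module = unname(modules$module_of[modules$ids]),
                     connectivity = unname(conn[modules$ids]),
                     z = unname(z[modules$ids]))
    .write_tsv(df, out("modules.tsv"))
    df
  })

  comparison <- NULL
  if (!is.null(cfg$reference)) {
    comparison <- .stage("comparison", {
      tabs <- lapply(setdiff(names(modules$sizes), "grey"), function(mod) {
        tab <- threshold_sweep(adj, cfg$reference,
                               wgcna_cutoffs = cfg$wgcna_cutoffs,
                               ref_cutoffs = cfg$ref_cutoffs,
                               ids = module_members(modules, mod),
                               n_rand = cfg$n_rand, seed = cfg$seed)
        cbind(module = mod, tab)
      })
      tab <- do.call(rbind, tabs)
      .write_tsv(tab, out("comparison.tsv"))
      tab
    })
  }

  if (!is.null(cfg$annotations)) {
    .stage("enrichment", {
      ann <- if (is.list(cfg$annotations)) cfg$annotations
             else read_annotations(cfg$annotations)
      for (mod in setdiff(names(modules$sizes), "grey")) {
        target <- module_members(modules, mod)
        background <- setdiff(modules$ids, target)
        et <- hypergeometric_enrichment(target, background, ann)
        .write_tsv(et, out(sprintf("enrichment_%s.tsv", mod)))
      }
    })
  }

  summary <- list(
    n_proteins = length(modules$ids),
    n_samples = ncol(x$values),
    beta = beta,
    chosen_beta = sf$chosen_beta,
    module_sizes = as.list(modules$sizes),
    n_modules = sum(names(modules$sizes) != "grey"),
    n_grey = unname(if ("grey" %in% names(modules$sizes))
      as.integer(modules$sizes[["grey"]]) else 0L),
    fdr_thresholds = c(as.list(fdr$beta1$thresholds),
                       as.list(fdr$soft$thresholds)),
    trait_correlation = if (!is.null(trait_cor))
      as.list(as.data.frame(trait_cor$r)),
    modules = lapply(module_stats, function(s)
      s[c("n_nodes", "n_edges", "main_complex_size", "n_hubs", "hub_ids",
          "subcluster_sizes")]),
    best_jaccard = if (!is.null(comparison)) max(comparison$jaccard),
    seed = cfg$seed)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(summary)
}
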