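#' Construct an expression matrix
#'
#' Container for a proteins x samples intensity matrix together with the
#' per-sample group labels and a flag recording whether the arcsinh
#' transform has been applied. Rows are proteins (unique identifiers),
#' columns are samples.
#'
#' @param values Numeric matrix, proteins in rows, samples in columns.
#'   Dimnames are required: rownames are protein identifiers, colnames are
#'   sample names.
#' @param gene_symbols Optional character vector of gene symbols parallel to
#'   the rows.
#' @param group Optional per-sample labels (e.g. `"control"`/`"tumour"`),
#'   recycled into a factor.
#' @param transformed Logical flag: `TRUE` once intensities are on the
#'   arcsinh scale.
#' @return An object of class `ExpressionMatrix`.
#' @seealso [read_expression()], [arcsinh_transform()]
#' @export
expression_matrix <- function(values, gene_symbols = NULL, group = NULL,
                              transformed = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry protein ids as rownames and sample names as colnames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate protein ids: ", paste(dup, collapse = ", "))
  if (ncol(values) < 4L)
    stop("need at least 4 samples, got ", ncol(values))
  all_na <- rowSums(is.finite(values)) == 0L
  if (any(all_na))
    stop("rows without any finite value: ",
         paste(rownames(values)[all_na], collapse = ", "))
  if (anyNA(values))
    stop("missing intensities are not supported; impute or drop rows upstream")
  if (!is.null(gene_symbols)) {
    if (length(gene_symbols) != nrow(values))
      stop("`gene_symbols` must be parallel to the rows")
    gene_symbols <- as.character(gene_symbols)
    names(gene_symbols) <- rownames(values)
  }
  if (!is.null(group)) {
    group <- factor(rep_len(as.character(group), ncol(values)))
    names(group) <- colnames(values)
  }
  structure(
    list(values = values, gene_symbols = gene_symbols, group = group,
         transformed = isTRUE(transformed)),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d proteins x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$transformed) "arcsinh" else "raw"))
  if (!is.null(x$group))
    cat("groups:", paste(sprintf("%s=%d", levels(x$group),
                                 tabulate(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read a wide intensity table
#'
#' Reads a proteins x samples intensity table from delimited text. The first
#' column (or `id_col`) holds unique protein identifiers; the remaining
#' numeric columns are samples. Non-sample annotation columns (gene symbol,
#' peptide counts) can be named and are pulled out of the matrix.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @param id_col Name or index of the identifier column.
#' @param symbol_col Optional name of a gene-symbol column.
#' @param group Optional per-sample group labels for the sample columns.
#' @param min_peptides_col Optional name of a peptide-count column used to
#'   filter rows.
#' @param min_peptides Minimum peptide count kept when `min_peptides_col`
#'   is given (default 2, the usual two-peptide identification rule).
#' @return An [expression_matrix()] with `transformed = FALSE`.
#' @export
read_expression <- function(path, dialect = c("auto", "tsv", "csv"),
                            id_col = 1L, symbol_col = NULL,
                            group = NULL, min_peptides_col = NULL,
                            min_peptides = 2) {
  dialect <- match.arg(dialect)
  sep <- .dialect_sep(path, dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (is.numeric(id_col)) id_col <- names(df)[id_col]
  ids <- as.character(df[[id_col]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate protein ids: ", paste(dup, collapse = ", "))
  drop_cols <- c(id_col, symbol_col, min_peptides_col)
  sample_cols <- setdiff(names(df), drop_cols)
  vals <- df[, sample_cols, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value %s at row %d, column %s",
                     dQuote(v[bad[1]]), bad[1], sample_cols[j]))
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  symbols <- if (!is.null(symbol_col)) as.character(df[[symbol_col]])
  keep <- rep(TRUE, nrow(m))
  if (!is.null(min_peptides_col)) {
    keep <- as.numeric(df[[min_peptides_col]]) >= min_peptides
    message(sprintf("peptide filter (>= %g): kept %d of %d proteins",
                    min_peptides, sum(keep), nrow(m)))
  }
  expression_matrix(m[keep, , drop = FALSE],
                    gene_symbols = if (!is.null(symbols)) symbols[keep],
                    group = group, transformed = FALSE)
}

#' Write an expression matrix to delimited text
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, dialect = c("tsv", "csv")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(protein = rownames(x$values), check.names = FALSE)
  if (!is.null(x$gene_symbols)) df$gene_symbol <- unname(x$gene_symbols)
  vals <- x$values
  storage.mode(vals) <- "double"
  df <- cbind(df, as.data.frame(signif(vals, 15)))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Arcsinh-transform raw intensities
#'
#' Applies `asinh(v) = ln(v + sqrt(v^2 + 1))` elementwise. Unlike the log
#' transform it is defined at zero (`asinh(0) = 0`), which matters for
#' label-free intensities where unobserved features are reported as 0. The
#' transform is strictly increasing, so within-row rank order is preserved.
#'
#' @param x An `ExpressionMatrix` with `transformed = FALSE`.
#' @return The matrix on the arcsinh scale, `transformed = TRUE`.
#' @export
arcsinh_transform <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$transformed)
    stop("matrix is already arcsinh transformed; refusing to transform twice")
  x$values <- asinh(x$values)
  x$transformed <- TRUE
  x
}

#' Read a sample trait table
#'
#' Reads a table of per-sample clinical traits (one row per sample). Must
#' contain a sample identifier column and a binary `state` column
#' (0 = control, 1 = disease); additional numeric columns (age, encoded
#' gender, ...) are carried through. When `expression` is supplied the rows
#' are checked against its sample order — the expression file is the
#' authority on sample order.
#'
#' @param path File path (TSV or CSV by extension).
#' @param expression Optional `ExpressionMatrix` whose sample order the
#'   traits must match.
#' @param sample_col Name or index of the sample identifier column.
#' @param on_reorder `"error"` (default) to reject traits whose rows are a
#'   permutation of the expression samples, or `"reorder"` to align them
#'   with a warning.
#' @return A `data.frame` of class `TraitTable`, samples in rownames.
#' @export
read_traits <- function(path, expression = NULL, sample_col = 1L,
                        on_reorder = c("error", "reorder")) {
  on_reorder <- match.arg(on_reorder)
  sep <- .dialect_sep(path, "auto")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.numeric(sample_col)) sample_col <- names(df)[sample_col]
  samples <- as.character(df[[sample_col]])
  df <- df[, setdiff(names(df), sample_col), drop = FALSE]
  rownames(df) <- samples
  trait_table(df, expression = expression, on_reorder = on_reorder)
}

#' Construct a trait table
#'
#' @param traits Data frame of numeric traits, samples in rownames; must
#'   contain a binary `state` column.
#' @inheritParams read_traits
#' @return A `data.frame` of class `TraitTable`.
#' @export
trait_table <- function(traits, expression = NULL,
                        on_reorder = c("error", "reorder")) {
  on_reorder <- match.arg(on_reorder)
  if (!"state" %in% names(traits)) stop("trait table must have a `state` column")
  st <- traits$state
  if (is.character(st) || is.logical(st)) {
    suppressWarnings(st <- as.numeric(st))
  }
  if (anyNA(st) || !all(st %in% c(0, 1)))
    stop("`state` must be binary 0/1; offending values: ",
         paste(unique(traits$state[!(st %in% c(0, 1)) | is.na(st)]),
               collapse = ", "))
  traits$state <- as.numeric(st)
  if (!is.null(expression)) {
    want <- colnames(expression$values)
    have <- rownames(traits)
    missing <- setdiff(want, have)
    if (length(missing))
      stop("trait table lacks samples: ", paste(missing, collapse = ", "))
    if (!identical(have, want)) {
      if (on_reorder == "error")
        stop("trait sample order differs from expression; the expression ",
             "file owns the sample order (use on_reorder = \"reorder\")")
      warning("reordering trait rows to match expression sample order")
      traits <- traits[want, , drop = FALSE]
    }
  }
  class(traits) <- c("TraitTable", "data.frame")
  traits
}

.dialect_sep <- function(path, dialect) {
  if (dialect == "tsv") return("\t")
  if (dialect == "csv") return(",")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}
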