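#' Construct an expression matrix
#'
#' Light S3 container for a samples-by-genes expression table: a numeric
#' matrix with sample identifiers as row names, gene identifiers as column
#' names, an optional per-sample class label, and a flag recording whether
#' values have been min-max scaled into `[0, 1]`.
#'
#' @param values Numeric matrix, one row per sample, one column per gene.
#' @param gene_ids Optional gene identifiers (defaults to column names).
#' @param sample_ids Optional sample identifiers (defaults to row names).
#' @param class_labels Optional per-sample labels; stored but never used by
#'   the inference itself.
#' @param scaled Logical; `TRUE` once values lie in `[0, 1]`.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, gene_ids = colnames(values),
                        sample_ids = rownames(values),
                        class_labels = NULL, scaled = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric", call. = FALSE)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty expression table", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  gene_ids <- dedupe_ids(as.character(gene_ids))
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length must equal the number of columns", call. = FALSE)
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length must equal the number of rows", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers", call. = FALSE)
  if (!is.null(class_labels) && length(class_labels) != nrow(values))
    stop("class_labels length must equal the number of samples", call. = FALSE)
  if (scaled && any(values < 0 | values > 1))
    stop("scaled data must lie in [0, 1]", call. = FALSE)
  dimnames(values) <- list(as.character(sample_ids), gene_ids)
  structure(values,
            class_labels = class_labels,
            scaled = isTRUE(scaled),
            class = c("expr_matrix", "matrix", "array"))
}

# duplicate identifiers get an occurrence-index suffix: X, X.2, X.3 ...
# (clones sharing a symbol stay distinct network nodes)
dedupe_ids <- function(ids) {
  occ <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  ifelse(occ > 1L, paste0(ids, ".", occ), ids)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d samples x %d genes (%s)\n",
              nrow(x), ncol(x),
              if (is_scaled(x)) "scaled to [0,1]" else "unscaled"))
  if (!is.null(attr(x, "class_labels")))
    cat("  class labels:", paste(names(table(attr(x, "class_labels"))),
                                 table(attr(x, "class_labels")),
                                 sep = "=", collapse = ", "), "\n")
  cat("  genes:", paste(utils::head(colnames(x), 5), collapse = ", "),
      if (ncol(x) > 5) "...", "\n")
  invisible(x)
}

is_scaled <- function(m) isTRUE(attr(m, "scaled"))

as_expr_matrix <- function(m) {
  if (inherits(m, "expr_matrix")) return(m)
  expr_matrix(as.matrix(m),
              scaled = all(m >= 0 & m <= 1))
}

#' Read a delimited expression table
#'
#' Reads a tab- or comma-separated expression table (delimiter
#' auto-detected) with one header row and an identifier column. Duplicate
#' gene identifiers are disambiguated with an occurrence suffix
#' (`IGF2`, `IGF2.2`, `IGF2.3`) so every column stays a distinct node.
#'
#' @param path Path to the table.
#' @param orientation `"samples_by_genes"` (rows are samples; default) or
#'   `"genes_by_samples"` (transposed on read).
#' @param class_col Optional name of a column holding per-sample class
#'   labels; it is stored on the result and excluded from the genes.
#' @return An unscaled [expr_matrix()].
#' @export
read_expression_table <- function(path,
                                  orientation = c("samples_by_genes",
                                                  "genes_by_samples"),
                                  class_col = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty table: ", path, call. = FALSE)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty table: ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  # [.data.frame would mangle duplicated gene symbols, so track names by hand
  col_names <- names(df)[-1L]
  cols <- unclass(df)[-1L]
  labels <- NULL
  if (!is.null(class_col)) {
    hit <- which(col_names == class_col)
    if (!length(hit)) stop("class column not found: ", class_col, call. = FALSE)
    labels <- as.character(cols[[hit[1L]]])
    cols <- cols[-hit[1L]]
    col_names <- col_names[-hit[1L]]
  }
  for (j in seq_along(cols)) {
    v <- cols[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value %s in column '%s', row %d",
                     dQuote(v[bad[1L]]), col_names[j], bad[1L]), call. = FALSE)
      cols[[j]] <- num
    }
    if (anyNA(cols[[j]]))
      stop(sprintf("missing value in column '%s'", col_names[j]), call. = FALSE)
  }
  values <- do.call(cbind, cols)
  colnames(values) <- col_names
  if (orientation == "genes_by_samples") {
    gene_ids <- ids
    sample_ids <- colnames(values)
    values <- t(values)
    expr_matrix(values, gene_ids = gene_ids, sample_ids = sample_ids,
                class_labels = labels)
  } else {
    expr_matrix(values, gene_ids = colnames(values), sample_ids = ids,
                class_labels = labels)
  }
}

#' Write an expression table
#'
#' Writes a samples-by-genes table as delimited text at full double
#' precision, so that reading it back reproduces the values exactly.
#'
#' @param m An [expr_matrix()] or numeric matrix.
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @export
write_expression_table <- function(m, path, sep = "\t") {
  m <- as_expr_matrix(m)
  cells <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  lines <- c(paste(c("sample", colnames(m)), collapse = sep),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], cells[i, ]), collapse = sep), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Min-max scale each gene to the unit interval
#'
#' Maps each gene column through `(x - min) / (max - min)` so that all
#' values are compatible with the sigmoid-bounded output node. Constant
#' columns are mapped to 0.5 (the sigmoid midpoint): they carry no signal
#' but must not derail inference. Idempotent on already-scaled data.
#'
#' @param m An [expr_matrix()] or numeric matrix.
#' @return A scaled `expr_matrix` with values in `[0, 1]`.
#' @examples
#' m <- expr_matrix(cbind(a = c(0, 5, 10), b = c(7, 7, 7)))
#' minmax_scale(m)[, "a"]   # 0, 0.5, 1
#' @export
minmax_scale <- function(m) {
  m <- as_expr_matrix(m)
  vals <- unclass(m)
  attributes(vals) <- list(dim = dim(m), dimnames = dimnames(m))
  rng <- apply(vals, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  const <- span == 0
  span[const] <- 1
  vals <- sweep(vals, 2L, rng[1L, ], "-")
  vals <- sweep(vals, 2L, span, "/")
  vals[, const] <- 0.5
  expr_matrix(vals, class_labels = attr(m, "class_labels"), scaled = TRUE)
}
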