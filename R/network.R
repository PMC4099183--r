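#' Simplify a score matrix to its strongest edge per gene
#'
#' For every gene, taken as a target, keeps only the single incoming edge
#' with the largest absolute interaction score among unmasked entries (ties
#' broken by lexicographic source key). A fully populated G-gene matrix
#' therefore reduces to exactly G edges, one anchored at each gene; genes
#' whose incoming entries are all masked are reported in the
#' `dropped_targets` attribute.
#'
#' @param object An `anni` fit (filtered or not) or a square numeric score
#'   matrix with gene identifiers as dimnames.
#' @return An object of class `anni_map`: a list with `nodes`, `edges`
#'   (a data frame of source, target, score, sign, expression_r) and
#'   optional `annotations`.
#' @export
strongest_edge_per_gene <- function(object) {
  if (!inherits(object, "anni")) object <- as_anni(as.matrix(object))
  s <- object$scores
  edges <- lapply(colnames(s), function(tg) {
    col <- s[, tg]
    col <- col[!is.na(col)]
    if (!length(col)) return(NULL)
    best <- max(abs(col))
    src <- sort(names(col)[abs(col) == best], method = "radix")[1L]
    data.frame(source = src, target = tg, score = col[[src]],
               stringsAsFactors = FALSE)
  })
  dropped <- colnames(s)[vapply(edges, is.null, TRUE)]
  edges <- do.call(rbind, edges)
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        score = numeric())
  edges$sign <- ifelse(edges$score < 0, "inhibitory", "stimulatory")
  edges$expression_r <- if (is.null(object$expression_r))
    rep(NA_real_, nrow(edges))
  else object$expression_r[cbind(edges$source, edges$target)]
  map <- structure(list(nodes = rownames(s), edges = edges,
                        annotations = NULL),
                   class = "anni_map")
  attr(map, "dropped_targets") <- dropped
  map
}

#' Construct a network map from an edge table
#'
#' @param edges Data frame with columns `source`, `target`, `score` and
#'   optionally `sign` and `expression_r`.
#' @param nodes Node set (defaults to all endpoint genes).
#' @param annotations Optional per-gene display attributes (data frame with
#'   a `gene` column).
#' @return An `anni_map` object.
#' @export
network_map <- function(edges, nodes = NULL, annotations = NULL) {
  stopifnot(all(c("source", "target", "score") %in% names(edges)))
  if (any(edges$source == edges$target))
    stop("self-edges are not allowed", call. = FALSE)
  if (is.null(edges$sign))
    edges$sign <- ifelse(edges$score < 0, "inhibitory", "stimulatory")
  if (is.null(edges$expression_r))
    edges$expression_r <- rep(NA_real_, nrow(edges))
  if (is.null(nodes)) nodes <- sort(unique(c(edges$source, edges$target)),
                                    method = "radix")
  if (!all(c(edges$source, edges$target) %in% nodes))
    stop("every edge endpoint must be in nodes", call. = FALSE)
  structure(list(nodes = nodes,
                 edges = edges[, c("source", "target", "score", "sign",
                                   "expression_r")],
                 annotations = annotations),
            class = "anni_map")
}

#' @export
print.anni_map <- function(x, ...) {
  cat(sprintf("interaction network map: %d nodes, %d edges (%d stimulatory, %d inhibitory)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "stimulatory"),
              sum(x$edges$sign == "inhibitory")))
  invisible(x)
}

#' @export
plot.anni_map <- function(x, ...) {
  g <- as_igraph(x)
  plot(g, edge.arrow.size = 0.4,
       edge.color = ifelse(igraph::E(g)$sign == "stimulatory",
                           "steelblue", "firebrick"), ...)
  invisible(x)
}

as_igraph <- function(map) {
  igraph::graph_from_data_frame(map$edges, directed = TRUE,
                                vertices = data.frame(name = map$nodes))
}

#' Hub genes of a network map
#'
#' Ranks genes by total degree (incoming plus outgoing edges) in the
#' simplified map and keeps those at or above `min_degree`; ordering is
#' deterministic (degree descending, then gene key).
#'
#' @param map An `anni_map`.
#' @param min_degree Minimum total degree to report (default 2).
#' @return Data frame with columns `gene` and `degree`.
#' @export
hubs <- function(map, min_degree = 2L) {
  stopifnot(inherits(map, "anni_map"), min_degree >= 1L)
  deg <- table(factor(c(map$edges$source, map$edges$target),
                      levels = map$nodes))
  out <- data.frame(gene = if (length(deg)) names(deg) else character(0),
                    degree = as.integer(deg), stringsAsFactors = FALSE)
  out <- out[out$degree >= min_degree, , drop = FALSE]
  if (nrow(out))
    out <- out[order(-out$degree, out$gene, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Truncated p-values with Benjamini-Hochberg adjustment
#'
#' Multiplies each raw p-value by the gene's selection rank (capping the
#' product at 1), then applies the Benjamini-Hochberg step-up false
#' discovery rate adjustment to the products. Multi-column p-value tables
#' should be adjusted one column at a time.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @param rank Positive integer selection ranks, same length as `p`.
#' @return Adjusted truncated p-values in `[0, 1]`, preserving the order of
#'   the raw products.
#' @examples
#' truncated_p_values(c(0.001, 0.02), c(3, 1))
#' @export
truncated_p_values <- function(p, rank) {
  if (length(p) != length(rank)) stop("length mismatch", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  if (any(rank < 1)) stop("ranks must be positive", call. = FALSE)
  stats::p.adjust(pmin(p * rank, 1), method = "BH")
}

#' Export a network map
#'
#' Writes a map in a Cytoscape-readable format: SIF
#' (`source stimulates|inhibits target`), a tab-separated edge table
#' carrying score, sign and expression correlation, or GraphML with the
#' same edge attributes.
#'
#' @param map An `anni_map`.
#' @param format One of `"sif"`, `"edge_tsv"`, `"graphml"`.
#' @param path Output path.
#' @export
export_network <- function(map, format = c("sif", "edge_tsv", "graphml"),
                           path) {
  stopifnot(inherits(map, "anni_map"))
  format <- match.arg(format)
  if (format == "sif") {
    rel <- ifelse(map$edges$sign == "stimulatory", "stimulates", "inhibits")
    writeLines(sprintf("%s %s %s", map$edges$source, rel, map$edges$target),
               path)
  } else if (format == "edge_tsv") {
    e <- map$edges
    e$score <- sprintf("%.17g", e$score)
    e$expression_r <- ifelse(is.na(map$edges$expression_r), "NA",
                             sprintf("%.17g", map$edges$expression_r))
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(map), path, format = "graphml")
  }
  invisible(path)
}

#' Read an exported edge table back into a network map
#'
#' @param path Path to a file written by
#'   `export_network(map, "edge_tsv", path)`.
#' @param nodes Optional node set (defaults to the edge endpoints).
#' @return An `anni_map`.
#' @export
read_network_edges <- function(path, nodes = NULL) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(e) == 0L)
    return(structure(list(nodes = if (is.null(nodes)) character() else nodes,
                          edges = data.frame(source = character(),
                                             target = character(),
                                             score = numeric(),
                                             sign = character(),
                                             expression_r = numeric()),
                          annotations = NULL),
                     class = "anni_map"))
  network_map(e, nodes = nodes)
}

#' Write a node-annotation table for display tools
#'
#' @param annotations Data frame with a `gene` column plus display
#'   attributes (e.g. an expression category).
#' @param path Output path.
#' @export
write_node_annotations <- function(annotations, path) {
  stopifnot("gene" %in% names(annotations))
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
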