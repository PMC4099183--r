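#' Monte-Carlo cross-validation partition
#'
#' Randomly partitions `n_samples` indices, without replacement, into
#' disjoint training, test and validation sets covering every sample. Each
#' partition receives `floor(ratio * n)` samples; any remainder goes to
#' training.
#'
#' @param n_samples Number of samples (at least 5).
#' @param ratios Train/test/validation proportions summing to 1
#'   (default `c(0.6, 0.2, 0.2)`).
#' @param seed Integer seed for the random assignment.
#' @return A list with integer vectors `train`, `test`, `val`.
#' @examples
#' p <- mccv_split(100, seed = 7)
#' lengths(p)   # 60 / 20 / 20
#' @export
mccv_split <- function(n_samples, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (n_samples < 5L) stop("need at least 5 samples", call. = FALSE)
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1", call. = FALSE)
  sizes <- floor(ratios * n_samples)
  sizes[1L] <- sizes[1L] + (n_samples - sum(sizes))
  if (any(sizes == 0L)) stop("a partition would be empty", call. = FALSE)
  perm <- with_seed(seed, sample.int(n_samples))
  list(train = perm[seq_len(sizes[1L])],
       test = perm[sizes[1L] + seq_len(sizes[2L])],
       val = perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])])
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation, returning `NA` (a flagged missing value)
#' when either side has zero variance instead of erroring.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Interaction scores for a single target gene
#'
#' Trains perceptrons that predict `target` from every other gene under
#' Monte-Carlo cross-validation: for each of `n_reshuffles` random
#' 60:20:20 partitions and `n_repeats` random restarts, weights are updated
#' on the training partition while the test partition's MSE drives early
#' stopping, the validation partition is scored, and the trained
#' connection-weight influence scores are recorded. Scores are averaged
#' over all `n_reshuffles * n_repeats` models.
#'
#' Input genes are processed in a fixed lexicographic order and all seeds
#' derive from the master seed and the target's key, so results are
#' invariant to the column order of the input matrix.
#'
#' @param m A scaled [expr_matrix()].
#' @param target Gene identifier to predict.
#' @param config An [anni_config()].
#' @return List with `scores` (named vector over the remaining genes, in
#'   the matrix's gene order) and `val_mse` (mean validation MSE).
#' @export
infer_single_target <- function(m, target, config = anni_config()) {
  m <- as_expr_matrix(m)
  if (!is_scaled(m)) stop("expression matrix must be scaled first", call. = FALSE)
  genes <- colnames(m)
  if (!target %in% genes) stop("unknown target gene: ", target, call. = FALSE)
  sources <- setdiff(genes, target)
  canon <- sort(sources, method = "radix")   # locale-independent order
  X <- unclass(m)[, canon, drop = FALSE]
  d <- unclass(m)[, target]
  n <- nrow(m)
  tseed <- target_seed(config$rng_seed, target)
  n_models <- config$n_reshuffles * config$n_repeats
  score_sum <- numeric(length(canon))
  val_sum <- 0
  for (r in seq_len(config$n_reshuffles)) {
    part <- mccv_split(n, config$split_ratios, seed = derive_seed(tseed, r, 0L))
    for (p in seq_len(config$n_repeats)) {
      fit <- train_mlp(X[part$train, , drop = FALSE], d[part$train], config,
                       seed = derive_seed(tseed, r, p),
                       monitor_X = X[part$test, , drop = FALSE],
                       monitor_d = d[part$test])
      score_sum <- score_sum + influence_scores(fit$model)
      pred <- predict(fit$model, X[part$val, , drop = FALSE])
      val_sum <- val_sum + mean((d[part$val] - pred)^2)
    }
  }
  scores <- stats::setNames(score_sum / n_models, canon)[sources]
  list(scores = scores, val_mse = val_sum / n_models)
}

#' Infer a gene-gene interaction score matrix
#'
#' The main fitting function. Each gene in turn is taken as the output node
#' of a 3-layer backpropagation perceptron whose inputs are all remaining
#' genes; the networks are trained under Monte-Carlo cross-validation (see
#' [infer_single_target()]) and the trained connection weights are averaged
#' into a G x G matrix of signed interaction scores, entry (source, target)
#' giving the influence of the source gene on the target gene. The diagonal
#' is undefined and kept masked (`NA`).
#'
#' Unscaled input is min-max scaled per gene first (the sigmoid output node
#' requires targets in `[0, 1]`). The whole procedure is a deterministic
#' function of the data and `config`, including `config$rng_seed`.
#'
#' @param x An [expr_matrix()] or numeric samples-by-genes matrix with at
#'   least 3 genes.
#' @param config An [anni_config()].
#' @param targets Optional subset of genes to use as outputs (columns of
#'   the score matrix); defaults to all genes.
#' @param verbose Print per-target progress (default `FALSE`).
#' @return An object of class `anni`: a list with `scores` (G x G matrix,
#'   sources in rows, targets in columns, diagonal `NA`), `val_mse` (mean
#'   validation MSE per target), `gene_ids`, `config` and `call`. Use
#'   [coef()] to extract the score matrix, [pearson_filter()] to filter it
#'   and [strongest_edge_per_gene()] to simplify it to a network map.
#' @examples
#' \donttest{
#' sim <- simulate_expression(n_samples = 40, n_features = 6,
#'                            n_correlated = 3, n_predictive = 0, seed = 1)
#' cfg <- anni_config(n_reshuffles = 2, n_repeats = 1, epochs = 50,
#'                    rng_seed = 1)
#' fit <- anni(sim$expr, cfg)
#' summary(fit)
#' }
#' @export
anni <- function(x, config = anni_config(), targets = NULL, verbose = FALSE) {
  m <- as_expr_matrix(x)
  if (ncol(m) < 3L) stop("need at least 3 genes", call. = FALSE)
  if (!is_scaled(m)) m <- minmax_scale(m)
  genes <- colnames(m)
  if (is.null(targets)) targets <- genes
  if (!all(targets %in% genes))
    stop("unknown target gene(s): ",
         paste(setdiff(targets, genes), collapse = ", "), call. = FALSE)
  scores <- matrix(NA_real_, ncol(m), length(targets),
                   dimnames = list(genes, targets))
  val_mse <- stats::setNames(numeric(length(targets)), targets)
  t0 <- Sys.time()
  for (k in seq_along(targets)) {
    res <- infer_single_target(m, targets[k], config)
    scores[names(res$scores), k] <- res$scores
    val_mse[k] <- res$val_mse
    if (verbose)
      message(sprintf("[%d/%d] %s  val MSE %.4f  (%.1fs elapsed)",
                      k, length(targets), targets[k], res$val_mse,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  structure(list(scores = scores, val_mse = val_mse, gene_ids = genes,
                 config = config, filtered = FALSE, expression_r = NULL,
                 call = match.call()),
            class = "anni")
}

#' Assemble an interaction-score object from a precomputed matrix
#'
#' Wraps an existing sources-by-targets score matrix (for example one read
#' back from an export) in the same class returned by [anni()], masking the
#' diagonal.
#'
#' @param scores Square numeric matrix with identical row and column gene
#'   identifiers.
#' @param config An [anni_config()] (metadata only).
#' @return An `anni` object.
#' @export
as_anni <- function(scores, config = anni_config()) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)))
    rownames(scores) <- colnames(scores) <- paste0("G", seq_len(nrow(scores)))
  stopifnot(nrow(scores) == ncol(scores),
            identical(rownames(scores), colnames(scores)))
  diag(scores) <- NA_real_
  structure(list(scores = scores, val_mse = NULL,
                 gene_ids = rownames(scores), config = config,
                 filtered = FALSE, expression_r = NULL,
                 call = match.call()),
            class = "anni")
}

#' Filter interactions by expression correlation
#'
#' Removes the least significant interaction scores: an entry
#' (source, target) is retained only when the absolute Pearson correlation
#' between the two genes' expression profiles reaches `cutoff`. Removed
#' entries are masked (`NA`); the pairwise expression correlations are
#' stored alongside so the retained edges carry their correlation sign.
#'
#' @param object An `anni` fit.
#' @param m The expression matrix the fit was computed from (scaled or
#'   not; correlation is scale-invariant under min-max scaling).
#' @param cutoff Absolute-correlation cutoff in `[0, 1]`
#'   (default `object$config$pearson_cutoff`, 0.7).
#' @return The `anni` object with masked scores, `expression_r` matrix and
#'   `filtered = TRUE`.
#' @export
pearson_filter <- function(object, m, cutoff = object$config$pearson_cutoff) {
  stopifnot(inherits(object, "anni"))
  m <- as_expr_matrix(m)
  if (!all(object$gene_ids %in% colnames(m)))
    stop("fit and expression matrix do not share gene identifiers",
         call. = FALSE)
  r <- stats::cor(unclass(m)[, object$gene_ids, drop = FALSE])
  keep <- abs(r) >= cutoff & !is.na(r)
  diag(keep) <- FALSE
  object$scores[!keep[object$gene_ids, colnames(object$scores)]] <- NA_real_
  object$expression_r <- r
  object$filtered <- TRUE
  object$cutoff <- cutoff
  object
}

#' @export
print.anni <- function(x, ...) {
  G <- length(x$gene_ids)
  defined <- sum(!is.na(x$scores))
  cat(sprintf("gene-gene interaction scores: %d genes, %d defined entries%s\n",
              G, defined,
              if (x$filtered) sprintf(" (filtered at |r| >= %g)", x$cutoff)
              else ""))
  if (!is.null(x$val_mse))
    cat(sprintf("  mean validation MSE %.4f (range %.4f-%.4f)\n",
                mean(x$val_mse), min(x$val_mse), max(x$val_mse)))
  invisible(x)
}

#' @export
summary.anni <- function(object, n_top = 5L, ...) {
  s <- object$scores
  idx <- which(!is.na(s), arr.ind = TRUE)
  ord <- order(-abs(s[idx]))[seq_len(min(n_top, nrow(idx)))]
  top <- data.frame(source = rownames(s)[idx[ord, 1L]],
                    target = colnames(s)[idx[ord, 2L]],
                    score = s[idx[ord, , drop = FALSE]])
  out <- list(n_genes = length(object$gene_ids),
              n_defined = nrow(idx),
              score_range = range(s[idx]),
              mean_val_mse = if (is.null(object$val_mse)) NA_real_
                             else mean(object$val_mse),
              top = top, filtered = object$filtered)
  class(out) <- "summary.anni"
  out
}

#' @export
print.summary.anni <- function(x, ...) {
  cat(sprintf("%d genes, %d defined interaction entries%s\n", x$n_genes,
              x$n_defined, if (x$filtered) " (filtered)" else ""))
  cat(sprintf("score range [%.4f, %.4f]; mean validation MSE %.4f\n",
              x$score_range[1], x$score_range[2], x$mean_val_mse))
  cat("strongest interactions:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.anni <- function(object, ...) object$scores

#' Heatmap of the interaction-score matrix
#'
#' @param x An `anni` fit.
#' @param ... Passed to [graphics::image()].
#' @export
plot.anni <- function(x, ...) {
  s <- x$scores
  s[is.na(s)] <- 0
  lim <- max(abs(s))
  graphics::image(seq_len(nrow(s)), seq_len(ncol(s)), s,
                  zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(51, "Blue-Red 3"),
                  xlab = "source gene", ylab = "target gene",
                  main = "interaction scores", ...)
  invisible(x)
}

#' Export interaction scores as delimited text
#'
#' `write_scores` writes the dense genes-by-genes matrix (masked entries
#' empty); `write_scores_long` writes one row per ordered pair with the
#' score, the expression correlation (if the fit was filtered) and a kept
#' flag.
#'
#' @param object An `anni` fit.
#' @param path Output path.
#' @export
write_scores <- function(object, path) {
  utils::write.table(format_full(object$scores), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

format_full <- function(m) {
  out <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
  out[!is.na(m)] <- sprintf("%.17g", m[!is.na(m)])
  out
}

#' @rdname write_scores
#' @export
write_scores_long <- function(object, path) {
  s <- object$scores
  pairs <- expand.grid(source = rownames(s), target = colnames(s),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs$score <- s[cbind(pairs$source, pairs$target)]
  pairs$expression_r <- if (is.null(object$expression_r)) NA_real_
                        else object$expression_r[cbind(pairs$source,
                                                       pairs$target)]
  pairs$kept <- !is.na(pairs$score)
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
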