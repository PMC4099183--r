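#' Simulate expression data with a planted correlated block
#'
#' Generates a samples-by-features Gaussian expression matrix carrying a
#' known correlation structure, for benchmarking interaction inference:
#'
#' * a block of `n_correlated` features shares a latent factor drawn once
#'   per sample, with loadings calibrated so the population correlation
#'   between any two block features has magnitude `within_block_r`;
#'   loadings alternate in sign, so roughly half the block pairs are
#'   negatively correlated;
#' * the first `n_predictive` block features additionally carry a
#'   class-mean shift of `class_shift` standardized units between two
#'   balanced classes (part of their shared variance is routed through the
#'   class indicator, keeping the within-block correlation at its nominal
#'   value);
#' * all remaining features are independent Gaussian noise with standard
#'   deviation `noise_sd`.
#'
#' The defaults emulate a two-class, 100-sample panel of 100 pre-selected
#' features of which 32 are highly correlated (`|r| = 0.9`) and 29 also
#' separate the classes. Optionally a large feature pool can be generated
#' first and the panel selected from it by class-difference t-statistic
#' (`n_pool`), emulating an upstream feature-selection step.
#'
#' @param n_samples Number of samples (default 100; classes are balanced).
#' @param n_features Number of features in the emitted panel (default 100).
#' @param n_correlated Size of the correlated block (default 32).
#' @param within_block_r Population correlation magnitude inside the block,
#'   in `(0, 1)` (default 0.9).
#' @param n_predictive Number of block features that also carry the class
#'   shift (default 29).
#' @param class_shift Difference between class means in standardized units
#'   (default 1).
#' @param noise_sd Noise standard deviation (default 1).
#' @param n_pool Optional pool size (e.g. 25000); when given, the pool is
#'   generated with the block embedded and the `n_features` panel is
#'   selected by largest absolute two-sample t-statistic.
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#' @return A list with `expr` (an unscaled [expr_matrix()] with class
#'   labels attached) and `truth`, a list holding `actual_r` (the
#'   population feature-feature correlation matrix implied by the
#'   generator), `correlated_set`, `predictive_set` and `class_labels`.
#' @examples
#' sim <- simulate_expression(seed = 1)
#' dim(sim$expr)                       # 100 x 100
#' sim$truth$actual_r[1, 2]            # +/- 0.9
#' @export
simulate_expression <- function(n_samples = 100L, n_features = 100L,
                                n_correlated = 32L, within_block_r = 0.9,
                                n_predictive = 29L, class_shift = 1,
                                noise_sd = 1, n_pool = NULL, seed = 1L) {
  if (within_block_r >= 1 || within_block_r <= 0)
    stop("within_block_r must lie strictly between 0 and 1", call. = FALSE)
  stopifnot(n_correlated <= n_features, n_predictive <= n_correlated,
            n_samples >= 2L, noise_sd > 0)
  n_total <- if (is.null(n_pool)) n_features else as.integer(n_pool)
  if (n_total < n_features) stop("n_pool must be >= n_features", call. = FALSE)

  # shared variance tau^2 gives corr tau^2 / (tau^2 + sigma^2) = r;
  # predictive features route part of tau^2 through the class indicator
  sigma2 <- noise_sd^2
  tau2 <- within_block_r / (1 - within_block_r) * sigma2
  b <- numeric(n_correlated)
  if (n_predictive > 0L) b[seq_len(n_predictive)] <- class_shift / 2
  if (any(tau2 <= b^2))
    stop("class_shift too large for the requested within_block_r",
         call. = FALSE)
  lam <- sqrt(tau2 - b^2)
  sgn <- rep_len(c(1, -1), n_correlated)

  n1 <- ceiling(n_samples / 2)
  labels <- rep(c("A", "B"), c(n1, n_samples - n1))
  u <- ifelse(labels == "A", 1, -1)

  ids <- sprintf("F%0*d", nchar(n_total), seq_len(n_total))
  vals <- with_seed(seed, {
    v <- matrix(rnorm(n_samples * n_total, sd = noise_sd), n_samples, n_total)
    z <- rnorm(n_samples)
    for (j in seq_len(n_correlated))
      v[, j] <- v[, j] + sgn[j] * (lam[j] * z + b[j] * u)
    v
  })
  colnames(vals) <- ids

  if (!is.null(n_pool)) {
    tstat <- vapply(seq_len(n_total), function(j) {
      x1 <- vals[u > 0, j]; x2 <- vals[u < 0, j]
      (mean(x1) - mean(x2)) /
        sqrt(var(x1) / length(x1) + var(x2) / length(x2))
    }, 0)
    sel <- sort(order(-abs(tstat))[seq_len(n_features)])
    vals <- vals[, sel, drop = FALSE]
    keep_corr <- which(sel <= n_correlated)
    corr_pos <- sel[keep_corr]
  } else {
    corr_pos <- seq_len(n_correlated)
  }

  # population correlations implied by the construction
  total_var <- tau2 + sigma2
  G <- ncol(vals)
  actual_r <- diag(G)
  dimnames(actual_r) <- list(colnames(vals), colnames(vals))
  if (length(corr_pos) >= 2L) {
    in_panel <- match(sprintf("F%0*d", nchar(n_total), corr_pos),
                      colnames(vals))
    for (a in seq_along(in_panel)) {
      for (bb in seq_along(in_panel)) {
        if (a == bb) next
        ja <- corr_pos[a]; jb <- corr_pos[bb]
        actual_r[in_panel[a], in_panel[bb]] <-
          sgn[ja] * sgn[jb] * (lam[ja] * lam[jb] + b[ja] * b[jb]) / total_var
      }
    }
  }
  corr_ids <- colnames(vals)[match(sprintf("F%0*d", nchar(n_total), corr_pos),
                                   colnames(vals))]
  pred_ids <- corr_ids[corr_pos <= n_predictive]

  expr <- expr_matrix(vals, class_labels = labels)
  list(expr = expr,
       truth = list(actual_r = actual_r,
                    correlated_set = corr_ids,
                    predictive_set = pred_ids,
                    class_labels = labels))
}

#' Evaluate inferred scores against planted truth
#'
#' Computes the three benchmark metrics over unordered feature pairs
#' (directed scores are averaged per pair):
#'
#' * `pearson_coefficient` — Pearson correlation between the predicted
#'   interaction scores and the actual (population) pairwise correlations;
#' * `sign_accuracy_pct` — percentage of pairs whose predicted score sign
#'   matches the sign of the actual correlation (pairs with zero actual
#'   correlation, where the sign is undefined, are excluded);
#' * `tpr_pct` — percentage of truly correlated pairs
#'   (`|actual r| >= cutoff`) whose edges survive the expression-correlation
#'   filter at the same cutoff.
#'
#' @param object An `anni` fit (unfiltered; the filter is applied here).
#' @param truth The `truth` component of [simulate_expression()].
#' @param m The expression matrix the fit was computed from.
#' @param scope `"correlated_only"` restricts evaluation to pairs within
#'   the planted correlated block; `"all_features"` uses every pair.
#' @param cutoff Correlation cutoff defining both the filter and a "truly
#'   correlated" pair (default 0.7).
#' @return One-row data frame: `pearson_coefficient`, `sign_accuracy_pct`,
#'   `tpr_pct`, `n_features_evaluated`, `n_pairs`, `n_hidden`.
#' @export
evaluate_inference <- function(object, truth, m,
                               scope = c("correlated_only", "all_features"),
                               cutoff = 0.7) {
  stopifnot(inherits(object, "anni"))
  scope <- match.arg(scope)
  feats <- switch(scope,
                  correlated_only = intersect(truth$correlated_set,
                                              object$gene_ids),
                  all_features = object$gene_ids)
  if (length(feats) < 2L) stop("empty evaluation scope", call. = FALSE)
  if (!all(feats %in% rownames(truth$actual_r)))
    stop("truth and fit do not share feature keys", call. = FALSE)

  pairs <- which(upper.tri(diag(length(feats))), arr.ind = TRUE)
  i <- feats[pairs[, 1L]]; j <- feats[pairs[, 2L]]
  pred <- (object$scores[cbind(i, j)] + object$scores[cbind(j, i)]) / 2
  act <- truth$actual_r[cbind(i, j)]

  nonzero <- act != 0
  filt <- pearson_filter(object, m, cutoff = cutoff)
  kept <- !is.na(filt$scores[cbind(i, j)]) & !is.na(filt$scores[cbind(j, i)])
  true_pos <- abs(act) >= cutoff
  data.frame(
    pearson_coefficient = pearson_r(pred, act),
    sign_accuracy_pct = if (any(nonzero))
      100 * mean(sign(pred[nonzero]) == sign(act[nonzero])) else NA_real_,
    tpr_pct = if (any(true_pos)) 100 * mean(kept[true_pos]) else NA_real_,
    n_features_evaluated = length(feats),
    n_pairs = nrow(pairs),
    n_hidden = object$config$n_hidden
  )
}

#' Write a simulated dataset to delimited text
#'
#' Writes the expression table, a truth table of population pairwise
#' correlations (one row per unordered pair) and a per-sample label table.
#'
#' @param sim Result of [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(sim$expr, file.path(dir, "expression.tsv"))
  r <- sim$truth$actual_r
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  utils::write.table(
    data.frame(feature_a = rownames(r)[pairs[, 1L]],
               feature_b = colnames(r)[pairs[, 2L]],
               actual_r = sprintf("%.17g", r[pairs])),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample = rownames(sim$expr),
               class = sim$truth$class_labels),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
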