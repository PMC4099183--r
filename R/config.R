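#' Interaction-algorithm configuration
#'
#' Bundles every tunable parameter of the inference algorithm. The defaults
#' are the published operating point of the method: a 3-layer perceptron with
#' 2 hidden nodes trained by backpropagation for up to 300 epochs (learning
#' rate 0.1, momentum 0.5), early stopping at mean squared error below 0.01
#' or after a 100-epoch window without improvement, Monte-Carlo
#' cross-validation with 50 reshuffles of a 60:20:20 train/test/validation
#' split and 10 repeats per target gene, and a Pearson correlation cutoff of
#' 0.7 for edge filtering.
#'
#' @param n_hidden Number of hidden units (default 2).
#' @param epochs Maximum training epochs per model (default 300).
#' @param mse_threshold Early-stopping threshold on the monitored mean
#'   squared error (default 0.01).
#' @param mse_window Number of consecutive epochs without MSE improvement
#'   (beyond `improve_tol`) after which training stops (default 100).
#' @param momentum Momentum coefficient in `[0, 1)` applied to the previous
#'   weight update (default 0.5).
#' @param learning_rate Backpropagation learning rate (default 0.1).
#' @param sigmoid_slope Slope parameter of the logistic activation
#'   (default 1).
#' @param pearson_cutoff Absolute Pearson correlation below which candidate
#'   interactions are removed (default 0.7).
#' @param n_reshuffles Number of Monte-Carlo cross-validation reshuffles
#'   (default 50).
#' @param split_ratios Train/test/validation proportions; must sum to 1
#'   (default `c(0.6, 0.2, 0.2)`).
#' @param n_repeats Number of training repeats per reshuffle (default 10).
#' @param weight_init_range Interval from which initial weights are drawn
#'   uniformly (default `c(-1, 1)`).
#' @param improve_tol Minimum MSE decrease counted as an improvement by the
#'   stopping window (default 1e-6).
#' @param rng_seed Master seed; all per-target and per-model seeds are
#'   derived from it deterministically (default 1).
#'
#' @return An object of class `anni_config` (a validated list).
#' @examples
#' cfg <- anni_config(n_reshuffles = 5, n_repeats = 2)
#' cfg$n_hidden
#' @export
anni_config <- function(n_hidden = 2L,
                        epochs = 300L,
                        mse_threshold = 0.01,
                        mse_window = 100L,
                        momentum = 0.5,
                        learning_rate = 0.1,
                        sigmoid_slope = 1,
                        pearson_cutoff = 0.7,
                        n_reshuffles = 50L,
                        split_ratios = c(0.6, 0.2, 0.2),
                        n_repeats = 10L,
                        weight_init_range = c(-1, 1),
                        improve_tol = 1e-6,
                        rng_seed = 1L) {
  cfg <- list(
    n_hidden = as.integer(n_hidden),
    epochs = as.integer(epochs),
    mse_threshold = as.numeric(mse_threshold),
    mse_window = as.integer(mse_window),
    momentum = as.numeric(momentum),
    learning_rate = as.numeric(learning_rate),
    sigmoid_slope = as.numeric(sigmoid_slope),
    pearson_cutoff = as.numeric(pearson_cutoff),
    n_reshuffles = as.integer(n_reshuffles),
    split_ratios = as.numeric(split_ratios),
    n_repeats = as.integer(n_repeats),
    weight_init_range = as.numeric(weight_init_range),
    improve_tol = as.numeric(improve_tol),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "anni_config"
  validate_anni_config(cfg)
}

validate_anni_config <- function(cfg) {
  stopifnot(
    cfg$n_hidden >= 1L, cfg$epochs >= 1L, cfg$mse_threshold > 0,
    cfg$mse_window >= 1L,
    cfg$momentum >= 0, cfg$momentum < 1,
    cfg$learning_rate > 0, cfg$sigmoid_slope > 0,
    cfg$pearson_cutoff >= 0, cfg$pearson_cutoff <= 1,
    cfg$n_reshuffles >= 1L, cfg$n_repeats >= 1L,
    length(cfg$split_ratios) == 3L, all(cfg$split_ratios > 0),
    length(cfg$weight_init_range) == 2L,
    cfg$weight_init_range[1] < cfg$weight_init_range[2],
    cfg$improve_tol >= 0
  )
  if (abs(sum(cfg$split_ratios) - 1) > 1e-9)
    stop("split_ratios must sum to 1", call. = FALSE)
  cfg
}

#' Read a configuration file
#'
#' Reads a YAML (or plain `key: value`) file whose keys are the
#' [anni_config()] argument names; unspecified keys keep their defaults.
#'
#' @param path Path to the configuration file.
#' @return An `anni_config` object.
#' @export
read_anni_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(anni_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(anni_config, vals)
}

#' @export
print.anni_config <- function(x, ...) {
  cat("Interaction-algorithm configuration\n")
  cat(sprintf("  architecture     N-%d-1 (N = genes - 1)\n", x$n_hidden))
  cat(sprintf("  epochs           %d (MSE threshold %g, window %d)\n",
              x$epochs, x$mse_threshold, x$mse_window))
  cat(sprintf("  learning rate    %g   momentum %g   sigmoid slope %g\n",
              x$learning_rate, x$momentum, x$sigmoid_slope))
  cat(sprintf("  MCCV             %d reshuffles x %d repeats, split %s\n",
              x$n_reshuffles, x$n_repeats,
              paste(x$split_ratios, collapse = ":")))
  cat(sprintf("  Pearson cutoff   %g   seed %d\n", x$pearson_cutoff, x$rng_seed))
  invisible(x)
}
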