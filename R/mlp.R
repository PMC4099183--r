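#' Logistic activation
#'
#' `sigmoid(v, a)` returns `1 / (1 + exp(-a * v))`, the activation applied
#' at every hidden and output node; `a` is the slope parameter.
#'
#' @param v Local signal (any numeric).
#' @param a Positive slope parameter (default 1).
#' @return Values in `(0, 1)` (0 or 1 only in the floating-point limit).
#' @examples
#' sigmoid(0)      # 0.5
#' sigmoid(2)      # 0.8807971
#' @export
sigmoid <- function(v, a = 1) {
  stopifnot(a > 0)
  1 / (1 + exp(-a * v))
}

#' Construct a perceptron weight set
#'
#' A 3-layer perceptron with `n_inputs` input nodes, `n_hidden` hidden
#' nodes and a single output node. `w_ih` holds the input-to-hidden
#' weights with the trainable bias in row 1 (a constant input of 1);
#' `w_ho` holds the hidden-to-output weights with the bias first.
#'
#' @param w_ih `(n_inputs + 1) x n_hidden` numeric matrix.
#' @param w_ho Numeric vector of length `n_hidden + 1`.
#' @param slope Sigmoid slope parameter.
#' @return An object of class `mlp`.
#' @export
mlp <- function(w_ih, w_ho, slope = 1) {
  w_ih <- as.matrix(w_ih)
  w_ho <- as.numeric(w_ho)
  if (length(w_ho) != ncol(w_ih) + 1L)
    stop("w_ho must have one weight per hidden unit plus a bias", call. = FALSE)
  structure(list(w_ih = w_ih, w_ho = w_ho, slope = slope,
                 n_inputs = nrow(w_ih) - 1L, n_hidden = ncol(w_ih)),
            class = "mlp")
}

#' @export
print.mlp <- function(x, ...) {
  cat(sprintf("perceptron %d-%d-1 (sigmoid slope %g)\n",
              x$n_inputs, x$n_hidden, x$slope))
  invisible(x)
}

#' Forward pass through a perceptron
#'
#' Propagates one input pattern: each hidden activation is
#' `sigmoid(bias + sum_i w_ih[i, h] * x[i])` and the output is the sigmoid
#' of the weighted hidden activations.
#'
#' @param model An [mlp()] object.
#' @param x Numeric input vector of length `n_inputs`.
#' @return A list with `hidden` (activations) and `y` (the scalar output).
#' @export
mlp_forward <- function(model, x) {
  if (length(x) != model$n_inputs)
    stop("input length ", length(x), " does not match ", model$n_inputs,
         " inputs", call. = FALSE)
  z <- drop(crossprod(model$w_ih, c(1, x)))
  hidden <- sigmoid(z, model$slope)
  y <- sigmoid(sum(model$w_ho * c(1, hidden)), model$slope)
  list(hidden = hidden, y = y)
}

#' Predict many samples at once
#'
#' @param object An [mlp()] object.
#' @param newdata Numeric matrix, samples in rows.
#' @param ... Unused.
#' @return Numeric vector of outputs in `(0, 1)`.
#' @export
predict.mlp <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_inputs)
    stop("newdata must have ", object$n_inputs, " columns", call. = FALSE)
  h <- sigmoid(cbind(1, newdata) %*% object$w_ih, object$slope)
  drop(sigmoid(cbind(1, h) %*% object$w_ho, object$slope))
}

#' Sum-of-squares training error
#'
#' Returns `0.5 * sum((d - y)^2)` over sample patterns. The 1/2 factor is
#' the textbook convention that makes the backpropagated error terms clean
#' derivatives; the stopping rule uses the mean squared error
#' `sum((d - y)^2) / N` instead (see [train_mlp()]).
#'
#' @param y Network outputs.
#' @param d Target outputs (same length).
#' @return Nonnegative scalar; 0 exactly when `y == d`.
#' @export
sse_error <- function(y, d) {
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (length(y) != length(d)) stop("length mismatch", call. = FALSE)
  0.5 * sum((d - y)^2)
}

#' Fresh training state
#'
#' Holds the previous weight updates used by the momentum term (all zero
#' before the first update), the epoch counter, and the per-epoch MSE trace.
#'
#' @param model An [mlp()] object.
#' @return An object of class `mlp_state`.
#' @export
mlp_state <- function(model) {
  structure(list(prev_ih = model$w_ih * 0,
                 prev_ho = model$w_ho * 0,
                 epoch = 0L, mse_trace = numeric(0)),
            class = "mlp_state")
}

#' One online backpropagation update
#'
#' Applies a single per-sample weight update with momentum:
#' `dw(T) = eta * delta * input + alpha * dw(T-1)`, where `delta` is the
#' standard backpropagated error term for sigmoid units — at the output
#' `(d - y) * a * y * (1 - y)`, at a hidden unit the output delta weighted
#' by the outgoing weight times the unit's own sigmoid derivative. If the
#' output matches the target exactly, no adjustment is made for this
#' pattern.
#'
#' @param model An [mlp()] object.
#' @param state An [mlp_state()] object congruent with `model`.
#' @param x Input pattern (length `n_inputs`, values in `[0, 1]`).
#' @param d Scalar target in `[0, 1]`.
#' @param config An [anni_config()] supplying `learning_rate` and
#'   `momentum`.
#' @return List with updated `model` and `state`.
#' @export
backprop_step <- function(model, state, x, d, config = anni_config()) {
  fwd <- mlp_forward(model, x)
  y <- fwd$y
  if (y == d) return(list(model = model, state = state))
  a <- model$slope
  eta <- config$learning_rate
  alpha <- config$momentum
  delta_o <- (d - y) * a * y * (1 - y)
  delta_h <- delta_o * model$w_ho[-1L] * a * fwd$hidden * (1 - fwd$hidden)
  dw_ho <- eta * delta_o * c(1, fwd$hidden) + alpha * state$prev_ho
  dw_ih <- eta * outer(c(1, x), delta_h) + alpha * state$prev_ih
  model$w_ho <- model$w_ho + dw_ho
  model$w_ih <- model$w_ih + dw_ih
  state$prev_ho <- dw_ho
  state$prev_ih <- dw_ih
  list(model = model, state = state)
}

#' Train a perceptron with online backpropagation
#'
#' Initializes all weights uniformly in `weight_init_range` from `seed`,
#' then runs up to `config$epochs` epochs of per-sample updates in a
#' seed-shuffled order redrawn each epoch. After each epoch the MSE on the
#' monitor set (the training data itself unless a separate monitor set is
#' supplied, as Monte-Carlo cross-validation does with its test partition)
#' is recorded; training stops early once that MSE falls below
#' `mse_threshold`, or when it has failed to improve by more than
#' `improve_tol` over the last `mse_window` epochs.
#'
#' @param X Scaled input matrix, samples in rows.
#' @param d Target vector in `[0, 1]`, one value per row of `X`.
#' @param config An [anni_config()].
#' @param seed Integer seed for weight initialization and sample order.
#' @param monitor_X,monitor_d Optional held-out set monitored for early
#'   stopping.
#' @return List with `model` (an [mlp()]), `mse_trace` (monitored MSE per
#'   completed epoch) and `epochs_run`.
#' @export
train_mlp <- function(X, d, config = anni_config(), seed = config$rng_seed,
                      monitor_X = NULL, monitor_d = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(d) != nrow(X)) stop("length of d must match rows of X", call. = FALSE)
  if (is.null(monitor_X)) {
    monitor_X <- X
    monitor_d <- d
  }
  monitor_X <- as.matrix(monitor_X)
  fit <- cpp_train_mlp(X, as.numeric(d), monitor_X, as.numeric(monitor_d),
                       config$n_hidden, config$epochs,
                       config$learning_rate, config$momentum,
                       config$sigmoid_slope,
                       config$mse_threshold, config$mse_window,
                       config$improve_tol,
                       config$weight_init_range[1], config$weight_init_range[2],
                       as.numeric(seed))
  list(model = mlp(fit$w_ih, fit$w_ho, slope = config$sigmoid_slope),
       mse_trace = fit$mse_trace, epochs_run = fit$epochs_run)
}

#' Connection-weight influence scores
#'
#' Reads one signed influence score per input off a trained model: the sum
#' over hidden units of the input-to-hidden weight times the corresponding
#' hidden-to-output weight (bias weights excluded). A positive score marks
#' a stimulatory influence of that input on the output, a negative score an
#' inhibitory one.
#'
#' @param model A trained [mlp()] object.
#' @return Numeric vector of length `n_inputs`.
#' @examples
#' m <- mlp(w_ih = rbind(0, c(1, -1)), w_ho = c(0, 0.5, 0.5))
#' influence_scores(m)   # 1*0.5 + (-1)*0.5 = 0
#' @export
influence_scores <- function(model) {
  drop(model$w_ih[-1L, , drop = FALSE] %*% model$w_ho[-1L])
}

#' Write / read a plain-text weight dump
#'
#' One weight per line with a header giving the architecture, for
#' inspection and exact round-tripping of trained models.
#'
#' @param model An [mlp()] object.
#' @param path File path.
#' @return `read_mlp` returns the reconstructed [mlp()].
#' @export
write_mlp <- function(model, path) {
  writeLines(c(sprintf("# mlp %d %d %.17g", model$n_inputs, model$n_hidden,
                       model$slope),
               sprintf("%.17g", c(model$w_ih, model$w_ho))), path)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# mlp ", "", lines[1L]), " ")[[1L]]
  ni <- as.integer(hdr[1L]); nh <- as.integer(hdr[2L])
  w <- as.numeric(lines[-1L])
  mlp(matrix(w[seq_len((ni + 1L) * nh)], ni + 1L, nh),
      w[-seq_len((ni + 1L) * nh)], slope = as.numeric(hdr[3L]))
}
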