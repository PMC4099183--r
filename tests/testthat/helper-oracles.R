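# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# central-difference gradient of the half-squared error of a 3-layer
# sigmoid net with respect to every weight
fd_gradient <- function(model, x, d, h = 1e-6) {
  loss <- function(m) {
    y <- mlp_forward(m, x)$y
    0.5 * (d - y)^2
  }
  g_ih <- model$w_ih * 0
  for (k in seq_along(model$w_ih)) {
    up <- model; up$w_ih[k] <- up$w_ih[k] + h
    dn <- model; dn$w_ih[k] <- dn$w_ih[k] - h
    g_ih[k] <- (loss(up) - loss(dn)) / (2 * h)
  }
  g_ho <- model$w_ho * 0
  for (k in seq_along(model$w_ho)) {
    up <- model; up$w_ho[k] <- up$w_ho[k] + h
    dn <- model; dn$w_ho[k] <- dn$w_ho[k] - h
    g_ho[k] <- (loss(up) - loss(dn)) / (2 * h)
  }
  list(w_ih = g_ih, w_ho = g_ho)
}

# random small perceptron
random_mlp <- function(n_inputs, n_hidden, slope = 1) {
  mlp(matrix(runif((n_inputs + 1) * n_hidden, -1, 1), n_inputs + 1, n_hidden),
      runif(n_hidden + 1, -1, 1), slope = slope)
}

# hand-rolled Benjamini-Hochberg step-up: sort, scale by m/i, cumulative
# minimum from the largest, cap at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# targets realizable by a planted 1-hidden-unit net (for learnability tests)
planted_target <- function(X, w = NULL, seed = 1) {
  if (is.null(w)) w <- with_seed2(seed, runif(ncol(X) + 1, -2, 2))
  h <- 1 / (1 + exp(-(w[1] + X %*% w[-1])))
  drop(1 / (1 + exp(-(0.5 + 2 * h))))
}

with_seed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
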