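test_that("cross-validation splits have floor sizes with remainder to training", {
  p <- mccv_split(100, seed = 1)
  expect_equal(lengths(p), c(train = 60L, test = 20L, val = 20L))
  p <- mccv_split(10, seed = 1)
  expect_equal(lengths(p), c(train = 6L, test = 2L, val = 2L))
  p <- mccv_split(88, seed = 1)
  expect_equal(lengths(p), c(train = 54L, test = 17L, val = 17L))
  expect_error(mccv_split(4), "at least 5")
  expect_error(mccv_split(6, c(0.9, 0.05, 0.05)), "empty")
  expect_error(mccv_split(10, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("splits are disjoint, cover all samples, and depend on the seed", {
  for (seed in 1:50) {
    p <- mccv_split(33, seed = seed)
    all_idx <- c(p$train, p$test, p$val)
    expect_identical(sort(all_idx), 1:33)   # disjoint and exhaustive
  }
  expect_identical(mccv_split(33, seed = 5), mccv_split(33, seed = 5))
  expect_false(identical(mccv_split(33, seed = 5), mccv_split(33, seed = 6)))
})

test_that("pearson_r matches the product-moment formula and flags degeneracy", {
  x <- c(1, 2, 4, 3, 5)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(9)
  a <- rnorm(30); b <- rnorm(30)
  byhand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), byhand)
  expect_true(is.na(pearson_r(rep(1, 5), rnorm(5))))
  expect_error(pearson_r(1:3, 1:4), "mismatch")
})

test_that("influence scores sum weight products and track output sensitivity", {
  m <- mlp(w_ih = rbind(0, c(1, -1)), w_ho = c(0, 0.5, 0.5))
  expect_equal(influence_scores(m), 0)
  mpos <- mlp(w_ih = rbind(c(0.1, 0.2), c(0.3, 0.7)), w_ho = c(0.1, 0.4, 0.9))
  expect_equal(influence_scores(mpos), 0.3 * 0.4 + 0.7 * 0.9)
  expect_gt(influence_scores(mpos), 0)

  # sign agrees with the finite-difference sensitivity dy/dx at the centroid
  # for nets trained on monotone targets
  set.seed(10)
  for (i in 1:5) {
    X <- matrix(runif(60 * 2), 60, 2)
    up <- sample(c(1, -1), 1)
    d <- sigmoid(up * (2 * X[, 1] - 1))          # monotone in x1 only
    fit <- train_mlp(X, d, anni_config(epochs = 200), seed = i)
    cen <- colMeans(X)
    eps <- 1e-4
    dy <- predict(fit$model, rbind(cen + c(eps, 0))) -
      predict(fit$model, rbind(cen - c(eps, 0)))
    sc <- influence_scores(fit$model)
    expect_equal(sign(sc[1]), sign(dy))
  }
})

test_that("single-target inference averages over partitions and repeats", {
  sim <- simulate_expression(n_samples = 30, n_features = 5,
                             n_correlated = 2, n_predictive = 0, seed = 21)
  m <- minmax_scale(sim$expr)
  cfg <- anni_config(n_reshuffles = 1, n_repeats = 1, epochs = 30,
                     rng_seed = 77)
  res <- infer_single_target(m, "F2", cfg)
  expect_named(res$scores, c("F1", "F3", "F4", "F5"))

  # with one reshuffle and one repeat the result is the single model's scores
  tseed <- anni:::target_seed(77, "F2")
  part <- mccv_split(30, cfg$split_ratios, seed = anni:::derive_seed(tseed, 1L, 0L))
  canon <- sort(c("F1", "F3", "F4", "F5"), method = "radix")
  X <- unclass(m)[, canon]
  d <- unclass(m)[, "F2"]
  fit <- train_mlp(X[part$train, ], d[part$train], cfg,
                   seed = anni:::derive_seed(tseed, 1L, 1L),
                   monitor_X = X[part$test, ], monitor_d = d[part$test])
  expect_equal(res$scores[canon], setNames(influence_scores(fit$model), canon))
  expect_equal(res$val_mse,
               mean((d[part$val] - predict(fit$model, X[part$val, ]))^2))

  expect_error(infer_single_target(m, "nope", cfg), "unknown target")
  expect_error(infer_single_target(sim$expr, "F2", cfg), "scaled")
})

test_that("inference is invariant to gene column order and deterministic", {
  sim <- simulate_expression(n_samples = 24, n_features = 5,
                             n_correlated = 3, n_predictive = 0, seed = 31)
  m <- minmax_scale(sim$expr)
  cfg <- anni_config(n_reshuffles = 2, n_repeats = 2, epochs = 30,
                     rng_seed = 13)
  f1 <- anni(m, cfg)
  f2 <- anni(m, cfg)
  expect_identical(f1$scores, f2$scores)

  perm <- c(3, 1, 5, 2, 4)
  mp <- expr_matrix(unclass(m)[, perm], scaled = TRUE)
  fp <- anni(mp, cfg)
  expect_equal(fp$scores[rownames(f1$scores), colnames(f1$scores)],
               f1$scores)
})

test_that("a G-gene panel yields G*(G-1) defined entries", {
  sim <- simulate_expression(n_samples = 20, n_features = 4,
                             n_correlated = 0, n_predictive = 0, seed = 41)
  cfg <- anni_config(n_reshuffles = 1, n_repeats = 1, epochs = 5,
                     rng_seed = 3)
  fit <- anni(sim$expr, cfg)   # auto-scales
  expect_equal(sum(!is.na(fit$scores)), 4 * 3)
  expect_true(all(is.na(diag(fit$scores))))
  expect_equal(length(fit$val_mse), 4L)
})

test_that("the correlation filter masks weakly correlated pairs only", {
  sim <- simulate_expression(n_samples = 50, n_features = 6,
                             n_correlated = 2, n_predictive = 0,
                             within_block_r = 0.95, seed = 51)
  cfg <- anni_config(n_reshuffles = 1, n_repeats = 1, epochs = 10, rng_seed = 1)
  fit <- anni(sim$expr, cfg)

  # cutoff 0 removes nothing
  f0 <- pearson_filter(fit, sim$expr, cutoff = 0)
  expect_equal(sum(!is.na(f0$scores)), 30)

  # two strongly correlated genes keep both directed entries
  f7 <- pearson_filter(fit, sim$expr, cutoff = 0.7)
  expect_false(is.na(f7$scores["F1", "F2"]))
  expect_false(is.na(f7$scores["F2", "F1"]))
  expect_true(f7$filtered)
  # sign of the recorded expression correlation matches the planted truth
  expect_equal(sign(f7$expression_r["F1", "F2"]),
               sign(sim$truth$actual_r["F1", "F2"]))
})

test_that("score exports round-trip and mask the diagonal", {
  sim <- simulate_expression(n_samples = 20, n_features = 4,
                             n_correlated = 0, seed = 61, n_predictive = 0)
  cfg <- anni_config(n_reshuffles = 1, n_repeats = 1, epochs = 5, rng_seed = 2)
  fit <- anni(sim$expr, cfg)
  dense <- withr::local_tempfile(fileext = ".tsv")
  write_scores(fit, dense)
  back <- as.matrix(utils::read.delim(dense, row.names = 1))
  expect_true(all(is.na(diag(back))))
  expect_equal(unname(back[1, 2]), fit$scores[1, 2])
  long <- withr::local_tempfile(fileext = ".tsv")
  write_scores_long(fit, long)
  tab <- utils::read.delim(long)
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$kept))
})
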