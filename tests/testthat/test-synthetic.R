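test_that("planted correlations converge to their population values", {
  sim <- simulate_expression(n_samples = 10000, n_features = 12,
                             n_correlated = 6, n_predictive = 3,
                             within_block_r = 0.9, seed = 81)
  emp <- cor(unclass(sim$expr))
  blk <- sim$truth$correlated_set
  for (a in seq_along(blk)) {
    for (b in seq_along(blk)) {
      if (a >= b) next
      expect_gt(abs(emp[blk[a], blk[b]]), 0.88)
      expect_lt(abs(emp[blk[a], blk[b]]), 0.92)
      # empirical value close to the declared truth, with its sign
      expect_equal(emp[blk[a], blk[b]],
                   sim$truth$actual_r[blk[a], blk[b]], tolerance = 0.03)
    }
  }
  # alternating loadings plant genuine negative correlations
  expect_true(any(sim$truth$actual_r[blk, blk] < -0.8))
  # off-block features stay uncorrelated
  noise <- setdiff(colnames(sim$expr), blk)
  expect_lt(max(abs(emp[noise, noise][upper.tri(diag(length(noise)))])), 0.1)
})

test_that("the truth table is symmetric with unit diagonal", {
  sim <- simulate_expression(n_samples = 10, n_features = 20,
                             n_correlated = 5, n_predictive = 2, seed = 82)
  r <- sim$truth$actual_r
  expect_equal(r, t(r))
  expect_equal(diag(r), rep(1, 20), ignore_attr = TRUE)
  expect_length(sim$truth$correlated_set, 5L)
  expect_length(sim$truth$predictive_set, 2L)
  expect_true(all(sim$truth$predictive_set %in% sim$truth$correlated_set))
})

test_that("predictive features separate the classes by the configured shift", {
  sim <- simulate_expression(n_samples = 5000, n_features = 10,
                             n_correlated = 4, n_predictive = 2,
                             class_shift = 1, seed = 83)
  v <- unclass(sim$expr)
  lab <- sim$truth$class_labels
  for (f in sim$truth$predictive_set) {
    gap <- abs(mean(v[lab == "A", f]) - mean(v[lab == "B", f]))
    expect_equal(gap, 1, tolerance = 0.15)
  }
  nonpred <- setdiff(sim$truth$correlated_set, sim$truth$predictive_set)
  for (f in nonpred) {
    gap <- abs(mean(v[lab == "A", f]) - mean(v[lab == "B", f]))
    expect_lt(gap, 0.3)
  }
})

test_that("generation is deterministic and validates its spec", {
  s1 <- simulate_expression(n_samples = 15, n_features = 8, seed = 84,
                            n_correlated = 3, n_predictive = 1)
  s2 <- simulate_expression(n_samples = 15, n_features = 8, seed = 84,
                            n_correlated = 3, n_predictive = 1)
  expect_identical(unclass(s1$expr)[, ], unclass(s2$expr)[, ])
  expect_error(simulate_expression(within_block_r = 1), "between 0 and 1")
  expect_error(simulate_expression(n_features = 5, n_correlated = 6))
  expect_error(simulate_expression(within_block_r = 0.05, class_shift = 3),
               "class_shift")
})

test_that("independent features show no spurious strong correlations", {
  sim <- simulate_expression(n_samples = 100, n_features = 30,
                             n_correlated = 0, n_predictive = 0, seed = 85)
  emp <- cor(unclass(sim$expr))
  expect_lt(max(abs(emp[upper.tri(emp)])), 0.5)
  expect_true(all(sim$truth$actual_r[upper.tri(emp)] == 0))
})

test_that("panel selection from a feature pool favours predictive features", {
  sim <- simulate_expression(n_samples = 100, n_features = 40,
                             n_correlated = 10, n_predictive = 8,
                             class_shift = 2, n_pool = 400, seed = 86)
  expect_equal(ncol(sim$expr), 40L)
  # class-shifted features should almost all survive selection
  expect_gte(length(sim$truth$predictive_set), 6L)
  expect_true(all(sim$truth$correlated_set %in% colnames(sim$expr)))
  # truth still matches the surviving block's empirical structure
  blk <- sim$truth$correlated_set
  if (length(blk) >= 2) {
    emp <- cor(unclass(sim$expr))
    expect_equal(sign(emp[blk[1], blk[2]]),
                 sign(sim$truth$actual_r[blk[1], blk[2]]))
  }
})

test_that("evaluation metrics match a brute-force pair enumeration", {
  sim <- simulate_expression(n_samples = 40, n_features = 10,
                             n_correlated = 4, n_predictive = 2, seed = 87)
  truth <- sim$truth
  # oracle predictor: scores equal to the actual correlations
  oracle <- truth$actual_r
  fit <- as_anni(oracle, anni_config())
  ev <- evaluate_inference(fit, truth, sim$expr, "correlated_only")
  expect_equal(ev$pearson_coefficient, 1)
  expect_equal(ev$sign_accuracy_pct, 100)
  # negated predictor inverts both
  evn <- evaluate_inference(as_anni(-oracle), truth, sim$expr,
                            "correlated_only")
  expect_equal(evn$pearson_coefficient, -1)
  expect_equal(evn$sign_accuracy_pct, 0)

  # random scores vs an exhaustive loop over pairs
  set.seed(88)
  s <- matrix(rnorm(100), 10, 10, dimnames = dimnames(oracle))
  fit <- as_anni(s)
  ev <- evaluate_inference(fit, truth, sim$expr, "all_features")
  feats <- colnames(oracle)
  emp <- cor(unclass(sim$expr))
  pred <- act <- keep <- c()
  for (a in 1:9) for (b in (a + 1):10) {
    pred <- c(pred, (s[a, b] + s[b, a]) / 2)
    act <- c(act, truth$actual_r[a, b])
    keep <- c(keep, abs(emp[a, b]) >= 0.7)
  }
  expect_equal(ev$pearson_coefficient, cor(pred, act))
  nz <- act != 0
  expect_equal(ev$sign_accuracy_pct, 100 * mean(sign(pred[nz]) == sign(act[nz])))
  tp <- abs(act) >= 0.7
  expect_equal(ev$tpr_pct, 100 * mean(keep[tp]))
  expect_equal(ev$n_pairs, 45)
  expect_no_error(evaluate_inference(fit, truth, sim$expr, "correlated_only",
                                     cutoff = 0.7))
})

test_that("simulated datasets round-trip through the text writers", {
  sim <- simulate_expression(n_samples = 12, n_features = 6,
                             n_correlated = 3, n_predictive = 1, seed = 89)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  m <- read_expression_table(file.path(dir, "expression.tsv"))
  expect_equal(unclass(m)[, ], unclass(sim$expr)[, ])
  truth <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), choose(6, 2))
  labs <- utils::read.delim(file.path(dir, "labels.tsv"))
  expect_identical(labs$class, sim$truth$class_labels)
})
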