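test_that("the split is stratified 80/20 and reproducible", {
  y <- setNames(rep(c(0, 1), each = 5), paste0("s", 1:10))
  sp <- make_split(y, seed = 3)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_true(all(c(0, 1) %in% y[sp$train]))
  expect_identical(make_split(y, seed = 3), sp)
  expect_false(identical(make_split(y, seed = 4)$test, sp$test))

  y2 <- setNames(rbinom(200, 1, 0.3), paste0("s", 1:200))
  sp2 <- make_split(y2, seed = 1)
  expect_lt(abs(mean(y2[sp2$train]) - mean(y2)), 1 / length(sp2$test))
})

test_that("a single-point grid is selected as-is", {
  d <- make_planted(n = 60, n_noise = 5, seed = 1)
  spec <- model_spec("random_forest",
                     tibble::tibble(num_trees = 50, max_depth = 3,
                                    min_node_size = 2))
  m <- tune_and_train(d$x, d$y, spec, cv_folds = 3, seed = 2)
  expect_equal(m$best_params$num_trees, 50)
  expect_equal(nrow(m$cv), 3)
})

test_that("linearly separable data reaches near-perfect CV MCC", {
  d <- make_planted(n = 120, n_noise = 10, noise_sd = 0.05, seed = 2)
  spec <- model_spec("random_forest",
                     tibble::tibble(num_trees = 100, max_depth = 0,
                                    min_node_size = 1))
  m <- tune_and_train(d$x, d$y, spec, cv_folds = 5, seed = 3)
  expect_gte(mean(m$cv$mcc), 0.95)
})

test_that("MCC matches hand-computed values and conventions", {
  expect_equal(mcc(10, 10, 0, 0), 1)
  expect_equal(mcc(10, 0, 10, 0), 0)   # zero-denominator convention
  expect_equal(mcc(0, 0, 0, 0), 0)
  expect_equal(mcc(50, 40, 10, 15), 0.5650, tolerance = 1e-3)
  expect_equal(mcc(0, 0, 10, 10), -1)  # perfectly wrong predictions
})

test_that("MCC equals the Pearson correlation of the binary vectors", {
  withr::with_seed(99, {
    for (i in 1:1000) {
      counts <- rmultinom(1, sample(8:60, 1), prob = runif(4, 0.05, 1))[, 1]
      tp <- counts[1]; tn <- counts[2]; fp <- counts[3]; fn <- counts[4]
      truth <- rep(c(1, 0, 0, 1), times = c(tp, tn, fp, fn))
      pred <- rep(c(1, 0, 1, 0), times = c(tp, tn, fp, fn))
      r <- suppressWarnings(stats::cor(pred, truth))
      m <- mcc(tp, tn, fp, fn)
      if (is.na(r)) {
        expect_equal(m, 0)
      } else {
        expect_equal(m, r, tolerance = 1e-12)
      }
    }
  })
})

test_that("AUC equals exhaustive pair counting and known examples", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- sample(6:50, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      s <- round(rnorm(n), 1)  # rounding forces ties
      expect_equal(roc_auc(s, y)$auc, auc_pair_oracle(s, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    y <- rbinom(80, 1, 0.5); y[1:2] <- c(0, 1)
    s <- rnorm(80) + y
  })
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-12)
})

test_that("random scores give chance-level AUC", {
  withr::with_seed(10, {
    y <- rbinom(4000, 1, 0.5)
    s <- rnorm(4000)
  })
  expect_lt(abs(roc_auc(s, y)$auc - 0.5), 0.03)
})

test_that("CV confidence intervals follow the t construction", {
  ci <- cv_confidence_interval(rep(0.8, 4))
  expect_equal(c(ci$mean, ci$lower, ci$upper), rep(0.8, 3))
  ci2 <- cv_confidence_interval(c(0.6, 0.8))
  expect_equal(ci2$mean, 0.7)
  expect_equal(ci2$upper - ci2$mean, ci2$mean - ci2$lower)
  ci3 <- cv_confidence_interval(c(0.7, 0.71, 0.72, 0.73, 0.74))
  expect_equal(ci3$mean, 0.72)
  expect_equal(ci3$lower, 0.700, tolerance = 1e-3)
  expect_equal(ci3$upper, 0.740, tolerance = 1e-3)
  expect_error(cv_confidence_interval(0.5),
               class = "metric_insufficient_data_error")
})

test_that("McNemar machinery matches hand computations", {
  y <- rep(0, 40)
  p <- rep(0, 40)
  same <- mcnemar_compare(p, p, y)
  expect_equal(same$p_value, 1)

  # b = 10 (only A right), c = 20 (only B right), plus 30 concordant
  y2 <- rep(0, 60)
  a <- c(rep(0, 10), rep(1, 20), rep(0, 30))
  b <- c(rep(1, 10), rep(0, 20), rep(0, 30))
  res <- mcnemar_compare(a, b, y2)
  expect_equal(res$statistic, 2.7)
  expect_equal(res$method, "continuity-corrected chi-squared")
  expect_equal(res$p_value, pchisq(2.7, 1, lower.tail = FALSE))

  # b = 1, c = 0: exact binomial path, two-sided p = 1
  y3 <- rep(0, 10)
  a3 <- c(0, rep(0, 9)); b3 <- c(1, rep(0, 9))
  res3 <- mcnemar_compare(a3, b3, y3)
  expect_equal(res3$method, "exact binomial")
  expect_equal(res3$p_value, 1)
})

test_that("test labels never leak into training", {
  d <- make_planted(n = 100, n_noise = 8, seed = 5)
  spec <- model_spec("random_forest",
                     tibble::tibble(num_trees = 60, max_depth = 0,
                                    min_node_size = 1))
  m <- tune_and_train(d$x[1:80, ], d$y[1:80], spec, cv_folds = 3, seed = 4)
  ev1 <- evaluate_model(m, d$x[81:100, ], d$y[81:100])
  ev2 <- evaluate_model(m, d$x[81:100, ],
                        withr::with_seed(1, sample(d$y[81:100])))
  expect_identical(ev1$predictions$prob, ev2$predictions$prob)
  expect_identical(m$cv, tune_and_train(d$x[1:80, ], d$y[1:80], spec,
                                        cv_folds = 3, seed = 4)$cv)
})

test_that("under label permutation test MCC is centred at zero", {
  withr::with_seed(12, {
    pred <- rbinom(60, 1, 0.5)
    truth <- rbinom(60, 1, 0.5)
    mccs <- vapply(1:100, function(i) mcc_labels(pred, sample(truth)), 0)
  })
  se <- sd(mccs) / sqrt(length(mccs))
  expect_lt(abs(mean(mccs)), 2 * se + 0.02)
})

test_that("the MLP learns a planted signal and is seed-reproducible", {
  d <- make_planted(n = 150, n_noise = 10, noise_sd = 0.3, seed = 13)
  m1 <- mlp_fit(d$x[1:120, ], d$y[1:120], hidden = c(16, 16), epochs = 60,
                seed = 2)
  m2 <- mlp_fit(d$x[1:120, ], d$y[1:120], hidden = c(16, 16), epochs = 60,
                seed = 2)
  expect_identical(m1$W, m2$W)
  p <- predict(m1, d$x[121:150, ])
  expect_gte(mcc_labels(as.integer(p >= 0.5), d$y[121:150]), 0.5)
})

test_that("two copies of the same dataset/model give identical rows and McNemar p = 1", {
  d <- make_planted(n = 100, n_noise = 12, seed = 14)
  beta <- t(d$x)
  rownames(beta) <- paste0("cg", seq_len(nrow(beta)))
  colnames(beta) <- paste0("s", seq_len(ncol(beta)))
  labels <- setNames(d$y, colnames(beta))
  split <- make_split(labels, seed = 6)
  ps <- probe_set("all", rownames(beta))
  spec <- model_spec("random_forest",
                     tibble::tibble(num_trees = 60, max_depth = 0,
                                    min_node_size = 1))
  cmp <- run_model_comparison(beta, labels,
                              list(copy1 = ps, copy2 = ps),
                              list(rf = spec), split, cv_folds = 3, seed = 8)
  r <- cmp$results
  expect_equal(r$mcc_test[1], r$mcc_test[2])
  expect_equal(r$acc_test[1], r$acc_test[2])
  expect_equal(cmp$mcnemar$p_value, 1)
})
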