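test_that("fixed-seed simulation is bitwise reproducible", {
  a <- simulate_cohort(tiny_config(seed = 1, n_samples = 200))
  b <- simulate_cohort(tiny_config(seed = 1, n_samples = 200))
  expect_identical(a, b)
  c2 <- simulate_cohort(tiny_config(seed = 2, n_samples = 200))
  expect_false(identical(a$beta, c2$beta))
})

test_that("null effect sizes give no beta difference between latent states", {
  co <- simulate_cohort(tiny_config(seed = 4, n_samples = 300, n_probes = 200,
                                    n_informative_probes = 40,
                                    effect_size_beta = 0,
                                    score_effect_size = 0))
  evading <- co$latent_state$state == "evading"
  inf <- co$truth$informative_probes
  v1 <- as.vector(co$beta[inf, evading])
  v0 <- as.vector(co$beta[inf, !evading])
  d <- mean(v1) - mean(v0)
  se <- sqrt(var(v1) / length(v1) + var(v0) / length(v0))
  expect_lt(abs(d), 3 * se)
})

test_that("beta values stay in [0, 1] across random configurations", {
  for (s in 1:5) {
    cfg <- withr::with_seed(s, tiny_config(
      seed = s,
      effect_size_beta = runif(1, 0, 0.7),
      beta_precision = runif(1, 2, 60),
      score_correlation = runif(1, -0.5, 0.9)))
    co <- simulate_cohort(cfg)
    expect_gte(min(co$beta), 0)
    expect_lte(max(co$beta), 1)
  }
})

test_that("GBM is depleted for the latent evading state", {
  co <- simulate_cohort(tiny_config(seed = 9, n_samples = 3000,
                                    gbm_fraction = 0.3, n_probes = 20,
                                    n_informative_probes = 5))
  tab <- table(co$clinical$grade, co$latent_state$state)
  frac <- prop.table(tab, 1)[, "evading"]
  expect_lt(frac[["GBM"]], frac[["LGG"]])
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_informative_probes = 50, n_probes = 10),
               class = "sim_config_error")
  expect_error(sim_config(effect_size_beta = 0.9),
               class = "sim_beta_param_error")
  expect_error(sim_config(censoring_rate = 1.2), class = "sim_config_error")
  expect_error(sim_config(score_correlation = 1), class = "sim_config_error")
})

test_that("write/read round trip preserves the cohort", {
  co <- simulate_cohort(tiny_config(seed = 1))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$beta, co$beta, tolerance = 1e-12)
  expect_equal(back$expression, co$expression, tolerance = 1e-12)
  expect_equal(as.data.frame(back$clinical), as.data.frame(co$clinical),
               tolerance = 1e-12)
  expect_identical(back$manifest$probe, co$manifest$probe)
  expect_identical(back$manifest$region, co$manifest$region)
  expect_identical(back$latent_state$state, co$latent_state$state)
})

test_that("reading a directory with a missing file fails distinctly", {
  co <- simulate_cohort(tiny_config(seed = 1))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  file.remove(file.path(dir, "clinical.csv"))
  expect_error(read_cohort(dir), class = "cohort_missing_file_error")
})

test_that("duplicate probe ids are rejected with a duplicate-id error", {
  co <- simulate_cohort(tiny_config(seed = 1))
  co$manifest$probe[2] <- co$manifest$probe[1]
  expect_error(validate_cohort(co), class = "cohort_duplicate_probe_error")
  expect_error(validate_cohort(co), regexp = co$manifest$probe[1])
})

test_that("a clinical table missing one sample names it in the error", {
  co <- simulate_cohort(tiny_config(seed = 1))
  dropped <- co$clinical$sample[3]
  co$clinical <- co$clinical[-3, ]
  err <- tryCatch(validate_cohort(co), error = function(e) e)
  expect_s3_class(err, "cohort_misaligned_error")
  expect_match(conditionMessage(err), dropped, fixed = TRUE)
})

test_that("out-of-range beta values are rejected", {
  co <- simulate_cohort(tiny_config(seed = 1))
  co$beta[1, 1] <- 1.5
  expect_error(validate_cohort(co), class = "cohort_beta_range_error")
})

test_that("larger methylation effect sizes give better classifiers on average", {
  spec <- model_spec("random_forest",
                     tibble::tibble(num_trees = 100, max_depth = 0,
                                    min_node_size = 1))
  mean_mcc <- vapply(c(0.02, 0.1, 0.3), function(eff) {
    mean(vapply(1:10, function(s) {
      co <- simulate_cohort(sim_config(
        n_samples = 150, n_probes = 100, n_informative_probes = 20,
        effect_size_beta = eff, seed = 5000 + s))
      y <- setNames(as.integer(co$latent_state$state == "evading"),
                    co$latent_state$sample)
      split <- make_split(y, seed = s)
      m <- tune_and_train(t(co$beta)[split$train, ], y[split$train], spec,
                          cv_folds = 3, seed = s)
      evaluate_model(m, t(co$beta)[split$test, ], y[split$test])$mcc_test
    }, 0))
  }, 0)
  expect_true(all(diff(mean_mcc) > 0))
})

test_that("log-rank between latent states holds its nominal level under no effect", {
  # state_hazard_ratio = 1: p-values should be uniform; check type-I error
  # at 0.05 stays inside the binomial band over repeated cohorts
  n_rep <- 500
  rejected <- vapply(seq_len(n_rep), function(s) {
    co <- simulate_cohort(sim_config(
      n_samples = 60, n_probes = 4, n_informative_probes = 0,
      state_hazard_ratio = 1, pfi_state_hazard_ratio = 1,
      censoring_rate = 0.2, seed = 10000 + s))
    dat <- tibble::tibble(time = co$clinical$os_time,
                          event = co$clinical$os_event,
                          group = as.integer(co$latent_state$state == "evading"))
    if (length(unique(dat$group)) < 2 || sum(dat$event) == 0) return(NA)
    log_rank(dat)$p_value < 0.05
  }, logical(1))
  rejected <- rejected[!is.na(rejected)]
  rate <- mean(rejected)
  band <- 3 * sqrt(0.05 * 0.95 / length(rejected))
  expect_lt(abs(rate - 0.05), band + 1e-9)
})
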