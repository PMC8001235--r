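test_that("product-limit estimates match hand computation", {
  # no censoring: survival drops 0.25 at each of 4 event times
  d <- tibble::tibble(time = 1:4, event = 1, group = "a")
  km <- kaplan_meier(d)
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))

  # times {1, 2+, 3, 4}: S(3) = (3/4) * (1/2) = 0.375
  d2 <- tibble::tibble(time = 1:4, event = c(1, 0, 1, 1), group = "a")
  km2 <- kaplan_meier(d2)
  expect_equal(km2$survival[km2$time == 3], 0.375)

  # all censored: flat at 1
  d3 <- tibble::tibble(time = 1:5, event = 0, group = "a")
  expect_true(all(kaplan_meier(d3)$survival == 1))
})

test_that("KM with no censoring equals the empirical survival function", {
  d <- make_survival(60, hr_group1 = 1, censor_rate = 0, seed = 3)
  d$group <- "all"
  km <- kaplan_meier(d)
  emp <- vapply(km$time, function(t) mean(d$time > t), 0)
  expect_equal(km$survival, emp, tolerance = 1e-12)
})

test_that("identical groups give a null log-rank statistic and HR 1", {
  base <- tibble::tibble(time = c(2, 4, 6, 8, 10), event = c(1, 1, 0, 1, 1))
  d <- dplyr::bind_rows(dplyr::mutate(base, group = 0),
                        dplyr::mutate(base, group = 1))
  lr <- log_rank(d)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  cx <- cox_univariate(d)
  expect_equal(cx$hr, 1, tolerance = 1e-8)
  expect_true(cx$ci_low <= 1 && cx$ci_high >= 1)
})

test_that("the log-rank statistic is invariant to monotone time transforms", {
  d <- make_survival(120, hr_group1 = 2, seed = 5)
  lr1 <- log_rank(d)
  d2 <- dplyr::mutate(d, time = exp(time / max(time) * 3))
  expect_equal(log_rank(d2)$statistic, lr1$statistic, tolerance = 1e-10)
})

test_that("strong separation gives a vanishing log-rank p-value", {
  d <- make_survival(500, hr_group1 = 5, seed = 6)
  expect_lt(log_rank(d)$p_value, 1e-6)
})

test_that("permuted group labels give uniform log-rank p-values", {
  d <- make_survival(80, hr_group1 = 3, seed = 7)
  ps <- withr::with_seed(8, vapply(1:200, function(i) {
    log_rank(dplyr::mutate(d, group = sample(group)))$p_value
  }, 0))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("the Cox null keeps its coverage and the effect is recovered", {
  covered_null <- vapply(1:20, function(s) {
    d <- make_survival(300, hr_group1 = 1, seed = 100 + s)
    cx <- cox_univariate(d)
    cx$ci_low <= 1 && cx$ci_high >= 1
  }, logical(1))
  expect_gte(sum(covered_null), 15)

  d <- make_survival(2000, hr_group1 = 2, seed = 9)
  cx <- cox_univariate(d)
  expect_lt(abs(cx$coef - log(2)) / log(2), 0.15)
})

test_that("complete separation raises a monotone-likelihood error", {
  d <- tibble::tibble(time = c(1, 2, 3, 10, 11, 12),
                      event = 1,
                      group = c(1, 1, 1, 0, 0, 0))
  expect_error(cox_univariate(d), class = "cox_monotone_error")
})

test_that("survival input validation is strict", {
  expect_error(log_rank(tibble::tibble(time = c(-1, 2), event = c(1, 1),
                                       group = c(0, 1))),
               class = "cohort_time_error")
  expect_error(cox_univariate(tibble::tibble(time = c(1, 2), event = c(0, 0),
                                             group = c(0, 1))),
               class = "survival_undefined_error")
})

test_that("a perfect linear relation gives correlation -1", {
  co <- simulate_cohort(tiny_config(seed = 2, n_samples = 30))
  beta <- co$beta[1:3, , drop = FALSE]
  expr <- rbind(g1 = -2 * beta[1, ] + 1,
                g2 = rnorm(30),
                g3 = rep(1, 30))
  colnames(expr) <- colnames(beta)
  man <- tibble::tibble(probe = rownames(beta),
                        genes = c("g1", "g2", "g3"),
                        region = "island")
  res <- cpg_expression_correlation(beta, expr, manifest = man)
  expect_equal(res$r[res$gene == "g1"], -1, tolerance = 1e-12)
  expect_lt(res$p_value[res$gene == "g1"], 1e-12)
  # constant expression row: missing with a zero-variance note, not 0
  expect_true(is.na(res$r[res$gene == "g3"]))
  expect_equal(unname(res$note[res$gene == "g3"]), "zero_variance")
})

test_that("independent pairs yield few BH-significant correlations", {
  n <- 50; n_pairs <- 500
  withr::with_seed(20, {
    beta <- matrix(runif(n_pairs * n), n_pairs, n,
                   dimnames = list(paste0("cg", 1:n_pairs),
                                   paste0("s", 1:n)))
    expr <- matrix(rnorm(n_pairs * n), n_pairs, n,
                   dimnames = list(paste0("g", 1:n_pairs),
                                   paste0("s", 1:n)))
  })
  man <- tibble::tibble(probe = rownames(beta), genes = rownames(expr),
                        region = "island")
  res <- cpg_expression_correlation(beta, expr, manifest = man)
  expect_lte(mean(res$p_adj < 0.05), 0.05)
})

test_that("EDISON survival validation recovers the generative direction", {
  co <- simulate_cohort(tiny_config(seed = 15, n_samples = 600,
                                    n_probes = 30,
                                    n_informative_probes = 5))
  lab <- label_cohort(co)
  sv <- edison_survival_validation(lab, co$clinical, "OS")
  expect_lt(sv$cox$hr, 1)                # positives live longer
  expect_s3_class(tidy(sv), "tbl_df")
  g <- glance(sv)
  expect_true(g$hr_ci_low <= g$hr && g$hr <= g$hr_ci_high)
  # PFS accepted as an alias of PFI
  sv2 <- edison_survival_validation(lab, co$clinical, "PFS")
  expect_equal(sv2$endpoint, "PFI")
})
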