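#' Configuration for shadow-feature (Boruta-style) selection
#'
#' @param max_iterations Maximum forest iterations per run.
#' @param alpha Two-sided binomial test level for confirm/reject decisions
#'   (Bonferroni-corrected over features and sequential looks).
#' @param n_trees Trees per random forest iteration. The modest default is
#'   deliberate: per-iteration importance noise keeps borderline
#'   chance-correlated features near the 1/2 hit-probability reference, which
#'   the family-wise error control of the binomial test relies on.
#' @param cv_folds Folds of the repeated cross-validation consensus scheme.
#' @param cv_repeats Repetitions of the scheme (scalable down).
#' @param consensus_fraction Fraction of runs in which a feature must be
#'   confirmed to enter the final set (0 = union of runs, 1 = intersection).
#' @param scheme `"cv"` runs one selection per cross-validation training
#'   split (`cv_repeats x cv_folds` runs); `"restart"` runs `cv_repeats`
#'   full-data restarts.
#' @param shadow_aggregate `"max"` (original algorithm) or `"percentile"`
#'   (90th percentile of shadow importances).
#' @param seed Integer seed controlling every run.
#' @return A `boruta_config` list.
#' @export
boruta_config <- function(max_iterations = 100, alpha = 0.05, n_trees = 50,
                          cv_folds = 10, cv_repeats = 100,
                          consensus_fraction = 0.5,
                          scheme = c("cv", "restart"),
                          shadow_aggregate = c("max", "percentile"),
                          seed = 1L) {
  if (alpha <= 0 || alpha >= 1) {
    abort_edison("`alpha` must lie in (0, 1).", "boruta_config_error")
  }
  if (cv_folds < 2) {
    abort_edison("`cv_folds` must be at least 2.", "boruta_config_error")
  }
  if (consensus_fraction < 0 || consensus_fraction > 1) {
    abort_edison("`consensus_fraction` must lie in [0, 1].",
                 "boruta_config_error")
  }
  structure(list(
    max_iterations = as.integer(max_iterations), alpha = alpha,
    n_trees = as.integer(n_trees), cv_folds = as.integer(cv_folds),
    cv_repeats = as.integer(cv_repeats),
    consensus_fraction = consensus_fraction,
    scheme = match.arg(scheme),
    shadow_aggregate = match.arg(shadow_aggregate),
    seed = as.integer(seed)
  ), class = "boruta_config")
}

#' Single shadow-feature selection run
#'
#' Each iteration permutes a shadow copy of every feature (the full shadow
#' pool keeps the importance threshold stationary across iterations), fits a
#' random forest on the non-rejected real features plus all shadows using
#' out-of-bag permutation importance, and scores a *hit* for a real feature
#' whose importance exceeds the aggregated shadow importance (maximum by
#' default). Features
#' whose cumulative hit counts are extreme under Binomial(iterations, 1/2) at
#' level `alpha` — two-sided, Bonferroni-corrected over the feature family
#' and the sequential per-iteration looks — are confirmed or rejected;
#' survivors at `max_iterations` stay tentative.
#'
#' @param x Samples x features numeric matrix (no missing values).
#' @param y Binary labels (both classes present).
#' @param config A [boruta_config()].
#' @return A tibble `feature, decision, hits, iterations` of class
#'   `boruta_run`.
#' @export
boruta_run <- function(x, y, config = boruta_config()) {
  y <- as_binary(y)
  check_both_classes(y)
  if (anyNA(x)) {
    abort_edison("Missing values are not allowed.", "boruta_input_error")
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  withr::with_seed(config$seed, boruta_run_impl(x, y, config))
}

boruta_run_impl <- function(x, y, cfg) {
  m <- ncol(x)
  feats <- colnames(x)
  status <- rep("tentative", m)
  hits <- integer(m)
  iters <- integer(m)
  yf <- factor(y, levels = c(0, 1))
  agg <- if (cfg$shadow_aggregate == "max") {
    function(v) max(v)
  } else {
    function(v) unname(quantile(v, 0.9, type = 7))
  }
  for (i in seq_len(cfg$max_iterations)) {
    active <- which(status == "tentative")
    if (length(active) == 0) break
    keep <- which(status != "rejected")
    # shadows copy every original feature, not just undecided ones: a
    # shrinking shadow pool would lower the importance threshold over
    # iterations and let borderline noise accumulate spurious hits
    shadows <- apply(x, 2, sample)
    colnames(shadows) <- paste0(".shadow.", feats)
    design <- cbind(x[, keep, drop = FALSE], shadows)
    # out-of-bag permutation importance: chance in-sample correlations do
    # not generalise out-of-bag, so null features stay near the shadows
    rf <- ranger::ranger(
      x = design, y = yf, num.trees = cfg$n_trees,
      importance = "permutation", scale.permutation.importance = TRUE,
      num.threads = 1,
      seed = sample.int(.Machine$integer.max - 1L, 1),
      respect.unordered.factors = "order")
    imp <- rf$variable.importance
    shadow_ref <- agg(imp[colnames(shadows)])
    hit <- imp[feats[active]] > shadow_ref
    hits[active] <- hits[active] + as.integer(hit)
    iters[active] <- i
    # Bonferroni over the full feature family and over the sequential
    # looks: the binomial test is applied after every iteration, and a
    # threshold that ignored the repeated looks (or shrank with the active
    # set) confirms chance streaks
    thr <- (cfg$alpha / 2) / (m * cfg$max_iterations)
    p_hi <- pbinom(hits[active] - 1L, i, 0.5, lower.tail = FALSE)
    p_lo <- pbinom(hits[active], i, 0.5)
    status[active[p_hi < thr]] <- "confirmed"
    status[active[p_lo < thr]] <- "rejected"
  }
  out <- tibble::tibble(feature = feats, decision = status,
                        hits = hits, iterations = iters)
  class(out) <- c("boruta_run", class(out))
  out
}

#' Consensus shadow-feature selection over repeated runs
#'
#' Runs [boruta_run()] on each training partition of a repeated stratified
#' cross-validation scheme (or on full-data restarts) and confirms a feature
#' overall when it is confirmed in at least `consensus_fraction` of runs
#' (and in at least one). Tentative features never enter the final set.
#'
#' @inheritParams boruta_run
#' @return A `boruta_result`: list with `summary` (per-feature tibble:
#'   decision, n_confirmed, n_runs, fraction), `confirmed` (a `probe_set`),
#'   `runs` and `config`.
#' @export
boruta_consensus <- function(x, y, config = boruta_config()) {
  y <- as_binary(y)
  check_both_classes(y)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (config$scheme == "cv") {
    n_runs <- config$cv_repeats * config$cv_folds
    if (min(table(y)) < config$cv_folds) {
      abort_edison("Too few samples per class for the requested folds.",
                   "boruta_input_error")
    }
  } else {
    n_runs <- config$cv_repeats
  }
  seeds <- child_seeds(config$seed, n_runs + config$cv_repeats)
  run_seeds <- seeds[seq_len(n_runs)]
  fold_seeds <- seeds[n_runs + seq_len(config$cv_repeats)]

  runs <- vector("list", n_runs)
  idx <- 1L
  if (config$scheme == "cv") {
    for (r in seq_len(config$cv_repeats)) {
      fold <- withr::with_seed(fold_seeds[r],
                               stratified_folds(y, config$cv_folds))
      for (k in seq_len(config$cv_folds)) {
        tr <- fold != k
        cfg_k <- config
        cfg_k$seed <- run_seeds[idx]
        runs[[idx]] <- boruta_run(x[tr, , drop = FALSE], y[tr], cfg_k)
        idx <- idx + 1L
      }
    }
  } else {
    for (r in seq_len(n_runs)) {
      cfg_r <- config
      cfg_r$seed <- run_seeds[r]
      runs[[r]] <- boruta_run(x, y, cfg_r)
      idx <- idx + 1L
    }
  }
  conf_mat <- vapply(runs, function(rn) rn$decision == "confirmed",
                     logical(ncol(x)))
  if (ncol(x) == 1L) conf_mat <- matrix(conf_mat, nrow = 1)
  n_confirmed <- rowSums(conf_mat)
  fraction <- n_confirmed / n_runs
  final <- fraction >= config$consensus_fraction & n_confirmed >= 1L
  summary <- tibble::tibble(
    feature = colnames(x),
    decision = ifelse(final, "confirmed", "rejected"),
    n_confirmed = as.integer(n_confirmed),
    n_runs = n_runs,
    fraction = fraction
  )
  structure(list(
    summary = summary,
    confirmed = probe_set(
      "BORUTA", colnames(x)[final],
      sprintf("shadow-feature consensus: %d/%d features over %d runs (scheme %s, consensus >= %.2f)",
              sum(final), ncol(x), n_runs, config$scheme,
              config$consensus_fraction)),
    runs = runs,
    config = config
  ), class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("<boruta_result> %d/%d features confirmed over %d runs\n",
              length(x$confirmed$probes), nrow(x$summary),
              x$summary$n_runs[1]))
  invisible(x)
}
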