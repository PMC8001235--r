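#' Stratified 80/20 train/test split
#'
#' One split plan is made per experiment and reused across every probe-set
#' dataset, so all models see identical training and test samples.
#'
#' @param labels Binary labels; a named vector or a data frame with columns
#'   `sample` and `edison` (or `label`).
#' @param seed Integer seed.
#' @param test_fraction Proportion held out (default 0.2).
#' @param stratify Preserve class proportions (default TRUE).
#' @return A `split_plan`: list with `train` and `test` id vectors.
#' @export
make_split <- function(labels, seed = 1L, test_fraction = 0.2,
                       stratify = TRUE) {
  if (is.data.frame(labels)) {
    lab_col <- intersect(c("edison", "label"), names(labels))[1]
    ids <- labels$sample
    y <- as_binary(labels[[lab_col]], "labels")
  } else {
    y <- as_binary(labels, "labels")
    ids <- names(labels) %||% as.character(seq_along(y))
  }
  if (min(table(y)) < 2) {
    abort_edison("Each class needs at least 2 samples to split.",
                 "split_error")
  }
  test <- withr::with_seed(as.integer(seed), {
    if (stratify) {
      unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, round(test_fraction * length(idx))))
      }), use.names = FALSE)
    } else {
      sample(length(y), max(1L, round(test_fraction * length(y))))
    }
  })
  test <- sort(test)
  train <- setdiff(seq_along(y), test)
  if (length(unique(y[train])) < 2 || length(unique(y[test])) < 2) {
    abort_edison("A class is absent from the train or test side.",
                 "split_error")
  }
  structure(list(train = ids[train], test = ids[test],
                 stratified = stratify, seed = as.integer(seed)),
            class = "split_plan")
}

#' Model specification with a hyperparameter grid
#'
#' Defaults: the random-forest grid varies number of trees, maximum tree
#' depth and minimum samples per leaf; the perceptron default is the
#' two-hidden-layer 128-128 architecture.
#'
#' @param family `"random_forest"` or `"mlp"`.
#' @param grid Optional tibble of hyperparameter combinations. Columns for
#'   `random_forest`: `num_trees`, `max_depth` (0 = unlimited),
#'   `min_node_size`; for `mlp`: `hidden` (list-column of integer vectors),
#'   `learning_rate`, `epochs`.
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("random_forest", "mlp"), grid = NULL) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- if (family == "random_forest") {
      tidyr::expand_grid(num_trees = 300, max_depth = c(0, 10),
                         min_node_size = c(1, 5))
    } else {
      tibble::tibble(hidden = list(c(128L, 128L)),
                     learning_rate = 1e-3, epochs = 150)
    }
  }
  if (nrow(grid) == 0) {
    abort_edison("Hyperparameter grid must be non-empty.", "model_spec_error")
  }
  structure(list(family = family, grid = tibble::as_tibble(grid)),
            class = "model_spec")
}

fit_model <- function(family, params, x, y, seed) {
  if (family == "random_forest") {
    ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)),
      num.trees = params$num_trees,
      max.depth = if (params$max_depth > 0) params$max_depth else NULL,
      min.node.size = params$min_node_size,
      probability = TRUE, num.threads = 1, seed = seed,
      respect.unordered.factors = "order")
  } else {
    mlp_fit(x, y, hidden = params$hidden[[1]],
            learning_rate = params$learning_rate,
            epochs = params$epochs, seed = seed)
  }
}

predict_prob <- function(model, x) {
  if (inherits(model, "ranger")) {
    predict(model, data = x, num.threads = 1)$predictions[, "1"]
  } else {
    predict(model, x)
  }
}

#' Grid-search cross-validation tuning and final fit
#'
#' Hyperparameters are chosen by mean cross-validated MCC on the training
#' data only; the winning configuration is refit on the full training set
#' and its per-fold metrics are retained for confidence intervals.
#'
#' @param x_train Samples x probes matrix (training samples only).
#' @param y_train Binary training labels.
#' @param spec A [model_spec()].
#' @param cv_folds Stratified folds for the grid search.
#' @param seed Integer seed.
#' @return An `edison_model`: list with `family`, `best_params`, `fit`,
#'   `cv` (tibble `fold, acc, mcc` of the winning configuration) and
#'   `cv_grid` (mean MCC per configuration).
#' @export
tune_and_train <- function(x_train, y_train, spec, cv_folds = 5, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  y <- as_binary(y_train)
  check_both_classes(y)
  x_train <- as.matrix(x_train)
  fold <- withr::with_seed(as.integer(seed), stratified_folds(y, cv_folds))
  if (any(tapply(y, fold, function(v) length(unique(v))) < 2)) {
    abort_edison("A cross-validation fold contains a single class.",
                 "split_error")
  }
  seeds <- child_seeds(seed, nrow(spec$grid) * cv_folds + 1L)

  eval_config <- function(g) {
    params <- spec$grid[g, ]
    purrr::map_dfr(seq_len(cv_folds), function(k) {
      tr <- fold != k
      fit <- fit_model(spec$family, params, x_train[tr, , drop = FALSE],
                       y[tr], seeds[(g - 1L) * cv_folds + k])
      p <- predict_prob(fit, x_train[!tr, , drop = FALSE])
      pred <- as.integer(p >= 0.5)
      tibble::tibble(fold = k,
                     acc = mean(pred == y[!tr]),
                     mcc = mcc_labels(pred, y[!tr]))
    })
  }
  cv_all <- lapply(seq_len(nrow(spec$grid)), eval_config)
  mean_mcc <- vapply(cv_all, function(tb) mean(tb$mcc), 0)
  best <- which.max(mean_mcc)
  fit <- fit_model(spec$family, spec$grid[best, ], x_train, y,
                   seeds[length(seeds)])
  structure(list(
    family = spec$family,
    best_params = spec$grid[best, ],
    fit = fit,
    cv = cv_all[[best]],
    cv_grid = tibble::tibble(config = seq_len(nrow(spec$grid)),
                             mean_mcc = mean_mcc),
    features = colnames(x_train),
    seed = as.integer(seed)
  ), class = "edison_model")
}

#' @export
print.edison_model <- function(x, ...) {
  cat(sprintf("<edison_model> %s on %d features; CV MCC %.3f\n",
              x$family, length(x$features), mean(x$cv$mcc)))
  invisible(x)
}

#' Evaluate a tuned model on held-out samples
#'
#' @param model An [tune_and_train()] result.
#' @param x_test,y_test Held-out samples and labels.
#' @return A `model_evaluation`: list with test ACC/MCC/AUC, the ROC curve,
#'   per-sample predictions, and cross-validation means with 95% t-intervals.
#' @export
evaluate_model <- function(model, x_test, y_test) {
  y <- as_binary(y_test)
  x_test <- as.matrix(x_test)[, model$features, drop = FALSE]
  p <- predict_prob(model$fit, x_test)
  pred <- as.integer(p >= 0.5)
  roc <- roc_auc(p, y)
  structure(list(
    family = model$family,
    acc_cv = cv_confidence_interval(model$cv$acc),
    mcc_cv = cv_confidence_interval(model$cv$mcc),
    acc_test = mean(pred == y),
    mcc_test = mcc_labels(pred, y),
    auc_test = roc$auc,
    roc_curve = roc$curve,
    predictions = tibble::tibble(prob = p, pred = pred, truth = y)
  ), class = "model_evaluation")
}

#' Train and compare models across probe-set datasets
#'
#' Every (probe set, model spec) pair is tuned on the same training samples
#' and evaluated on the same test samples; the winner is the best test MCC,
#' and the top two rows are compared with the McNemar test.
#'
#' @param beta Probes x samples beta matrix.
#' @param labels Data frame `sample, edison` (or named 0/1 vector).
#' @param probe_sets Named list of `probe_set`s defining the datasets.
#' @param specs Named list of [model_spec()]s.
#' @param split A [make_split()] plan shared by every dataset.
#' @param cv_folds Folds of the tuning grid search.
#' @param seed Integer seed.
#' @return A `model_comparison`: list with `results` (one row per dataset x
#'   model), `winner`, `mcnemar`, `evaluations`.
#' @export
run_model_comparison <- function(beta, labels, probe_sets, specs, split,
                                 cv_folds = 5, seed = 1L) {
  stopifnot(inherits(split, "split_plan"))
  if (is.data.frame(labels)) {
    y_all <- setNames(as_binary(labels$edison, "labels"), labels$sample)
  } else {
    y_all <- setNames(as_binary(labels, "labels"), names(labels))
  }
  x_all <- t(beta)
  if (is.null(names(probe_sets))) {
    names(probe_sets) <- vapply(probe_sets, function(ps) ps$name, "")
  }
  combos <- tidyr::expand_grid(dataset = names(probe_sets),
                               model = names(specs))
  # one shared seed: identical (dataset, model) inputs give identical rows
  evaluations <- purrr::pmap(
    list(combos$dataset, combos$model, rep(as.integer(seed), nrow(combos))),
    function(ds, md, sd_i) {
      probes <- probe_sets[[ds]]$probes
      xt <- x_all[split$train, probes, drop = FALSE]
      xv <- x_all[split$test, probes, drop = FALSE]
      model <- tune_and_train(xt, y_all[split$train], specs[[md]],
                              cv_folds = cv_folds, seed = sd_i)
      evaluate_model(model, xv, y_all[split$test])
    })
  results <- purrr::imap_dfr(evaluations, function(ev, i) {
    tibble::tibble(
      dataset = combos$dataset[i], model = combos$model[i],
      n_probes = length(probe_sets[[combos$dataset[i]]]$probes),
      acc_cv = ev$acc_cv$mean, acc_cv_low = ev$acc_cv$lower,
      acc_cv_high = ev$acc_cv$upper,
      acc_test = ev$acc_test,
      mcc_cv = ev$mcc_cv$mean, mcc_cv_low = ev$mcc_cv$lower,
      mcc_cv_high = ev$mcc_cv$upper,
      mcc_test = ev$mcc_test, auc_test = ev$auc_test)
  })
  ord <- order(results$mcc_test, decreasing = TRUE)
  winner <- results[ord[1], c("dataset", "model")]
  mcn <- if (length(evaluations) >= 2) {
    a <- evaluations[[ord[1]]]$predictions
    b <- evaluations[[ord[2]]]$predictions
    mcnemar_compare(a$pred, b$pred, a$truth)
  }
  structure(list(results = results, winner = winner, mcnemar = mcn,
                 evaluations = setNames(
                   evaluations, paste(combos$dataset, combos$model, sep = "/")),
                 split = split),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$results)
  cat(sprintf("winner: %s / %s", x$winner$dataset, x$winner$model))
  if (!is.null(x$mcnemar)) {
    cat(sprintf(" (McNemar vs runner-up: p = %.3g)", x$mcnemar$p_value))
  }
  cat("\n")
  invisible(x)
}
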