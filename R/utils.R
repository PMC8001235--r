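# shared internal helpers

abort_edison <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "edisonr_error"), ...)
}

# coerce labels to integer 0/1; positive class is 1 / TRUE / second factor level
as_binary <- function(y, arg = "y") {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) {
      abort_edison(sprintf("`%s` must have exactly 2 levels.", arg),
                   "edisonr_label_error")
    }
    y <- as.integer(y) - 1L
  } else if (is.logical(y)) {
    y <- as.integer(y)
  } else {
    y <- as.integer(round(as.numeric(y)))
  }
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    abort_edison(sprintf("`%s` must be binary (0/1).", arg),
                 "edisonr_label_error")
  }
  y
}

check_both_classes <- function(y, arg = "y") {
  if (length(unique(y)) < 2L) {
    abort_edison(sprintf("`%s` contains a single class; both classes are required.", arg),
                 "edisonr_single_class_error")
  }
  invisible(y)
}

# population-SD standardization used for immune scores
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# row variances of a matrix without forming apply() overhead
row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  (rowSums(m * m) - n * mu^2) / (n - 1)
}

# stratified fold assignment, deterministic given the current RNG state
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# derive reproducible child seeds below 2^31 from one parent seed
child_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}
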