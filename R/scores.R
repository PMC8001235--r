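#' Preprocess raw immune-composition inputs into standardized scores
#'
#' The CD163 channel is log-transformed (it is raw expression, strictly
#' positive; exact zeros receive a pseudocount first) and every channel is
#' then standardized to zero mean and unit variance using the population-SD
#' convention. The transformation parameters (pseudocount, log flag, centre,
#' scale) are recorded in the `"transform"` attribute so that new samples can
#' be mapped onto the training scale without re-estimation.
#'
#' @param scores A data frame with columns `sample`, `cd163`, `m2`, `treg`
#'   (raw values; `cd163` on the positive expression scale).
#' @param log_channels Channels to log-transform before standardizing
#'   (default `"cd163"`).
#' @param pseudocount Added to log channels that contain exact zeros.
#' @param transform Optional transform table from a previous call (the
#'   `"transform"` attribute); when supplied, its parameters are applied
#'   as-is instead of being re-estimated.
#' @return A tibble `sample, cd163, m2, treg` of standardized scores with a
#'   `"transform"` attribute.
#' @export
#' @examples
#' raw <- tibble::tibble(sample = letters[1:4],
#'                       cd163 = exp(0:3), m2 = rnorm(4), treg = rnorm(4))
#' preprocess_scores(raw)
preprocess_scores <- function(scores, log_channels = "cd163",
                              pseudocount = 1, transform = NULL) {
  channels <- c("cd163", "m2", "treg")
  missing_ch <- setdiff(c("sample", channels), names(scores))
  if (length(missing_ch)) {
    abort_edison(sprintf("Missing score column(s): %s",
                         paste(missing_ch, collapse = ", ")),
                 "score_schema_error")
  }
  out <- tibble::as_tibble(scores[, c("sample", channels)])
  if (is.null(transform)) {
    transform <- purrr::map_dfr(channels, function(ch) {
      x <- out[[ch]]
      lg <- ch %in% log_channels
      pc <- 0
      if (lg) {
        if (any(x < 0)) {
          abort_edison(sprintf(
            "Channel '%s' must be non-negative before log transform.", ch),
            "score_negative_error")
        }
        if (any(x == 0)) pc <- pseudocount
        x <- log(x + pc)
      }
      s <- pop_sd(x)
      if (s < 1e-12) {
        abort_edison(sprintf(
          "Channel '%s' has zero variance and cannot be standardized.", ch),
          "score_zero_variance_error")
      }
      tibble::tibble(channel = ch, log = lg, pseudocount = pc,
                     center = mean(x), scale = s)
    })
  }
  for (i in seq_len(nrow(transform))) {
    tr <- transform[i, ]
    x <- out[[tr$channel]]
    if (tr$log) x <- log(x + tr$pseudocount)
    out[[tr$channel]] <- (x - tr$center) / tr$scale
  }
  attr(out, "transform") <- transform
  out
}

#' First-quartile thresholds of the immune scores
#'
#' Computes the per-channel 25th percentile under the linear-interpolation
#' convention (type 7). Thresholds are estimated once on a reference cohort
#' and reused, so new samples can be flagged without re-estimation.
#'
#' @param scores A data frame with columns `cd163`, `m2`, `treg`.
#' @return A tibble `channel, q1` of class `quartile_thresholds`.
#' @export
compute_quartiles <- function(scores) {
  channels <- c("cd163", "m2", "treg")
  if (nrow(scores) < 4) {
    abort_edison("At least 4 samples are needed to estimate quartiles.",
                 "score_insufficient_data_error")
  }
  out <- purrr::map_dfr(channels, function(ch) {
    tibble::tibble(channel = ch,
                   q1 = unname(quantile(scores[[ch]], 0.25, type = 7)))
  })
  class(out) <- c("quartile_thresholds", class(out))
  out
}

#' Assign the EDISON immune-evasion flag
#'
#' A case is flagged EDISON positive (putative escape from the
#' immunosuppressive state) when the number of channels strictly below their
#' first-quartile threshold satisfies the rule: at least two of the three
#' (default) or all three. Ties at the threshold count as not-below.
#'
#' @param scores Standardized scores (see [preprocess_scores()]).
#' @param thresholds A [compute_quartiles()] result on the same score scale.
#' @param rule `"at_least_two"` (default) or `"all_three"`.
#' @return The scores tibble with `n_below` and `edison` (0/1) columns.
#' @export
assign_edison <- function(scores, thresholds,
                          rule = c("at_least_two", "all_three")) {
  rule <- match.arg(rule)
  channels <- c("cd163", "m2", "treg")
  missing_ch <- setdiff(channels, names(scores))
  if (length(missing_ch)) {
    abort_edison(sprintf("Missing score channel(s): %s",
                         paste(missing_ch, collapse = ", ")),
                 "score_schema_error")
  }
  q <- setNames(thresholds$q1, thresholds$channel)
  below <- vapply(channels, function(ch) scores[[ch]] < q[[ch]],
                  logical(nrow(scores)))
  if (nrow(scores) == 1L) below <- matrix(below, nrow = 1)
  n_below <- rowSums(below)
  need <- if (rule == "at_least_two") 2L else 3L
  out <- tibble::as_tibble(scores)
  out$n_below <- as.integer(n_below)
  out$edison <- as.integer(n_below >= need)
  attr(out, "rule") <- rule
  attr(out, "transform") <- attr(scores, "transform", exact = TRUE)
  out
}

#' Full labelling pipeline for a cohort
#'
#' Convenience wrapper: extract raw immune inputs from a cohort, preprocess,
#' estimate first-quartile thresholds, and assign the flag.
#'
#' @param cohort A `glioma_cohort`.
#' @inheritParams assign_edison
#' @return Labelled score tibble (see [assign_edison()]); the thresholds are
#'   attached as the `"thresholds"` attribute.
#' @export
label_cohort <- function(cohort, rule = c("at_least_two", "all_three")) {
  rule <- match.arg(rule)
  scores <- preprocess_scores(cohort_immune_scores(cohort))
  thr <- compute_quartiles(scores)
  out <- assign_edison(scores, thr, rule = rule)
  attr(out, "thresholds") <- thr
  out
}

#' Prognostic validation of the EDISON flag
#'
#' Kaplan-Meier curves by flag, the two-group log-rank test, and a univariate
#' Cox model of the flag, for either the overall-survival or the
#' progression-free-interval endpoint.
#'
#' @param labels A data frame with columns `sample` and `edison`, or a 0/1
#'   vector aligned with `clinical`.
#' @param clinical Clinical tibble with `sample`, `os_time`, `os_event`,
#'   `pfi_time`, `pfi_event`.
#' @param endpoint `"OS"` or `"PFI"` (`"PFS"` accepted as an alias of PFI).
#' @return An `edison_survival` object: list with `km` (step-function
#'   tibble), `logrank` (statistic, p), `cox` (see [cox_univariate()]),
#'   `endpoint`, `n`.
#' @export
edison_survival_validation <- function(labels, clinical,
                                       endpoint = c("OS", "PFI", "PFS")) {
  endpoint <- toupper(match.arg(endpoint))
  if (endpoint == "PFS") endpoint <- "PFI"
  if (is.data.frame(labels)) {
    merged <- dplyr::inner_join(
      dplyr::select(labels, "sample", "edison"),
      clinical, by = "sample")
    if (nrow(merged) < nrow(clinical)) {
      abort_edison("Some clinical samples have no label.",
                   "cohort_misaligned_error")
    }
    flag <- merged$edison
    clin <- merged
  } else {
    stopifnot(length(labels) == nrow(clinical))
    flag <- as_binary(labels, "labels")
    clin <- clinical
  }
  dat <- if (endpoint == "OS") {
    tibble::tibble(time = clin$os_time, event = clin$os_event, group = flag)
  } else {
    tibble::tibble(time = clin$pfi_time, event = clin$pfi_event, group = flag)
  }
  events_per_arm <- tapply(dat$event, dat$group, sum)
  if (length(events_per_arm) < 2 || all(events_per_arm == 0)) {
    abort_edison("Survival comparison needs events and both flag levels.",
                 "survival_undefined_error")
  }
  structure(list(
    km = kaplan_meier(dat),
    logrank = log_rank(dat),
    cox = cox_univariate(dat),
    endpoint = endpoint,
    n = nrow(dat)
  ), class = "edison_survival")
}

#' @export
print.edison_survival <- function(x, ...) {
  cat(sprintf("<edison_survival> endpoint %s, n = %d\n", x$endpoint, x$n))
  cat(sprintf("  log-rank chi-sq = %.3f, p = %.3g\n",
              x$logrank$statistic, x$logrank$p_value))
  cat(sprintf("  Cox HR (flag positive) = %.3f [%.3f, %.3f], p = %.3g\n",
              x$cox$hr, x$cox$ci_low, x$cox$ci_high, x$cox$p_value))
  invisible(x)
}
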