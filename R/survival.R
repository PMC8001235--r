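#' Kaplan-Meier product-limit curves per group
#'
#' Tied event times decrement the risk set simultaneously, as in the standard
#' product-limit estimator.
#'
#' @param data A data frame with columns `time` (> 0), `event` (0/1) and
#'   `group`.
#' @return A tibble with one row per observed time per group: `group`,
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
kaplan_meier <- function(data) {
  check_survival_data(data)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = data)
  if (is.null(fit$strata)) {
    grp <- rep(as.character(data$group[1]), length(fit$time))
  } else {
    grp <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  tibble::tibble(
    group = grp,
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
}

#' Two-group log-rank test
#'
#' @inheritParams kaplan_meier
#' @return List with `statistic` (chi-squared, 1 df) and `p_value`.
#' @export
log_rank <- function(data) {
  check_survival_data(data)
  if (length(unique(data$group)) != 2L) {
    abort_edison("log_rank() compares exactly two groups.",
                 "survival_group_error")
  }
  if (sum(data$event) == 0) {
    abort_edison("log_rank() needs at least one event.",
                 "survival_undefined_error")
  }
  d <- survival::survdiff(survival::Surv(time, event) ~ group, data = data)
  list(statistic = unname(d$chisq),
       p_value = pchisq(unname(d$chisq), df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards model of a binary group
#'
#' Partial-likelihood fit with Efron tie handling; the hazard ratio reported
#' is for group level 1 versus level 0, with a Wald 95% confidence interval.
#' Monotone likelihood (complete separation of events) is reported as a
#' distinct error rather than a silent huge estimate.
#'
#' @inheritParams kaplan_meier
#' @return An `edison_cox` object: list with `hr`, `ci_low`, `ci_high`,
#'   `p_value`, `coef`, `se`, `n`, `n_event`.
#' @export
cox_univariate <- function(data) {
  check_survival_data(data)
  grp <- as_binary(data$group, "group")
  check_both_classes(grp, "group")
  if (any(tapply(data$event, grp, sum) == 0)) {
    abort_edison("Each group level needs at least one event.",
                 "survival_undefined_error")
  }
  dat <- data.frame(time = data$time, event = data$event, group = grp)
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ group, data = dat,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- unname(fit$coefficients[1])
  se <- sqrt(unname(fit$var[1, 1]))
  if (monotone || !is.finite(co) || abs(co) > 15 || se > 100) {
    abort_edison(
      "Monotone partial likelihood (complete separation); hazard ratio not estimable.",
      "cox_monotone_error")
  }
  structure(list(
    hr = exp(co),
    ci_low = exp(co - 1.96 * se),
    ci_high = exp(co + 1.96 * se),
    p_value = 2 * pnorm(-abs(co / se)),
    coef = co, se = se,
    n = nrow(dat), n_event = sum(dat$event),
    fit = fit
  ), class = "edison_cox")
}

#' @export
print.edison_cox <- function(x, ...) {
  cat(sprintf("<edison_cox> HR = %.3f [%.3f, %.3f], p = %.3g (n = %d, events = %d)\n",
              x$hr, x$ci_low, x$ci_high, x$p_value, x$n, x$n_event))
  invisible(x)
}

check_survival_data <- function(data) {
  need <- c("time", "event", "group")
  if (!all(need %in% names(data))) {
    abort_edison("Survival data needs columns time, event, group.",
                 "survival_schema_error")
  }
  if (any(data$time <= 0)) {
    abort_edison("Survival times must be positive.", "cohort_time_error")
  }
  if (!all(data$event %in% 0:1)) {
    abort_edison("Event indicators must be 0/1.", "cohort_time_error")
  }
  invisible(data)
}

#' Pearson correlation between CpG methylation and gene expression
#'
#' In `local` mode each probe is paired with the gene(s) it is annotated to
#' in the manifest; in `distant` mode all supplied probes are paired with all
#' supplied genes. P-values come from the t distribution and are adjusted
#' across all tested pairs by Benjamini-Hochberg. Zero-variance vectors give
#' a missing correlation with a note, not a zero.
#'
#' @param beta Probes x samples beta matrix.
#' @param expression Genes x samples expression matrix (same samples, same
#'   order).
#' @param manifest Probe manifest (needed for `local` mode); `genes` may hold
#'   several symbols separated by `;`.
#' @param pairing `"local"` or `"distant"`.
#' @param probes,genes Optional restrictions (required for `distant`).
#' @return Tibble `probe, gene, n, r, p_value, p_adj, note`.
#' @export
cpg_expression_correlation <- function(beta, expression, manifest = NULL,
                                       pairing = c("local", "distant"),
                                       probes = NULL, genes = NULL) {
  pairing <- match.arg(pairing)
  if (!identical(colnames(beta), colnames(expression))) {
    abort_edison("beta and expression must share identical sample columns.",
                 "cohort_misaligned_error")
  }
  n <- ncol(beta)
  if (n < 3) {
    abort_edison("At least 3 samples are required for correlation.",
                 "score_insufficient_data_error")
  }
  if (pairing == "local") {
    if (is.null(manifest)) {
      abort_edison("local pairing requires a manifest.", "score_schema_error")
    }
    man <- manifest
    if (!is.null(probes)) man <- man[man$probe %in% probes, , drop = FALSE]
    pairs <- tidyr::separate_rows(
      tibble::tibble(probe = man$probe, gene = man$genes), "gene", sep = ";")
    pairs <- dplyr::filter(pairs,
                           .data$probe %in% rownames(beta),
                           .data$gene %in% rownames(expression))
  } else {
    if (is.null(probes) || is.null(genes)) {
      abort_edison("distant pairing requires `probes` and `genes`.",
                   "score_schema_error")
    }
    pairs <- tidyr::expand_grid(probe = probes, gene = genes)
  }
  pairs <- dplyr::distinct(pairs)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(probe = character(), gene = character(),
                          n = integer(), r = double(), p_value = double(),
                          p_adj = double(), note = character()))
  }
  b <- beta[pairs$probe, , drop = FALSE]
  e <- expression[pairs$gene, , drop = FALSE]
  sd_b <- sqrt(row_vars(b))
  sd_e <- sqrt(row_vars(e))
  bc <- b - rowMeans(b)
  ec <- e - rowMeans(e)
  r <- rowSums(bc * ec) / ((n - 1) * sd_b * sd_e)
  zero_var <- sd_b < 1e-12 | sd_e < 1e-12
  r[zero_var] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  p[zero_var] <- NA_real_
  out <- tibble::tibble(
    probe = pairs$probe, gene = pairs$gene, n = n,
    r = unname(r), p_value = unname(p),
    p_adj = NA_real_,
    note = ifelse(zero_var, "zero_variance", NA_character_)
  )
  tested <- !is.na(out$p_value)
  out$p_adj[tested] <- p.adjust(out$p_value[tested], method = "BH")
  out
}
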