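# broom-style tidiers

#' @exportS3Method generics::tidy
tidy.probe_set <- function(x, ...) {
  tibble::tibble(name = x$name, probe = x$probes)
}

#' @exportS3Method generics::glance
glance.probe_set <- function(x, ...) {
  tibble::tibble(name = x$name, n_probes = length(x$probes),
                 provenance = x$provenance)
}

#' @exportS3Method generics::tidy
tidy.boruta_result <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.boruta_result <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$summary),
    n_confirmed = length(x$confirmed$probes),
    n_runs = x$summary$n_runs[1],
    scheme = x$config$scheme,
    consensus_fraction = x$config$consensus_fraction
  )
}

#' @exportS3Method generics::tidy
tidy.edison_cox <- function(x, ...) {
  tibble::tibble(term = "group", estimate = x$coef, std_error = x$se,
                 hr = x$hr, ci_low = x$ci_low, ci_high = x$ci_high,
                 p_value = x$p_value)
}

#' @exportS3Method generics::glance
glance.edison_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event)
}

#' @exportS3Method generics::tidy
tidy.edison_survival <- function(x, ...) {
  dplyr::mutate(tidy.edison_cox(x$cox), endpoint = x$endpoint,
                .before = 1)
}

#' @exportS3Method generics::glance
glance.edison_survival <- function(x, ...) {
  tibble::tibble(endpoint = x$endpoint, n = x$n,
                 logrank_statistic = x$logrank$statistic,
                 logrank_p = x$logrank$p_value,
                 hr = x$cox$hr, hr_ci_low = x$cox$ci_low,
                 hr_ci_high = x$cox$ci_high, cox_p = x$cox$p_value)
}

#' @exportS3Method generics::tidy
tidy.edison_model <- function(x, ...) x$cv

#' @exportS3Method generics::glance
glance.edison_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(family = x$family),
    x$best_params[, setdiff(names(x$best_params), "hidden"), drop = FALSE],
    tibble::tibble(cv_mcc = mean(x$cv$mcc), cv_acc = mean(x$cv$acc))
  )
}

#' @exportS3Method generics::glance
glance.model_evaluation <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    acc_cv = x$acc_cv$mean, acc_cv_low = x$acc_cv$lower,
    acc_cv_high = x$acc_cv$upper, acc_test = x$acc_test,
    mcc_cv = x$mcc_cv$mean, mcc_cv_low = x$mcc_cv$lower,
    mcc_cv_high = x$mcc_cv$upper, mcc_test = x$mcc_test,
    auc_test = x$auc_test
  )
}

#' @exportS3Method generics::tidy
tidy.model_comparison <- function(x, ...) x$results
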