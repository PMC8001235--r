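#' Validate the internal consistency of a cohort
#'
#' Checks the invariants every downstream stage relies on: identical,
#' identically ordered sample ids across the beta matrix, expression matrix
#' and clinical table; beta values in \[0, 1\]; positive survival times;
#' unique probe ids; a regional class for every probe.
#'
#' @param cohort A `glioma_cohort` (or a bare list with the same elements).
#' @return The cohort, invisibly, if valid; otherwise an error with a class
#'   naming the violated invariant (`cohort_misaligned_error`,
#'   `cohort_beta_range_error`, `cohort_duplicate_probe_error`,
#'   `cohort_region_error`, `cohort_time_error`).
#' @export
validate_cohort <- function(cohort) {
  s_beta <- colnames(cohort$beta)
  s_expr <- colnames(cohort$expression)
  s_clin <- cohort$clinical$sample
  if (!identical(s_beta, s_expr) || !identical(s_beta, s_clin)) {
    missing <- unique(c(setdiff(s_beta, s_clin), setdiff(s_clin, s_beta),
                        setdiff(s_beta, s_expr), setdiff(s_expr, s_beta)))
    abort_edison(
      if (length(missing)) {
        sprintf("Sample ids misaligned across tables; offending sample(s): %s",
                paste(head(missing, 5), collapse = ", "))
      } else {
        "Sample ids are identical but not identically ordered across tables."
      },
      "cohort_misaligned_error", samples = missing)
  }
  if (anyNA(cohort$beta) || min(cohort$beta) < 0 || max(cohort$beta) > 1) {
    abort_edison("Beta values must lie in [0, 1] with no missing entries.",
                 "cohort_beta_range_error")
  }
  if (anyDuplicated(cohort$manifest$probe)) {
    dup <- unique(cohort$manifest$probe[duplicated(cohort$manifest$probe)])
    abort_edison(sprintf("Duplicate probe id(s) in manifest: %s",
                         paste(head(dup, 5), collapse = ", ")),
                 "cohort_duplicate_probe_error", probes = dup)
  }
  if (!setequal(rownames(cohort$beta), cohort$manifest$probe)) {
    abort_edison("Manifest probes and beta rows do not match.",
                 "cohort_misaligned_error")
  }
  if (!all(cohort$manifest$region %in%
           c("island", "shore", "shelf", "open_sea"))) {
    abort_edison(
      "Every probe needs a region in {island, shore, shelf, open_sea}.",
      "cohort_region_error")
  }
  cl <- cohort$clinical
  if (any(cl$os_time <= 0) || any(cl$pfi_time <= 0)) {
    abort_edison("Survival times must be positive.", "cohort_time_error")
  }
  if (!all(cl$os_event %in% 0:1) || !all(cl$pfi_event %in% 0:1)) {
    abort_edison("Event indicators must be 0/1.", "cohort_time_error")
  }
  invisible(cohort)
}

#' Write a cohort to a directory of plain-text files
#'
#' Writes `beta.tsv` and `expression.tsv` (first column `probe`/`gene`, one
#' column per sample), `clinical.csv`, `manifest.tsv` (genes
#' semicolon-separated) and, when present, `panel.tsv` and
#' `latent_state.csv` (synthetic ground truth).
#'
#' @param cohort A `glioma_cohort`.
#' @param directory Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  validate_cohort(cohort)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  mat_tbl <- function(m, id) {
    tibble::as_tibble(m, rownames = id)
  }
  readr::write_tsv(mat_tbl(cohort$beta, "probe"),
                   file.path(directory, "beta.tsv"))
  readr::write_tsv(mat_tbl(cohort$expression, "gene"),
                   file.path(directory, "expression.tsv"))
  readr::write_csv(cohort$clinical, file.path(directory, "clinical.csv"))
  readr::write_tsv(cohort$manifest, file.path(directory, "manifest.tsv"))
  if (!is.null(cohort$panel)) {
    readr::write_tsv(cohort$panel, file.path(directory, "panel.tsv"))
  }
  if (!is.null(cohort$latent_state)) {
    readr::write_csv(cohort$latent_state,
                     file.path(directory, "latent_state.csv"))
  }
  invisible(directory)
}

#' Read a cohort back from a directory
#'
#' Counterpart of [write_cohort()]; validates all cohort invariants after
#' reading, so misaligned sample ids, out-of-range beta values or duplicate
#' probes raise distinct errors.
#'
#' @param directory Directory containing the cohort files.
#' @return A `glioma_cohort` (without the simulation config; `truth` only as
#'   far as `latent_state.csv` was written).
#' @export
read_cohort <- function(directory) {
  need <- c("beta.tsv", "expression.tsv", "clinical.csv", "manifest.tsv")
  paths <- file.path(directory, need)
  if (any(!file.exists(paths))) {
    abort_edison(sprintf("Missing cohort file(s): %s",
                         paste(need[!file.exists(paths)], collapse = ", ")),
                 "cohort_missing_file_error")
  }
  read_mat <- function(path, id) {
    tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(tb[, -1])
    rownames(m) <- tb[[id]]
    m
  }
  beta <- read_mat(file.path(directory, "beta.tsv"), "probe")
  expression <- read_mat(file.path(directory, "expression.tsv"), "gene")
  clinical <- readr::read_csv(file.path(directory, "clinical.csv"),
                              show_col_types = FALSE, progress = FALSE)
  manifest <- readr::read_tsv(file.path(directory, "manifest.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  panel_path <- file.path(directory, "panel.tsv")
  latent_path <- file.path(directory, "latent_state.csv")
  cohort <- structure(list(
    beta = beta,
    expression = expression,
    clinical = clinical,
    manifest = manifest,
    panel = if (file.exists(panel_path)) {
      readr::read_tsv(panel_path, show_col_types = FALSE, progress = FALSE)
    },
    latent_state = if (file.exists(latent_path)) {
      readr::read_csv(latent_path, show_col_types = FALSE, progress = FALSE)
    },
    truth = NULL,
    config = NULL
  ), class = "glioma_cohort")
  validate_cohort(cohort)
  cohort
}
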