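#' Construct a probe set
#'
#' A named, ordered, unique collection of CpG probe ids with a free-text
#' provenance record.
#'
#' @param name Set name (e.g. `"AllCpGs"`, `"ImmuneAngioICIs"`).
#' @param probes Character vector of probe ids.
#' @param provenance Free-text derivation record.
#' @return A `probe_set` object.
#' @export
probe_set <- function(name, probes, provenance = "") {
  probes <- as.character(probes)
  if (anyDuplicated(probes)) {
    abort_edison("Probe ids in a probe set must be unique.",
                 "probe_set_duplicate_error")
  }
  structure(list(name = name, probes = probes, provenance = provenance),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("<probe_set> %s: %d probes\n", x$name, length(x$probes)))
  if (nzchar(x$provenance)) cat(" ", x$provenance, "\n")
  invisible(x)
}

#' @export
length.probe_set <- function(x) length(x$probes)

#' Label-free independent filtering of the beta matrix
#'
#' Ranks probes by overall variance of beta values (a statistic independent
#' of any class label by construction) and keeps the top fraction. The
#' default keep fraction reproduces a reduction from a full 450k array to
#' roughly 74% of probes (355,314 / 482,421).
#'
#' @param beta Probes x samples beta matrix.
#' @param keep_fraction Fraction of probes to retain, in (0, 1\].
#' @return A `probe_set` named `"AllCpGs"` containing the retained probes in
#'   manifest order.
#' @export
independent_filter <- function(beta, keep_fraction = 355314 / 482421) {
  if (is.null(dim(beta)) || nrow(beta) == 0) {
    abort_edison("Beta matrix is empty.", "probe_set_empty_error")
  }
  if (keep_fraction <= 0 || keep_fraction > 1) {
    abort_edison("`keep_fraction` must lie in (0, 1].", "probe_set_error")
  }
  v <- row_vars(beta)
  k <- ceiling(keep_fraction * nrow(beta))
  keep <- sort(order(v, decreasing = TRUE)[seq_len(k)])
  probe_set("AllCpGs", rownames(beta)[keep],
            sprintf("variance filter, keep_fraction = %.4f (%d of %d probes)",
                    keep_fraction, k, nrow(beta)))
}

#' The five expert gene-panel source tags
#' @export
panel_sources <- function() {
  c("immune_subtype", "angiomatrix", "ici_response", "prognostic", "ecm")
}

#' Select probes annotated to an expert gene panel
#'
#' A probe is included when any of its annotated gene symbols belongs to a
#' panel gene from the requested sources (union semantics). An empty overlap
#' yields an empty probe set, not an error.
#'
#' @param manifest Probe manifest (`probe`, `genes` semicolon-separated,
#'   `region`).
#' @param panel Tibble with columns `gene` and `source` (tags among
#'   [panel_sources()]).
#' @param sources Subset of source tags to use; default all present.
#' @param name Optional set name; defaults to the joined source tags.
#' @return A `probe_set` in manifest order.
#' @export
select_by_genes <- function(manifest, panel, sources = NULL, name = NULL) {
  if (is.null(sources)) sources <- unique(panel$source)
  unknown <- setdiff(sources, panel_sources())
  if (length(unknown)) {
    abort_edison(sprintf("Unknown panel source tag(s): %s",
                         paste(unknown, collapse = ", ")),
                 "panel_source_error")
  }
  genes <- unique(panel$gene[panel$source %in% sources])
  if (length(genes) == 0) {
    return(probe_set(name %||% "empty", character(), "empty panel"))
  }
  gene_lists <- strsplit(manifest$genes, ";", fixed = TRUE)
  hit <- vapply(gene_lists, function(g) any(g %in% genes), logical(1))
  probe_set(name %||% paste(sources, collapse = "+"),
            manifest$probe[hit],
            sprintf("expert panel, sources: %s (%d genes)",
                    paste(sources, collapse = ", "), length(genes)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard expert probe sets
#'
#' Builds the two nested expert sets used throughout the pipeline:
#' `ImmuneAngioICIs` (immune-subtype, angiomatrix and ICI-response genes) and
#' `ImmuneAngioICIsMesECM` (adding prognostic/mesenchymal and ECM genes).
#'
#' @inheritParams select_by_genes
#' @return Named list of two `probe_set`s; the first is a subset of the
#'   second by construction.
#' @export
expert_probe_sets <- function(manifest, panel) {
  list(
    ImmuneAngioICIs = select_by_genes(
      manifest, panel,
      sources = intersect(c("immune_subtype", "angiomatrix", "ici_response"),
                          unique(panel$source)),
      name = "ImmuneAngioICIs"),
    ImmuneAngioICIsMesECM = select_by_genes(
      manifest, panel,
      sources = intersect(panel_sources(), unique(panel$source)),
      name = "ImmuneAngioICIsMesECM")
  )
}

#' Partition a probe set by genomic regional class
#'
#' @param probe_set_obj A `probe_set`.
#' @param manifest Probe manifest with a `region` column covering every probe
#'   in the set.
#' @return Named list of four disjoint `probe_set`s (`island`, `shore`,
#'   `shelf`, `open_sea`) whose union is the input set.
#' @export
partition_by_region <- function(probe_set_obj, manifest) {
  stopifnot(inherits(probe_set_obj, "probe_set"))
  reg <- setNames(manifest$region, manifest$probe)[probe_set_obj$probes]
  if (anyNA(reg)) {
    abort_edison("Some probes lack a region annotation in the manifest.",
                 "cohort_region_error")
  }
  regions <- c("island", "shore", "shelf", "open_sea")
  out <- lapply(regions, function(rg) {
    probe_set(paste0(probe_set_obj$name, ":", rg),
              probe_set_obj$probes[reg == rg],
              sprintf("regional partition (%s) of %s", rg, probe_set_obj$name))
  })
  setNames(out, regions)
}

#' Read an expert gene panel from plain-text files
#'
#' Reads `<source>.txt` files (one gene symbol per line) from a directory;
#' the file name (without extension) is the source tag.
#'
#' @param directory Directory containing `*.txt` panel files.
#' @return Tibble `gene, source`, deduplicated within the union.
#' @export
read_gene_panel <- function(directory) {
  files <- list.files(directory, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0) {
    abort_edison("No panel .txt files found.", "panel_source_error")
  }
  tags <- sub("\\.txt$", "", basename(files))
  unknown <- setdiff(tags, panel_sources())
  if (length(unknown)) {
    abort_edison(sprintf("Unknown panel source tag(s): %s",
                         paste(unknown, collapse = ", ")),
                 "panel_source_error")
  }
  purrr::map2_dfr(files, tags, function(f, tag) {
    genes <- readLines(f)
    genes <- trimws(genes[nzchar(trimws(genes))])
    tibble::tibble(gene = genes, source = tag)
  }) |> dplyr::distinct()
}
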