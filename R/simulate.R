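#' Configuration for the synthetic glioma cohort generator
#'
#' Builds the parameter set that [simulate_cohort()] consumes. The generator
#' emulates the joint structure the downstream pipeline assumes: a latent
#' binary immune state (evading vs suppressed) whose prevalence depends on
#' tumour grade, three correlated immune-composition scores shifted downwards
#' in evading samples, a methylation beta matrix with a configurable set of
#' informative CpG probes, marker and bystander gene expression, and
#' exponential survival with a state-dependent hazard.
#'
#' Beta values are drawn from Beta distributions parameterised by
#' (mean, precision), so the \[0, 1\] range holds by construction rather than
#' by clipping.
#'
#' @param n_samples Number of cases; default 573 mirrors the LGG+GBM cohort
#'   size the pipeline was designed around.
#' @param gbm_fraction Proportion of cases of grade GBM (rest LGG).
#' @param n_probes Total number of CpG probes.
#' @param n_informative_probes Number of probes whose mean beta differs
#'   between latent states.
#' @param probes_per_gene Probes annotated per gene in the manifest.
#' @param effect_size_beta Difference in mean beta between latent states for
#'   informative probes (beta scale, in \[0, 0.78\]).
#' @param score_effect_size Standardised downward mean shift of the three
#'   immune scores in latent evading samples.
#' @param score_correlation Pairwise correlation of the three scores within a
#'   latent state, in (-1, 1).
#' @param baseline_hazard Overall-survival event rate (events per day) for
#'   evading samples.
#' @param state_hazard_ratio Multiplicative hazard applied to suppressed
#'   samples; the default 1/0.55 makes the hazard ratio of flag-positive
#'   (evading) cases 0.55.
#' @param pfi_hazard_scale Progression events occur at this multiple of the
#'   overall-survival baseline hazard.
#' @param pfi_state_hazard_ratio Suppressed-state hazard multiplier for the
#'   progression endpoint (default 1/0.57).
#' @param censoring_rate Target proportion of censored observations under the
#'   baseline hazard (independent exponential censoring).
#' @param p_evading_lgg,p_evading_gbm Probability of the latent evading state
#'   given grade. Defaults (0.23, 0.09) keep GBM depleted for the evading
#'   state while placing overall prevalence below the per-channel first
#'   quartile, so the quartile-based flag can recover the latent state; see
#'   the methods vignette for the rationale.
#' @param beta_precision Precision (shape1 + shape2) of the per-probe Beta
#'   distributions.
#' @param decoy_panel_factor Bystander genes added to the expert panel per
#'   informative gene, so that expert selection over-covers the signal and
#'   data-driven selection has pruning to do.
#' @param seed Integer seed; every random draw in [simulate_cohort()] flows
#'   from it.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 60, n_probes = 100, seed = 7)
#' cohort <- simulate_cohort(cfg)
sim_config <- function(n_samples = 573,
                       gbm_fraction = 47 / 573,
                       n_probes = 2000,
                       n_informative_probes = 50,
                       probes_per_gene = 5,
                       effect_size_beta = 0.15,
                       score_effect_size = 3,
                       score_correlation = 0.3,
                       baseline_hazard = 1 / 1500,
                       state_hazard_ratio = 1 / 0.55,
                       pfi_hazard_scale = 1.6,
                       pfi_state_hazard_ratio = 1 / 0.57,
                       censoring_rate = 0.4,
                       p_evading_lgg = 0.23,
                       p_evading_gbm = 0.09,
                       beta_precision = 30,
                       decoy_panel_factor = 3,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    gbm_fraction = gbm_fraction,
    n_probes = as.integer(n_probes),
    n_informative_probes = as.integer(n_informative_probes),
    probes_per_gene = as.integer(probes_per_gene),
    effect_size_beta = effect_size_beta,
    score_effect_size = score_effect_size,
    score_correlation = score_correlation,
    baseline_hazard = baseline_hazard,
    state_hazard_ratio = state_hazard_ratio,
    pfi_hazard_scale = pfi_hazard_scale,
    pfi_state_hazard_ratio = pfi_state_hazard_ratio,
    censoring_rate = censoring_rate,
    p_evading_lgg = p_evading_lgg,
    p_evading_gbm = p_evading_gbm,
    beta_precision = beta_precision,
    decoy_panel_factor = decoy_panel_factor,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 2, cfg$n_probes >= 1, cfg$probes_per_gene >= 1)
  if (cfg$n_informative_probes > cfg$n_probes) {
    abort_edison("`n_informative_probes` must not exceed `n_probes`.",
                 "sim_config_error")
  }
  props <- c(gbm_fraction = cfg$gbm_fraction,
             censoring_rate = cfg$censoring_rate,
             p_evading_lgg = cfg$p_evading_lgg,
             p_evading_gbm = cfg$p_evading_gbm)
  if (any(props < 0 | props > 1)) {
    abort_edison("All proportions must lie in [0, 1].", "sim_config_error")
  }
  if (abs(cfg$score_correlation) >= 1) {
    abort_edison("`score_correlation` must lie in (-1, 1).", "sim_config_error")
  }
  # mean range used below is [0.1, 0.88 + effect]; effect > 0.78 would push a
  # Beta mean outside (0, 1) and make a shape parameter non-positive
  if (cfg$effect_size_beta < 0 || cfg$effect_size_beta > 0.78) {
    abort_edison(
      "`effect_size_beta` must lie in [0, 0.78] so that Beta shape parameters stay positive.",
      "sim_beta_param_error")
  }
  if (cfg$beta_precision <= 0 || cfg$baseline_hazard <= 0 ||
      cfg$state_hazard_ratio <= 0) {
    abort_edison("Precision and hazard parameters must be positive.",
                 "sim_config_error")
  }
  invisible(cfg)
}

#' Simulate a glioma methylation cohort
#'
#' Draws a full synthetic cohort: clinical table (grade, OS and PFI endpoints),
#' latent immune state, immune scores, gene expression (three marker
#' constructs plus bystander genes coupled to their probes' methylation), a
#' probes-by-samples beta matrix, a probe manifest (gene annotation and
#' CpG-island regional class), and an expert gene panel that covers the
#' informative probes together with decoy genes.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `glioma_cohort`: a list with elements `beta`
#'   (probes x samples matrix), `expression` (genes x samples matrix,
#'   log scale), `clinical` (tibble), `manifest` (tibble: probe, genes,
#'   region), `panel` (tibble: gene, source), `latent_state` (tibble),
#'   `truth` (informative probe ids and true scores) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  samples <- sprintf("S%04d", seq_len(n))

  grade <- ifelse(rbinom(n, 1L, cfg$gbm_fraction) == 1L, "GBM", "LGG")
  p_evade <- ifelse(grade == "GBM", cfg$p_evading_gbm, cfg$p_evading_lgg)
  evading <- rbinom(n, 1L, p_evade) == 1L
  state <- ifelse(evading, "evading", "suppressed")

  # correlated scores via a Gaussian copula with equicorrelation
  r <- cfg$score_correlation
  sigma <- matrix(r, 3, 3); diag(sigma) <- 1
  scores <- MASS::mvrnorm(n, mu = c(0, 0, 0), Sigma = sigma)
  scores <- scores - cfg$score_effect_size * evading
  colnames(scores) <- c("cd163", "m2", "treg")

  # manifest: genes, regions, informative probe placement
  probes <- sprintf("cg%08d", seq_len(cfg$n_probes))
  n_genes <- ceiling(cfg$n_probes / cfg$probes_per_gene)
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  gene_of_probe <- genes[rep(seq_len(n_genes),
                             each = cfg$probes_per_gene)[seq_len(cfg$n_probes)]]
  region <- sample(c("island", "shore", "shelf", "open_sea"),
                   cfg$n_probes, replace = TRUE,
                   prob = c(0.31, 0.23, 0.10, 0.36))
  informative <- sort(sample.int(cfg$n_probes, cfg$n_informative_probes))

  # expert panel: genes carrying informative probes plus decoy genes,
  # tags cycling through the five panel sources
  sources <- c("immune_subtype", "angiomatrix", "ici_response",
               "prognostic", "ecm")
  core_genes <- unique(gene_of_probe[informative])
  other <- setdiff(genes, core_genes)
  n_decoy <- min(length(other),
                 ceiling(cfg$decoy_panel_factor * length(core_genes)))
  decoy_genes <- if (n_decoy > 0) sort(sample(other, n_decoy)) else character()
  panel_genes <- c(core_genes, decoy_genes)
  panel <- tibble::tibble(
    gene = c("CD163", panel_genes),
    source = c("immune_subtype",
               rep_len(sources, length(panel_genes)))
  )

  # beta matrix: Beta(mean, precision); informative probes shift mean by
  # effect_size_beta between states, direction random per probe
  phi <- cfg$beta_precision
  mu <- 0.05 + 0.9 * rbeta(cfg$n_probes, 0.6, 0.6)   # bimodal baseline means
  mu_mat <- matrix(mu, nrow = cfg$n_probes, ncol = n)
  if (cfg$n_informative_probes > 0) {
    eff <- cfg$effect_size_beta
    mu_low <- runif(cfg$n_informative_probes, 0.10, max(0.10, 0.88 - eff))
    hyper_in_evading <- rbinom(cfg$n_informative_probes, 1L, 0.5) == 1L
    mu_evade <- ifelse(hyper_in_evading, mu_low + eff, mu_low)
    mu_suppr <- ifelse(hyper_in_evading, mu_low, mu_low + eff)
    mu_mat[informative, ] <- outer(mu_evade, as.numeric(evading)) +
      outer(mu_suppr, as.numeric(!evading))
  }
  shape1 <- mu_mat * phi
  shape2 <- (1 - mu_mat) * phi
  if (any(shape1 <= 0) || any(shape2 <= 0)) {
    abort_edison("Informative-probe Beta parameters are non-positive.",
                 "sim_beta_param_error")
  }
  beta <- matrix(rbeta(length(mu_mat), shape1, shape2),
                 nrow = cfg$n_probes, ncol = n,
                 dimnames = list(probes, samples))

  # expression: marker constructs are monotone transforms of the scores plus
  # noise; bystander genes are negatively coupled to their probes' mean beta
  gene_beta <- rowsum(beta, gene_of_probe) /
    as.vector(table(gene_of_probe)[sort(unique(gene_of_probe))])
  gene_beta <- gene_beta[genes, , drop = FALSE]
  base_expr <- rnorm(n_genes, 6, 1.5)
  gb_centered <- gene_beta - rowMeans(gene_beta)
  expr_genes <- base_expr - 1.2 * gb_centered +
    matrix(rnorm(n_genes * n, 0, 0.5), n_genes, n)
  markers <- rbind(
    CD163          = 5 + scores[, "cd163"] + rnorm(n, 0, 0.15),
    M2_signature   = scores[, "m2"] + rnorm(n, 0, 0.15),
    Treg_signature = scores[, "treg"] + rnorm(n, 0, 0.15)
  )
  expression <- rbind(markers, expr_genes)
  rownames(expression) <- c(rownames(markers), genes)
  colnames(expression) <- samples

  # survival: exponential event times, independent exponential censoring
  cr <- cfg$censoring_rate
  cens_rate <- function(h) if (cr <= 0) 0 else h * cr / (1 - cr)
  draw_endpoint <- function(h0, hr_state) {
    rate <- h0 * ifelse(evading, 1, hr_state)
    t_event <- rexp(n, rate)
    t_cens <- if (cr <= 0) rep(Inf, n) else rexp(n, cens_rate(h0))
    tibble::tibble(time = pmin(t_event, t_cens),
                   event = as.integer(t_event <= t_cens))
  }
  os <- draw_endpoint(cfg$baseline_hazard, cfg$state_hazard_ratio)
  pfi <- draw_endpoint(cfg$baseline_hazard * cfg$pfi_hazard_scale,
                       cfg$pfi_state_hazard_ratio)

  clinical <- tibble::tibble(
    sample = samples, grade = grade,
    os_time = os$time, os_event = os$event,
    pfi_time = pfi$time, pfi_event = pfi$event
  )
  manifest <- tibble::tibble(probe = probes, genes = gene_of_probe,
                             region = region)

  cohort <- structure(list(
    beta = beta,
    expression = expression,
    clinical = clinical,
    manifest = manifest,
    panel = panel,
    latent_state = tibble::tibble(sample = samples, state = state),
    truth = list(informative_probes = probes[informative],
                 scores = tibble::tibble(sample = samples,
                                         cd163 = scores[, "cd163"],
                                         m2 = scores[, "m2"],
                                         treg = scores[, "treg"])),
    config = cfg
  ), class = "glioma_cohort")
  validate_cohort(cohort)
  cohort
}

#' Extract raw immune-score inputs from a cohort
#'
#' Returns the per-sample raw immune-composition inputs the labelling stage
#' consumes: CD163 expression on the natural (positive) scale and the M2 and
#' Treg deconvolution-style signature scores.
#'
#' @param cohort A `glioma_cohort`.
#' @return A tibble with columns `sample`, `cd163`, `m2`, `treg`.
#' @export
cohort_immune_scores <- function(cohort) {
  stopifnot(inherits(cohort, "glioma_cohort"))
  e <- cohort$expression
  tibble::tibble(
    sample = colnames(e),
    cd163 = exp(e["CD163", ]),
    m2 = e["M2_signature", ],
    treg = e["Treg_signature", ]
  )
}

#' @export
print.glioma_cohort <- function(x, ...) {
  cat("<glioma_cohort>\n")
  cat(sprintf("  samples: %d (%d GBM / %d LGG)\n", ncol(x$beta),
              sum(x$clinical$grade == "GBM"), sum(x$clinical$grade == "LGG")))
  cat(sprintf("  probes:  %d (%d informative)\n", nrow(x$beta),
              length(x$truth$informative_probes)))
  cat(sprintf("  genes:   %d expression rows\n", nrow(x$expression)))
  invisible(x)
}
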