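#' Run the full stratification pipeline on a cohort
#'
#' End-to-end demonstration wrapper: label the cohort via the quartile rule,
#' variance-filter the beta matrix, build the nested expert probe sets from
#' the gene panel, prune the larger expert set with shadow-feature consensus
#' selection, train and compare a random forest and a multilayer perceptron
#' on the shared split, and validate the flag's prognostic value on both
#' endpoints.
#'
#' Component stages are exported individually; this wrapper fixes a modest
#' default scale so the whole pipeline runs in minutes on one CPU.
#'
#' @param cohort A `glioma_cohort`.
#' @param keep_fraction Variance-filter keep fraction.
#' @param boruta Optional [boruta_config()]; default is a single full-data
#'   run with 40 iterations.
#' @param specs Named list of [model_spec()]s; defaults to a small
#'   random-forest grid and the 128-128 perceptron.
#' @param cv_folds Tuning folds.
#' @param rule Flag rule passed to [assign_edison()].
#' @param seed Integer seed for the split, selection and model training.
#' @return List with `labels`, `probe_sets`, `boruta`, `split`,
#'   `comparison`, `survival_os`, `survival_pfi`.
#' @export
run_edison_pipeline <- function(cohort,
                                keep_fraction = 355314 / 482421,
                                boruta = NULL,
                                specs = NULL,
                                cv_folds = 5,
                                rule = "at_least_two",
                                seed = 1L) {
  labels <- label_cohort(cohort, rule = rule)

  filtered <- independent_filter(cohort$beta, keep_fraction)
  experts <- expert_probe_sets(cohort$manifest, cohort$panel)
  experts <- lapply(experts, function(ps) {
    probe_set(ps$name, intersect(ps$probes, filtered$probes), ps$provenance)
  })

  if (is.null(boruta)) {
    boruta <- boruta_config(max_iterations = 40, n_trees = 150,
                            cv_repeats = 1, scheme = "restart",
                            consensus_fraction = 1, seed = seed)
  }
  y <- setNames(labels$edison, labels$sample)
  x_expert <- t(cohort$beta[experts$ImmuneAngioICIsMesECM$probes, ,
                            drop = FALSE])
  bres <- boruta_consensus(x_expert, y, boruta)
  selected <- probe_set("ImmuneAngioICIsMesECM+BORUTA",
                        bres$confirmed$probes,
                        bres$confirmed$provenance)

  if (is.null(specs)) {
    specs <- list(
      rf = model_spec("random_forest",
                      tidyr::expand_grid(num_trees = 300, max_depth = c(0, 8),
                                         min_node_size = c(1, 5))),
      mlp = model_spec("mlp")
    )
  }
  split <- make_split(labels, seed = seed)
  probe_sets <- list(
    AllCpGs = filtered,
    ImmuneAngioICIs = experts$ImmuneAngioICIs,
    ImmuneAngioICIsMesECM = experts$ImmuneAngioICIsMesECM
  )
  if (length(selected$probes) >= 2) {
    probe_sets[["ImmuneAngioICIsMesECM+BORUTA"]] <- selected
  }
  comparison <- run_model_comparison(cohort$beta, labels, probe_sets, specs,
                                     split, cv_folds = cv_folds, seed = seed)

  list(
    labels = labels,
    probe_sets = probe_sets,
    boruta = bres,
    split = split,
    comparison = comparison,
    survival_os = edison_survival_validation(labels, cohort$clinical, "OS"),
    survival_pfi = edison_survival_validation(labels, cohort$clinical, "PFI")
  )
}
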