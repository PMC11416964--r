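# End-to-end demonstration pipeline on a synthetic breeding population:
# simulate -> filter -> heritability -> evaluate methods -> fit HEBLP|A on
# all phenotyped hybrids -> predict the full half-diallel -> GCA ->
# heterotic summary -> tree + groups. Every artifact is written to the
# output directory together with a manifest recording seeds and inputs.

#' Run the full demonstration pipeline on synthetic data
#'
#' @param config a [sim_config()]; its seed drives every stochastic stage.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param n_hybrids phenotyped crosses sampled from the half-diallel.
#' @param traits named vector of per-trait heritabilities (see
#'   [simulate_study()]).
#' @param methods prediction methods for the accuracy evaluation.
#' @param n_train training-set size per replicate.
#' @param n_replicates evaluation replicates.
#' @param top_fractions fractions profiled in the heterotic summary.
#' @param k_groups clusters for germplasm grouping (defaults to the number
#'   of simulated groups).
#' @return invisibly, a list with every intermediate result: `study`,
#'   `filter`, `heritability`, `accuracy`, `model`, `crosses`, `gca`,
#'   `heterotic`, `tree`, `groups`, `manifest`.
#' @export
run_demo <- function(config = sim_config(), out_dir = NULL,
                     n_hybrids = 1000,
                     traits = c(trait = config$h2_target),
                     methods = c("rrblup", "heblp_a"),
                     n_train = floor(0.85 * n_hybrids),
                     n_replicates = 10,
                     top_fractions = c(0.05, 0.10),
                     k_groups = length(config$n_lines_per_group)) {
  t0 <- Sys.time()
  study <- simulate_study(config, n_hybrids = n_hybrids, traits = traits)

  flt <- filter_hybrid_markers(study$founders)
  founders_f <- impute_missing(flt$genotypes)
  hybrids <- study$hybrids[, colnames(founders_f), drop = FALSE]

  herit <- estimate_heritability(hybrids, study$phenotypes,
                                 traits = names(traits))
  acc <- evaluate_methods(hybrids, study$phenotypes, traits = names(traits),
                          methods = methods, n_train = n_train,
                          n_replicates = n_replicates, seed = config$seed)

  first_trait <- names(traits)[1]
  keep <- !is.na(study$phenotypes[[first_trait]])
  model <- fit_heblp_a(hybrids[study$phenotypes$hybrid_id[keep], , drop = FALSE],
                       study$phenotypes[[first_trait]][keep])
  crosses <- predict_all_crosses(model, founders_f)
  gca_tab <- gca(crosses)

  truth_groups <- tibble::tibble(
    line_id = names(study$truth$group_of_line),
    group = unname(study$truth$group_of_line))
  het <- heterotic_summary(crosses, truth_groups,
                           top_fractions = top_fractions)

  d <- p_distance_matrix(study$founders)
  tree <- nj_tree(d)
  groups <- assign_groups(d, k = k_groups)

  manifest <- list(
    seed = config$seed,
    config = config[setdiff(names(config), "group_shift")],
    group_shift = as.list(config$group_shift),
    n_hybrids = n_hybrids, traits = as.list(traits),
    methods = methods, n_train = n_train, n_replicates = n_replicates,
    n_markers_kept = flt$report$n_kept,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  result <- list(study = study, filter = flt$report, heritability = herit,
                 accuracy = acc, model = model, crosses = crosses,
                 gca = gca_tab, heterotic = het, tree = tree,
                 groups = groups, manifest = manifest)
  if (!is.null(out_dir)) write_demo_artifacts(result, out_dir)
  invisible(result)
}

write_demo_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(out_dir, ...)
  write_genotypes(result$study$founders, path("founders.tsv"), "tsv")
  write_phenotypes(result$study$phenotypes, path("phenotypes.csv"))
  write_filter_report(result$filter, path("filter_report.json"))
  write.table(result$heritability, path("heritability.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write.table(result$accuracy, path("accuracy_replicates.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write.table(summarize_accuracy(result$accuracy), path("accuracy_summary.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  write_gp_model(result$model, path("model_heblp_a.json"))
  write.table(result$crosses, path("crosses.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write.table(result$gca, path("gca.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  write_heterotic_summary(result$heterotic, path("heterotic_summary.json"))
  write_newick(result$tree, path("tree.nwk"))
  write_groups(result$groups, path("groups.tsv"))
  jsonlite::write_json(result$manifest, path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
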