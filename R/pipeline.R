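#' Configuration for the end-to-end demonstration pipeline
#'
#' Bundles the stage parameters of the full workflow: simulate a reference
#' compendium and metastasis-like queries, QC-gate specimens, normalize
#' counts, optionally inject and then correct batch effects, select the
#' marker panel, train the classifier, score the queries, run the PCA
#' centroid-concordance validation, and evaluate concordance against the
#' true primaries.
#'
#' @param sim a [sim_config()]; its `seed` is the master seed of the run.
#' @param n_queries number of metastasis-like query specimens.
#' @param qc a [qc_policy()].
#' @param rfe an [rfe_params()].
#' @param cost classifier regularization parameter C.
#' @param pca_d number of PCA components for the concordance validation;
#'   the default `NULL` uses `n_types - 1`, the dimension of the
#'   between-type subspace (two components suffice for plotting but can
#'   merge distinct type clusters when more than three types are present).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), n_queries = 60L,
                            qc = qc_policy(), rfe = rfe_params(),
                            cost = 1, pca_d = NULL) {
  stopifnot(inherits(sim, "sim_config"), inherits(qc, "qc_policy"),
            inherits(rfe, "rfe_params"))
  if (n_queries < 1L) stop("`n_queries` must be >= 1")
  if (is.null(pca_d)) pca_d <- sim$n_types - 1L
  structure(list(sim = sim, n_queries = as.integer(n_queries), qc = qc,
                 rfe = rfe, cost = cost, pca_d = as.integer(pca_d)),
            class = "pipeline_config")
}

#' Demonstration pipeline configuration
#'
#' A complete workflow at a scale that runs end-to-end in well under five
#' minutes on one CPU: 4 tumor types, 120 genes, 30 reference samples per
#' type, 40 metastasis-like queries with 10% QC failures, and injected
#' batch effects that the correction stage must remove.
#'
#' @param seed master seed of the run.
#' @return a [pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 1L) {
  pipeline_config(
    sim = sim_config(n_types = 4L, n_genes = 120L, n_per_type = 30L,
                     batch_shift_sd = 1, batch_scale_sdlog = 0.05,
                     qc_fail_fraction = 0.1, seed = seed),
    n_queries = 40L)
}

#' Run the full tissue-of-origin workflow on synthetic data
#'
#' Executes every stage in order and, when `out_dir` is given, writes the
#' artifacts: reference/query matrices and tables, QC verdicts, the panel,
#' the model JSON, the score table, the PCA assignments, the evaluation
#' report, and a manifest recording the configuration and seed. Re-running
#' with the same configuration reproduces identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if absent).
#' @return a list with the in-memory artifacts: `reference`, `query`,
#'   `qc_verdicts`, `panel`, `model`, `scores`, `pca`, `assignment`,
#'   `evaluation`, `discordant`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim

  ref <- generate_reference(sim)
  qry <- generate_query(sim, ref, config$n_queries)

  # QC gate: only passing query specimens continue (reference specimens are
  # drawn within the gate by construction)
  verdicts <- qc_filter(qry$metadata, config$qc)
  keep <- verdicts$sample_id[verdicts$pass]
  if (length(keep) == 0L) stop("pipeline aborted at stage qc: no query passed")
  qry_counts <- reclass_expr(unclass(qry$counts)[, keep, drop = FALSE], qry$counts)

  # joint normalization of reference and surviving queries
  combined <- expr_matrix(cbind(unclass(ref$counts), unclass(qry_counts)), "counts")
  norm <- normalize_counts(combined, size_factors(combined))

  metadata <- rbind(ref$metadata, qry$metadata[qry$metadata$sample_id %in% keep, ])
  if (sim$batch_shift_sd > 0 || sim$batch_scale_sdlog > 0) {
    norm <- inject_batch_effects(norm, metadata, sim$batch_shift_sd,
                                 sim$batch_scale_sdlog,
                                 derive_seed(sim$seed, "batch_effects"))
    norm <- correct_batches(norm, metadata)
  }

  ref_expr <- reclass_expr(unclass(norm)[, ref$labels$sample_id, drop = FALSE], norm)
  qry_expr <- reclass_expr(unclass(norm)[, keep, drop = FALSE], norm)

  panel <- select_panel(ref_expr, ref$labels, config$rfe)
  model <- train_model(ref_expr, ref$labels, panel, cost = config$cost,
                       seed = derive_seed(sim$seed, "train"))
  scores <- predict(model, qry_expr)

  genes <- panel_gene_set(panel)
  pca <- pca_fit(reclass_expr(unclass(ref_expr)[genes, , drop = FALSE], ref_expr),
                 d = config$pca_d)
  assignment <- centroid_assign(
    pca, reclass_expr(unclass(ref_expr)[genes, , drop = FALSE], ref_expr),
    ref$labels,
    reclass_expr(unclass(qry_expr)[genes, , drop = FALSE], qry_expr),
    qry$labels)

  truth <- qry$labels[qry$labels$sample_id %in% keep, ]
  evaluation <- concordance(as_label_table(scores), truth)
  discordant <- discordance_report(scores, truth)

  result <- list(reference = ref, query = qry, qc_verdicts = verdicts,
                 panel = panel, model = model, scores = scores, pca = pca,
                 assignment = assignment, evaluation = evaluation,
                 discordant = discordant)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, ...)
    write_expression(ref$counts, p("reference_counts.tsv"))
    write_labels(ref$labels, p("reference_labels.tsv"))
    write_metadata(ref$metadata, p("reference_metadata.tsv"))
    write_expression(qry$counts, p("query_counts.tsv"))
    write_labels(qry$labels, p("query_labels.tsv"))
    write_metadata(qry$metadata, p("query_metadata.tsv"))
    write_tsv(verdicts, p("qc_verdicts.tsv"))
    write_panel(panel, p("panel.tsv"))
    write_model(model, p("model.json"))
    write_scores(scores, p("scores.tsv"), raw = TRUE)
    write_tsv(assignment$assignments, p("pca_assignments.tsv"),
              comments = sprintf("#concordant_fraction=%.6f",
                                 assignment$concordant_fraction))
    jsonlite::write_json(
      list(n_total = evaluation$n_total, n_agree = evaluation$n_agree,
           accuracy_pct = evaluation$accuracy_pct,
           display = evaluation$display,
           per_class = evaluation$per_class,
           confusion = as.data.frame(evaluation$confusion)),
      p("evaluation.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_tsv(discordant, p("discordant_cases.tsv"))
    jsonlite::write_json(
      list(package = "cuporigin",
           version = as.character(utils::packageVersion("cuporigin")),
           seed = sim$seed,
           config = list(sim = unclass(sim), n_queries = config$n_queries,
                         qc = unclass(config$qc), rfe = unclass(config$rfe),
                         cost = config$cost, pca_d = config$pca_d)),
      p("manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
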