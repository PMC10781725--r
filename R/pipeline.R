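#' Run the full meta-analysis pipeline
#'
#' Orchestrates the end-to-end flow: per-study preprocessing and differential
#' expression (for inputs supplied as expression matrices), concordance
#' classification, within-database AW-Fisher meta-analysis with imputation for
#' truncated tables, cross-database combination, common-DEG selection, pooled
#' log-fold-changes, and the optional downstream stages — over-representation
#' analysis (given gene sets), connectivity scoring (given a perturbagen
#' library) and leave-one-study-out prediction (given expression studies).
#'
#' Database inputs are asymmetric by design: each element of `db_a` / `db_b`
#' may be an `expression_study` (raw or normalized; preprocessed and run
#' through [moderated_t_dge()]) or a ready [dge_table()] (consumed as-is) —
#' matching the setting where one disease database exists only as published
#' summary tables while the other has expression data.
#'
#' @param db_a,db_b lists of `expression_study` and/or `dge_table` inputs.
#' @param config a [pipeline_config()].
#' @param gene_sets optional [gene_set_collection()] for enrichment.
#' @param perturbagen_lib optional [perturbagen_library()] for connectivity.
#' @param prediction_studies optional list of normalized `expression_study`
#'   objects for LOSO-CV prediction on the common DEGs.
#' @param prediction_models model families to run when prediction is enabled.
#' @param out_dir optional directory; when given, every stage output is
#'   written as annotated TSV and digested into the manifest.
#' @return list of class `psymeta_run`: stage outputs (`dge_a`, `dge_b`,
#'   `concordance_a/b`, `meta_a/b`, `cross`, `meta_results`, `query`,
#'   `enrichment`, `connectivity`, `prediction`) plus a `manifest` with the
#'   config hash, seed, per-stage timings and output digests.
#' @export
run_pipeline <- function(db_a, db_b, config = pipeline_config(),
                         gene_sets = NULL, perturbagen_lib = NULL,
                         prediction_studies = NULL,
                         prediction_models = c("elastic_net", "random_forest"),
                         out_dir = NULL) {
  stopifnot(inherits(config, "psymeta_config"))
  if (!length(db_a) || !length(db_b)) {
    stopf("pipeline aborted at stage 'meta': both databases must contain studies (database %s is empty)",
          if (!length(db_a)) "A" else "B")
  }
  manifest <- list(config_hash = config_hash(config), seed = config$rng_seed,
                   version = as.character(utils::packageVersion("psymeta")),
                   timings = list(), digests = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()["elapsed"]
    out <- tryCatch(expr, error = function(e) {
      stopf("pipeline aborted at stage '%s': %s", name, conditionMessage(e))
    })
    manifest$timings[[name]] <<- unname(proc.time()["elapsed"] - t0)
    message(sprintf("[psymeta] stage %-12s %6.2fs", name,
                    manifest$timings[[name]]))
    out
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(out_dir, paste0(name, ".tsv"))
      write_results(as.data.frame(df), path, config = config)
      manifest$digests[[paste0(name, ".tsv")]] <<- unname(tools::md5sum(path))
    }
  }

  to_tables <- function(db, label) {
    lapply(seq_along(db), function(i) {
      x <- db[[i]]
      if (inherits(x, "dge_table")) return(x)
      if (inherits(x, "expression_study")) {
        st <- preprocess_study(x)
        return(moderated_t_dge(st))
      }
      stopf("database %s element %d is neither an expression_study nor a dge_table",
            label, i)
    })
  }
  dge_a <- t_stage("dge_a", to_tables(db_a, "A"))
  dge_b <- t_stage("dge_b", to_tables(db_b, "B"))
  for (i in seq_along(dge_a)) emit(dge_a[[i]], sprintf("dge_a_%d", i))
  for (i in seq_along(dge_b)) emit(dge_b[[i]], sprintf("dge_b_%d", i))

  conc_a <- t_stage("concordance", {
    classify_concordance(dge_a, config$concordance_p_cutoff, "A")
  })
  conc_b <- classify_concordance(dge_b, config$concordance_p_cutoff, "B")
  emit(conc_a, "concordance_a"); emit(conc_b, "concordance_b")

  meta_a <- t_stage("meta_a", {
    meta_database(dge_a, B = config$monte_carlo_B,
                  seed = derive_seed(config$rng_seed, "meta", 1),
                  imputation = config$imputation)
  })
  meta_b <- t_stage("meta_b", {
    meta_database(dge_b, B = config$monte_carlo_B,
                  seed = derive_seed(config$rng_seed, "meta", 2),
                  imputation = config$imputation)
  })
  cross <- t_stage("cross", {
    combine_databases(meta_a, meta_b, B = config$monte_carlo_B,
                      seed = derive_seed(config$rng_seed, "meta", 3))
  })
  pooled_a <- combine_logfc(attr(meta_a, "logFC_matrix"), attr(meta_a, "p_matrix"))
  pooled_b <- combine_logfc(attr(meta_b, "logFC_matrix"), attr(meta_b, "p_matrix"))
  meta_results <- t_stage("select", {
    select_common_degs(cross, conc_a, conc_b, pooled_a, pooled_b,
                       alpha = config$alpha_meta)
  })
  emit(meta_results, "meta_results")

  query <- NULL
  if (any(meta_results$is_common_deg)) {
    query <- build_query(meta_results)
  }

  enr <- NULL
  if (!is.null(gene_sets)) {
    enr <- t_stage("enrich", {
      enrich(meta_results$gene[meta_results$is_common_deg],
             background = meta_results$gene, sets = gene_sets,
             min_overlap = config$min_overlap,
             min_enrichment = config$min_enrichment,
             p_cutoff = config$enrichment_p_cutoff,
             min_pathway_size = config$min_pathway_size)
    })
    emit(enr, "enrichment")
  }

  conn <- NULL
  if (!is.null(perturbagen_lib) && !is.null(query)) {
    conn <- t_stage("connect", {
      scores <- connectivity_scores(query$up, query$down, perturbagen_lib)
      scores$discordant <- scores$score <= config$connectivity_cutoff
      scores
    })
    emit(conn, "connectivity")
  }

  pred <- NULL
  if (!is.null(prediction_studies) && any(meta_results$is_common_deg)) {
    pred <- t_stage("predict", {
      feat <- standardize_per_gene(prediction_studies,
                                   meta_results$gene[meta_results$is_common_deg])
      lapply(stats::setNames(nm = prediction_models), function(m) {
        loso_cv(feat$features, feat$labels, feat$study_ids,
                prediction_config(model = m,
                                  seed = derive_seed(config$rng_seed, "pred", m)))
      })
    })
  }

  if (!is.null(out_dir)) {
    mf <- data.frame(file = names(manifest$digests),
                     md5 = unlist(manifest$digests),
                     stringsAsFactors = FALSE)
    write_results(mf, file.path(out_dir, "manifest.tsv"), config = config,
                  meta = c(stages = paste(names(manifest$timings), collapse = ",")))
  }
  structure(list(dge_a = dge_a, dge_b = dge_b,
                 concordance_a = conc_a, concordance_b = conc_b,
                 meta_a = meta_a, meta_b = meta_b, cross = cross,
                 meta_results = meta_results, query = query,
                 enrichment = enr, connectivity = conn, prediction = pred,
                 manifest = manifest),
            class = "psymeta_run")
}

#' Simulate a two-database scenario and run the whole pipeline on it
#'
#' Convenience wrapper: generates per-study DGE tables (with the configured
#' truncated and logFC-free studies), an optional perturbagen library with a
#' planted reverser, and expression studies for prediction, then calls
#' [run_pipeline()].  The returned object additionally carries the simulation
#' `truth`, so recovery of the planted shared DEGs can be scored.
#'
#' @param sim a [sim_config()].
#' @param config a [pipeline_config()].
#' @param n_perturbagens perturbagen-library size (0 disables connectivity).
#' @param with_prediction run LOSO-CV prediction on database B's expression
#'   studies?
#' @param ... passed to [run_pipeline()].
#' @return a `psymeta_run` with extra elements `truth` and `recovery`
#'   (sensitivity and observed FDR for the planted shared DEGs).
#' @export
run_synthetic_pipeline <- function(sim = sim_config(),
                                   config = pipeline_config(rng_seed = sim$seed),
                                   n_perturbagens = 50,
                                   with_prediction = FALSE, ...) {
  tabs <- simulate_dge_tables(sim)
  lib <- if (n_perturbagens > 0) {
    simulate_perturbagen_library(sim, n_perturbagens, include_reverser = TRUE,
                                 truth = tabs$truth)
  }
  pred_studies <- if (with_prediction) {
    lapply(seq_len(sim$n_studies), function(i) {
      simulate_expression_study(sim, "B", i, truth = tabs$truth)
    })
  }
  run <- run_pipeline(tabs$A, tabs$B, config, perturbagen_lib = lib,
                      prediction_studies = pred_studies, ...)
  run$truth <- tabs$truth
  called <- run$meta_results$gene[run$meta_results$is_common_deg]
  shared <- tabs$truth$gene[tabs$truth$role == "shared"]
  run$recovery <- list(
    n_called = length(called),
    sensitivity = if (length(shared)) mean(shared %in% called) else NA_real_,
    fdr = if (length(called)) mean(!(called %in% shared)) else NA_real_)
  run
}
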