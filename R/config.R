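#' Pipeline configuration
#'
#' Collects every tunable threshold of the meta-analysis pipeline in one
#' validated object.  Defaults are the pipeline's reference analysis settings:
#' significance at 0.05 for the cross-database combined test, a 0.05 cutoff for
#' the conditional concordance rule, over-representation parameters (minimum
#' overlap 3, minimum enrichment ratio 1, p < 0.05, pathways with fewer than 6
#' members excluded), and a connectivity (reversal) score cutoff of -0.321.
#'
#' @param db_a,db_b named lists (or character vectors of paths) describing the
#'   study inputs of each database; free-form, consumed by [run_pipeline()].
#' @param alpha_meta significance level for the combined AW-Fisher test.
#' @param concordance_p_cutoff per-study p cutoff for conditional concordance.
#' @param min_overlap minimum DEG/pathway overlap for an enrichment row.
#' @param min_enrichment minimum enrichment ratio.
#' @param enrichment_p_cutoff enrichment p-value cutoff.
#' @param min_pathway_size smallest pathway size (within background) tested.
#' @param connectivity_cutoff score at or below which a perturbagen is flagged
#'   as a reversal (discordant) candidate.
#' @param rng_seed integer seed recorded in every output header.
#' @param monte_carlo_B Monte-Carlo replicates for the AW-Fisher null table
#'   (at least 100).
#' @param imputation censored-interval mean (`"censored_mean"`, the default)
#'   or grand mean of observed p-values (`"grand_mean"`) for genes missing
#'   from truncated tables.
#' @return an object of class `psymeta_config`.
#' @export
pipeline_config <- function(db_a = NULL, db_b = NULL,
                            alpha_meta = 0.05,
                            concordance_p_cutoff = 0.05,
                            min_overlap = 3,
                            min_enrichment = 1,
                            enrichment_p_cutoff = 0.05,
                            min_pathway_size = 6,
                            connectivity_cutoff = -0.321,
                            rng_seed = 1L,
                            monte_carlo_B = 10000L,
                            imputation = c("censored_mean", "grand_mean")) {
  check_prob(alpha_meta, "alpha_meta")
  check_prob(concordance_p_cutoff, "concordance_p_cutoff")
  check_prob(enrichment_p_cutoff, "enrichment_p_cutoff")
  if (!is.numeric(monte_carlo_B) || monte_carlo_B < 100) {
    stopf("monte_carlo_B must be >= 100, got %s", format(monte_carlo_B))
  }
  if (!is.numeric(connectivity_cutoff) || !is.finite(connectivity_cutoff)) {
    stopf("connectivity_cutoff must be a finite number")
  }
  if (min_overlap < 0 || min_pathway_size < 1) {
    stopf("enrichment size parameters must be non-negative")
  }
  cfg <- structure(list(
    db_a = db_a, db_b = db_b,
    alpha_meta = alpha_meta,
    concordance_p_cutoff = concordance_p_cutoff,
    min_overlap = as.integer(min_overlap),
    min_enrichment = min_enrichment,
    enrichment_p_cutoff = enrichment_p_cutoff,
    min_pathway_size = as.integer(min_pathway_size),
    connectivity_cutoff = connectivity_cutoff,
    rng_seed = as.integer(rng_seed),
    monte_carlo_B = as.integer(monte_carlo_B),
    imputation = match.arg(imputation)
  ), class = "psymeta_config")
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path path to a YAML file.
#' @return a `psymeta_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' @export
print.psymeta_config <- function(x, ...) {
  cat("psymeta pipeline configuration\n")
  for (k in setdiff(names(x), c("db_a", "db_b"))) {
    cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  }
  invisible(x)
}
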