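#' Simulation configuration for the two-database synthetic scenario
#'
#' Describes a pair of study "databases" with planted differential expression:
#' a set of genes differentially expressed in BOTH databases (the signal the
#' meta-analysis is built to find), database-private DEGs, and null genes.
#' Expression is Gaussian on the log2 scale — the source studies the pipeline
#' emulates are normalized microarray intensities — with per-study baseline
#' offsets supplying between-study heterogeneity.  A configurable fraction of
#' studies per database emits truncated ("partial") tables reporting only
#' genes below a p threshold, and a fraction reports p-values without
#' log-fold-changes, mirroring summary-statistic-only source studies.
#'
#' @param n_genes number of genes.
#' @param n_studies studies per database (same for both).
#' @param n_per_arm samples per arm in every study (at least 3).
#' @param n_shared_deg genes differentially expressed in both databases, with
#'   the same true sign in both.
#' @param n_private_deg genes differentially expressed in exactly one database
#'   (this many in each).
#' @param effect_size mean |log2 fold-change| of planted DEGs (log2 units).
#' @param noise_sd residual standard deviation (log2 units).
#' @param baseline_mean,baseline_sd per-gene baseline intensity distribution.
#' @param study_offset_sd sd of per-study per-gene baseline offsets
#'   (between-study heterogeneity).
#' @param partial_fraction fraction of studies per database emitting truncated
#'   tables.
#' @param partial_threshold p threshold at which partial studies truncate.
#' @param logfc_missing_fraction fraction of studies per database whose tables
#'   report p-values only (logFC blanked).
#' @param seed integer seed; every study gets its own derived child stream.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000, n_studies = 3, n_per_arm = 20,
                       n_shared_deg = 200, n_private_deg = 100,
                       effect_size = 1.0, noise_sd = 1.0,
                       baseline_mean = 7, baseline_sd = 1,
                       study_offset_sd = 0.25,
                       partial_fraction = 0, partial_threshold = 0.05,
                       logfc_missing_fraction = 0, seed = 1L) {
  if (n_shared_deg + 2 * n_private_deg > n_genes) {
    stopf("n_shared_deg + private DEGs of both databases exceed n_genes")
  }
  if (effect_size <= 0 && n_shared_deg + n_private_deg > 0 && effect_size != 0) {
    stopf("effect_size must be positive (or exactly 0 for a null scenario)")
  }
  if (effect_size < 0) stopf("effect_size must be >= 0")
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  for (f in c(partial_fraction, logfc_missing_fraction)) {
    if (f < 0 || f > 1) stopf("fractions must lie in [0,1]")
  }
  check_prob(partial_threshold, "partial_threshold", open = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_studies = as.integer(n_studies),
                 n_per_arm = as.integer(n_per_arm),
                 n_shared_deg = as.integer(n_shared_deg),
                 n_private_deg = as.integer(n_private_deg),
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 study_offset_sd = study_offset_sd,
                 partial_fraction = partial_fraction,
                 partial_threshold = partial_threshold,
                 logfc_missing_fraction = logfc_missing_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Ground truth of a simulation
#'
#' Per-gene planted role and true direction per database.  Roles are mutually
#' exclusive; shared DEGs carry the same true sign in both databases.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `gene`, `role`
#'   (`shared`/`private_A`/`private_B`/`null`), `sign_A`, `sign_B` (+1/-1/NA)
#'   and `baseline`.
#' @export
ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "truth"), {
    gene <- sprintf("G%05d", seq_len(cfg$n_genes))
    role <- rep("null", cfg$n_genes)
    idx <- sample.int(cfg$n_genes, cfg$n_shared_deg + 2 * cfg$n_private_deg)
    sh <- idx[seq_len(cfg$n_shared_deg)]
    pa <- idx[cfg$n_shared_deg + seq_len(cfg$n_private_deg)]
    pb <- idx[cfg$n_shared_deg + cfg$n_private_deg + seq_len(cfg$n_private_deg)]
    role[sh] <- "shared"; role[pa] <- "private_A"; role[pb] <- "private_B"
    sign_A <- sign_B <- rep(NA_real_, cfg$n_genes)
    shared_sign <- sample(c(-1, 1), cfg$n_shared_deg, replace = TRUE)
    sign_A[sh] <- shared_sign; sign_B[sh] <- shared_sign
    sign_A[pa] <- sample(c(-1, 1), cfg$n_private_deg, replace = TRUE)
    sign_B[pb] <- sample(c(-1, 1), cfg$n_private_deg, replace = TRUE)
    baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
    data.frame(gene = gene, role = role, sign_A = sign_A, sign_B = sign_B,
               baseline = baseline, stringsAsFactors = FALSE)
  })
}

#' Simulate one case/control expression study
#'
#' Null genes are Normal(baseline + study offset, noise_sd) in both arms;
#' planted DEGs of the study's database are shifted by sign * effect_size in
#' the case arm.  Deterministic given (seed, database, study_index): each
#' study draws from its own derived random stream, so adding studies never
#' changes earlier studies' data.
#'
#' @param cfg a [sim_config()].
#' @param database `"A"` or `"B"`.
#' @param study_index 1-based study index within the database.
#' @param truth optional precomputed [ground_truth()] (recomputed otherwise).
#' @return an `expression_study` with attribute `truth`.
#' @export
simulate_expression_study <- function(cfg, database = c("A", "B"),
                                      study_index = 1, truth = NULL) {
  database <- match.arg(database)
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_per_arm < 3) {
    stopf("fewer than 3 samples per arm: per-gene variance estimation downstream is undefined")
  }
  if (study_index < 1 || study_index > cfg$n_studies) {
    stopf("study_index %d outside 1..%d", study_index, cfg$n_studies)
  }
  if (is.null(truth)) truth <- ground_truth(cfg)
  sgn <- if (database == "A") truth$sign_A else truth$sign_B
  shift <- ifelse(is.na(sgn), 0, sgn * cfg$effect_size)
  n <- cfg$n_per_arm
  vals <- with_seed(derive_seed(cfg$seed, database, study_index), {
    offset <- stats::rnorm(cfg$n_genes, 0, cfg$study_offset_sd)
    mu <- truth$baseline + offset
    noise <- matrix(stats::rnorm(cfg$n_genes * 2L * n, 0, cfg$noise_sd),
                    nrow = cfg$n_genes)
    m <- mu + noise
    m[, seq_len(n)] <- m[, seq_len(n)] + shift  # case arm first
    m
  })
  sid <- sprintf("%s_s%d", database, study_index)
  st <- expression_study(vals, truth$gene,
                         samples = sprintf("%s_%s%02d", sid,
                                           rep(c("case", "ctrl"), each = n),
                                           c(seq_len(n), seq_len(n))),
                         group = rep(c("case", "control"), each = n),
                         study_id = sid, transform = "normalized")
  attr(st, "truth") <- truth
  st
}

#' Simulate per-study DGE tables for both databases
#'
#' Runs [simulate_expression_study()] and [moderated_t_dge()] per study.  The
#' last `round(partial_fraction * n_studies)` studies of each database are
#' truncated at `partial_threshold` (rows with larger p dropped, threshold
#' recorded); the first `round(logfc_missing_fraction * n_studies)` studies
#' have their logFC column blanked, so both degradations can coexist in one
#' database without stacking on the same study when fractions are small.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `A` and `B` (lists of [dge_table()]s) and
#'   `truth`.
#' @export
simulate_dge_tables <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- ground_truth(cfg)
  n_partial <- round(cfg$partial_fraction * cfg$n_studies)
  n_nolfc <- round(cfg$logfc_missing_fraction * cfg$n_studies)
  make_db <- function(db) {
    lapply(seq_len(cfg$n_studies), function(i) {
      st <- simulate_expression_study(cfg, db, i, truth = truth)
      tab <- moderated_t_dge(st)
      if (i <= n_nolfc) {
        tab$logFC <- NA_real_
        tab$t <- NULL
      }
      if (i > cfg$n_studies - n_partial) {
        tab <- truncate_table(tab, cfg$partial_threshold)
      }
      tab
    })
  }
  list(A = make_db("A"), B = make_db("B"), truth = truth)
}

#' Construct a perturbagen signature library
#'
#' @param logfc numeric matrix, perturbagens in rows, genes in columns.
#' @param perturbagens unique perturbagen ids.
#' @param genes gene symbols for the columns.
#' @param metadata optional data.frame of per-perturbagen annotations.
#' @return an object of class `perturbagen_library`.
#' @export
perturbagen_library <- function(logfc, perturbagens, genes, metadata = NULL) {
  logfc <- as.matrix(logfc)
  if (length(perturbagens) != nrow(logfc) || length(genes) != ncol(logfc)) {
    stopf("library dimensions do not match id lists")
  }
  if (anyDuplicated(perturbagens)) stopf("duplicate perturbagen ids")
  if (nrow(logfc) && any(!is.finite(logfc))) stopf("library entries must be finite")
  dimnames(logfc) <- list(perturbagens, normalize_gene(genes))
  structure(list(logfc = logfc, perturbagens = perturbagens,
                 genes = colnames(logfc), metadata = metadata),
            class = "perturbagen_library")
}

#' Simulate a perturbagen library, optionally with a planted reverser
#'
#' Random perturbagens carry i.i.d. Normal(0, 1) log-fold-changes across the
#' simulated gene space.  With `include_reverser = TRUE` the first perturbagen
#' (`REVERSER`) equals the negated true shared-DEG signature plus small noise,
#' i.e. the drug the connectivity stage is supposed to surface.
#'
#' @param cfg a [sim_config()].
#' @param n_perturbagens number of random perturbagens (0 allowed).
#' @param include_reverser plant the reverser perturbagen?
#' @param reverser_noise_sd sd of the noise on the planted reverser.
#' @param truth optional precomputed [ground_truth()].
#' @return a [perturbagen_library()].
#' @export
simulate_perturbagen_library <- function(cfg, n_perturbagens = 100,
                                         include_reverser = TRUE,
                                         reverser_noise_sd = 0.05,
                                         truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(truth)) truth <- ground_truth(cfg)
  with_seed(derive_seed(cfg$seed, "perturbagens"), {
    m <- matrix(stats::rnorm(n_perturbagens * cfg$n_genes),
                nrow = n_perturbagens, ncol = cfg$n_genes)
    ids <- sprintf("PERT%04d", seq_len(n_perturbagens))
    if (include_reverser) {
      sig <- ifelse(truth$role == "shared", truth$sign_A * cfg$effect_size, 0)
      rev_row <- -sig + stats::rnorm(cfg$n_genes, 0, reverser_noise_sd)
      m <- rbind(rev_row, m)
      ids <- c("REVERSER", ids)
    }
    perturbagen_library(m, ids, truth$gene)
  })
}
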