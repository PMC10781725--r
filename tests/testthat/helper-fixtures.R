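# Small builders and independent oracles shared across the test files.

make_study <- function(values, group = NULL, transform = "normalized",
                       study_id = "s1", genes = NULL) {
  values <- as.matrix(values)
  genes <- genes %||% sprintf("G%03d", seq_len(nrow(values)))
  group <- group %||% rep(c("case", "control"), length.out = ncol(values))
  psymeta::expression_study(values, genes,
                            samples = sprintf("%s_smp%02d", study_id, seq_len(ncol(values))),
                            group = group, study_id = study_id,
                            transform = transform)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dge_table <- function(n = 20, study_id = "s", with_logfc = TRUE) {
  dge_table(gene = sprintf("R%04d", sample.int(99999, n)),
            p = runif(n),
            logFC = if (with_logfc) rnorm(n) else NA_real_,
            study_id = study_id)
}

# Independent brute-force AW-Fisher oracle: enumerates study subsets with
# utils::combn, computes each weighted Fisher tail directly, and resolves
# ties by an explicit comparison (larger subsets first, then the
# lexicographically smallest weight vector).
aw_oracle <- function(p) {
  K <- length(p)
  p <- pmin(pmax(p, 1e-300), 1)
  best <- NULL
  for (size in K:1) {
    for (subset in as.data.frame(utils::combn(K, size))) {
      w <- integer(K); w[subset] <- 1L
      stat <- sum(-2 * log(p[subset]))
      cand <- pchisq(stat, df = 2 * size, lower.tail = FALSE)
      better <- is.null(best) || cand < best$cand ||
        (cand == best$cand && size > sum(best$w)) ||
        (cand == best$cand && size == sum(best$w) &&
           paste(w, collapse = "") < paste(best$w, collapse = ""))
      if (better) best <- list(cand = cand, w = w, stat = stat)
    }
  }
  best
}

# Exhaustive hypergeometric upper tail: sum of the mass function over j >= k.
hyper_tail_oracle <- function(k, N, m, n) {
  js <- k:min(m, n)
  if (k > min(m, n)) return(0)
  sum(choose(m, js) * choose(N - m, n - js)) / choose(N, n)
}

# Label permutation within studies, seeded, for permutation-null checks.
permute_within_study <- function(labels, study_ids, seed) {
  out <- as.character(labels)
  set.seed(seed)
  for (s in unique(study_ids)) {
    idx <- which(study_ids == s)
    out[idx] <- sample(out[idx])
  }
  factor(out, levels = levels(labels))
}

# Hand-enumerated 12-gene, 3-study concordance fixture covering every C/S/D
# rule branch (expected labels worked out by hand from the rules before
# implementation; cutoff 0.05).
concordance_fixture <- function() {
  s1 <- dge_table(
    gene = c("ALLPOS", "ALLNEG", "CONDPOS", "DISC", "NOSIG", "ZEROIG",
             "ONESTUDY", "NOLFC", "NOLFC2", "CONDNEG", "MIXSIGONE", "VACZERO"),
    logFC = c(1, -1, 1, 1, 1, 0, 1, NA, NA, -1, 1, 0),
    p = c(0.2, 0.01, 0.01, 0.01, 0.2, 0.01, 0.01, 0.01, 0.01, 0.01, 0.04, 0.01),
    study_id = "s1")
  s2 <- dge_table(
    gene = c("ALLPOS", "ALLNEG", "CONDPOS", "DISC", "NOSIG", "ZEROIG",
             "NOLFC", "NOLFC2", "CONDNEG", "MIXSIGONE", "VACZERO"),
    logFC = c(1, -1, -1, -1, -1, 1, 1, 1, -1, -1, NA),
    p = c(0.5, 0.01, 0.30, 0.01, 0.3, 0.02, 0.03, 0.03, 0.04, 0.2, 0.5),
    study_id = "s2")
  s3 <- dge_table(
    gene = c("ALLPOS", "ALLNEG", "CONDPOS", "DISC", "NOSIG", "ZEROIG",
             "NOLFC", "NOLFC2", "CONDNEG", "MIXSIGONE"),
    logFC = c(1, -1, 1, 1, 1, 1, 1, -1, 1, -1),
    p = c(0.01, 0.9, 0.6, 0.9, 0.4, 0.7, 0.2, 0.02, 0.5, 0.3),
    study_id = "s3")
  list(
    tables = list(s1, s2, s3),
    expected = c(ALLPOS = "C", ALLNEG = "C", CONDPOS = "S", DISC = "D",
                 NOSIG = "D", ZEROIG = "C", ONESTUDY = "C", NOLFC = "C",
                 NOLFC2 = "D", CONDNEG = "S", MIXSIGONE = "S", VACZERO = "C"),
    vacuous = c("ONESTUDY", "VACZERO"))
}

# Five-study separable prediction scenario: a handful of strongly planted
# genes (effect far above noise) so LOSO classification is perfect.
separable_features <- function(seed = 3, n_genes = 20, n_deg = 5,
                               effect = 4, n_studies = 5) {
  cfg <- sim_config(n_genes = n_genes, n_studies = n_studies, n_per_arm = 12,
                    n_shared_deg = n_deg, n_private_deg = 0,
                    effect_size = effect, noise_sd = 1, seed = seed)
  tr <- ground_truth(cfg)
  studies <- lapply(seq_len(n_studies), function(i) {
    simulate_expression_study(cfg, "B", i, truth = tr)
  })
  feat <- standardize_per_gene(studies, tr$gene[tr$role == "shared"])
  feat$truth <- tr
  feat$studies <- studies
  feat
}
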