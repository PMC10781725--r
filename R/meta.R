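# All nonzero binary weight vectors over K studies, ordered so that the FIRST
# minimum found respects the tie-break: more included studies first, then
# lexicographically smallest.
weight_matrix <- function(K) {
  if (K < 1) stopf("need at least one study")
  if (K > 20) stopf("AW-Fisher enumeration is bounded at K = 20 studies")
  W <- as.matrix(expand.grid(rep(list(c(0, 1)), K)))[-1, , drop = FALSE]
  colnames(W) <- NULL
  ord <- do.call(order, c(list(-rowSums(W)), lapply(seq_len(K), function(j) W[, j])))
  W[ord, , drop = FALSE]
}

#' Weighted Fisher statistic and its candidate p-value
#'
#' For p-values \eqn{p_1,\dots,p_K} and a binary inclusion weight vector
#' \eqn{w}, the statistic is \eqn{T(w) = \sum_k w_k (-2 \ln p_k)}; under the
#' null of the included studies, T(w) is chi-square with \eqn{2\sum_k w_k}
#' degrees of freedom, and the candidate p-value is that upper tail.
#'
#' @param pvals numeric p-value vector (clamped into \[1e-300, 1\] before the
#'   log).
#' @param w binary 0/1 vector, same length, not all zero.
#' @return list with `stat` and `candidate_p`.
#' @export
fisher_stat <- function(pvals, w) {
  if (length(pvals) != length(w)) stopf("pvals and w must have equal length")
  if (!any(w == 1) || !all(w %in% c(0, 1))) stopf("w must be binary with at least one 1")
  p <- clamp_p(pvals)
  stat <- sum(w * (-2 * log(p)))
  list(stat = stat,
       candidate_p = stats::pchisq(stat, df = 2 * sum(w), lower.tail = FALSE))
}

# Vectorized core: G x K matrix of p-values -> per row the minimum candidate
# p over all nonzero weight vectors plus the index of the winning weight.
aw_min_candidate <- function(pmat, W = weight_matrix(ncol(pmat))) {
  lp <- -2 * log(clamp_p(pmat))           # G x K
  Tm <- lp %*% t(W)                       # G x nW
  dfs <- 2 * rowSums(W)
  cand <- stats::pchisq(Tm, df = rep(dfs, each = nrow(Tm)), lower.tail = FALSE)
  best <- max.col(-cand, ties.method = "first")   # W rows pre-ordered for ties
  list(min_p = cand[cbind(seq_len(nrow(cand)), best)], best = best)
}

# Shared Monte-Carlo null table: B draws of K independent Uniform(0,1)
# p-values, reduced to the null distribution of the minimum candidate p.
aw_null_table <- function(K, B, seed) {
  with_seed(derive_seed(seed, "awnull", K, B), {
    U <- matrix(stats::runif(B * K), nrow = B)
    sort(aw_min_candidate(U)$min_p)
  })
}

#' Adaptively weighted Fisher combination of study p-values
#'
#' Enumerates every nonzero binary study-inclusion weight vector, takes the
#' weight minimizing the candidate (weighted Fisher chi-square tail) p-value,
#' and calibrates that minimum against its Monte-Carlo null distribution: the
#' combined p-value is the null probability that the minimum candidate p is at
#' most the observed one, estimated as (count + 1)/(B + 1) from a shared
#' seeded table of B draws of K independent uniforms (so the combined p is
#' floored at 1/(B+1)).  Weight ties prefer the vector including more studies,
#' then the lexicographically smallest.
#'
#' @param pvals either a numeric vector (one gene) or a genes-by-studies
#'   matrix of p-values.
#' @param B Monte-Carlo replicates for the null table.
#' @param seed seed for the null table.
#' @param null_table optional precomputed sorted null vector (from a previous
#'   call's attribute) to share across calls.
#' @return for a vector input, a list with `combined_p`, `weights`,
#'   `min_candidate_p`; for a matrix, a data.frame with one row per gene
#'   (columns `combined_p`, `min_candidate_p`, `weight` as a "101"-style
#'   string) and the sorted null table in attribute `null_table`.
#' @export
aw_fisher <- function(pvals, B = 10000, seed = 1L, null_table = NULL) {
  vec <- is.null(dim(pvals))
  pmat <- if (vec) matrix(pvals, nrow = 1) else as.matrix(pvals)
  K <- ncol(pmat)
  if (K < 1 || !nrow(pmat)) stopf("need at least one study and one gene")
  W <- weight_matrix(K)
  obs <- aw_min_candidate(pmat, W)
  if (is.null(null_table)) null_table <- aw_null_table(K, B, seed)
  Bn <- length(null_table)
  combined <- (findInterval(obs$min_p, null_table) + 1) / (Bn + 1)
  wstr <- apply(W, 1, paste, collapse = "")[obs$best]
  if (vec) {
    return(list(combined_p = combined[1],
                weights = W[obs$best[1], ],
                min_candidate_p = obs$min_p[1]))
  }
  out <- data.frame(gene = rownames(pmat) %||% seq_len(nrow(pmat)),
                    combined_p = combined,
                    min_candidate_p = obs$min_p,
                    weight = wstr,
                    stringsAsFactors = FALSE)
  attr(out, "null_table") <- null_table
  out
}

#' Impute missing p-values for truncated (partial) tables
#'
#' The gene universe is the union of genes over all tables.  Within each
#' partial study with truncation threshold t, every universe gene the study
#' did not report is known only to have p in the censored interval (t, 1];
#' under the default `censored_mean` rule it receives that interval's mean,
#' (t + 1)/2.  The alternative `grand_mean` rule imputes the grand mean of the
#' study's observed p-values.  Imputed entries are flagged; full tables and
#' reported rows are untouched.
#'
#' @param tables list of [dge_table()]s.
#' @param method `"censored_mean"` (default) or `"grand_mean"`.
#' @return list of completed tables, each with an `imputed` logical column.
#' @export
impute_missing_pvalues <- function(tables,
                                   method = c("censored_mean", "grand_mean")) {
  method <- match.arg(method)
  universe <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  lapply(tables, function(tab) {
    stopifnot(inherits(tab, "dge_table"))
    if (attr(tab, "reporting") == "full") {
      tab$imputed <- rep(FALSE, nrow(tab))
      return(tab)
    }
    thr <- attr(tab, "threshold")
    if (is.null(thr)) {
      stopf("partial table '%s' has no truncation threshold", attr(tab, "study_id"))
    }
    missing <- setdiff(universe, tab$gene)
    pval <- switch(method,
                   censored_mean = (thr + 1) / 2,
                   grand_mean = mean(tab$p))
    out <- dge_table(gene = c(tab$gene, missing),
                     p = c(tab$p, rep(pval, length(missing))),
                     logFC = c(tab$logFC, rep(NA_real_, length(missing))),
                     study_id = attr(tab, "study_id"),
                     reporting = "full")
    out$imputed <- c(rep(FALSE, nrow(tab)), rep(TRUE, length(missing)))
    attr(out, "was_partial") <- TRUE
    attr(out, "threshold") <- thr
    out
  })
}

# Align a list of completed DGE tables to the union gene universe; returns a
# genes x studies p matrix plus parallel logFC matrix.
align_tables <- function(tables) {
  universe <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  K <- length(tables)
  pm <- matrix(NA_real_, length(universe), K,
               dimnames = list(universe, vapply(tables, attr, "", "study_id")))
  fm <- pm
  for (k in seq_len(K)) {
    idx <- match(tables[[k]]$gene, universe)
    pm[idx, k] <- tables[[k]]$p
    fm[idx, k] <- tables[[k]]$logFC
  }
  list(p = pm, logFC = fm, universe = universe)
}

#' Meta-analyze one database's studies with AW-Fisher
#'
#' Imputes missing p-values of partial tables, aligns the tables on the union
#' gene universe, and combines per-gene p-values with [aw_fisher()].  Genes
#' absent from a full table (possible when studies profiled different gene
#' panels) receive p = 1 for the combination, contributing no evidence.
#'
#' @param tables list of [dge_table()]s for one database.
#' @param B,seed Monte-Carlo null-table parameters.
#' @param imputation imputation rule, see [impute_missing_pvalues()].
#' @return data.frame per gene: `gene`, `combined_p`, `min_candidate_p`,
#'   `weight`, plus a `logFC` matrix and per-study `p` matrix in attributes.
#' @export
meta_database <- function(tables, B = 10000, seed = 1L,
                          imputation = c("censored_mean", "grand_mean")) {
  completed <- impute_missing_pvalues(tables, match.arg(imputation))
  al <- align_tables(completed)
  pmat <- al$p
  pmat[is.na(pmat)] <- 1
  res <- aw_fisher(pmat, B = B, seed = seed)
  res$gene <- al$universe
  attr(res, "p_matrix") <- al$p
  attr(res, "logFC_matrix") <- al$logFC
  res
}

#' Combine two database-level AW-Fisher results
#'
#' Applies [aw_fisher()] to the pair of database p-values per gene, over the
#' intersection of the two gene universes; genes missing from either database
#' are dropped and listed in the `dropped` attribute.
#'
#' @param meta_a,meta_b outputs of [meta_database()].
#' @param B,seed Monte-Carlo null-table parameters.
#' @return data.frame per gene: `gene`, `p_a`, `p_b`, `combined_p`,
#'   `min_candidate_p`, `weight` (e.g. `"11"`).
#' @export
combine_databases <- function(meta_a, meta_b, B = 10000, seed = 1L) {
  common <- intersect(meta_a$gene, meta_b$gene)
  if (!length(common)) stopf("empty gene-universe intersection between databases")
  dropped <- setdiff(union(meta_a$gene, meta_b$gene), common)
  pa <- meta_a$combined_p[match(common, meta_a$gene)]
  pb <- meta_b$combined_p[match(common, meta_b$gene)]
  pmat <- cbind(pa, pb)
  rownames(pmat) <- common
  res <- aw_fisher(pmat, B = B, seed = seed)
  out <- data.frame(gene = common, p_a = pa, p_b = pb,
                    combined_p = res$combined_p,
                    min_candidate_p = res$min_candidate_p,
                    weight = res$weight,
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Pool log-fold-changes with inverse-p weights
#'
#' Per gene, the pooled logFC is the weighted average of study logFCs over the
#' studies that report one, with weight 1/p (p clamped below at 1e-300).
#' Genes with no reported logFC get `NA`.
#'
#' @param logfc_mat genes x studies matrix of log-fold-changes (NA where
#'   unreported).
#' @param p_mat matching matrix of p-values.
#' @return named numeric vector of pooled logFCs.
#' @export
combine_logfc <- function(logfc_mat, p_mat) {
  stopifnot(all(dim(logfc_mat) == dim(p_mat)))
  w <- 1 / clamp_p(p_mat)
  w[is.na(logfc_mat) | is.na(p_mat)] <- NA
  num <- rowSums(w * logfc_mat, na.rm = TRUE)
  den <- rowSums(w, na.rm = TRUE)
  out <- ifelse(den > 0, num / den, NA_real_)
  names(out) <- rownames(logfc_mat)
  out
}

#' Select common DEGs across the two databases
#'
#' A gene is a common DEG when (1) its cross-database AW-Fisher p is below
#' `alpha` with weight (1,1) — both databases contribute — and (2) it is
#' concordant or conditionally concordant (status C or S) in BOTH databases.
#' Direction is `up`/`down` when the pooled logFCs of the two databases share
#' that sign, `mixed` otherwise, `NA` when either pooled logFC is unavailable.
#'
#' @param cross output of [combine_databases()].
#' @param concordance_a,concordance_b outputs of [classify_concordance()].
#' @param pooled_logfc_a,pooled_logfc_b named vectors from [combine_logfc()],
#'   one per database.
#' @param alpha significance level for the cross-database combined p.
#' @return data.frame of class `meta_gene_result`: per gene the cross
#'   statistics, per-database concordance status and pooled logFC, the
#'   `is_common_deg` flag and `direction`.
#' @export
select_common_degs <- function(cross, concordance_a, concordance_b,
                               pooled_logfc_a, pooled_logfc_b,
                               alpha = 0.05) {
  check_prob(alpha, "alpha")
  g <- cross$gene
  st_a <- concordance_a$status[match(g, concordance_a$gene)]
  st_b <- concordance_b$status[match(g, concordance_b$gene)]
  lfc_a <- unname(pooled_logfc_a[match(g, names(pooled_logfc_a))])
  lfc_b <- unname(pooled_logfc_b[match(g, names(pooled_logfc_b))])
  ok_p <- cross$combined_p < alpha & cross$weight == "11"
  ok_c <- !is.na(st_a) & !is.na(st_b) & st_a %in% c("C", "S") & st_b %in% c("C", "S")
  direction <- ifelse(is.na(lfc_a) | is.na(lfc_b), NA_character_,
                      ifelse(lfc_a > 0 & lfc_b > 0, "up",
                             ifelse(lfc_a < 0 & lfc_b < 0, "down", "mixed")))
  out <- data.frame(gene = g,
                    p_a = cross$p_a, p_b = cross$p_b,
                    combined_p = cross$combined_p,
                    weight = cross$weight,
                    status_a = st_a, status_b = st_b,
                    pooled_logfc_a = lfc_a, pooled_logfc_b = lfc_b,
                    is_common_deg = ok_p & ok_c,
                    direction = direction,
                    stringsAsFactors = FALSE)
  class(out) <- c("meta_gene_result", "data.frame")
  out
}
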