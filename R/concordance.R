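#' Classify per-gene cross-study direction concordance
#'
#' Within one database, each gene is assigned a signal-homogeneity status:
#' \describe{
#'   \item{C (concordant)}{the same direction of differential expression in
#'     ALL studies that report an effect size for the gene.}
#'   \item{S (conditionally concordant)}{not C, but the same direction across
#'     all studies with p below `p_cutoff` that report an effect size (at
#'     least one such study) — the p filter removes marginal, noise-dominated
#'     signals.}
#'   \item{D (discordant)}{neither.}
#' }
#' A zero logFC carries no direction and is treated like a missing effect
#' size.  Genes with an effect size in at most one study are vacuously C and
#' flagged in the `vacuous` column.
#'
#' @param tables list of at least two [dge_table()]s from one database.
#' @param p_cutoff per-study significance cutoff for the conditional rule.
#' @param database database label recorded in the output.
#' @return data.frame of class `concordance` with columns `gene`, `database`,
#'   `status` (C/S/D), `n_studies_with_effect_size`, `n_studies_significant`,
#'   `vacuous`.
#' @export
classify_concordance <- function(tables, p_cutoff = 0.05, database = "db") {
  if (length(tables) < 2) stopf("concordance needs at least 2 studies")
  check_prob(p_cutoff, "p_cutoff")
  for (tab in tables) stopifnot(inherits(tab, "dge_table"))
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  K <- length(tables)
  sgn <- matrix(NA_real_, length(genes), K)   # NA = no usable effect size
  pm <- matrix(NA_real_, length(genes), K)
  for (k in seq_len(K)) {
    idx <- match(tables[[k]]$gene, genes)
    s <- sign(tables[[k]]$logFC)
    s[!is.na(s) & s == 0] <- NA               # zero logFC: no direction
    sgn[idx, k] <- s
    pm[idx, k] <- tables[[k]]$p
  }
  has_es <- !is.na(sgn)
  sig <- !is.na(pm) & pm < p_cutoff
  n_es <- rowSums(has_es)
  n_sig <- rowSums(sig & has_es)
  same_dir <- function(m) {
    # TRUE when all non-NA entries of each row share one sign
    rng_ok <- rowSums(m == 1, na.rm = TRUE) == 0 |
      rowSums(m == -1, na.rm = TRUE) == 0
    rng_ok
  }
  all_conc <- same_dir(sgn)
  sgn_sig <- sgn
  sgn_sig[!sig] <- NA
  cond_conc <- same_dir(sgn_sig) & rowSums(!is.na(sgn_sig)) >= 1
  status <- ifelse(n_es <= 1, "C",
                   ifelse(all_conc, "C", ifelse(cond_conc, "S", "D")))
  data.frame(gene = genes, database = database, status = status,
             n_studies_with_effect_size = n_es,
             n_studies_significant = n_sig,
             vacuous = n_es <= 1,
             stringsAsFactors = FALSE) |>
    structure(class = c("concordance", "data.frame"))
}

#' Summarize concordance statuses
#'
#' @param records a `concordance` data.frame from [classify_concordance()].
#' @return data.frame with one row per status (C, S, D): count and percentage
#'   (one decimal place).
#' @export
summarize_concordance <- function(records) {
  if (!nrow(records)) stopf("no concordance records to summarize")
  counts <- vapply(c("C", "S", "D"), function(s) sum(records$status == s), 0L)
  data.frame(status = c("C", "S", "D"),
             n = as.integer(counts),
             percent = round(100 * counts / sum(counts), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}
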