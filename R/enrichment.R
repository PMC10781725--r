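#' Over-representation analysis of a gene list against gene-set collections
#'
#' For each pathway, membership is first intersected with the background
#' universe; pathways with fewer than `min_pathway_size` background members
#' are excluded (small pathways resist interpretation).  The overlap k between
#' the DEG list (size n) and the pathway (size m within a background of size
#' N) is tested with the one-sided hypergeometric upper tail
#' \eqn{P(X \ge k)}.  Rows are retained when k is at least `min_overlap`, the
#' enrichment ratio (k/n)/(m/N) is at least `min_enrichment`, and p is below
#' `p_cutoff`; results are sorted by p ascending.  A Benjamini-Hochberg column
#' is included for information only — the selection uses raw p-values.
#'
#' @param deg_genes character vector of DEG symbols (must be a subset of the
#'   background).
#' @param background character vector: the gene universe actually tested (the
#'   genes that overlapped across studies).
#' @param sets a [gene_set_collection()].
#' @param min_overlap minimum k.
#' @param min_enrichment minimum enrichment ratio.
#' @param p_cutoff p-value cutoff.
#' @param min_pathway_size minimum pathway size within the background.
#' @return data.frame of class `enrichment_result`: `pathway`, `k`, `m`, `n`,
#'   `N`, `ratio`, `p`, `bh_q`, `neg_log10_p`, `overlap` (formatted "k/m"),
#'   `genes_found`.
#' @export
enrich <- function(deg_genes, background, sets,
                   min_overlap = 3, min_enrichment = 1,
                   p_cutoff = 0.05, min_pathway_size = 6) {
  deg_genes <- unique(normalize_gene(deg_genes))
  background <- unique(normalize_gene(background))
  if (!length(background)) stopf("empty background universe")
  outside <- setdiff(deg_genes, background)
  if (length(outside)) {
    stopf("DEG genes not in the background: %s",
          paste(utils::head(outside, 5), collapse = ", "))
  }
  N <- length(background)
  n <- length(deg_genes)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], background)
    m <- length(members)
    if (m < min_pathway_size) return(NULL)
    found <- intersect(deg_genes, members)
    k <- length(found)
    p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    ratio <- if (n > 0 && m > 0) (k / n) / (m / N) else 0
    data.frame(pathway = nm, k = k, m = m, n = n, N = N,
               ratio = ratio, p = p,
               genes_found = paste(sort(found), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame(pathway = character(), k = integer(),
                                      m = integer(), n = integer(), N = integer(),
                                      ratio = numeric(), p = numeric(),
                                      genes_found = character(),
                                      stringsAsFactors = FALSE)
  res$bh_q <- if (nrow(res)) stats::p.adjust(res$p, "BH") else numeric()
  keep <- res$k >= min_overlap & res$ratio >= min_enrichment & res$p < p_cutoff
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Format an enrichment result for reporting
#'
#' Adds the -log10(p) column and the "k/m" overlap string used in pathway
#' tables.
#'
#' @param rows an `enrichment_result` from [enrich()].
#' @return data.frame with `pathway`, `overlap` ("k/m"), `neg_log10_p`,
#'   `ratio`, `genes_found`.
#' @export
report_enrichment <- function(rows) {
  data.frame(pathway = rows$pathway,
             overlap = sprintf("%d/%d", rows$k, rows$m),
             neg_log10_p = -log10(rows$p),
             ratio = rows$ratio,
             genes_found = rows$genes_found,
             stringsAsFactors = FALSE)
}
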