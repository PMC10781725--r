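#' Build the up/down disease query signature from meta-analysis results
#'
#' Keeps common DEGs dysregulated in the same direction in both databases,
#' based on the sign of the pooled (inverse-p-weighted average) log-fold
#' change: `up` genes are positive in both databases, `down` genes negative in
#' both.  Mixed-direction genes are excluded and reported.
#'
#' @param meta a `meta_gene_result` from [select_common_degs()].
#' @return list with `up`, `down` (character vectors) and `excluded` (mixed
#'   or direction-less common DEGs).
#' @export
build_query <- function(meta) {
  stopifnot(inherits(meta, "meta_gene_result"))
  cd <- meta[meta$is_common_deg, , drop = FALSE]
  if (!nrow(cd)) stopf("no common DEGs: cannot build a query signature")
  up <- cd$gene[!is.na(cd$direction) & cd$direction == "up"]
  down <- cd$gene[!is.na(cd$direction) & cd$direction == "down"]
  excluded <- setdiff(cd$gene, c(up, down))
  list(up = up, down = down, excluded = excluded)
}

#' Score perturbagens against a disease signature
#'
#' Per perturbagen, the connectivity (concordance) score is the correlation
#' between the perturbagen's log-fold-changes restricted to the matched query
#' genes and the query direction vector (+1 for up genes, -1 for down genes);
#' Pearson by default, Spearman as a rank-based option.  Scores near -1 mean
#' the perturbagen reverses the disease signature.  Perturbagens matching
#' fewer than `min_matched` query genes, or with zero variance over the
#' matched genes, are skipped with a warning.
#'
#' @param up,down character vectors of up-/down-regulated query genes.
#' @param lib a [perturbagen_library()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_matched minimum query genes present in the library gene space.
#' @return data.frame of class `connectivity_result`, sorted ascending by
#'   score: `perturbagen`, `score`, `n_matched`.
#' @export
connectivity_scores <- function(up, down, lib,
                                method = c("pearson", "spearman"),
                                min_matched = 10) {
  method <- match.arg(method)
  stopifnot(inherits(lib, "perturbagen_library"))
  up <- unique(normalize_gene(up))
  down <- unique(normalize_gene(down))
  both <- intersect(up, down)
  if (length(both)) stopf("genes in both up and down sets: %s", both[1])
  query <- c(up, down)
  dirvec <- c(rep(1, length(up)), rep(-1, length(down)))
  matched <- query %in% lib$genes
  if (sum(matched) < min_matched) {
    stopf("only %d query genes match the library gene space (min_matched = %d)",
          sum(matched), min_matched)
  }
  q <- query[matched]
  d <- dirvec[matched]
  sub <- lib$logfc[, q, drop = FALSE]
  rows <- lapply(seq_len(nrow(sub)), function(i) {
    v <- sub[i, ]
    if (stats::sd(v) == 0) {
      warnf("perturbagen '%s' has zero variance over matched genes; skipped",
            lib$perturbagens[i])
      return(NULL)
    }
    data.frame(perturbagen = lib$perturbagens[i],
               score = stats::cor(v, d, method = method),
               n_matched = length(q), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("connectivity_result", "data.frame")
  out
}

#' Flag reversal (discordant) perturbagens
#'
#' @param rows a `connectivity_result`.
#' @param cutoff score threshold; perturbagens scoring at or below it
#'   (inclusive) are flagged as reversal candidates.
#' @return the rows with a `discordant` logical column; only flagged rows are
#'   returned.
#' @export
select_discordant <- function(rows, cutoff = -0.321) {
  rows$discordant <- rows$score <= cutoff
  rows[rows$discordant, , drop = FALSE]
}
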