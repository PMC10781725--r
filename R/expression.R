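#' Construct an expression study
#'
#' A genes-by-samples expression matrix with a two-level case/control group
#' label per sample and a transform state tracking where the study sits in the
#' preprocessing chain (`raw` intensities, `log2`, or quantile-`normalized`).
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param genes gene symbols, one per row (duplicates allowed until
#'   [resolve_duplicates()]).
#' @param samples unique sample ids, one per column.
#' @param group character/factor of length `ncol(values)` with exactly two
#'   levels; the level named `"case"` (if present) is the case arm, otherwise
#'   the second level sorted.
#' @param study_id study identifier.
#' @param transform one of `"raw"`, `"log2"`, `"normalized"`.
#' @return an object of class `expression_study`.
#' @export
expression_study <- function(values, genes, samples, group,
                             study_id = "study",
                             transform = c("raw", "log2", "normalized")) {
  transform <- match.arg(transform)
  values <- as.matrix(values)
  if (nrow(values) != length(genes) || ncol(values) != length(samples)) {
    stopf("matrix dimensions (%d x %d) do not match %d genes / %d samples",
          nrow(values), ncol(values), length(genes), length(samples))
  }
  if (anyDuplicated(samples)) stopf("duplicate sample ids in study '%s'", study_id)
  group <- as.character(group)
  if (length(group) != length(samples)) {
    stopf("group labels must match sample count")
  }
  lev <- unique(group)
  if (length(lev) != 2) {
    stopf("group labels must cover exactly two levels, got: %s",
          paste(lev, collapse = ", "))
  }
  case_level <- if ("case" %in% lev) "case" else sort(lev)[2]
  dimnames(values) <- list(normalize_gene(genes), samples)
  structure(list(values = values,
                 genes = rownames(values),
                 samples = samples,
                 group = group,
                 case_level = case_level,
                 study_id = study_id,
                 transform = transform,
                 raw_values = NULL),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study '%s': %d genes x %d samples (%d %s / %d other), state=%s\n",
              x$study_id, nrow(x$values), ncol(x$values),
              sum(x$group == x$case_level), x$case_level,
              sum(x$group != x$case_level), x$transform))
  invisible(x)
}
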