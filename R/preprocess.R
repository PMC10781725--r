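#' Decide whether a raw study needs log2 transformation
#'
#' The rule, applied to the pooled matrix entries: transform if the 99th
#' quantile exceeds 100, or the range (max - min) exceeds 50 while the first
#' quartile is positive.  Quantiles use the linear-interpolation definition
#' (R's type 7) over all entries pooled.
#'
#' @param study an `expression_study` in the `raw` state.
#' @return `TRUE` if the study should be log2-transformed.
#' @export
needs_log2 <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  v <- as.vector(study$values)
  if (!length(v)) stopf("empty expression matrix in study '%s'", study$study_id)
  q <- stats::quantile(v, c(0.25, 0.99), names = FALSE)
  rng <- max(v) - min(v)
  unname(q[2] > 100 || (rng > 50 && q[1] > 0))
}

#' Apply log2 transformation
#'
#' Values become `log2(x + offset)`.  The offset defaults to 1 when the matrix
#' contains values at or below zero (avoiding non-finite results) and 0
#' otherwise, so clean intensity data are left untouched.
#'
#' @param study an `expression_study`.
#' @param offset pseudo-value added before the log; `NULL` picks 0 or 1 as
#'   described.
#' @return the study with transformed values, state `log2`, and the raw
#'   matrix retained in `raw_values` for the low-expression filter.
#' @export
log2_transform <- function(study, offset = NULL) {
  stopifnot(inherits(study, "expression_study"))
  if (is.null(offset)) offset <- if (any(study$values <= 0)) 1 else 0
  study$raw_values <- study$raw_values %||% study$values
  study$values <- log2(study$values + offset)
  study$transform <- "log2"
  study
}

#' Filter genes with low expression
#'
#' Drops genes whose raw (pre-transformation) values are negative in strictly
#' more than half of the samples, except genes in `keep_genes` — the gene
#' symbols already established in the companion database, which must survive
#' so the meta-analysis can intersect universes.
#'
#' @param study an `expression_study`; the negativity test always uses the
#'   pre-transformation matrix (kept by [log2_transform()]) when one exists.
#' @param keep_genes character vector of symbols exempt from filtering.
#' @return the filtered study, with attribute `dropped` listing removed genes.
#' @export
filter_low_expression <- function(study, keep_genes = character()) {
  stopifnot(inherits(study, "expression_study"))
  raw <- study$raw_values %||% study$values
  keep_genes <- normalize_gene(keep_genes)
  neg_frac <- rowMeans(raw < 0)
  drop <- neg_frac > 0.5 & !(study$genes %in% keep_genes)
  dropped <- study$genes[drop]
  study$values <- study$values[!drop, , drop = FALSE]
  if (!is.null(study$raw_values)) {
    study$raw_values <- study$raw_values[!drop, , drop = FALSE]
  }
  study$genes <- study$genes[!drop]
  attr(study, "dropped") <- dropped
  study
}

#' Quantile-normalize an expression matrix across samples
#'
#' Every sample's sorted values are replaced by the across-sample mean of
#' sorted values; ties within a sample receive the average of the reference
#' values at their rank positions.  Afterwards every column has the identical
#' sorted vector.
#'
#' @param study an `expression_study` (state `log2` or later).
#' @return the study with normalized values, state `normalized`.
#' @export
quantile_normalize <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  m <- study$values
  if (ncol(m) < 2) {
    warnf("single-sample study '%s': quantile normalization is a no-op",
          study$study_id)
    study$transform <- "normalized"
    return(study)
  }
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # non-integer ranks (ties) take the mean of the bracketing reference values
    lo <- ref[floor(r)]
    hi <- ref[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(m)
  study$values <- out
  study$transform <- "normalized"
  study
}

#' Resolve duplicate gene symbols
#'
#' For each duplicated symbol only the row with the greatest across-sample
#' variance is retained; exact variance ties keep the first-occurring row.
#'
#' @param study an `expression_study`.
#' @return the study with unique gene symbols.
#' @export
resolve_duplicates <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (!anyDuplicated(study$genes)) return(study)
  v <- apply(study$values, 1, stats::var)
  ord <- order(factor(study$genes, levels = unique(study$genes)),
               -v, seq_along(v))
  first <- !duplicated(study$genes[ord])
  keep <- sort(ord[first])
  study$values <- study$values[keep, , drop = FALSE]
  if (!is.null(study$raw_values)) {
    study$raw_values <- study$raw_values[keep, , drop = FALSE]
  }
  study$genes <- study$genes[keep]
  rownames(study$values) <- study$genes
  study
}

#' Run the full per-study preprocessing chain
#'
#' Fixed order: log2 decision, transform (if the rule fires), low-expression
#' filter (always on pre-transformation values), quantile normalization,
#' duplicate resolution.
#'
#' @param study a raw `expression_study`.
#' @param keep_genes symbols exempt from the low-expression filter.
#' @return a normalized, de-duplicated `expression_study`.
#' @export
preprocess_study <- function(study, keep_genes = character()) {
  stopifnot(inherits(study, "expression_study"))
  if (study$transform == "raw") {
    if (needs_log2(study)) study <- log2_transform(study)
    study <- filter_low_expression(study, keep_genes)
    study <- quantile_normalize(study)
  }
  resolve_duplicates(study)
}
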