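#' Construct a differential-expression summary table
#'
#' The exchange object between every stage of the pipeline: one study's
#' per-gene summary with gene symbol, log2 fold-change (possibly unavailable),
#' and two-sided p-value.  Truncated ("partial") tables — studies that only
#' reported genes passing a significance threshold — carry that threshold.
#'
#' @param gene character vector of gene symbols (upper-cased, trimmed,
#'   must be unique).
#' @param p numeric p-values in \[0,1\].
#' @param logFC numeric log2 fold-changes, `NA` where unavailable.
#' @param t optional moderated statistics.
#' @param study_id study identifier.
#' @param reporting `"full"` or `"partial"`.
#' @param threshold truncation threshold for partial tables (every reported
#'   p must be at or below it).
#' @return a data.frame of class `dge_table` with attributes `study_id`,
#'   `reporting` and `threshold`.
#' @export
dge_table <- function(gene, p, logFC = NA_real_, t = NULL,
                      study_id = "study", reporting = c("full", "partial"),
                      threshold = NULL) {
  reporting <- match.arg(reporting)
  gene <- normalize_gene(gene)
  if (anyDuplicated(gene)) {
    stopf("duplicate gene symbols in DGE table '%s' (e.g. %s); resolve duplicates upstream with resolve_duplicates()",
          study_id, gene[duplicated(gene)][1])
  }
  p <- as.numeric(p)
  bad <- which(!is.finite(p) | p < 0 | p > 1)
  if (length(bad)) {
    stopf("p-value outside [0,1] in table '%s' at row %d (gene %s): %s",
          study_id, bad[1], gene[bad[1]], format(p[bad[1]]))
  }
  if (reporting == "partial") {
    if (is.null(threshold)) {
      stopf("partial DGE table '%s' must declare its truncation threshold",
            study_id)
    }
    check_prob(threshold, "threshold", open = FALSE)
    if (any(p > threshold + 1e-12)) {
      stopf("partial table '%s' contains p above its threshold %g",
            study_id, threshold)
    }
  }
  tab <- data.frame(gene = gene, logFC = as.numeric(logFC), p = p,
                    stringsAsFactors = FALSE)
  if (!is.null(t)) tab$t <- as.numeric(t)
  structure(tab,
            class = c("dge_table", "data.frame"),
            study_id = study_id,
            reporting = reporting,
            threshold = if (reporting == "partial") threshold else NULL)
}

#' Read a per-study differential-expression table from TSV
#'
#' Expects a tab-separated file with a header naming a gene column, a p-value
#' column and (optionally) a log-fold-change column.  Column names are matched
#' case-insensitively against common spellings (`gene`/`symbol`,
#' `p`/`pvalue`/`p.value`, `logfc`/`log2fc`/`lfc`).  Partial tables must either
#' declare their truncation threshold or fall back to the maximum reported p.
#'
#' @param path file path.
#' @param reporting `"full"` or `"partial"`.
#' @param threshold truncation threshold for partial tables; if `NULL` for a
#'   partial table, set to the maximum reported p-value (automatic fallback).
#' @param study_id study identifier; defaults to the file name.
#' @return a [dge_table()].
#' @export
read_dge_table <- function(path, reporting = c("full", "partial"),
                           threshold = NULL, study_id = NULL) {
  reporting <- match.arg(reporting)
  if (!file.exists(path)) stopf("DGE table not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  nm <- tolower(names(df))
  gcol <- which(nm %in% c("gene", "symbol", "gene_symbol", "genesymbol"))[1]
  pcol <- which(nm %in% c("p", "pvalue", "p.value", "p_value", "pval"))[1]
  fcol <- which(nm %in% c("logfc", "log2fc", "lfc", "log_fc"))[1]
  if (is.na(gcol) || is.na(pcol)) {
    stopf("format error in %s: need a gene column and a p column (header: %s)",
          path, paste(names(df), collapse = ", "))
  }
  if (reporting == "partial" && is.null(threshold)) {
    threshold <- max(as.numeric(df[[pcol]]))
  }
  dge_table(gene = df[[gcol]],
            p = df[[pcol]],
            logFC = if (is.na(fcol)) NA_real_ else df[[fcol]],
            study_id = study_id %||% sub("\\.[^.]*$", "", basename(path)),
            reporting = reporting,
            threshold = threshold)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Members are de-duplicated preserving first occurrence; empty sets and
#' duplicate set names are errors.
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors of class `gene_set_collection`,
#'   with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warnf("empty GMT file: %s", path)
    return(gene_set_collection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3)
  if (length(short)) {
    stopf("format error in %s line %d: GMT lines need name, description and at least one member",
          path, short[1])
  }
  sets <- lapply(fields, function(f) unique(normalize_gene(f[-(1:2)])))
  names(sets) <- vapply(fields, `[`, "", 1L)
  desc <- vapply(fields, `[`, "", 2L)
  gene_set_collection(sets, description = desc)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene symbols.
#' @param description optional per-set descriptions.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      stopf("gene set names must be present and unique")
    }
    sets <- lapply(sets, function(s) unique(normalize_gene(s)))
    if (any(!lengths(sets))) stopf("empty gene sets are not allowed")
  }
  structure(sets, class = "gene_set_collection",
            description = description %||% rep("", length(sets)))
}

# ---- generic TSV result writer/readers ------------------------------------

# Floating-point columns are serialized with %.17g: fixed formatting (repeated
# runs are byte-identical) that still round-trips doubles losslessly.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, "")
  out
}

#' Write a results table as annotated TSV
#'
#' Deterministic column order, tab-separated, with `#`-prefixed metadata
#' header lines carrying the configuration hash and seed so outputs are
#' self-describing and byte-identical across reruns.  Read back with
#' [read_results()].
#'
#' @param results a data.frame (possibly empty).
#' @param path output path.
#' @param config optional `psymeta_config`; its hash and seed go in the header.
#' @param meta optional named character vector of extra header fields.
#' @return invisibly, the path.
#' @export
write_results <- function(results, path, config = NULL, meta = NULL) {
  stopifnot(is.data.frame(results))
  hdr <- c(sprintf("# psymeta_version=%s",
                   as.character(utils::packageVersion("psymeta"))))
  if (!is.null(config)) {
    hdr <- c(hdr,
             sprintf("# config_hash=%s", config_hash(config)),
             sprintf("# seed=%d", config$rng_seed))
  }
  if (!is.null(meta)) {
    hdr <- c(hdr, sprintf("# %s=%s", names(meta), as.character(meta)))
  }
  cols <- lapply(results, function(col) {
    if (is.double(col)) format_num(col) else as.character(col)
  })
  body <- if (nrow(results)) {
    do.call(paste, c(cols, sep = "\t"))
  } else {
    character()
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, paste(names(results), collapse = "\t"), body), con)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path file path.
#' @param numeric_cols column names to coerce to numeric; by default every
#'   column that parses cleanly as numeric.
#' @return a data.frame with a `meta` attribute holding the header fields.
#' @export
read_results <- function(path, numeric_cols = NULL) {
  if (!file.exists(path)) stopf("results file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- NULL
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", hdr)
    eq <- regexpr("=", kv, fixed = TRUE)
    meta <- stats::setNames(substring(kv, eq + 1), substring(kv, 1, eq - 1))
  }
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stopf("no header row in %s", path)
  cn <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (length(body) == 1) {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(cn)), cn),
                        stringsAsFactors = FALSE)
  } else {
    rows <- strsplit(body[-1], "\t", fixed = TRUE)
    mat <- do.call(rbind, rows)
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- cn
  }
  for (j in seq_along(df)) {
    coerce <- if (is.null(numeric_cols)) {
      all(is.na(df[[j]]) | df[[j]] == "NA" |
            !is.na(suppressWarnings(as.numeric(df[[j]]))))
    } else {
      names(df)[j] %in% numeric_cols
    }
    if (coerce && names(df)[j] != "gene") {
      suppressWarnings(df[[j]] <- as.numeric(df[[j]]))
    }
  }
  attr(df, "meta") <- meta
  df
}

#' Write a DGE table as TSV (round-trips through [read_dge_table()])
#'
#' @param tab a [dge_table()].
#' @param path output path.
#' @param config optional config for the provenance header.
#' @return invisibly, the path.
#' @export
write_dge_table <- function(tab, path, config = NULL) {
  stopifnot(inherits(tab, "dge_table"))
  meta <- c(study_id = attr(tab, "study_id"),
            reporting = attr(tab, "reporting"))
  if (!is.null(attr(tab, "threshold"))) {
    meta <- c(meta, threshold = sprintf("%.17g", attr(tab, "threshold")))
  }
  write_results(as.data.frame(tab), path, config = config, meta = meta)
}
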