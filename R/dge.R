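# Newton solve of trigamma(y) = x, needed by the method-of-moments fit of the
# prior df.  trigamma is convex decreasing on (0, Inf); the update below
# (on 1/trigamma scale) converges monotonically from y0 = 0.5 + 1/x.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(if (xi > 0) 0 else Inf)
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (-dif / y < 1e-10) break
    }
    y
  }, 0)
}

# Method-of-moments fit of a scaled-F prior to the sample variances s2 (each
# on df degrees of freedom): log s2 - digamma(df/2) + log(df/2) has variance
# trigamma(df/2) + trigamma(d0/2) under the model, which identifies d0; the
# prior variance s0^2 then comes from the mean.
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  if (!any(ok)) stopf("zero within-group variance for all genes: variance prior unestimable")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- mean(s2[ok])
  }
  list(prior_df = d0, prior_var = s0)
}

#' Two-group differential expression with a moderated t-statistic
#'
#' For each gene: logFC = mean(case) - mean(control); the pooled residual
#' variance is shrunk toward a prior estimated from the across-gene variance
#' distribution (empirical Bayes, shrunken variance
#' \eqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)} with hyperparameters by
#' method-of-moments on log variances); the two-sided p-value comes from the t
#' distribution on \eqn{d + d_0} degrees of freedom.  No multiple-testing
#' adjustment is applied: the meta-analysis consumes raw p-values.
#'
#' @param study a normalized `expression_study` with at least 2 samples per
#'   group.
#' @param prior_df override the estimated prior degrees of freedom; `0` gives
#'   the ordinary pooled-variance two-sample t-test, `Inf` full shrinkage to
#'   the prior variance.
#' @return a [dge_table()] with columns `gene`, `logFC`, `p`, `t`.
#' @export
moderated_t_dge <- function(study, prior_df = NULL) {
  stopifnot(inherits(study, "expression_study"))
  is_case <- study$group == study$case_level
  n1 <- sum(is_case); n2 <- sum(!is_case)
  if (n1 < 2 || n2 < 2) stopf("need at least 2 samples per group, got %d/%d", n1, n2)
  if (anyDuplicated(study$genes)) {
    stopf("duplicate gene symbols; run resolve_duplicates() first")
  }
  x1 <- study$values[, is_case, drop = FALSE]
  x2 <- study$values[, !is_case, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  logfc <- m1 - m2
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  single_gene <- length(s2) == 1
  if (is.null(prior_df)) {
    if (single_gene) {
      warnf("single gene: falling back to the ordinary two-sample t-test")
      prior <- list(prior_df = 0, prior_var = 0)
    } else {
      prior <- fit_variance_prior(s2, df)
    }
  } else {
    prior <- list(prior_df = prior_df,
                  prior_var = if (prior_df > 0) {
                    fit_variance_prior(s2, df)$prior_var
                  } else 0)
  }
  d0 <- prior$prior_df
  s2_tilde <- if (is.infinite(d0)) {
    rep(prior$prior_var, length(s2))
  } else {
    (d0 * prior$prior_var + df * s2) / (d0 + df)
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, logfc / se, 0)
  total_df <- min(d0 + df, .Machine$double.xmax)
  p <- 2 * stats::pt(-abs(tstat), df = total_df)
  out <- dge_table(gene = study$genes, p = p, logFC = logfc, t = tstat,
                   study_id = study$study_id, reporting = "full")
  attr(out, "prior") <- prior
  out
}

#' Truncate a full DGE table at a significance threshold
#'
#' Emulates studies that report significant genes only: rows with p above the
#' threshold are removed, the table is marked `partial`, and the threshold is
#' recorded for downstream imputation.
#'
#' @param table a full [dge_table()].
#' @param threshold truncation p threshold in (0, 1\].
#' @return a partial [dge_table()].
#' @export
truncate_table <- function(table, threshold) {
  stopifnot(inherits(table, "dge_table"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stopf("truncation threshold must lie in (0,1], got %s", format(threshold))
  }
  keep <- table$p <= threshold
  dge_table(gene = table$gene[keep], p = table$p[keep],
            logFC = table$logFC[keep],
            t = if (!is.null(table$t)) table$t[keep] else NULL,
            study_id = attr(table, "study_id"),
            reporting = "partial", threshold = threshold)
}
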