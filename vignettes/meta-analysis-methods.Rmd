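---
title: "Cross-database transcriptomic meta-analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-database transcriptomic meta-analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psymeta)
```

# The problem and the two-level design

The package asks whether two disease conditions — studied in two separate
collections of case/control transcriptomic studies ("databases") — share a
gene-expression signature. The practical obstacles it is built around are
the realities of published summary data: studies within a database disagree
in direction for many genes; some studies publish only the genes passing a
significance threshold (truncated tables); some publish p-values without
fold-changes; and one database may have no raw expression data at all.

The analysis is two-level. Study p-values are first combined *within* each
database with the adaptively weighted Fisher method (AW-Fisher), after
imputing the censored p-values of truncated tables; the two database-level
p-values are then combined *across* databases with the same method. A gene
is a **common DEG** when the cross-database combined p is below
`alpha_meta` (default 0.05) with weight (1,1) — i.e. both databases
contribute evidence — *and* the gene's per-database direction pattern is
concordant (C) or conditionally concordant (S) in both databases.

# Per-study differential expression

Expression matrices are assumed to be (or become) approximately Gaussian
intensities on the log2 scale. Preprocessing is a fixed chain:

1. **log2 decision rule.** Transform when the pooled 99th percentile
   exceeds 100, or the pooled range exceeds 50 with a positive pooled first
   quartile. The rule's quantiles are computed over the pooled matrix with
   the linear-interpolation definition; a per-sample variant would be
   defensible, but the pooled reading is the simpler one and is what the
   implementation pins (`needs_log2`). The log offset is +1 only when the
   matrix contains non-positive values, so clean intensity data are left
   untouched.
2. **Low-expression filter.** A gene is dropped when its *raw* (always
   pre-transformation) values are negative in strictly more than half the
   samples, unless the gene is protected by a `keep_genes` list — the gene
   symbols already established in the companion database, which must
   survive for the cross-database intersection.
3. **Quantile normalization.** Each sample's sorted values are replaced by
   the cross-sample mean of sorted values; ties take the interpolated
   reference value at the average rank (this matches limma's
   `normalizeQuantiles(ties = TRUE)`, which the tests use as an independent
   cross-check).
4. **Duplicate resolution.** For duplicated gene symbols only the row with
   the greatest across-sample variance survives; exact ties keep the first
   occurrence (deterministic).

Differential expression uses the standard empirical-Bayes moderated t: the
pooled two-group variance $s_g^2$ on $d$ df is shrunk to
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$, with $(d_0, s_0^2)$
estimated by method-of-moments on $\log s_g^2$ (Newton inversion of the
trigamma function), and $p$ from the t distribution on $d + d_0$ df. Tests
verify exact agreement with limma's `lmFit`/`eBayes` (the package's own
implementation is kept so the prior df can be forced — `prior_df = 0`
recovers the ordinary pooled t-test exactly). No per-study multiple-testing
adjustment is applied: the meta-analysis consumes raw p-values.

# Concordance classification

Within a database each gene is labeled from the per-study signs of logFC:

* **C** — one direction across *all* studies reporting an effect size;
* **S** — not C, but one direction across all studies with $p <$
  `concordance_p_cutoff` (default 0.05) that report an effect size, with at
  least one such study;
* **D** — neither.

Pinned conventions where the rules are genuinely open: a zero logFC carries
no direction and is treated as a missing effect size; studies reporting p
but no logFC are excluded from the sign check; genes with an effect size in
at most one study are vacuously C and flagged; one significant study
suffices for S (requiring two would silently reclassify single-signal genes
as D). Note that under these rules a gene with *no* significant study and
imperfect sign agreement is D — in simulated data with independent noise
this makes D common among null genes (~40% in the reference scenario),
whereas real studies of a shared biological signal show far lower
discordance; the classifier is a filter, not an estimate of biology.

# Imputation for truncated tables and AW-Fisher

A truncated table with threshold $t$ tells us that each unreported gene has
$p \in (t, 1]$. The default imputation is the mean of that censored
interval, $(t+1)/2$ — for $t = 0.05$, an imputed $p = 0.525$ — because the
only information available about the missing value is the censoring
interval itself. A `grand_mean` switch imputes the mean of the study's
observed p-values instead, for users who prefer that reading of "mean
imputation"; it is systematically too small (observed p-values are all
below $t$) and is not the default. Truncation thresholds must be declared,
with an automatic fallback to the maximum reported p. Imputed entries are
flagged in the output for audit. The gene universe is the union of genes
over the database's tables; genes absent from a *full* table contribute
$p = 1$ (no evidence) rather than being dropped.

AW-Fisher enumerates all $2^K - 1$ binary study-inclusion vectors $w$,
computes the weighted Fisher statistic $T(w) = \sum_k w_k(-2\ln p_k)$ and
its chi-square$(2\sum w_k)$ upper tail, and takes the minimum tail
("candidate") p-value. Because that minimum is itself a selection, it is
calibrated against its Monte-Carlo null: a shared seeded table of `B`
(default 10,000) draws of $K$ independent uniforms, reduced to the null
distribution of the minimum candidate p. The combined p is
$(\#\{\text{null} \le \text{obs}\} + 1)/(B + 1)$, which floors it at
$1/(B+1)$ — so `monte_carlo_B` bounds the smallest reportable p, and the
all-null false-positive rate at 0.05 is correct to Monte-Carlo error
(checked at $\pm 0.02$ on 2,000 null genes). The closed-form null
approximation of the original AW-Fisher literature is deliberately not
used: the Monte-Carlo table is transparent and testable at desk scale.
Numerical pins: p-values are clamped to $[10^{-300}, 1]$ before logs;
candidate-p ties prefer the weight vector with more included studies, then
the lexicographically smallest (deterministic); enumeration is bounded at
$K \le 20$.

Pooled log-fold-changes use inverse-p weights over the studies reporting a
logFC: $\widehat{\text{logFC}}_g = \sum_s \text{logFC}_{gs}/p_{gs} \big/
\sum_s 1/p_{gs}$. Direction (up/down) requires the pooled logFC of *both*
databases to share the sign.

# Over-representation analysis

Membership-only ORA with the one-sided hypergeometric upper tail
$P(X \ge k)$, parameters mirroring the reference analysis: overlap
$k \ge 3$, enrichment ratio $(k/n)/(m/N) \ge 1$, $p < 0.05$, and pathways
with fewer than 6 members *within the background* excluded. The background
is the user's tested universe (the genes that overlapped across studies),
never the whole genome. Selection uses raw p-values; a Benjamini–Hochberg
column is emitted for information. This module is an explicit local
stand-in for web-service enrichment tools; it makes no attempt to reproduce
their pathway clustering.

# Biomarker prediction

Expression of each common DEG is centered and scaled to mean 0, sd 1
*within each study* — the standardization constants are per-study, so
nothing crosses the leave-one-study-out boundary (a test corrupts a held-out
study and asserts the training rows are bit-identical). The outer loop
holds out one study at a time; nested stratified 5-fold CV over the pooled
training samples tunes the grid (elastic net: mixing $\alpha \in \{0, 0.25,
0.5, 0.75, 1\}$ and 50 log-spaced $\lambda$; random forest: ntree
$\in \{500, 1000\}$, mtry $\in \{\sqrt p, p/3, p/2\}$); accuracy is the
fraction correct at the 0.5 probability threshold, and the reported figure
is the mean over held-out studies. Tuning optimizes that same accuracy —
the reported metric — rather than deviance or AUC. Feature rankings come
from one final tuned fit on all studies pooled: absolute nonzero
coefficients (elastic net) or permutation importance (random forest).

# Connectivity (reversal) scoring

The query is the same-direction common-DEG signature (up/down gene sets).
Each perturbagen's score is the Pearson correlation between its log-FCs
restricted to the matched query genes and the signed membership vector
(+1 up, −1 down); a Spearman option is available. Membership-only querying
is pinned because the reference workflow submits gene lists, not
magnitudes. Scores are antisymmetric under vector negation (exactly) and
invariant under positive rescaling (to machine precision); perturbagens
matching fewer than `min_matched = 10` query genes or with zero variance
over them are skipped. Reversal candidates are flagged at score
$\le -0.321$, inclusive, the conventional discordance cutoff carried as the
default.

# The synthetic-data generator

`sim_config()` describes two databases of case/control studies over one
gene universe: planted **shared** DEGs (same true sign in both databases),
**database-private** DEGs, and nulls. Expression is Gaussian on the log2
scale — baseline per gene $\sim N(7, 1)$, per-study per-gene offsets
$\sim N(0, 0.25)$ supplying between-study heterogeneity, residual sd 1 —
with cases shifted by sign × `effect_size`. Study streams are seed-split
(one child seed per database/study), so enlarging a scenario never changes
earlier studies' data. Truncated tables are produced by running the real
DGE module and dropping rows above the threshold (the last
`partial_fraction` of studies per database); logFC-free tables blank the
column (the first `logfc_missing_fraction`).

The generator emulates the *statistical* structure the meta-analysis
assumes — Gaussian log-intensities, direction-consistent shared signal,
independent study noise, truncated and partial reporting — and deliberately
not: probe-level artifacts, correlated gene-gene structure, batch effects
beyond mean offsets, or RNA-seq counts. Passing tests therefore demonstrate
correctness of the machinery under its own model, not performance on any
real dataset; the headline real-data quantities of the motivating study
(e.g. its 221-gene list or 0.71/0.73 CV accuracies) depend on sources that
are not packaged and are out of scope.

# Reference scenario and problem sizes

The recovery benchmark used by the test suite and `scripts/acceptance.R` is
5,000 genes, 200 shared and 100 private DEGs per database, effect size 1.0
log2 units, noise sd 1, 3 studies per database with 20 samples/arm, and one
truncated (p ≤ 0.05) study per database, with `monte_carlo_B = 10000`.
Pass bounds (sensitivity ≥ 0.95, observed FDR ≤ 0.30, and margins of 0.85 /
0.50 over the label-permuted null) were pinned from a 10-seed calibration
of this scenario and then frozen. Null calibration uses 2,000 all-null
genes with $K = 3$; prediction checks use a 5-study separable scenario
(effect 4, 5 planted genes) where LOSO accuracy must be exactly 1 and
label-permuted accuracy 0.5 ± 0.1. Smaller grids than the defaults are used
inside tests; the grids are configuration, not part of the method.

# Known limitations

* The Monte-Carlo combined p is granular at $1/(B+1)$; ranking genes below
  that floor relies on the stored minimum candidate p.
* Inverse-p logFC weights are heuristic (they ignore standard errors); a
  random-effects pooled estimate is out of scope by design.
* The concordance rules treat studies symmetrically; a single noisy study
  can demote a gene from C to S but never inflate evidence.
* Gene matching is by exact upper-cased symbol; no alias or ortholog
  mapping is attempted.
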