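test_that("the weighted Fisher statistic matches its closed form", {
  # worked value: p = (0.5, 0.5), w = (1,1)
  fs <- fisher_stat(c(0.5, 0.5), c(1, 1))
  expect_equal(fs$stat, -2 * log(0.25), tolerance = 1e-12)
  expect_equal(round(fs$stat, 4), 2.7726)
  expect_equal(round(fs$candidate_p, 4), 0.5966)
  expect_equal(fs$candidate_p, pchisq(fs$stat, 4, lower.tail = FALSE),
               tolerance = 1e-15)
  # single-study reduction
  fs1 <- fisher_stat(c(0.3, 0.02), c(0, 1))
  expect_equal(fs1$stat, -2 * log(0.02), tolerance = 1e-12)
  # degenerate all-ones p
  fs0 <- fisher_stat(c(1, 1), c(1, 1))
  expect_equal(fs0$stat, 0)
  expect_equal(fs0$candidate_p, 1)
  expect_error(fisher_stat(c(0.5, 0.5), c(0, 0)), "at least one")
  expect_error(fisher_stat(0.5, c(1, 1)), "equal length")
})

test_that("all-ones weights reproduce classical Fisher's method to 1e-12", {
  set.seed(41)
  for (K in 2:5) {
    p <- runif(K)
    fs <- fisher_stat(p, rep(1, K))
    classical <- pchisq(-2 * sum(log(p)), df = 2 * K, lower.tail = FALSE)
    expect_equal(fs$candidate_p, classical, tolerance = 1e-12)
  }
})

test_that("AW-Fisher matches the brute-force oracle exactly for K in 2..4", {
  set.seed(42)
  for (K in 2:4) {
    pmat <- matrix(runif(1000 * K), ncol = K)
    # sprinkle strong signals so nontrivial weights win
    pmat[sample(length(pmat), 200)] <- 10^(-runif(200, 1, 12))
    res <- aw_fisher(pmat, B = 200, seed = 1)
    for (i in seq_len(nrow(pmat))) {
      oracle <- aw_oracle(pmat[i, ])
      expect_identical(res$weight[i], paste(oracle$w, collapse = ""))
      expect_equal(res$min_candidate_p[i], oracle$cand, tolerance = 1e-14)
    }
  }
})

test_that("AW-Fisher single-study and two-study behaviour", {
  # K = 1: combined p equals the input up to Monte-Carlo resolution
  r1 <- aw_fisher(matrix(c(0.3, 0.9, 0.02), ncol = 1), B = 20000, seed = 2)
  expect_lt(max(abs(r1$combined_p - c(0.3, 0.9, 0.02))), 0.02)
  expect_true(all(r1$weight == "1"))
  # dropping a null study minimizes the candidate p
  expect_equal(aw_fisher(c(0.001, 0.9), B = 500, seed = 3)$weights, c(1, 0))
  # two strong studies are both included
  expect_equal(aw_fisher(c(0.01, 0.01), B = 500, seed = 3)$weights, c(1, 1))
  expect_error(aw_fisher(matrix(numeric(), 0, 2)), "at least one")
})

test_that("decreasing one study p never increases the min candidate p", {
  set.seed(43)
  for (rep in 1:200) {
    K <- sample(2:5, 1)
    p <- runif(K)
    k <- sample(K, 1)
    p2 <- p
    p2[k] <- p[k] * runif(1)
    m1 <- aw_fisher(p, B = 100, seed = 1)$min_candidate_p
    m2 <- aw_fisher(p2, B = 100, seed = 1)$min_candidate_p
    expect_lte(m2, m1 + 1e-15)
  }
})

test_that("combined p-values are calibrated under the global null", {
  set.seed(44)
  pmat <- matrix(runif(2000 * 3), ncol = 3)
  res <- aw_fisher(pmat, B = 10000, seed = 7)
  expect_lt(abs(mean(res$combined_p < 0.05) - 0.05), 0.02)
})

test_that("censored-interval mean imputation completes partial tables", {
  full <- dge_table(c("A", "B", "C"), p = c(0.2, 0.5, 0.9),
                    logFC = c(1, -1, 0), study_id = "f")
  part <- dge_table(c("A", "B"), p = c(0.01, 0.04), logFC = c(2, -2),
                    study_id = "p", reporting = "partial", threshold = 0.05)
  out <- impute_missing_pvalues(list(full, part))
  comp <- out[[2]]
  expect_equal(comp$p[comp$gene == "C"], (0.05 + 1) / 2)  # = 0.525
  expect_true(comp$imputed[comp$gene == "C"])
  expect_equal(comp$p[comp$gene == "A"], 0.01)            # reported row untouched
  expect_false(any(out[[1]]$imputed))
  # grand-mean alternative
  out2 <- impute_missing_pvalues(list(full, part), method = "grand_mean")
  expect_equal(out2[[2]]$p[out2[[2]]$gene == "C"], mean(c(0.01, 0.04)))
  # degenerate threshold 1.0: the censored interval collapses to p = 1
  part1 <- dge_table(c("A", "B"), p = c(0.3, 0.6), logFC = c(1, 1),
                     study_id = "p1", reporting = "partial", threshold = 1)
  out3 <- impute_missing_pvalues(list(full, part1))
  expect_equal(out3[[2]]$p[out3[[2]]$gene == "C"], 1.0)
})

test_that("inverse-p-weighted logFC pooling follows the formula", {
  lf <- rbind(G1 = c(1.0, 0.0), G2 = c(0.5, NA), G3 = c(1, 3))
  pp <- rbind(G1 = c(0.01, 0.1), G2 = c(0.2, 0.5), G3 = c(0.3, 0.3))
  pooled <- combine_logfc(lf, pp)
  expect_equal(unname(pooled["G1"]), (100 * 1 + 10 * 0) / 110)  # 0.9091
  expect_equal(round(pooled[["G1"]], 4), 0.9091)
  expect_equal(unname(pooled["G2"]), 0.5)        # single reporting study
  expect_equal(unname(pooled["G3"]), 2)          # equal p: arithmetic mean
  none <- combine_logfc(rbind(G4 = c(NA_real_, NA_real_)),
                        rbind(G4 = c(0.1, 0.2)))
  expect_true(is.na(none[["G4"]]))
})

test_that("cross-database combination intersects universes and logs drops", {
  ma <- data.frame(gene = c("A", "B", "C"), combined_p = c(0.001, 0.001, 0.5))
  mb <- data.frame(gene = c("A", "B", "D"), combined_p = c(0.001, 0.99, 0.5))
  cross <- combine_databases(ma, mb, B = 5000, seed = 5)
  expect_setequal(cross$gene, c("A", "B"))
  expect_setequal(attr(cross, "dropped"), c("C", "D"))
  expect_equal(cross$weight[cross$gene == "A"], "11")
  expect_lt(cross$combined_p[cross$gene == "A"], 0.05)
  expect_equal(cross$weight[cross$gene == "B"], "10")
  expect_error(combine_databases(ma[1, ][0, ], mb), "empty")
})

test_that("common DEGs require p, weight (1,1) and concordance in both", {
  cross <- data.frame(gene = c("A", "B", "C"),
                      p_a = c(0.001, 0.001, 0.001),
                      p_b = c(0.002, 0.9, 0.002),
                      combined_p = c(0.01, 0.01, 0.01),
                      weight = c("11", "10", "11"),
                      stringsAsFactors = FALSE)
  conc <- function(db, st) data.frame(gene = c("A", "B", "C"), database = db,
                                      status = st, stringsAsFactors = FALSE)
  res <- select_common_degs(cross,
                            conc("A", c("C", "C", "D")),
                            conc("B", c("S", "C", "C")),
                            pooled_logfc_a = c(A = 1, B = 1, C = 1),
                            pooled_logfc_b = c(A = 0.5, B = 1, C = -1),
                            alpha = 0.05)
  expect_true(res$is_common_deg[res$gene == "A"])    # p ok, 11, (C,S)
  expect_false(res$is_common_deg[res$gene == "B"])   # weight 10
  expect_false(res$is_common_deg[res$gene == "C"])   # D in database A
  expect_equal(res$direction[res$gene == "A"], "up")
  expect_equal(res$direction[res$gene == "C"], "mixed")
})

test_that("meta_database imputes, aligns and stays deterministic", {
  set.seed(45)
  full1 <- dge_table(sprintf("G%02d", 1:20), p = runif(20), logFC = rnorm(20),
                     study_id = "f1")
  full2 <- dge_table(sprintf("G%02d", 1:20), p = runif(20), logFC = rnorm(20),
                     study_id = "f2")
  part <- truncate_table(dge_table(sprintf("G%02d", 1:20),
                                   p = sort(runif(20)), logFC = rnorm(20),
                                   study_id = "p1"), 0.5)
  r1 <- meta_database(list(full1, full2, part), B = 1000, seed = 6)
  r2 <- meta_database(list(full1, full2, part), B = 1000, seed = 6)
  expect_identical(r1$combined_p, r2$combined_p)
  expect_setequal(r1$gene, sprintf("G%02d", 1:20))
  pm <- attr(r1, "p_matrix")
  expect_equal(dim(pm), c(20, 3))
  expect_error(impute_missing_pvalues(list(structure(part, threshold = NULL))),
               "threshold")
})
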