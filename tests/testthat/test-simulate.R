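test_that("expression studies are reproducible and stream-split by study", {
  cfg <- sim_config(n_genes = 1000, n_studies = 3, n_per_arm = 10, seed = 1)
  st1 <- simulate_expression_study(cfg, "A", 1)
  st1b <- simulate_expression_study(cfg, "A", 1)
  expect_identical(st1$values, st1b$values)
  expect_equal(dim(st1$values), c(1000, 20))

  # adding studies must not shift earlier studies' data
  cfg5 <- sim_config(n_genes = 1000, n_studies = 5, n_per_arm = 10, seed = 1)
  expect_identical(simulate_expression_study(cfg5, "A", 1)$values, st1$values)
  # different databases and indices draw from different streams
  expect_false(identical(simulate_expression_study(cfg, "B", 1)$values, st1$values))
  expect_false(identical(simulate_expression_study(cfg, "A", 2)$values, st1$values))

  expect_error(simulate_expression_study(sim_config(n_per_arm = 2), "A", 1),
               "3 samples per arm")
})

test_that("ground truth partitions genes with matched shared signs", {
  cfg <- sim_config(n_genes = 500, n_shared_deg = 50, n_private_deg = 30, seed = 2)
  tr <- ground_truth(cfg)
  expect_equal(table(tr$role)[["shared"]], 50)
  expect_equal(table(tr$role)[["private_A"]], 30)
  expect_equal(sum(tr$role == "null"), 500 - 50 - 60)
  sh <- tr$role == "shared"
  expect_identical(tr$sign_A[sh], tr$sign_B[sh])
  expect_true(all(is.na(tr$sign_B[tr$role == "private_A"])))
  expect_error(sim_config(n_genes = 100, n_shared_deg = 60, n_private_deg = 30),
               "exceed")
})

test_that("zero effect size makes planted genes indistinguishable from null", {
  cfg <- sim_config(n_genes = 2000, n_shared_deg = 500, n_private_deg = 0,
                    n_per_arm = 10, effect_size = 0, seed = 3)
  tr <- ground_truth(cfg)
  tab <- moderated_t_dge(simulate_expression_study(cfg, "A", 1, truth = tr))
  planted <- tab$p[tr$role == "shared"]
  null <- tab$p[tr$role == "null"]
  expect_gt(suppressWarnings(ks.test(planted, null)$p.value), 0.01)
})

test_that("large planted effects are detectable (Monte-Carlo power check)", {
  cfg <- sim_config(n_genes = 2000, n_shared_deg = 200, n_private_deg = 0,
                    n_per_arm = 10, effect_size = 3, noise_sd = 1, seed = 4)
  tr <- ground_truth(cfg)
  tab <- moderated_t_dge(simulate_expression_study(cfg, "A", 1, truth = tr))
  expect_gt(mean(abs(tab$t[tr$role == "shared"]) > 2), 0.9)
})

test_that("null DGE p-values are Uniform(0,1)", {
  cfg <- sim_config(n_genes = 5000, n_shared_deg = 0, n_private_deg = 0,
                    n_per_arm = 10, seed = 5)
  tab <- moderated_t_dge(simulate_expression_study(cfg, "A", 1))
  expect_gt(ks.test(tab$p, "punif")$p.value, 0.001)
})

test_that("doubling the effect size never decreases the median planted |t|", {
  med_t <- vapply(c(0.5, 1, 2, 4), function(es) {
    cfg <- sim_config(n_genes = 1000, n_shared_deg = 100, n_private_deg = 0,
                      n_per_arm = 10, effect_size = es, seed = 6)
    tr <- ground_truth(cfg)
    tab <- moderated_t_dge(simulate_expression_study(cfg, "A", 1, truth = tr))
    median(abs(tab$t[tr$role == "shared"]))
  }, 0)
  expect_true(all(diff(med_t) >= 0))
})

test_that("simulated DGE tables honour partial and logFC-missing contracts", {
  cfg <- sim_config(n_genes = 400, n_studies = 3, n_per_arm = 5,
                    n_shared_deg = 20, n_private_deg = 10,
                    partial_fraction = 1/3, partial_threshold = 0.05,
                    logfc_missing_fraction = 1/3, seed = 7)
  tabs <- simulate_dge_tables(cfg)
  expect_length(tabs$A, 3)
  # first study: p-only; last study: truncated
  expect_true(all(is.na(tabs$A[[1]]$logFC)))
  expect_equal(attr(tabs$A[[3]], "reporting"), "partial")
  expect_true(all(tabs$A[[3]]$p <= 0.05))
  expect_equal(attr(tabs$A[[3]], "threshold"), 0.05)
  expect_equal(attr(tabs$A[[2]], "reporting"), "full")
  # determinism
  tabs2 <- simulate_dge_tables(cfg)
  expect_identical(tabs$B[[2]]$p, tabs2$B[[2]]$p)

  full <- simulate_dge_tables(sim_config(n_genes = 200, n_per_arm = 5,
                                         n_shared_deg = 10, n_private_deg = 5,
                                         partial_fraction = 0, seed = 8))
  expect_true(all(vapply(c(full$A, full$B), attr, "", "reporting") == "full"))
})

test_that("perturbagen library plants a near-perfect reverser", {
  cfg <- sim_config(n_genes = 500, n_shared_deg = 60, n_private_deg = 0,
                    effect_size = 1, seed = 9)
  tr <- ground_truth(cfg)
  lib <- simulate_perturbagen_library(cfg, n_perturbagens = 100,
                                      include_reverser = TRUE, truth = tr)
  expect_equal(lib$perturbagens[1], "REVERSER")
  up <- tr$gene[tr$role == "shared" & tr$sign_A > 0]
  down <- tr$gene[tr$role == "shared" & tr$sign_A < 0]
  rows <- connectivity_scores(up, down, lib)
  expect_lt(rows$score[rows$perturbagen == "REVERSER"], -0.9)
  # random perturbagens average near zero
  expect_lt(abs(mean(rows$score[rows$perturbagen != "REVERSER"])), 0.1)

  empty <- simulate_perturbagen_library(cfg, n_perturbagens = 0,
                                        include_reverser = FALSE, truth = tr)
  expect_equal(nrow(empty$logfc), 0)
})
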