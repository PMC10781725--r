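test_that("the log2 decision rule fires on its boundary fixtures", {
  # condition 1: 99th quantile above 100
  st <- make_study(matrix(c(rep(1, 99), 150), 10, 10), transform = "raw")
  expect_true(needs_log2(st))
  # neither condition: everything within [0, 10]
  st2 <- make_study(matrix(seq(0, 10, length.out = 100), 10, 10), transform = "raw")
  expect_false(needs_log2(st2))
  # condition 2: range above 50 with positive first quartile
  v <- c(rep(2, 25), seq(2, 60, length.out = 74), 62)  # range 60, q1 = 2, q99 ~ 60
  st3 <- make_study(matrix(v, 10, 10), transform = "raw")
  expect_true(needs_log2(st3))
  expect_error(needs_log2(make_study(matrix(numeric(), 0, 0),
                                     group = character(), genes = character(),
                                     transform = "raw")),
               "two levels|empty")
})

test_that("log2 transform is exact, offset-aware and monotone", {
  st <- make_study(matrix(c(8, 2, 4, 16), 2, 2), transform = "raw")
  tr <- log2_transform(st, offset = 0)
  expect_equal(tr$values[1, 1], 3)
  expect_equal(tr$transform, "log2")
  # zero entries trigger the +1 offset automatically
  st0 <- make_study(matrix(c(0, 1, 3, 7), 2, 2), transform = "raw")
  tr0 <- log2_transform(st0)
  expect_equal(tr0$values[1, 1], 0)
  expect_equal(tr0$values[2, 1], 1)
  # strictly positive matrices are transformed with offset 0
  expect_equal(log2_transform(st)$values[1, 1], 3)
  # monotone in the original values
  x <- sort(runif(20, 0, 50))
  tx <- log2_transform(make_study(matrix(x, 4, 5), transform = "raw"))$values
  expect_identical(order(as.vector(tx)), order(x))
})

test_that("low-expression filter drops raw-negative genes unless protected", {
  m <- rbind(c(-1, -2, -3, 5),   # negative in 3 of 4: dropped
             c(-1, -2, 3, 5),    # negative in 2 of 4: kept (strict majority)
             c(-1, -2, -3, -4),  # all negative but protected
             c(1, 2, 3, 4))
  st <- make_study(m, transform = "raw", genes = c("DROP", "KEEP", "PROT", "OK"))
  out <- filter_low_expression(st, keep_genes = "prot")
  expect_setequal(out$genes, c("KEEP", "PROT", "OK"))
  expect_equal(attr(out, "dropped"), "DROP")
  # the negativity test uses pre-transformation values even after log2
  # (entries below -1 have no finite log2; the filter drops them anyway)
  st2 <- suppressWarnings(log2_transform(st))
  out2 <- filter_low_expression(st2, keep_genes = "PROT")
  expect_setequal(out2$genes, c("KEEP", "PROT", "OK"))
})

test_that("quantile normalization equalizes column distributions exactly", {
  st <- make_study(cbind(c(1, 2, 3), c(4, 5, 6)), group = c("case", "control"),
                   transform = "log2")
  qn <- quantile_normalize(st)
  expect_equal(unname(qn$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values[, 2]), c(2.5, 3.5, 4.5))
  expect_equal(qn$transform, "normalized")

  # identical columns are a fixed point
  same <- make_study(cbind(c(3, 1, 2), c(3, 1, 2)), transform = "log2")
  expect_equal(quantile_normalize(same)$values, same$values)

  set.seed(11)
  m <- matrix(rnorm(200), 40, 5)
  qn2 <- quantile_normalize(make_study(m, transform = "log2"))$values
  # postcondition: every column has the identical sorted vector (exact)
  sorted <- apply(qn2, 2, sort)
  for (j in 2:5) expect_identical(sorted[, j], sorted[, 1])
  # within-sample rank order preserved
  for (j in 1:5) expect_equal(cor(m[, j], qn2[, j], method = "spearman"), 1)
})

test_that("quantile normalization agrees with limma on tied data", {
  skip_if_not_installed("limma")
  set.seed(12)
  for (i in 1:10) {
    m <- matrix(sample(1:6, 60, replace = TRUE) + 0, 12, 5)  # heavy ties
    qn <- quantile_normalize(make_study(m, transform = "log2"))$values
    ref <- limma::normalizeQuantiles(m, ties = TRUE)
    expect_equal(unname(qn), unname(ref), tolerance = 1e-12)
  }
})

test_that("duplicate resolution keeps the highest-variance record", {
  m <- rbind(c(1, 1, 1, 1), c(0, 2, 4, 6), c(5, 5, 6, 6), c(9, 9, 9, 9))
  st <- make_study(m, genes = c("G1", "G1", "G2", "G3"))
  out <- resolve_duplicates(st)
  expect_equal(out$genes, c("G1", "G2", "G3"))
  expect_equal(unname(out$values[1, ]), c(0, 2, 4, 6))  # variance 20/3 beats 0
  # exact tie: first occurrence wins
  tie <- make_study(rbind(c(1, 2), c(2, 3)), group = c("case", "control"),
                    genes = c("T", "T"))
  expect_equal(unname(resolve_duplicates(tie)$values[1, ]), c(1, 2))
  # unique genes untouched
  expect_identical(resolve_duplicates(out)$values, out$values)
})

test_that("the preprocessing chain is idempotent from the normalized state", {
  set.seed(13)
  st <- make_study(matrix(rexp(300, 1 / 200), 30, 10), transform = "raw")
  once <- preprocess_study(st)
  expect_equal(once$transform, "normalized")
  twice <- preprocess_study(once)
  expect_identical(once$values, twice$values)
})
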