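test_that("quantile normalization matches the rank-mean oracle", {
  m <- expr_matrix(cbind(a = c(5, 3, 1), b = c(4, 2, 6)))
  out <- quantile_normalize(m)
  expect_equal(unclass(out), cbind(a = c(5.5, 3.5, 1.5), b = c(3.5, 1.5, 5.5)),
               ignore_attr = TRUE)
  expect_identical(norm_state(out), "quantile")
  # identical columns are a fixed point
  fix <- quantile_normalize(expr_matrix(cbind(a = c(2, 7, 4), b = c(2, 7, 4))))
  expect_equal(unclass(fix), cbind(a = c(2, 7, 4), b = c(2, 7, 4)),
               ignore_attr = TRUE)
  # permuted columns stay permutations of one multiset
  p <- quantile_normalize(expr_matrix(cbind(a = c(1, 9, 4), b = c(9, 4, 1))))
  expect_identical(order(p[, "a"]), order(c(1, 9, 4)))
  expect_identical(sort(p[, "a"]), sort(p[, "b"]))
  # random tie-free matrices against the hand oracle
  set.seed(41)
  for (i in 1:20) {
    x <- matrix(sample(1000, 20), 5, 4)
    got <- quantile_normalize(expr_matrix(x))
    expect_equal(unclass(got), hand_qn(x), ignore_attr = TRUE)
    # after normalization every column holds the same sorted vector
    srt <- apply(unclass(got), 2, sort)
    expect_equal(srt, srt[, c(1, 1, 1, 1)], ignore_attr = TRUE)
    expect_equal(colMeans(got), rep(mean(colMeans(x)), 4),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("quantile normalization averages ties over their rank slots", {
  # column a has a tie at value 4 occupying ranks 1-2; reference is the
  # across-column rank mean, computed by hand below
  x <- cbind(a = c(4, 4, 10), b = c(1, 5, 9))
  ref <- rowMeans(cbind(sort(x[, "a"]), sort(x[, "b"])))  # 2.5, 4.5, 9.5
  out <- unclass(quantile_normalize(expr_matrix(x)))
  expect_equal(out[, "a"], c(mean(ref[1:2]), mean(ref[1:2]), ref[3]),
               ignore_attr = TRUE)
  expect_equal(out[, "b"], ref, ignore_attr = TRUE)
})

test_that("normalization state transitions are enforced", {
  m <- expr_matrix(cbind(a = c(1, 2), b = c(3, 4)))
  expect_error(quantile_normalize(quantile_normalize(m)), "already normalized")
  expect_error(quantile_normalize(expr_matrix(matrix(1:3, ncol = 1))),
               ">= 2 samples")
})

test_that("regularized fold change damps low-expression genes", {
  expect_identical(regularized_log2fc(15, 5, r = 5), 1)
  expect_identical(regularized_log2fc(0, 0, r = 5), 0)
  expect_identical(regularized_log2fc(5, 0, r = 5), 1)
  expect_identical(log2(5 / 0), Inf)  # the unregularized contrast diverges
  expect_error(regularized_log2fc(1, 1, r = 0), "> 0")
  # antisymmetry
  set.seed(51)
  a <- runif(50, 0, 100); b <- runif(50, 0, 100)
  expect_equal(regularized_log2fc(a, b, 5), -regularized_log2fc(b, a, 5))
  # the stated purpose: a,b <= 5 with r = 5 can never exceed |1|
  g <- expand.grid(a = seq(0, 5, by = 0.1), b = seq(0, 5, by = 0.1))
  expect_true(all(abs(regularized_log2fc(g$a, g$b, 5)) <= 1))
  # monotone decreasing in r for fixed a != b
  for (i in 1:20) {
    aa <- runif(1, 0, 50); bb <- runif(1, 0, 50)
    if (aa == bb) next
    v <- abs(vapply(c(1, 2, 5, 10, 20), function(r)
      regularized_log2fc(aa, bb, r), numeric(1)))
    expect_true(all(diff(v) < 0))
  }
})

test_that("paired_test matches the t-distribution oracle", {
  # differences (1,2,3): t = 2 / (1 / sqrt(3)), df = 2
  t_oracle <- 2 / (1 / sqrt(3))
  expect_equal(t_oracle, 3.4641, tolerance = 1e-4)
  expect_equal(paired_test(c(1, 2, 3)), 2 * pt(-t_oracle, df = 2),
               tolerance = 1e-12)
  expect_equal(paired_test(c(1, 2, 3)), 0.0742, tolerance = 1e-3)
  expect_equal(paired_test(c(0, 0.001, -0.001)), 1, tolerance = 1e-6)
  expect_true(is.na(paired_test(c(5, 5, 5))))
  # vectorised form agrees with stats::t.test row by row
  set.seed(61)
  d <- matrix(rnorm(60), nrow = 12)
  got <- paired_test(d)
  for (i in seq_len(nrow(d)))
    expect_equal(got[i], t.test(d[i, ])$p.value, tolerance = 1e-12)
})

test_that("fdr_adjust reproduces brute-force Benjamini-Hochberg", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_identical(fdr_adjust(c(0.5)), 0.5)
  expect_equal(fdr_adjust(rep(0.2, 6)), rep(0.2, 6))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(71)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))
    expect_equal(fdr_adjust(p), brute_bh(p), tolerance = 1e-14)
  }
  # NA p-values stay NA and do not enter m
  p <- c(0.01, NA, 0.04)
  q <- fdr_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], brute_bh(c(0.01, 0.04)))
  # q >= p always (consistency of the step-up correction)
  set.seed(72)
  pp <- runif(200)
  expect_true(all(fdr_adjust(pp) >= pp))
})

test_that("call_degs applies the three-way conjunction", {
  res <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    log2fc_reg = c(log2(1.6), log2(1.4), -log2(2), log2(3)),
    p_value = c(0.01, 0.001, 0.02, NA),
    q_value = c(0.01, 0.001, 0.03, NA)
  )
  out <- call_degs(res)
  expect_identical(out$is_deg, c(TRUE, FALSE, TRUE, FALSE))
  s <- attr(out, "deg_summary")
  expect_identical(unname(s), c(2L, 1L, 1L))
})

test_that("volcano and heatmap transforms are as specified", {
  res <- data.frame(gene_id = c("a", "b"),
                    log2fc_reg = c(log2(2), 0),
                    p_value = c(0.01, 1), q_value = c(0.02, 1))
  v <- volcano_table(res)
  expect_equal(v$log2fc, c(1, 0))
  expect_equal(v$neg_log10_p, c(2, 0))
  expect_identical(v$highlight, c(TRUE, FALSE))
  # p = 0 stays finite via the floor
  res$p_value <- c(0, 1)
  expect_true(all(is.finite(volcano_table(res)$neg_log10_p)))
  # smaller p => larger -log10 p
  set.seed(81)
  p <- sort(runif(20))
  res2 <- data.frame(gene_id = letters[1:20], log2fc_reg = 0, p_value = p,
                     q_value = p)
  expect_true(all(diff(volcano_table(res2)$neg_log10_p) <= 0))

  expect_equal(heatmap_matrix(matrix(c(0, 1, 7, 3), 2)),
               matrix(c(0, 1, 3, 2), 2))
  expect_error(heatmap_matrix(matrix(c(-1, 1), 1)), "non-negative")
})

test_that("diff_expression wires normalization, testing and calling together", {
  set.seed(91)
  n <- 60L
  base <- rlnorm(n, log(200), 0.5)
  mult <- c(rep(4, 6), rep(1, n - 6))
  mk <- function(lam) rpois(n, lam)
  m <- expr_matrix(cbind(c1 = mk(base), c2 = mk(base), c3 = mk(base),
                         t1 = mk(base * mult), t2 = mk(base * mult),
                         t3 = mk(base * mult)))
  rownames(m) <- sprintf("g%02d", 1:n)
  design <- data.frame(control = c("c1", "c2", "c3"),
                       treated = c("t1", "t2", "t3"))
  res <- diff_expression(m, design)
  expect_s3_class(res, "differential_result")
  expect_identical(nrow(res), n)
  expect_true(all(res$q_value >= res$p_value, na.rm = TRUE))
  expect_gte(sum(res$is_deg[1:6]), 4)           # planted 4-fold genes found
  expect_lte(sum(res$is_deg[-(1:6)]), 2)        # nulls mostly quiet
  pr <- attr(res, "params")
  expect_identical(pr$fdr_method, "BH")
  expect_identical(norm_state(attr(res, "matrix_norm")), "quantile")
  # design validation
  expect_error(diff_expression(m, data.frame(control = "c1", treated = "t1")),
               ">= 2 pairs")
  bad <- data.frame(control = c("c1", "c1"), treated = c("t1", "t2"))
  expect_error(diff_expression(m, bad), "reused")
})
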