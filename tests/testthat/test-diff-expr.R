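test_that("group abundance is the arithmetic replicate mean", {
  vals <- matrix(c(1, 2, 3, 10, 20, 30,
                   0, 0, 0, 0, 0, 0), 2, 6, byrow = TRUE,
                 dimnames = list(c("f1", "f2"), NULL))
  expr <- toy_expr(vals)
  expect_equal(unname(group_abundance(expr, "anagen")["f1"]), 2)
  expect_equal(unname(group_abundance(expr, "catagen")["f1"]), 20)
  expect_equal(unname(group_abundance(expr, "anagen")["f2"]), 0)
  expect_error(group_abundance(expr, "telogen"), "not present")
})

test_that("fold changes follow the catagen/anagen ratio convention", {
  expect_equal(log2_fold_change(4, 4), 0)
  expect_equal(log2_fold_change(8, 2), 2)
  expect_error(log2_fold_change(-1, 2), "non-negative")
  # degenerate ratios are flagged, not dropped
  expect_identical(log2_fold_change(3, 0), Inf)
  expect_identical(log2_fold_change(0, 3), -Inf)
  expect_true(is.nan(log2_fold_change(0, 0)))

  # antisymmetry and scale invariance
  set.seed(21)
  a <- runif(50, 0.1, 100); b <- runif(50, 0.1, 100)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
  expect_equal(log2_fold_change(7 * a, 7 * b), log2_fold_change(a, b))
})

test_that("the Welch surrogate handles degenerate and separated features", {
  vals <- matrix(c(5, 5, 5, 5, 5, 5,
                   1, 1, 1, 1000.2, 1000.1, 1000.3,
                   2, 2, 2, 8, 8, 8), 3, 6, byrow = TRUE,
                 dimnames = list(c("const", "sep", "shift"), NULL))
  expr <- toy_expr(vals)
  expect_equal(de_test(expr, "const"), 1)
  expect_lt(de_test(expr, "sep"), 0.001)
  # constant within each group, different between: perfect separation
  expect_equal(de_test(expr, "shift"), 0)
  expect_error(de_test(expr, "absent"), "absent")
})

test_that("BH adjustment matches hand-computed examples and is stable", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.02, 7)), rep(0.02, 7))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  set.seed(22)
  p <- runif(100)
  perm <- sample(100)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_true(all(diff(bh_fdr(p)[order(p)]) >= 0))
})

test_that("DE calling uses a strict threshold and sign-based direction", {
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    log2fc = c(1.2, -0.5, 0, NaN),
                    pvalue = c(0.05, 0.01, 0.001, 0.04))
  de <- call_de(res, alpha = 0.05)
  expect_false("a" %in% de$feature_id)  # p = 0.05 exactly is not DE
  expect_equal(de$direction[de$feature_id == "b"], "down")
  expect_equal(de$direction[de$feature_id == "c"], "unchanged")
  expect_equal(de$direction[de$feature_id == "d"], "undefined")
})

test_that("de_table columns agree with their per-feature building blocks", {
  sim <- small_sim0()
  tab <- de_table(sim$fpkm)
  expect_equal(tab$catagen_abundance,
               unname(group_abundance(sim$fpkm, "catagen")))
  expect_equal(tab$log2fc,
               log2_fold_change(tab$catagen_abundance,
                                tab$anagen_abundance))
  some <- sample(tab$feature_id, 10)
  expect_equal(tab$pvalue[match(some, tab$feature_id)],
               vapply(some, function(f) de_test(sim$fpkm, f), 0),
               ignore_attr = TRUE)
  expect_equal(tab$qvalue, bh_fdr(tab$pvalue))
})

test_that("DE recall grows with the planted effect size", {
  set.seed(23)
  recall_at <- function(lfc) {
    n <- 60
    mu <- runif(n, 2, 8)
    vals <- 2^(outer(mu, rep(c(0, lfc), each = 3)) +
                 matrix(rnorm(n * 6, 0, 1), n))
    rownames(vals) <- paste0("f", seq_len(n))
    mean(de_table(toy_expr(vals))$pvalue < 0.05)
  }
  recalls <- vapply(c(0.5, 2, 4), recall_at, 0)
  expect_true(all(diff(recalls) >= 0))
  expect_gt(recalls[3], 0.9)
})

test_that("ddCt relative quantification follows the closed form", {
  expect_equal(ddct_relative_expression(20, 18, 22, 20), 1)
  expect_equal(ddct_relative_expression(21, 18, 22, 20), 0.5)
  # ddCt of -3.3219 is a 10-fold increase
  expect_equal(ddct_relative_expression(18.6781, 20, 22, 20), 10,
               tolerance = 1e-3)
  expect_error(ddct_relative_expression(Inf, 1, 1, 1), "finite")
})
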