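test_that("identical groups give a minimal statistic and a large p", {
  x <- c(1, 2, 3, 4, 5)
  ks <- ks_permutation_test(x, x, n_perm = 499, seed = 1)
  expect_equal(ks$observed, 0)
  expect_gt(ks$p_value, 0.5)
  md <- mean_diff_permutation_test(x, x, n_perm = 499, seed = 1)
  expect_equal(md$observed, 0)
  expect_gt(md$p_value, 0.5)
})

test_that("empirical p-values use the add-one estimator and its lower bound", {
  x <- rep(0, 10); y <- rep(10, 10)
  ks <- ks_permutation_test(x, y, n_perm = 999, seed = 3)
  expect_equal(ks$observed, 1)
  # complete separation: permuted statistics essentially never reach 1
  expect_equal(ks$p_value, 1 / 1000)
  expect_gte(ks$p_value, 1 / (ks$n_permutations + 1))
  md <- mean_diff_permutation_test(x, y, n_perm = 999, seed = 3)
  expect_gte(md$p_value, 1 / 1000)
  expect_lte(md$p_value, 1)
})

test_that("permutation p-values agree with exact enumeration on tiny groups", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  # enumerate all 20 label assignments of 3-vs-3
  pool <- c(x, y)
  combs <- combn(6, 3)
  ks_stat <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(abs(vapply(v, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
  }
  obs <- ks_stat(x, y)
  exact <- mean(apply(combs, 2, function(idx) {
    ks_stat(pool[idx], pool[-idx]) >= obs - 1e-12
  }))
  est <- ks_permutation_test(x, y, n_perm = 9999, seed = 5)$p_value
  expect_lt(abs(est - exact), 0.012)
})

test_that("p-values are exactly reproducible under a fixed seed", {
  set.seed(123)
  x <- rnorm(12); y <- rnorm(15, 1)
  p1 <- ks_permutation_test(x, y, n_perm = 999, seed = 77)$p_value
  p2 <- ks_permutation_test(x, y, n_perm = 999, seed = 77)$p_value
  expect_identical(p1, p2)
  m1 <- mean_diff_permutation_test(x, y, n_perm = 999, seed = 77)$p_value
  m2 <- mean_diff_permutation_test(x, y, n_perm = 999, seed = 77)$p_value
  expect_identical(m1, m2)
  # the caller's RNG stream is not consumed by a seeded test
  set.seed(99); before <- .Random.seed
  ks_permutation_test(x, y, n_perm = 99, seed = 1)
  expect_identical(before, .Random.seed)
})

test_that("a real group difference is detected by the mean-difference test", {
  set.seed(11)
  x <- rnorm(40, 8.3, 3); y <- rnorm(40, 3.8, 2)
  md <- mean_diff_permutation_test(x, y, n_perm = 999, seed = 2)
  expect_lt(md$p_value, 0.01)
  expect_gt(md$observed, 2)
})

test_that("empty groups are an argument error", {
  expect_error(ks_permutation_test(numeric(0), 1:3), "non-empty")
  expect_error(mean_diff_permutation_test(1:3, numeric(0)), "non-empty")
})

test_that("burden-covariate correlation handles perfect, null and degenerate cases", {
  counts <- c(1, 2, 3, 4, 5, 6)
  bc <- burden_vs_covariate(counts, counts * 10, n_perm = 999, seed = 1)
  expect_equal(bc$rho, 1)
  expect_lte(bc$p_value, 0.05)
  set.seed(21)
  null <- burden_vs_covariate(rpois(50, 5), rnorm(50), n_perm = 999, seed = 2)
  expect_lt(abs(null$rho), 0.4)
  expect_warning(deg <- burden_vs_covariate(counts, rep(1, 6)), "constant")
  expect_true(deg$undefined)
  expect_error(burden_vs_covariate(1:2, 1:2), "at least 3")
})

test_that("a planted expression shift in fused samples is detected", {
  set.seed(31)
  samples <- sprintf("s%02d", 1:40)
  expr <- matrix(rnorm(3 * 40, 8, 1), nrow = 3,
                 dimnames = list(c("G1", "G2", "G3"), samples))
  fused <- samples[1:10]
  expr["G1", fused] <- expr["G1", fused] + 2
  cohort <- make_consensus(fused, "G1", "PARTNER")
  res <- fused_expression_tests(cohort, expr, genes = c("G1", "G2"))
  expect_true(res$significant[res$gene == "G1"])
  expect_false(res$significant[res$gene == "G2"])
  expect_gt(res$mean_fused[1] - res$mean_unfused[1], 1)
})

test_that("multiple-testing adjustment is the identity for a single gene", {
  set.seed(32)
  samples <- sprintf("s%02d", 1:20)
  expr <- matrix(rnorm(20, 8, 1), nrow = 1,
                 dimnames = list("G1", samples))
  cohort <- make_consensus(samples[1:5], "G1", "PARTNER")
  res <- fused_expression_tests(cohort, expr, genes = "G1")
  expect_equal(res$p_adjusted, res$p_value)
})

test_that("genes with too few fused samples are untestable and excluded from adjustment", {
  set.seed(33)
  samples <- sprintf("s%02d", 1:20)
  expr <- matrix(rnorm(2 * 20, 8, 1), nrow = 2,
                 dimnames = list(c("G1", "G2"), samples))
  cohort <- rbind(make_consensus(samples[1:6], "G1", "PARTNER"),
                  make_consensus(samples[1], "G2", "PARTNER"))
  res <- fused_expression_tests(cohort, expr)
  expect_false(res$testable[res$gene == "G2"])
  expect_true(is.na(res$p_adjusted[res$gene == "G2"]))
  expect_error(fused_expression_tests(cohort, expr, genes = "NOPE"), "NOPE")
})

test_that("under the null about alpha of recurrent-gene tests are flagged", {
  set.seed(34)
  samples <- sprintf("s%02d", 1:60)
  genes <- sprintf("G%02d", 1:40)
  expr <- matrix(rnorm(40 * 60, 8, 1), nrow = 40,
                 dimnames = list(genes, samples))
  cohort <- do.call(rbind, lapply(genes, function(g) {
    make_consensus(sample(samples, 10), g, "PARTNER")
  }))
  res <- fused_expression_tests(cohort, expr, genes = genes, alpha = 0.05,
                                method = "none")
  expect_lte(sum(res$significant), 8)  # ~ alpha * 40 false flags, not many more
})

test_that("recurrent partner genes are ranked by sample involvement", {
  x <- rbind(make_consensus(c("s1", "s2", "s3"), "HOT", c("A", "B", "C")),
             make_consensus(c("s1", "s2"), "WARM", c("D1", "D2")),
             make_consensus("s1", "E", "F"))
  rg <- recurrent_partner_genes(x, n = 2)
  expect_equal(rg, c("HOT", "WARM"))
})
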