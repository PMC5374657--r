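test_that("absolute t scores match the pooled-variance formula and t.test", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  em <- expression_matrix(rbind(g = c(a, b)),
                          group_labels = rep(c("A", "B"), each = 5))
  got <- unname(two_sample_t_scores(em))
  # direct hand evaluation: |mean diff| / (s_p * sqrt(1/5 + 1/5))
  sp <- sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 8)
  expect_equal(got, abs(mean(a) - mean(b)) / (sp * sqrt(2 / 5)))
  # independent route: classical equal-variance t test
  expect_equal(got, abs(t.test(a, b, var.equal = TRUE)$statistic),
               ignore_attr = TRUE)
})

test_that("t scores are 0 under symmetry and invariant to label swap", {
  em <- expression_matrix(rbind(g = c(0, 1, 0, 1)),
                          group_labels = c("A", "A", "B", "B"))
  expect_equal(unname(two_sample_t_scores(em)), 0)

  x <- matrix(rnorm(60), nrow = 6)
  s1 <- two_sample_t_scores(x, labels = rep(c("A", "B"), each = 5))
  s2 <- two_sample_t_scores(x, labels = rep(c("B", "A"), each = 5))
  expect_equal(s1, s2)
})

test_that("zero pooled variance is handled deterministically", {
  em <- expression_matrix(rbind(flat = c(1, 1, 1, 1),
                                jump = c(1, 1, 2, 2),
                                norm = c(0.3, -0.2, 1.1, 0.9)),
                          group_labels = c("A", "A", "B", "B"))
  expect_warning(s <- two_sample_t_scores(em), "zero pooled variance")
  expect_equal(unname(s["flat"]), 0)
  norm_score <- unname(s["norm"])
  expect_equal(unname(s["jump"]), norm_score + 1)
  expect_true(all(is.finite(s)))
})

test_that("designs with fewer than 2 samples per group are rejected", {
  expect_error(two_sample_t_scores(matrix(rnorm(9), 3),
                                   labels = c("A", "B", "B")),
               "at least 2 samples")
})

test_that("balanced relabeling enumeration has the right count and content", {
  expect_equal(ncol(enumerate_balanced_relabelings(5, 5)), 126)
  expect_equal(ncol(enumerate_balanced_relabelings(1, 1)), 1)
  # exhaustive check at 2+2: C(4,2) = 6 splits collapse to 3 under swap
  r22 <- enumerate_balanced_relabelings(2, 2)
  expect_equal(ncol(r22), 3)
  keys <- apply(r22, 2, paste, collapse = ",")
  expect_equal(length(unique(keys)), 3)
  expect_equal(r22[, 1], 1:2) # identity split first
  # unbalanced designs keep all C(n, n1) splits
  expect_equal(ncol(enumerate_balanced_relabelings(2, 3)), choose(5, 2))
  expect_error(enumerate_balanced_relabelings(0, 3), "at least 1")
})

test_that("exhaustive pool has r = m * B and contains the observed scores", {
  em <- toy_expression()
  pool <- build_null_pool(em, mode = "exhaustive")
  expect_equal(pool$B, 3) # 2+2 design
  expect_equal(pool$r, nrow(em$values) * pool$B)
  expect_equal(pool$null_scores, sort(pool$null_scores))
  obs <- two_sample_t_scores(em)
  for (s in obs) expect_true(any(abs(pool$null_scores - s) < 1e-12))

  # single gene: identity relabeling reproduces the observed score
  em1 <- expression_matrix(rbind(g = c(0.1, 0.9, 2.3, 3.1)),
                           group_labels = c("A", "A", "B", "B"))
  p1 <- build_null_pool(em1, mode = "exhaustive", include_observed = TRUE)
  expect_true(min(abs(p1$null_scores - two_sample_t_scores(em1))) < 1e-12)
})

test_that("permuted scores ignore within-group sample order", {
  set.seed(42)
  x <- matrix(rnorm(50), nrow = 5)
  labs <- rep(c("A", "B"), each = 5)
  p1 <- build_null_pool(x, labels = labs, mode = "exhaustive")
  # shuffling columns within each group leaves the pooled null unchanged
  x2 <- x[, c(sample(1:5), sample(6:10))]
  p2 <- build_null_pool(x2, labels = labs, mode = "exhaustive")
  expect_equal(p1$null_scores, p2$null_scores)
})

test_that("sampled pools are seed-reproducible and include observed scores", {
  set.seed(99)
  x <- matrix(rnorm(80), nrow = 8)
  labs <- rep(c("A", "B"), each = 5)
  p1 <- build_null_pool(x, labels = labs, mode = "sampled", n_random = 20,
                        seed = 11)
  p2 <- build_null_pool(x, labels = labs, mode = "sampled", n_random = 20,
                        seed = 11)
  expect_identical(p1$null_scores, p2$null_scores)
  expect_true(p1$r %in% (8 * c(20, 21))) # identity appended when not drawn
  expect_true(p1$includes_observed)
  obs <- two_sample_t_scores(x, labels = labs)
  for (s in obs) expect_true(any(abs(p1$null_scores - s) < 1e-12))
  expect_error(build_null_pool(x, labels = labs, mode = "sampled",
                               n_random = 10),
               "seed")
})

test_that("exhaustive enumeration refuses above the cap", {
  x <- matrix(rnorm(2 * 20), nrow = 2)
  labs <- rep(c("A", "B"), each = 10)
  expect_error(build_null_pool(x, labels = labs, mode = "exhaustive",
                               cap = 1000),
               "sampled")
})

test_that("expression_matrix validates its invariants", {
  expect_error(expression_matrix(matrix(c(1, NA, 3, 4), 2),
                                 group_labels = c("A", "B")),
               "missing")
  expect_error(expression_matrix(matrix(1:12, 3), gene_ids = c("a", "a", "b"),
                                 group_labels = c("A", "A", "B", "B")),
               "duplicate")
  expect_error(expression_matrix(matrix(1:12, 3),
                                 group_labels = c("A", "B", "C", "A")),
               "two sample groups")
})
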