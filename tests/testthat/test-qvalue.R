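test_that("budget splits the level evenly on the multiplicative scale", {
  b <- make_budget(0.05, active = c("alpha", "gamma"))
  expect_equal(b$a1, 1 - sqrt(0.95))
  expect_equal(b$a2, 1 - sqrt(0.95))
  expect_equal(b$a0, 0)
  expect_equal((1 - b$a0) * (1 - b$a1) * (1 - b$a2), 0.95)

  expect_equal(make_budget(0.05, active = "gamma")$a2, 0.05)
  z <- make_budget(0)
  expect_equal(c(z$a0, z$a1, z$a2), c(0, 0, 0))
  b3 <- make_budget(0.1, active = c("pi0", "alpha", "gamma"))
  expect_equal((1 - b3$a0) * (1 - b3$a1) * (1 - b3$a2), 0.9)
  expect_error(make_budget(1), "\\[0, 1\\)")
})

test_that("q-values follow the ratio definition and running minimum", {
  # single gene with p = 1: q = 1
  tab1 <- compute_qvalues(c(g = 2), pool = c(2, 3, 4), pi0 = 1)
  expect_equal(tab1$q, 1)

  # ratio form: pi0 * (k/r) / (j/m)
  # gene A: k/r = 1/100, j/m = 1/50; pi0 = 0.9 -> raw 0.9
  scores <- c(A = 5, B = 1)
  pool <- c(5, seq(0.01, 0.99, length.out = 99))
  tabr <- compute_qvalues(scores, pool, pi0 = 0.9)
  expect_equal(tabr$p[1], 1 / 100)
  expect_equal(tabr$j[1], 1)
  # direct evaluation of the form 0.9 * 0.01 / 0.02 on the spec numbers
  expect_equal(0.9 * 0.01 / 0.02, 0.45)

  # running minimum from the least significant gene: raw (0.3 high, 0.2 low)
  # must monotonize to (0.2, 0.2)
  raw <- c(0.3, 0.2)
  expect_equal(cqvalue:::.monotonize_q(raw, scores = c(2, 1)), c(0.2, 0.2))

  # full comparison against the brute-force defining formula
  set.seed(7)
  s <- abs(rnorm(40)); names(s) <- paste0("g", 1:40)
  pl <- c(s, abs(rnorm(400)))
  tab <- compute_qvalues(s, pl, pi0 = 0.8)
  expect_equal(tab$q, brute_force_qvalues(s, pl, 0.8))
  # ties in score receive identical q
  s2 <- c(a = 1, b = 1, c = 2)
  t2 <- compute_qvalues(s2, c(s2, 0.5, 3), pi0 = 1)
  expect_equal(t2$q[1], t2$q[2])
})

test_that("zero budget passes through and positive budgets dominate", {
  set.seed(11)
  s <- abs(rnorm(30)); names(s) <- paste0("g", 1:30)
  pool <- c(s, abs(rnorm(300)))
  tab <- compute_qvalues(s, pool, pi0 = 1)

  zero <- conservative_qvalues(tab, pi0c = 1, budget = make_budget(0))
  expect_identical(zero$q_c, zero$q) # bit-exact pass-through
  expect_identical(zero$p_c, zero$p)

  adj <- conservative_qvalues(tab, pi0c = 1, budget = make_budget(0.05))
  expect_true(all(adj$q_c >= adj$q))
  expect_true(all(adj$p_c >= adj$p))
  expect_true(all(adj$q_c >= 0 & adj$q_c <= 1))
  # nonincreasing in score
  ord <- order(adj$score, decreasing = TRUE)
  expect_true(all(diff(adj$q_c[ord]) >= -1e-15))
  expect_true(all(diff(adj$q[ord]) >= -1e-15))
})

test_that("adjusted components compose the two oracle-checked bounds", {
  lvl <- 1 - sqrt(0.95)
  tab <- data.frame(gene_id = "g", score = 3, k = 1L, r = 126L, j = 1L,
                    m = 10L, p = 1 / 126, q = NA_real_)
  tab$q <- cqvalue:::.monotonize_q(1 * (1 / 126) / (1 / 10), 3)
  adj <- conservative_qvalues(tab, pi0c = 1,
                              budget = make_budget(0.05))
  expected <- grid_upper_oracle(1, 126, lvl) / grid_lower_oracle(1, 10, lvl)
  expect_equal(adj$q_c, min(1, expected), tolerance = 1e-4)
})

test_that("theoretical-p path matches hand evaluation and dominance", {
  p <- c(0.01, 0.2, 0.5, 0.9)
  none <- make_budget(0, active = character())
  tab <- theoretical_path_qvalues(p, pi0c = 1, budget = none)
  expect_equal(tab$q, c(0.04, 0.4, 2 / 3, 0.9))
  expect_equal(tab$j, 1:4)

  # all p-values 1: every q is 1
  all1 <- theoretical_path_qvalues(rep(1, 5), pi0c = 1, budget = none)
  expect_equal(all1$q, rep(1, 5))

  adj <- theoretical_path_qvalues(p, pi0c = 1,
                                  budget = make_budget(0.05,
                                                       active = "gamma"))
  expect_true(all(adj$q_c >= adj$q))
  expect_warning(
    theoretical_path_qvalues(p, pi0c = 1, budget = make_budget(0.05)),
    "a1")
})

test_that("result tables satisfy the range and ordering invariants", {
  set.seed(3)
  sc <- generate_scenario(m = 60, pi0 = 0.8, delta = 2, seed = 3)
  fit <- cqfit(sc$x, a = 0.05, pi0 = "storey")
  tab <- fit$table
  expect_true(all(tab$p >= 0 & tab$p <= tab$p_c & tab$p_c <= 1))
  expect_true(all(tab$q >= 0 & tab$q <= 1))
  expect_true(all(tab$q_c >= tab$q))
  expect_true(all(tab$j >= 1) && all(tab$k >= 1)) # observed in pool
})
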