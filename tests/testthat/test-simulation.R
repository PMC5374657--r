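test_that("scenario generator realizes the stated mixture", {
  sc <- generate_scenario(m = 500, pi0 = 0.9, delta = 2, seed = 4)
  expect_equal(sum(!sc$true_null), 50)
  expect_equal(dim(sc$x$values), c(500, 10))

  # pi0 = 1: no DE genes at all
  sc1 <- generate_scenario(m = 100, pi0 = 1, delta = 2, seed = 4)
  expect_true(all(sc1$true_null))

  # deterministic given seed
  sc2 <- generate_scenario(m = 500, pi0 = 0.9, delta = 2, seed = 4)
  expect_identical(sc$x$values, sc2$x$values)

  # grand mean of DE-gene group-2 values: CLT bound 4 / sqrt(500)
  scd <- generate_scenario(m = 1000, pi0 = 0.9, delta = 1.5, n1 = 5, n2 = 5,
                           seed = 8)
  de_g2 <- scd$x$values[!scd$true_null, 6:10]
  expect_lt(abs(mean(de_g2) - 1.5), 4 / sqrt(length(de_g2)))
})

test_that("theoretical FDR matches its boundary values and quadrature", {
  expect_equal(theoretical_fdr(0, pi0 = 0.37, delta = 2), 0.37)
  expect_equal(theoretical_fdr(c(0, 1, 3), pi0 = 1, delta = 2), rep(1, 3))

  # independent oracle: numerical integration of the t densities
  nu <- 8; ncp <- 2 * sqrt(25 / 10); t0 <- 3
  s0 <- 2 * integrate(function(x) dt(x, nu), t0, Inf)$value
  # dt() emits harmless 'full precision' notes in the noncentral tails
  s1 <- suppressWarnings(
    integrate(function(x) dt(x, nu, ncp), t0, Inf)$value +
      integrate(function(x) dt(x, nu, ncp), -Inf, -t0)$value)
  oracle <- 0.9 * s0 / (0.9 * s0 + 0.1 * s1)
  expect_equal(theoretical_fdr(3, pi0 = 0.9, delta = 2, n1 = 5, n2 = 5),
               oracle, tolerance = 1e-6)

  # nonincreasing in t for positive shifts, for each scenario on the grid
  grid <- seq(0, 8, by = 0.05)
  for (par in list(c(0.9, 1), c(0.9, 2), c(0.8, 1), c(0.8, 2),
                   c(0.85, 1.5))) {
    curve <- theoretical_fdr(grid, pi0 = par[1], delta = par[2])
    expect_true(all(diff(curve) <= 1e-12))
    expect_true(all(curve >= 0 & curve <= 1))
  }
  expect_error(theoretical_fdr(-1, 0.9, 2), "nonnegative")
})

test_that("empirical FDP counts false positives among selections", {
  truth <- c(rep(TRUE, 6), rep(FALSE, 4)) # 6 nulls
  expect_equal(empirical_fdp(truth, integer()), 0) # 0/0 convention
  expect_equal(empirical_fdp(truth, c(1, 2, 7, 8, 9, 10, 4, 5, 6, 3)), 0.6)
  expect_equal(empirical_fdp(truth, c(7, 8, 1, 9, 2, 10, 3)), 3 / 7)
  expect_equal(empirical_fdp(truth, seq_along(truth)), 0.6) # all selected
  expect_equal(empirical_fdp(truth, truth), 1) # logical selection
  expect_error(empirical_fdp(truth, 11), "out of range")
})

test_that("coverage harness is reproducible and structurally sound", {
  empty <- run_coverage_experiment(reps = 0)
  expect_equal(nrow(empty$summary), 0)

  r1 <- run_coverage_experiment(m = 150, pi0 = 0.8, delta = 2, reps = 3,
                                seed = 21)
  r2 <- run_coverage_experiment(m = 150, pi0 = 0.8, delta = 2, reps = 3,
                                seed = 21)
  expect_identical(r1$curves, r2$curves)
  expect_identical(r1$summary, r2$summary)
  expect_equal(nrow(r1$summary), 3)
  cv <- r1$curves[[1]]
  expect_named(cv, c("score", "q", "q_c", "q_tilde", "fdp"))
  expect_equal(nrow(cv), 150)
  expect_true(all(cv$q_c >= cv$q))
  expect_true(all(cv$q_tilde >= 0 & cv$q_tilde <= 1))
  expect_true(r1$coverage >= 0 && r1$coverage <= 1)
})

test_that("mean FDP at a fixed threshold tracks the theoretical FDR", {
  # cheap version of the oracle-consistency check (full scale runs in the
  # acceptance suite): 60 replicates at m = 300
  set.seed(60)
  t0 <- 3
  fdp <- replicate(60, {
    sc <- generate_scenario(m = 300, pi0 = 0.9, delta = 2)
    s <- two_sample_t_scores(sc$x)
    empirical_fdp(sc$true_null, s >= t0)
  })
  target <- theoretical_fdr(t0, pi0 = 0.9, delta = 2)
  se <- sd(fdp) / sqrt(length(fdp))
  expect_lt(abs(mean(fdp) - target), 3 * se)
})
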