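test_that("the nonlinear schedule spans 2 to 0 with slow early decay", {
  expect_equal(nonlinear_a(0, 100), 2)
  expect_equal(nonlinear_a(100, 100), 0)
  # closed form at the midpoint ratio
  expect_equal(nonlinear_a(50, 100), 2 - 2 * sin(pi / 16))
  expect_equal(nonlinear_a(50, 100), 1.60982, tolerance = 1e-5)
  # monotone nonincreasing across the full grid
  a <- nonlinear_a(0:200, 200)
  expect_true(all(diff(a) <= 0))
  expect_true(all(a >= 0 & a <= 2))
  expect_error(nonlinear_a(-1, 10), "0..T")
  expect_error(nonlinear_a(11, 10), "0..T")
})

test_that("the nonlinear schedule dominates the linear one early in the search", {
  # slower decay early = more exploration; check on a dense ratio grid
  T <- 1000
  t <- 1:999
  nl <- nonlinear_a(t, T)
  lin <- 2 * (1 - t / T)
  crossover <- which(nl <= lin)[1]
  expect_true(all(nl[seq_len(crossover - 1)] > lin[seq_len(crossover - 1)]))
  expect_gt(crossover / T, 0.5)  # dominance persists past mid-search
})

test_that("FDB scores reproduce the worked normalization example", {
  pos <- rbind(c(0, 0), c(3, 4), c(6, 8))
  fit <- c(0.2, 0.4, 0.8)
  sc <- fdb_scores(pos, fit, best_position = c(0, 0))
  expect_equal(sc$dp, c(0, 5, 10))  # 3-4-5 triangle scaled
  expect_equal(sc$norm_f, c(1, 2/3, 0))
  expect_equal(sc$norm_dp, c(0, 1/2, 1))
  expect_equal(sc$score, c(1, 7/6, 1))
  expect_equal(which.max(sc$score), 2)
})

test_that("FDB scoring degenerates to all-zero scores for identical populations", {
  pos <- matrix(0.4, nrow = 5, ncol = 3)
  sc <- fdb_scores(pos, rep(0.1, 5), best_position = rep(0.4, 3))
  expect_equal(sc$score, rep(0, 5))
  expect_error(fdb_scores(pos[1, , drop = FALSE], 0.1, rep(0.4, 3)),
               "at least 2")
})

test_that("FDB scores match the brute-force oracle on random populations", {
  worst <- 0
  for (s in 1:100) {
    set.seed(s)
    n <- sample(2:10, 1)
    D <- sample(1:5, 1)
    pos <- matrix(runif(n * D), n, D)
    fit <- runif(n)
    best <- runif(D)
    sc <- fdb_scores(pos, fit, best)
    orc <- oracle_fdb(pos, fit, best)
    worst <- max(worst, abs(sc$dp - orc$dp), abs(sc$norm_f - orc$norm_f),
                 abs(sc$norm_dp - orc$norm_dp), abs(sc$score - orc$score))
  }
  expect_lt(worst, 1e-12)
})

test_that("reference selection alternates by iteration parity", {
  own <- c(0.1, 0.2)
  fdb <- c(0.9, 0.8)
  expect_identical(select_reference(2, own, fdb), own)
  expect_identical(select_reference(4, own, NULL), own)
  expect_identical(select_reference(1, own, fdb), fdb)
  expect_identical(select_reference(3, own, fdb), fdb)
  expect_error(select_reference(3, own, NULL), "required")
})

test_that("adaptive mutation is anchored at the best and unbiased in expectation", {
  g <- list(x1 = c(0.2, 0.4), x2 = c(0.5, 0.5), x3 = c(0.9, 0.1))
  best <- c(0.6, 0.6)
  # zero offset: a guide already at the best never moves
  g0 <- g; g0$x1 <- best
  set.seed(1)
  m0 <- adaptive_mutation(g0, best)
  expect_identical(m0$x1, best)
  # noise forced to one maps every guide exactly onto the best
  x1 <- g$x1; off <- best - x1
  expect_equal(x1 + off * 1, best)
  # Monte Carlo: mean-zero noise leaves the guide unbiased
  set.seed(2)
  draws <- replicate(10000, adaptive_mutation(g, best)$x2)
  mc_mean <- rowMeans(draws)
  mc_se <- apply(draws, 1, stats::sd) / sqrt(ncol(draws))
  expect_true(all(abs(mc_mean - g$x2) < 3 * mc_se))
})

test_that("all-mechanisms-off AMGWO is bit-identical to the baseline GWO", {
  fx <- make_worked_fixture()
  cfg <- optimizer_config(n = 8, T = 10, seed = 77,
                          use_apc = FALSE, use_afdb = FALSE, use_adv = FALSE)
  a <- run_amgwo(fx$dataset, cfg)
  g <- run_gwo(fx$dataset, cfg)
  expect_identical(a$trace, g$trace)
  expect_identical(as.integer(a$best_mask), as.integer(g$best_mask))
  expect_identical(a$best_position, g$best_position)
  expect_identical(a$best_fitness, g$best_fitness)
})

test_that("every variant performs exactly n evaluations per iteration", {
  fx <- make_worked_fixture()
  for (alg in c("gwo", "apcgwo", "afdbgwo", "advgwo", "amgwo")) {
    tog <- algorithm_toggles(alg)
    cfg <- optimizer_config(n = 6, T = 7, seed = 3,
                            use_apc = tog[["use_apc"]],
                            use_afdb = tog[["use_afdb"]],
                            use_adv = tog[["use_adv"]])
    r <- run_amgwo(fx$dataset, cfg)
    expect_equal(r$n_evals, 6 * (7 + 1))
    expect_true(all(diff(r$trace) <= 0))
  }
  expect_error(algorithm_toggles("pso"), "unknown algorithm")
})

test_that("AMGWO solves the worked fixture and keeps the separator", {
  fx <- make_worked_fixture()
  wins <- 0
  for (seed in 1:10) {
    r <- run_amgwo(fx$dataset, optimizer_config(n = 10, T = 30, seed = seed))
    if (r$best_fitness == 0 && as.integer(r$best_mask)[1] == 1L) wins <- wins + 1
  }
  expect_gte(wins, 8)
})
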