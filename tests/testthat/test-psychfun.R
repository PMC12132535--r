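test_that("psychometric function has the right midpoint value and asymptotes", {
  pf <- psychfun(alpha = 30, beta = 0.5, gamma = 0.125)
  expect_equal(prob_correct(30, pf), 0.5625)           # gamma + (1-gamma)/2
  expect_equal(prob_correct(1e9, pf), 1)
  expect_equal(prob_correct(-1e9, pf), 0.125)
  # 70% is reached 1.3012 above the midpoint for the default slope/guess
  expect_equal(prob_correct(30 + 2 * log(0.575 / 0.3), pf), 0.70)
})

test_that("constructor rejects invalid slope and guess rate", {
  expect_error(psychfun(0, beta = 0), "beta")
  expect_error(psychfun(0, beta = -1), "beta")
  expect_error(psychfun(0, gamma = 1), "gamma")
  expect_error(psychfun(0, gamma = -0.1), "gamma")
})

test_that("level_for_target inverts prob_correct in closed form", {
  pf <- psychfun(alpha = 30)
  expect_equal(level_for_target(pf, 0.70), 31.30118, tolerance = 1e-6)
  expect_equal(level_for_target(pf, 0.5625), 30)
  expect_error(level_for_target(pf, 0.10), "gamma")
  expect_error(level_for_target(pf, 1))
  # roundtrip over a grid of targets and random parameterisations
  set.seed(11)
  for (i in 1:20) {
    pf <- psychfun(runif(1, -10, 110), runif(1, 0.1, 3), runif(1, 0, 0.5))
    for (p in seq(pf$gamma + 0.01, 0.99, length.out = 9)) {
      expect_lt(abs(prob_correct(level_for_target(pf, p), pf) - p), 1e-9)
    }
  }
})

test_that("prob_correct is monotone in level and in midpoint", {
  pf <- psychfun(50)
  x <- seq(-20, 120, by = 0.5)
  expect_true(all(diff(prob_correct(x, pf)) > 0))
  p_by_alpha <- vapply(seq(0, 100, by = 1),
                       function(a) prob_correct(40, psychfun(a)), 0)
  expect_true(all(diff(p_by_alpha) < 0))
})

test_that("hypothesis grid spans the presentable level range", {
  g <- hypothesis_grid(count = 2)
  expect_equal(g$alphas, c(-1.301175, 98.698825), tolerance = 1e-6)
  g150 <- hypothesis_grid()
  expect_equal(g150$count, 150L)
  expect_true(all(diff(g150$alphas) > 0))
  # target levels of first/last member hit the range bounds exactly
  lv <- vapply(c(1, 150), function(i)
    level_for_target(grid_member(g150, i), 0.70), 0)
  expect_equal(lv, c(0, 100))
  expect_error(hypothesis_grid(count = 1), "count")
  expect_error(hypothesis_grid(level_range = c(50, 50)), "increasing")
  expect_error(hypothesis_grid(level_range = c(-5, 100)))
})

test_that("log-likelihood matches an independently coded summation oracle", {
  pf <- psychfun(40)
  h1 <- trial_record(40, TRUE)
  expect_equal(log_likelihood(h1, pf), log(0.5625))
  h2 <- trial_record(c(40, 40), c(TRUE, FALSE))
  expect_equal(log_likelihood(h2, pf), log(0.5625) + log(1 - 0.5625))
  set.seed(21)
  for (i in 1:30) {
    h <- random_history(sample(1:50, 1))
    pf <- psychfun(runif(1, 0, 100))
    expect_equal(log_likelihood(h, pf),
                 oracle_loglik(h, pf$alpha, pf$beta, pf$gamma),
                 tolerance = 1e-12)
  }
  expect_error(log_likelihood(trial_record(numeric(0), logical(0)), pf),
               "at least one")
})

test_that("maximum-likelihood selection agrees with a brute-force scan", {
  g <- hypothesis_grid()
  set.seed(31)
  for (i in 1:200) {
    h <- random_history(sample(1:40, 1))
    k <- attr(select_mle(g, h), "index")
    expect_identical(k, oracle_select_index(g$alphas, g$beta, g$gamma, h))
  }
  expect_error(select_mle(g, NULL), "at least one")
})

test_that("a single correct trial at high coherence selects the most sensitive hypothesis", {
  g <- hypothesis_grid()
  h <- trial_record(100, TRUE)
  sel <- select_mle(g, h)
  expect_identical(attr(sel, "index"), 1L)
  expect_equal(sel$alpha, min(g$alphas))
})

test_that("long histories generated from one grid member recover that member", {
  g <- hypothesis_grid()
  set.seed(41)
  true_k <- 60L
  pf <- grid_member(g, true_k)
  lv <- runif(600, 0, 100)
  h <- trial_record(lv, runif(600) < prob_correct(lv, pf))
  expect_lt(abs(attr(select_mle(g, h), "index") - true_k), 4)
})
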