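# Fitness oracle used across optimizer tests: MCC surrogate = fraction of
# bits matching a target mask, hyperparameters ignored.
match_evaluator <- function(target) {
  function(mask, C, gamma) mean(as.integer(mask) == target)
}

test_that("firefly distance is Euclidean over all dimensions", {
  expect_equal(firefly_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(1, 0, 1, 0, 1, 1)
  b <- c(0, 1, 0, 1, 1, 1)
  expect_equal(firefly_distance(a, b), 2)   # 4 differing binary dims
  expect_equal(firefly_distance(a, b), firefly_distance(b, a))
  expect_error(firefly_distance(1:3, 1:4), "length")
})

test_that("attractiveness decays from beta0 with distance", {
  expect_equal(firefly_attractiveness(0, beta0 = 3), 3)
  expect_equal(firefly_attractiveness(10, beta0 = 3, absorption = 0), 3)
  r <- seq(0, 5, by = 0.5)
  expect_true(all(diff(firefly_attractiveness(r)) <= 0))
})

test_that("sigmoid discretization honours its identities", {
  expect_equal(firefly_bit_probability(0), 0.5)
  x <- seq(-10, 10, by = 0.37)
  expect_equal(firefly_bit_probability(x) + firefly_bit_probability(-x),
               rep(1, length(x)))
  set.seed(30)
  draws <- vapply(1:1e5, function(i) discretize_position(20), integer(1))
  expect_gte(mean(draws), 0.9999)
})

test_that("movement follows the attractiveness step with clipped ranges", {
  cfg <- dfa_config(group_size = 2, max_generation = 1, randomness = 0,
                    absorption = 0, beta0 = 1, seed = 1)
  xi <- c(-1, -1, 0, 0)   # 2 feature dims + log2 C + log2 gamma
  xj <- c(1, 1, 5, -5)
  expect_equal(firefly_move(xi, xj, cfg), xj)
  expect_equal(firefly_move(xj, xj, cfg), xj)

  # clipping of the hyperparameter dimensions
  cfg2 <- dfa_config(group_size = 2, max_generation = 1, randomness = 0,
                     absorption = 0, beta0 = 2, c_log2_range = c(-5, 15),
                     gamma_log2_range = c(-15, 5), seed = 1)
  moved <- firefly_move(c(0, 0, 14, 4), c(0, 0, 16, 6), cfg2)
  expect_lte(moved[3], 15)
  expect_lte(moved[4], 5)

  set.seed(77)
  m1 <- firefly_move(xi, xj, dfa_config(group_size = 2, seed = 1))
  set.seed(77)
  m2 <- firefly_move(xi, xj, dfa_config(group_size = 2, seed = 1))
  expect_identical(m1, m2)
})

test_that("fitness trades MCC against subset size", {
  cfg <- dfa_config(group_size = 2, w_mcc = 1, w_size = 0, seed = 1)
  expect_equal(dfa_fitness(0.7, c(1, 0, 1), cfg), 0.7)
  cfg2 <- dfa_config(group_size = 2, w_mcc = 0.9, w_size = 0.1, seed = 1)
  expect_equal(dfa_fitness(1, rep(1, 10), cfg2), 0.9)
  expect_equal(dfa_fitness(1, c(1, rep(0, 9)), cfg2), 0.9 + 0.1 * 0.9)
  expect_error(dfa_fitness(1, rep(0, 5), cfg2), "active")
  expect_error(dfa_config(group_size = 2, w_mcc = 0.5, w_size = 0.1),
               "sum to 1")
})

test_that("the optimizer finds a small planted optimum", {
  target <- c(1L, 0L, 1L, 0L, 0L, 1L)
  cfg <- dfa_config(group_size = 10, max_generation = 30, w_mcc = 1,
                    w_size = 0, seed = 4)
  res <- dfa_optimize(match_evaluator(target), n = 6, config = cfg)
  expect_equal(res$best_fitness, 1)
  expect_equal(res$best_mask, target)
})

test_that("optimizer invariants: trace, ranges, reproducibility", {
  target <- c(1L, 1L, 0L, 0L, 1L)
  cfg <- dfa_config(group_size = 8, max_generation = 10, seed = 6)
  res1 <- dfa_optimize(match_evaluator(target), n = 5, config = cfg)
  res2 <- dfa_optimize(match_evaluator(target), n = 5, config = cfg)
  expect_identical(res1, res2)

  expect_true(all(diff(res1$trace) >= 0))
  expect_equal(res1$best_fitness, res1$trace[length(res1$trace)])
  expect_gte(sum(res1$best_mask), 1)
  expect_gte(log2(res1$best_C), cfg$c_log2_range[1])
  expect_lte(log2(res1$best_C), cfg$c_log2_range[2])
  expect_gte(log2(res1$best_gamma), cfg$gamma_log2_range[1])
  expect_lte(log2(res1$best_gamma), cfg$gamma_log2_range[2])

  one <- dfa_optimize(match_evaluator(target), n = 5,
                      config = dfa_config(group_size = 8,
                                          max_generation = 1, seed = 6))
  expect_length(one$trace, 1)
  expect_true(all(one$best_mask %in% c(0L, 1L)))
})

test_that("empty masks are repaired to a single active bit", {
  # an evaluator that records masks; strongly negative positions make empty
  # draws overwhelmingly likely before repair
  seen <- list()
  ev <- function(mask, C, gamma) {
    seen[[length(seen) + 1]] <<- mask
    0
  }
  cfg <- dfa_config(group_size = 4, max_generation = 2, seed = 8)
  res <- dfa_optimize(ev, n = 3, config = cfg)
  expect_true(all(vapply(seen, sum, numeric(1)) >= 1))
  expect_gte(sum(res$best_mask), 1)
})
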