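# Stochastic operant-process simulator.

test_that("paths are deterministic given a seed and never leave [0,1]", {
  m <- preset_model("lyubich_shapiro", a1 = "3/10", a2 = "6/10")
  p1 <- simulate_two_choice(m, x0 = 0.5, seed = 42)
  p2 <- simulate_two_choice(m, x0 = 0.5, seed = 42)
  expect_identical(p1$states, p2$states)
  expect_identical(p1$outcome, p2$outcome)
  expect_true(all(p1$states >= 0 & p1$states <= 1))
  p3 <- simulate_two_choice(m, x0 = 0.5, seed = 43)
  expect_false(identical(p1$states, p3$states))
})

test_that("degenerate processes behave as their closed forms dictate", {
  ident <- discrete_model(make_affine_operator("1", "0"),
                          make_affine_operator("1", "0"), classical = FALSE)
  p <- simulate_two_choice(ident, x0 = 0.7, max_steps = 50)
  expect_identical(p$outcome, "censored")
  expect_true(all(p$states == 0.7))
  expect_identical(p$steps, 50L)

  # g1 = 1, g2 = 0: a single Bernoulli(x0) trial decides fixation
  bern <- discrete_model(make_affine_operator("0", "1"),
                         make_affine_operator("0", "0"), classical = FALSE)
  one <- simulate_two_choice(bern, x0 = 0.7, seed = 5)
  expect_identical(one$steps, 1L)
  est <- estimate_fixation_probability(bern, x0 = 0.7, n_reps = 4000, seed = 9)
  expect_lt(abs(est$p_hat - 0.7), 3 * est$se)

  m <- preset_model("lyubich_shapiro", a1 = "3/10", a2 = "3/10")
  expect_identical(estimate_fixation_probability(m, 0, 50, seed = 1)$p_hat, 0)
  expect_identical(estimate_fixation_probability(m, 1, 50, seed = 1)$p_hat, 1)
})

test_that("the symmetric process is a martingale: fixation probability equals x0", {
  set.seed(1) # master seeds drawn once per cell
  cells <- expand.grid(a = c("1/10", "3/10", "1/2"), x0 = c(0.25, 0.5, 0.75),
                       stringsAsFactors = FALSE)
  ok <- 0L
  for (i in seq_len(nrow(cells))) {
    m <- preset_model("lyubich_shapiro", a1 = cells$a[i], a2 = cells$a[i])
    est <- estimate_fixation_probability(m, cells$x0[i], n_reps = 1500,
                                         seed = sample.int(1e6, 1))
    if (abs(est$p_hat - cells$x0[i]) <= 3 * est$se) ok <- ok + 1L
  }
  expect_gte(ok, ceiling(0.95 * nrow(cells)) - 1L) # allow one 3-sigma miss
})

test_that("four-outcome draws follow the reward table probabilities", {
  ops <- replicate(4, make_affine_operator("1/5", "1/5"), simplify = FALSE)
  # one-step outcome frequencies at x0 = 0.5, p = 0.3
  n <- 20000L
  draws <- vapply(seq_len(n), function(i) {
    p <- simulate_four_outcome(0.3, ops, x0 = 0.5, seed = i, max_steps = 1)
    attr(p, "outcomes")[1]
  }, integer(1))
  freq <- tabulate(draws, nbins = 4) / n
  expected <- c(0.15, 0.35, 0.15, 0.35)
  for (k in 1:4) {
    se <- sqrt(expected[k] * (1 - expected[k]) / n)
    expect_lt(abs(freq[k] - expected[k]), 3 * se)
  }
  # p = 1 suppresses the (1-p) outcomes entirely
  p1 <- simulate_four_outcome(1, ops, x0 = 0.5, seed = 3, max_steps = 300)
  expect_true(all(attr(p1, "outcomes") %in% c(1L, 3L)))
  # all operators contract to the interior point 1/4: no fixation, censored
  expect_identical(p1$outcome, "censored")
  expect_true(all(p1$states >= 0 & p1$states <= 1))
})

test_that("simulation agrees with the solved fixation probability", {
  m <- preset_model("lyubich_shapiro", a1 = "3/10", a2 = "6/10")
  rep <- compare_to_solution(m, x_grid = c(0.25, 0.5, 0.75), n_reps = 3000,
                             seed = 17)
  expect_identical(nrow(rep), 3L)
  expect_true(all(!rep$flagged))
  expect_true(all(rep$z <= 3))

  empty <- compare_to_solution(m, x_grid = c(0.5), n_reps = 0)
  expect_identical(nrow(empty), 0L)
})

test_that("the simulate method returns reproducible replicate paths", {
  m <- preset_model("lyubich_shapiro", a1 = "3/10", a2 = "6/10")
  paths <- simulate(m, nsim = 3, seed = 7, x0 = 0.5)
  expect_length(paths, 3L)
  paths2 <- simulate(m, nsim = 3, seed = 7, x0 = 0.5)
  expect_identical(lapply(paths, `[[`, "states"),
                   lapply(paths2, `[[`, "states"))
  expect_false(identical(paths[[1]]$states, paths[[2]]$states))
})
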