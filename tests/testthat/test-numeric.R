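# Grid Picard solver and discrete fixed-point solver.

test_that("one numeric step matches the exact first iterate within quadrature error", {
  m <- preset_model("example1")
  g1_exact <- picard_iterates(m, 1)$iterates[[2]]
  f0 <- grid_function(fun = identity, n_points = 1001)
  g1 <- picard_step_numeric(m, f0)
  expect_identical(g1$values[1], 0)
  expect_lt(max(abs(g1$values - as.function(g1_exact)(g1$x))), 5e-6)

  m2 <- preset_model("example2", p = "1/2")
  g1b <- picard_step_numeric(m2, f0)
  expect_lt(max(abs(g1b$values - (g1b$x^2 / 10 + g1b$x / 5))), 1e-5)

  z <- picard_step_numeric(m, grid_function(values = rep(0, 501)))
  expect_identical(max(abs(z$values)), 0)
})

test_that("quadrature error shrinks about fourfold per grid doubling", {
  m <- preset_model("example1")
  g1_exact <- as.function(picard_iterates(m, 1)$iterates[[2]])
  errs <- vapply(c(501L, 1001L, 2001L), function(np) {
    g <- picard_step_numeric(m, grid_function(fun = identity, n_points = np))
    max(abs(g$values - g1_exact(g$x)))
  }, numeric(1))
  ratios <- errs[-length(errs)] / errs[-1L]
  expect_true(all(ratios > 3 & ratios < 5))
})

test_that("x-dependent weights are integrated correctly", {
  # weights x and 1-x with identity-like affine operators: for f(t)=t the
  # step gives int_0^x [x t + (1-x) t] dt = x^2/2 exactly (up to quadrature)
  m <- preset_model("berinde_khan", a1 = "1/2", a2 = "1/2")
  # overwrite operators with identity to get a closed form
  m2 <- integral_model(
    list(poly_weight(1, 0, "1"), poly_weight(c(0, 1), c(0, 0), c("1", "-1"))),
    list(make_affine_operator("1", "0"), make_affine_operator("1", "0")))
  g <- picard_step_numeric(m2, grid_function(fun = identity, n_points = 501))
  expect_lt(max(abs(g$values - g$x^2 / 2)), 1e-5)
  # and the exact engine agrees on the same model
  ge <- picard_step_exact(m2, rational_polynomial(c("0", "1")))
  expect_identical(attr(coefficient_query(ge, 2), "exact"), "1/2")
})

test_that("the integral solve contracts to the zero function with non-increasing deltas", {
  m <- preset_model("example1")
  res <- solve_integral(m, tol = 1e-8)
  expect_true(res$converged)
  expect_lte(max(abs(res$solution$values)), 1e-7)
  expect_true(all(diff(res$delta_history) <= 1e-15))
  h <- 1 / 1000
  expect_true(all(res$delta_history[-1L] / res$delta_history[-length(res$delta_history)]
                  <= 1 + 10 * h))

  z <- solve_integral(m, gamma0 = grid_function(values = rep(0, 101)))
  expect_true(z$converged)
  expect_identical(z$iterations_used, 1L)
  expect_identical(z$final_delta, 0)
})

test_that("the discrete solver recovers f(x) = x whenever a1 = a2", {
  for (a in c("1/10", "3/10", "1/2", "9/10")) {
    m <- preset_model("lyubich_shapiro", a1 = a, a2 = a)
    s <- solve_discrete(m, n_points = 1001)
    expect_true(s$converged)
    expect_lte(max(abs(s$solution$values - s$solution$x)), 1e-6)
  }
})

test_that("the asymmetric discrete solution is a monotone probability curve, stable under refinement", {
  m <- preset_model("lyubich_shapiro", a1 = "3/10", a2 = "6/10")
  s <- solve_discrete(m, n_points = 1001)
  expect_true(s$converged)
  v <- s$solution$values
  expect_identical(v[1], 0); expect_identical(v[length(v)], 1)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(diff(v) >= -1e-12))

  s501 <- solve_discrete(m, n_points = 501)
  s2001 <- solve_discrete(m, n_points = 2001)
  on_common <- function(s) predict(s, seq(0, 1, length.out = 501))
  expect_lte(max(abs(on_common(s501) - on_common(s2001))), 2e-4)
})

test_that("identity operators leave every function fixed and are flagged non-contractive", {
  m <- discrete_model(make_affine_operator("1", "0"),
                      make_affine_operator("1", "0"), classical = FALSE)
  s <- solve_discrete(m, n_points = 101)
  expect_true(s$converged)
  expect_identical(s$iterations_used, 1L)
  expect_lte(max(abs(s$solution$values - s$solution$x)), 1e-12)
  expect_true(any(grepl("non-contractive", s$warnings)))
})

test_that("residual norms match their closed forms and the exact trace deltas", {
  m <- preset_model("example1")
  expect_identical(residual_norm(m, grid_function(values = rep(0, 501))), 0)

  d <- preset_model("lyubich_shapiro", a1 = "3/10", a2 = "3/10")
  expect_lte(residual_norm(d, grid_function(fun = identity, n_points = 501)),
             1e-10)

  tr <- picard_iterates(m, 2)
  f1 <- grid_function(fun = as.function(tr$iterates[[2]]), n_points = 2001)
  expect_equal(residual_norm(m, f1), tr$sup_norm_deltas[2], tolerance = 1e-3)
})

test_that("operators leaving [0,1] stop the numeric step with a located error", {
  m <- integral_model(
    list(poly_weight(0, 1, "1"), poly_weight(c(0, 0), c(0, 1), c("1", "-1"))),
    list(make_affine_operator("1/4", "1/4"),
         generic_operator(function(t) pmin(1, pmax(0, t)))))
  m$terms[[2]]$op$fun <- function(t) 1.2 * t # corrupt after validation
  expect_error(picard_step_numeric(m, grid_function(fun = identity,
                                                    n_points = 101)),
               "outside \\[0,1\\] at node")
})
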