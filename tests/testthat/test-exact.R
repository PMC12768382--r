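# Exact symbolic Picard engine.

test_that("affine composition expands exactly", {
  x <- rational_polynomial(c("0", "1"))
  c1 <- poly_compose_affine(x, make_affine_operator("1/4", "1/4"))
  expect_identical(attr(coefficient_query(c1, 0), "exact"), "1/4")
  expect_identical(attr(coefficient_query(c1, 1), "exact"), "1/4")

  x2 <- rational_polynomial(c("0", "0", "1"))
  ident <- make_affine_operator("1", "0")
  expect_identical(attr(coefficient_query(poly_compose_affine(x2, ident), 2),
                        "exact"), "1")

  # the inner term of the two-step computation, checked against an
  # independent symbolic expansion
  g1 <- rational_polynomial(c("0", "2/5", "1/40", "1/60"))
  comp <- poly_compose_affine(g1, make_affine_operator("1/5", "2/5"))
  expect_iterate_coeffs_full(comp, ORACLE_COMPOSE)

  expect_error(
    poly_compose_affine(x, generic_operator(function(t) t^2)),
    "affine")
})

test_that("one exact Picard step reproduces the first iterate of both worked models", {
  m1 <- preset_model("example1")
  x <- rational_polynomial(c("0", "1"))
  g1 <- picard_step_exact(m1, x)
  expect_iterate_coeffs(g1, ORACLE_EX1$g1)

  g1b <- picard_step_exact(preset_model("example2"), x)
  expect_iterate_coeffs(g1b, ORACLE_EX2$g1)

  # T is linear and homogeneous: the zero polynomial is fixed
  z <- picard_step_exact(m1, rational_polynomial(character(0)))
  expect_identical(attr(coefficient_query(z, 0), "exact"), "0")
  expect_identical(attr(coefficient_query(z, 1), "exact"), "0")
})

test_that("two and three exact steps reproduce the full worked-example iterates", {
  tr <- picard_iterates(preset_model("example1"), n = 3)
  expect_length(tr$iterates, 4L)
  expect_iterate_coeffs(tr$iterates[[3]], ORACLE_EX1$g2)
  expect_iterate_coeffs(tr$iterates[[4]], ORACLE_EX1$g3)
  expect_identical(evaluate_poly(tr$iterates[[2]], "1"), ORACLE_EX1$g1_at_1)
  expect_identical(evaluate_poly(tr$iterates[[3]], "1"), ORACLE_EX1$g2_at_1)
  expect_identical(evaluate_poly(tr$iterates[[4]], "1"), ORACLE_EX1$g3_at_1)

  tr2 <- picard_iterates(preset_model("example2"), n = 3)
  expect_iterate_coeffs(tr2$iterates[[3]], ORACLE_EX2$g2)
  expect_iterate_coeffs(tr2$iterates[[4]], ORACLE_EX2$g3)
})

test_that("coefficient queries return lowest-terms pairs and (0,1) for absent degrees", {
  tr <- picard_iterates(preset_model("example1"), n = 2)
  cq <- coefficient_query(tr$iterates[[3]], 3)
  expect_equal(as.numeric(cq), c(3217, 480000))
  expect_identical(attr(cq, "exact"), "3217/480000")
  expect_equal(as.numeric(coefficient_query(tr$iterates[[2]], 1)), c(2, 5))
  expect_equal(as.numeric(coefficient_query(rational_polynomial(character(0)), 5)),
               c(0, 1))
})

test_that("the exact step is linear over random rational combinations", {
  m <- preset_model("example1")
  set.seed(21)
  for (i in 1:10) {
    p <- random_rpoly(); q <- random_rpoly()
    a <- random_rational(); b <- random_rational()
    lhs <- picard_step_exact(m, poly_add(poly_scale(p, a), poly_scale(q, b)))
    rhs <- poly_add(poly_scale(picard_step_exact(m, p), a),
                    poly_scale(picard_step_exact(m, q), b))
    for (k in 0:max(length(lhs$coeffs), length(rhs$coeffs)))
      expect_identical(attr(coefficient_query(lhs, k), "exact"),
                       attr(coefficient_query(rhs, k), "exact"))
  }
})

test_that("the operator is non-expansive in sup norm on random polynomial pairs", {
  m <- preset_model("example1")
  xs <- seq(0, 1, length.out = 2001)
  set.seed(22)
  for (i in 1:10) {
    p <- random_rpoly(); q <- random_rpoly()
    tp <- picard_step_exact(m, p); tq <- picard_step_exact(m, q)
    d_in <- max(abs(as.function(p)(xs) - as.function(q)(xs)))
    d_out <- max(abs(as.function(tp)(xs) - as.function(tq)(xs)))
    expect_lte(d_out, d_in + 1e-12)
  }
})

test_that("every iterate vanishes at x = 0 and the degree law holds", {
  # degree grows by 1 + (t-degree of the surviving weight) per step: by 2 for
  # the pigeon model; by 1 for the four-outcome model, whose t-linear weight
  # terms cancel when the operators coincide (the printed second iterate is
  # cubic, not quintic)
  growth <- c(example1 = 2L, example2 = 1L)
  for (preset in names(growth)) {
    tr <- picard_iterates(preset_model(preset), n = 3)
    for (i in seq_along(tr$iterates)) {
      expect_identical(evaluate_poly(tr$iterates[[i]], "0"), "0")
      expect_equal(length(tr$iterates[[i]]$coeffs) - 1L,
                   growth[[preset]] * (i - 1L) + 1L)
    }
  }
  expect_error(picard_iterates(preset_model("example1"), n = 1,
                               gamma0 = rational_polynomial(c("1", "1"))),
               "vanish")
})

test_that("four-outcome iterates do not depend on p", {
  ref <- picard_iterates(preset_model("example2", p = "1/2"), n = 2)
  for (p in c("0", "1/4", "1")) {
    tr <- picard_iterates(preset_model("example2", p = p), n = 2)
    for (k in 0:3)
      expect_identical(attr(coefficient_query(tr$iterates[[3]], k), "exact"),
                       attr(coefficient_query(ref$iterates[[3]], k), "exact"))
  }
})

test_that("the homogeneous iterates decay monotonically in sup norm", {
  tr <- picard_iterates(preset_model("example1"), n = 3)
  norms <- vapply(tr$iterates[-1L], function(p)
    max(abs(as.function(p)(seq(0, 1, length.out = 2001)))), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_equal(length(tr$sup_norm_deltas), 3L)
  expect_true(all(tr$sup_norm_deltas > 0))
})

test_that("the exact engine rejects models it cannot solve symbolically", {
  m <- integral_model(
    list(callable_weight(function(x, t) t, t_only = TRUE),
         callable_weight(function(x, t) 1 - t, t_only = TRUE)),
    list(make_affine_operator("1/4", "1/4"), make_affine_operator("1/5", "2/5")))
  expect_error(picard_step_exact(m, rational_polynomial(c("0", "1"))),
               "polynomial weights")
  expect_error(picard_iterates(preset_model("example1"), n = 30), "max_n")
})
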