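# Frozen expected values.
#
# The exact iterate coefficients below were computed with an independent
# general-purpose symbolic integrator (sympy 1.14) applied directly to the
# integral recursions, and cross-checked against the printed worked-example
# values where those exist. They are stored as lowest-terms rational strings.

# pigeon-type model, weights t / 1-t, E1(t)=(t+1)/4, E2(t)=(t+2)/5,
# Gamma0(x)=x; coefficients listed from degree 1 upward.
ORACLE_EX1 <- list(
  g1 = c("2/5", "1/40", "1/60"),
  g2 = c("619/3750", "3577/320000", "3217/480000", "13/76800", "61/2400000"),
  g3 = c("85310867/1250000000", "35622000511/7680000000000",
         "510092477/184320000000", "57051161/768000000000",
         "39825883/3840000000000", "1694537/23040000000000",
         "128161/53760000000000"),
  g1_at_1 = "53/120",
  g2_at_1 = "586053/3200000",
  g3_at_1 = "339311330807/4480000000000"
)

# four-outcome model, all operators E(t) = (t+1)/5, any p.
ORACLE_EX2 <- list(
  g1 = c("1/5", "1/10"),
  g2 = c("11/250", "3/125", "1/750"),
  g3 = c("458/46875", "84/15625", "31/93750", "1/375000")
)

# (x^3/60 + x^2/40 + 2x/5) composed with t -> (t+2)/5, expanded:
ORACLE_COMPOSE <- c("619/3750", "107/1250", "9/5000", "1/7500")

expect_exact_coef <- function(poly, k, expected) {
  got <- attr(coefficient_query(poly, k), "exact")
  expect_identical(got, expected)
}

expect_iterate_coeffs_full <- function(poly, coeffs_from_deg0) {
  for (k in seq_along(coeffs_from_deg0))
    expect_exact_coef(poly, k - 1L, coeffs_from_deg0[k])
}

expect_iterate_coeffs <- function(poly, coeffs_from_deg1) {
  expect_exact_coef(poly, 0, "0")
  for (k in seq_along(coeffs_from_deg1))
    expect_exact_coef(poly, k, coeffs_from_deg1[k])
}

# random small polynomial with rational coefficients vanishing at 0
random_rpoly <- function(max_deg = 4L) {
  deg <- sample(1:max_deg, 1)
  coeffs <- c("0", paste0(sample(-9:9, deg, replace = TRUE), "/",
                          sample(1:12, deg, replace = TRUE)))
  rational_polynomial(coeffs)
}

random_rational <- function() paste0(sample(-9:9, 1), "/", sample(1:12, 1))
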