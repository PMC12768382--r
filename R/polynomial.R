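# Univariate polynomials with exact rational coefficients: the representation
# of every Picard iterate in the exact engine. Coefficients are stored densely
# (index k+1 holds the x^k coefficient) with trailing zeros stripped; the zero
# polynomial has an empty coefficient list.

rp_new <- function(coeffs, var = "x") {
  while (length(coeffs) && q_is_zero(coeffs[[length(coeffs)]]))
    coeffs[[length(coeffs)]] <- NULL
  structure(list(coeffs = coeffs, var = var), class = "rational_poly")
}

#' Construct a polynomial with exact rational coefficients
#'
#' Coefficients are given in increasing degree order (constant term first) as
#' rational strings (\code{"num/den"}), integers, or short decimals with an
#' exact decimal expansion.
#'
#' @param coeffs character or numeric vector of coefficients, degree 0 upward.
#' @param var variable label used when printing.
#' @return an object of class \code{rational_poly}.
#' @examples
#' rational_polynomial(c("0", "2/5", "1/40", "1/60")) # the pigeon-model Gamma1
#' @export
rational_polynomial <- function(coeffs, var = "x") {
  rp_new(lapply(coeffs, q_from), var = var)
}

rp_zero <- function(var = "x") rp_new(list(), var = var)
rp_x <- function(var = "x") rp_new(list(q_zero(), q_one()), var = var)

rp_degree <- function(p) length(p$coeffs) - 1L
rp_is_zero <- function(p) length(p$coeffs) == 0L

rp_coef_q <- function(p, k) {
  if (k < 0L || k >= length(p$coeffs)) return(q_zero())
  p$coeffs[[k + 1L]]
}

rp_add <- function(p, q) {
  n <- max(length(p$coeffs), length(q$coeffs))
  out <- vector("list", n)
  for (k in seq_len(n))
    out[[k]] <- q_add(rp_coef_q(p, k - 1L), rp_coef_q(q, k - 1L))
  rp_new(out, var = p$var)
}

rp_scale <- function(p, a) {
  if (q_is_zero(a)) return(rp_zero(p$var))
  rp_new(lapply(p$coeffs, function(c) q_mul(c, a)), var = p$var)
}

# multiply by (s*x + c)
rp_mul_linear <- function(p, s, c) {
  if (rp_is_zero(p)) return(p)
  n <- length(p$coeffs)
  out <- rep(list(q_zero()), n + 1L)
  for (k in seq_len(n)) {
    ck <- p$coeffs[[k]]
    out[[k]] <- q_add(out[[k]], q_mul(ck, c))
    out[[k + 1L]] <- q_add(out[[k + 1L]], q_mul(ck, s))
  }
  rp_new(out, var = p$var)
}

# exact composition p(s*t + c), Horner in the affine argument
rp_compose_affine_sc <- function(p, s, c, var = "t") {
  if (rp_is_zero(p)) return(rp_zero(var))
  acc <- rp_new(list(p$coeffs[[length(p$coeffs)]]), var = var)
  for (k in (length(p$coeffs) - 1L):1) {
    if (k < 1L) break
    acc <- rp_mul_linear(acc, s, c)
    acc <- rp_add(acc, rp_new(list(p$coeffs[[k]]), var = var))
  }
  acc
}

# exact antiderivative with zero constant term
rp_integrate <- function(p) {
  if (rp_is_zero(p)) return(p)
  n <- length(p$coeffs)
  out <- vector("list", n + 1L)
  out[[1L]] <- q_zero()
  for (k in seq_len(n))
    out[[k + 1L]] <- q_div(p$coeffs[[k]], q_from(k))
  rp_new(out, var = p$var)
}

rp_eval_q <- function(p, x) {
  x <- q_from(x)
  acc <- q_zero()
  for (k in rev(seq_along(p$coeffs)))
    acc <- q_add(q_mul(acc, x), p$coeffs[[k]])
  acc
}

rp_coef_num <- function(p) vapply(p$coeffs, q_to_double, numeric(1))

rp_eval_num <- function(p, x) {
  cf <- rp_coef_num(p)
  acc <- rep(0, length(x))
  for (k in rev(seq_along(cf))) acc <- acc * x + cf[k]
  acc
}

#' Exact polynomial arithmetic
#'
#' Add two polynomials, or scale one by an exact rational.
#'
#' @param p,q \code{rational_poly} objects.
#' @param a a rational (string, numeric, or exact value).
#' @return a \code{rational_poly}.
#' @export
poly_add <- function(p, q) {
  stopifnot(inherits(p, "rational_poly"), inherits(q, "rational_poly"))
  rp_add(p, q)
}

#' @rdname poly_add
#' @export
poly_scale <- function(p, a) {
  stopifnot(inherits(p, "rational_poly"))
  rp_scale(p, q_from(a))
}

#' Evaluate an exact polynomial at a rational point
#'
#' Horner evaluation in exact rational arithmetic.
#'
#' @param poly a \code{rational_poly}.
#' @param x evaluation point, as a rational string or numeric.
#' @param as character: return a \code{"string"} (\code{"num/den"}) or a
#'   \code{"double"}.
#' @return the exact value as a string, or its double approximation.
#' @export
evaluate_poly <- function(poly, x, as = c("string", "double")) {
  stopifnot(inherits(poly, "rational_poly"))
  as <- match.arg(as)
  v <- rp_eval_q(poly, x)
  if (as == "string") q_to_string(v) else q_to_double(v)
}

#' Query one exact coefficient of a polynomial
#'
#' @param poly a \code{rational_poly}.
#' @param k degree (non-negative integer).
#' @return named numeric vector \code{c(numerator, denominator)} in lowest
#'   terms (\code{c(0, 1)} for absent degrees), with the exact decimal string
#'   in attribute \code{"exact"}. Numerator/denominator are returned as
#'   doubles and are exact whenever they are below 2^53; the attribute is
#'   always exact.
#' @export
coefficient_query <- function(poly, k) {
  stopifnot(inherits(poly, "rational_poly"), k >= 0)
  q <- rp_coef_q(poly, as.integer(k))
  out <- c(numerator = bi_to_double(q$n), denominator = bi_to_double(q$d))
  attr(out, "exact") <- q_to_string(q)
  out
}

#' @export
format.rational_poly <- function(x, ...) {
  if (rp_is_zero(x)) return("0")
  terms <- character(0)
  for (k in rev(seq_along(x$coeffs) - 1L)) {
    q <- x$coeffs[[k + 1L]]
    if (q_is_zero(q)) next
    mono <- if (k == 0L) "" else if (k == 1L) x$var else paste0(x$var, "^", k)
    cs <- q_to_string(q)
    terms <- c(terms, if (nzchar(mono)) paste0("(", cs, ")*", mono) else cs)
  }
  paste(terms, collapse = " + ")
}

#' @export
print.rational_poly <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.function.rational_poly <- function(x, ...) {
  p <- x
  function(x) rp_eval_num(p, x)
}
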