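# Exact symbolic Picard iteration.
#
# For polynomial weights and affine operators every iterate of the Volterra
# operator (T Gamma)(x) = int_0^x sum_i w_i(x,t) Gamma(E_i(t)) dt is again a
# polynomial with rational coefficients: composition with an affine map
# preserves degree, multiplication by a bivariate monomial and term-wise
# integration raise it by at most 1 + deg_t(w). All arithmetic is exact.

#' Compose a polynomial with an affine response operator
#'
#' Exact expansion of \eqn{p(s\,t + c)}; degree is preserved.
#'
#' @param poly a \code{rational_poly}.
#' @param op an affine \code{response_operator}.
#' @return a \code{rational_poly} in the variable \code{t}.
#' @examples
#' p <- rational_polynomial(c("0", "1")) # p(x) = x
#' poly_compose_affine(p, make_affine_operator("1/4", "1/4")) # t/4 + 1/4
#' @export
poly_compose_affine <- function(poly, op) {
  stopifnot(inherits(poly, "rational_poly"), inherits(op, "response_operator"))
  if (!op_is_affine(op))
    stop("exact composition requires an affine operator")
  rp_compose_affine_sc(poly, op$slope, op$intercept, var = "t")
}

#' One exact Picard step
#'
#' Applies the integral operator once:
#' \eqn{(T\Gamma)(x) = \int_0^x \sum_i w_i(x,t)\,\Gamma(E_i(t))\,dt},
#' computed term-wise in exact rational arithmetic. The result always
#' vanishes at \eqn{x = 0}.
#'
#' @param model an \code{integral_model} with polynomial weights and affine
#'   operators.
#' @param poly the current iterate, a \code{rational_poly}.
#' @return the next iterate, a \code{rational_poly}.
#' @examples
#' m <- preset_model("example1")
#' picard_step_exact(m, rational_polynomial(c("0", "1"))) # x^3/60 + x^2/40 + 2x/5
#' @export
picard_step_exact <- function(model, poly) {
  stopifnot(inherits(model, "integral_model"), inherits(poly, "rational_poly"))
  out <- list() # map degree -> rational, built sparsely then densified
  add_term <- function(deg, val) {
    key <- as.character(deg)
    out[[key]] <<- if (is.null(out[[key]])) val else q_add(out[[key]], val)
  }
  for (term in model$terms) {
    w <- term$weight; op <- term$op
    if (!wf_is_poly(w))
      stop("exact engine requires polynomial weights (got a callable)")
    if (!op_is_affine(op))
      stop("exact engine requires affine operators")
    comp <- poly_compose_affine(poly, op) # poly(E(t)) as polynomial in t
    for (tm in w$terms) {
      # c x^i t^j * sum_k b_k t^k integrated in t from 0 to x:
      #   sum_k c b_k / (j+k+1) * x^{i+j+k+1}
      for (k in seq_along(comp$coeffs)) {
        bk <- comp$coeffs[[k]]
        if (q_is_zero(bk)) next
        kk <- k - 1L
        add_term(tm$xd + tm$td + kk + 1L,
                 q_div(q_mul(tm$c, bk), q_from(tm$td + kk + 1)))
      }
    }
  }
  if (!length(out)) return(rp_zero())
  degs <- as.integer(names(out))
  coeffs <- rep(list(q_zero()), max(degs) + 1L)
  for (i in seq_along(degs)) coeffs[[degs[i] + 1L]] <- out[[i]]
  rp_new(coeffs, var = "x")
}

#' Run exact Picard iteration
#'
#' Generates the Picard sequence \eqn{\Gamma_{n+1} = T\Gamma_n} in exact
#' rational arithmetic, starting from \eqn{\Gamma_0(x) = x} by default (the
#' starting point of the worked examples). Successive sup-norm differences
#' \eqn{\|\Gamma_{n+1}-\Gamma_n\|_\infty} are evaluated numerically on a
#' dense grid as a convergence diagnostic.
#'
#' @param model an \code{integral_model} solvable by the exact engine.
#' @param n number of Picard steps (\eqn{\ge 0}).
#' @param gamma0 initial iterate, a \code{rational_poly} vanishing at 0.
#' @param max_n safety cap on the iteration depth; degree (and coefficient
#'   size) grows with every step, so deep exact iteration is expensive.
#' @param norm_grid number of grid points for the sup-norm diagnostic.
#' @return an object of class \code{picard_trace}: fields \code{iterates}
#'   (list of \code{rational_poly}, length \code{n + 1}),
#'   \code{sup_norm_deltas}, \code{model}.
#' @examples
#' tr <- picard_iterates(preset_model("example1"), n = 2)
#' coefficient_query(tr$iterates[[3]], 3) # 3217/480000
#' @export
picard_iterates <- function(model, n, gamma0 = rational_polynomial(c("0", "1")),
                            max_n = 25L, norm_grid = 10001L) {
  stopifnot(inherits(model, "integral_model"), n >= 0)
  if (n > max_n)
    stop("iteration depth ", n, " exceeds max_n = ", max_n,
         " (raise max_n explicitly for deep exact iteration)")
  if (!q_is_zero(rp_eval_q(gamma0, 0)))
    stop("gamma0 must vanish at x = 0")
  iterates <- vector("list", n + 1L)
  iterates[[1L]] <- gamma0
  for (i in seq_len(n))
    iterates[[i + 1L]] <- picard_step_exact(model, iterates[[i]])
  xs <- seq(0, 1, length.out = norm_grid)
  deltas <- if (n >= 1L)
    vapply(seq_len(n), function(i)
      max(abs(rp_eval_num(iterates[[i + 1L]], xs) -
              rp_eval_num(iterates[[i]], xs))), numeric(1))
  else numeric(0)
  structure(list(iterates = iterates, sup_norm_deltas = deltas, model = model),
            class = "picard_trace")
}

#' @export
print.picard_trace <- function(x, ...) {
  n <- length(x$iterates) - 1L
  cat(sprintf("exact Picard trace: %d steps (Gamma0 .. Gamma%d)\n", n, n))
  for (i in seq_along(x$iterates)) {
    lab <- sprintf("Gamma%d", i - 1L)
    s <- format(x$iterates[[i]])
    if (nchar(s) > 100) s <- paste0(substr(s, 1, 97), "...")
    cat(sprintf("  %s = %s\n", lab, s))
  }
  if (length(x$sup_norm_deltas))
    cat("  sup-norm deltas:", format(x$sup_norm_deltas, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.picard_trace <- function(object, iterate = length(object$iterates) - 1L,
                              exact = FALSE, ...) {
  p <- object$iterates[[iterate + 1L]]
  if (exact) {
    out <- vapply(seq_along(p$coeffs), function(k) q_to_string(p$coeffs[[k]]),
                  character(1))
  } else out <- rp_coef_num(p)
  if (length(out)) names(out) <- paste0("x^", seq_along(out) - 1L)
  out
}

#' @export
predict.picard_trace <- function(object, x = seq(0, 1, length.out = 101L),
                                 iterate = length(object$iterates) - 1L, ...) {
  rp_eval_num(object$iterates[[iterate + 1L]], x)
}

#' @export
as.data.frame.picard_trace <- function(x, row.names = NULL, optional = FALSE,
                                       n_grid = 101L, ...) {
  xs <- seq(0, 1, length.out = n_grid)
  cols <- lapply(x$iterates, rp_eval_num, x = xs)
  names(cols) <- paste0("Gamma", seq_along(cols) - 1L)
  data.frame(x = xs, cols, row.names = row.names)
}

#' @export
plot.picard_trace <- function(x, n_grid = 201L, ...) {
  df <- as.data.frame(x, n_grid = n_grid)
  graphics::matplot(df$x, as.matrix(df[-1L]), type = "l", lty = 1,
                    xlab = "x", ylab = expression(Gamma[n](x)),
                    main = "Picard iterates", ...)
  graphics::legend("topleft", legend = names(df)[-1L], lty = 1,
                   col = seq_len(ncol(df) - 1L), bty = "n")
  invisible(df)
}
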