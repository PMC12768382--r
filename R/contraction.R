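# Contraction certificates: Lipschitz constants of the response operators,
# the aggregate condition sum(kappa_i) < 1 guaranteeing a unique solution via
# the Matkowski fixed-point theorem with linear comparison function
# phi(t) = k t, and the Banach-type a-priori iteration bound for linear phi.

#' Lipschitz constant of a response operator
#'
#' Affine operators have the exact constant \eqn{\kappa = |slope|}; generic
#' operators are estimated by the maximum absolute difference quotient over
#' adjacent grid pairs and flagged \code{"estimated"}.
#'
#' @param op a \code{response_operator}.
#' @param method \code{"exact"} (affine only) or \code{"grid"}.
#' @param n_grid grid resolution for the estimate (>= 100).
#' @return list with \code{kappa} (numeric), \code{method}, and
#'   \code{kappa_exact} (rational string, exact method only).
#' @export
lipschitz_constant <- function(op, method = c("auto", "exact", "grid"),
                               n_grid = 10001L) {
  stopifnot(inherits(op, "response_operator"))
  method <- match.arg(method)
  if (method == "auto") method <- if (op_is_affine(op)) "exact" else "grid"
  if (method == "exact") {
    if (!op_is_affine(op)) stop("exact Lipschitz constants exist only for affine operators")
    k <- q_abs(op$slope)
    return(list(kappa = q_to_double(k), method = "exact",
                kappa_exact = q_to_string(k)))
  }
  stopifnot(n_grid >= 100L)
  x <- seq(0, 1, length.out = n_grid)
  v <- op_eval(op, x)
  h <- x[2L] - x[1L]
  list(kappa = max(abs(diff(v))) / h, method = "estimated", kappa_exact = NULL)
}

#' Contraction certificate for a model
#'
#' Aggregates the Lipschitz constants \eqn{\kappa_i} of all response
#' operators and checks the sufficient conditions for a unique solution:
#' the Matkowski condition \eqn{\sum_i \kappa_i < 1} (with comparison
#' function \eqn{\varphi(t) = (\sum_i \kappa_i)\,t}) and its symmetric
#' corollary \eqn{2\max_i \kappa_i < 1}. Both inequalities are strict and,
#' for affine models, decided in exact rational arithmetic. The report is
#' \code{certified} only when every \eqn{\kappa_i} is exact.
#'
#' @param model an \code{integral_model} or \code{discrete_model}.
#' @param n_grid grid resolution for estimated constants.
#' @return an object of class \code{contraction_report}.
#' @examples
#' contraction_report(preset_model("example1")) # aggregate 9/20, satisfied
#' @export
contraction_report <- function(model, n_grid = 10001L) {
  ops <- if (inherits(model, "integral_model"))
    lapply(model$terms, `[[`, "op")
  else if (inherits(model, "discrete_model")) list(model$g1, model$g2)
  else stop("contraction_report needs an integral_model or discrete_model")
  per <- lapply(seq_along(ops), function(i) {
    lc <- lipschitz_constant(ops[[i]], n_grid = n_grid)
    list(id = i, kappa = lc$kappa, method = lc$method,
         kappa_exact = lc$kappa_exact,
         kappa_q = if (lc$method == "exact") q_abs(ops[[i]]$slope) else NULL)
  })
  certified <- all(vapply(per, function(p) p$method == "exact", logical(1)))
  if (certified) {
    agg_q <- Reduce(q_add, lapply(per, `[[`, "kappa_q"), q_zero())
    max_q <- Reduce(function(a, b) if (q_cmp(a, b) >= 0) a else b,
                    lapply(per, `[[`, "kappa_q"))
    theorem2 <- q_cmp(agg_q, q_one()) < 0
    corollary1 <- q_cmp(q_mul(q_from(2), max_q), q_one()) < 0
    aggregate_k <- q_to_double(agg_q)
    aggregate_exact <- q_to_string(agg_q)
  } else {
    aggregate_k <- sum(vapply(per, `[[`, numeric(1), "kappa"))
    theorem2 <- aggregate_k < 1
    corollary1 <- 2 * max(vapply(per, `[[`, numeric(1), "kappa")) < 1
    aggregate_exact <- NULL
  }
  structure(list(per_operator_kappa = per,
                 aggregate_k = aggregate_k,
                 aggregate_exact = aggregate_exact,
                 theorem2_satisfied = theorem2,
                 corollary1_satisfied = corollary1,
                 phi_description = sprintf("phi(t) = %s * t",
                                           aggregate_exact %||%
                                             format(aggregate_k, digits = 6)),
                 certified = certified),
            class = "contraction_report")
}

#' @export
print.contraction_report <- function(x, ...) {
  cat("contraction certificate\n")
  for (p in x$per_operator_kappa)
    cat(sprintf("  operator %d: kappa = %s  (%s)\n", p$id,
                p$kappa_exact %||% format(p$kappa, digits = 6), p$method))
  cat(sprintf("  aggregate k = %s\n",
              x$aggregate_exact %||% format(x$aggregate_k, digits = 6)))
  cat(sprintf("  Matkowski/Theorem condition sum(kappa) < 1: %s\n",
              if (x$theorem2_satisfied) "satisfied" else "NOT satisfied"))
  cat(sprintf("  corollary condition 2*max(kappa) < 1: %s\n",
              if (x$corollary1_satisfied) "satisfied" else "NOT satisfied"))
  cat(sprintf("  comparison function: %s\n", x$phi_description))
  cat(sprintf("  certificate status: %s\n",
              if (x$certified) "certified (all kappa exact)" else "heuristic (estimated kappa)"))
  invisible(x)
}

#' Iterate the linear comparison function
#'
#' Computes \eqn{[t_0, k t_0, \ldots, k^n t_0]}, the orbit of
#' \eqn{\varphi(t) = k t}. For \eqn{0 < k < 1} the orbit decreases strictly
#' to 0, which is exactly the comparison-function property the fixed-point
#' certificate relies on; for \eqn{k \ge 1} the result is flagged as not a
#' comparison function.
#'
#' @param k contraction factor (>= 0).
#' @param t0 starting value (>= 0).
#' @param n number of iterations.
#' @return an object of class \code{phi_trace}: fields \code{values}
#'   (length \code{n + 1}) and \code{is_comparison}.
#' @examples
#' phi_iterate(9/20, 1, 3)$values # 1, 0.45, 0.2025, 0.091125
#' @export
phi_iterate <- function(k, t0, n) {
  stopifnot(k >= 0, t0 >= 0, n >= 0)
  structure(list(values = t0 * k^(0:n), k = k, t0 = t0,
                 is_comparison = k < 1),
            class = "phi_trace")
}

#' @export
print.phi_trace <- function(x, ...) {
  cat("phi-orbit (phi(t) =", x$k, "* t):", format(x$values, digits = 6), "\n")
  if (!x$is_comparison)
    cat("  flag: not a comparison function (phi(t) < t fails for k >=", 1, ")\n")
  invisible(x)
}

#' A-priori iteration count from the Banach bound
#'
#' For a contraction with factor \eqn{k < 1} and first-step displacement
#' \eqn{d_1}, the a-priori error bound after \eqn{n} steps is
#' \eqn{k^n d_1 / (1-k)}. Returns the smallest \eqn{n} making the bound at
#' most \code{eps}.
#'
#' @param k contraction factor, strictly in (0, 1).
#' @param d1 first-step displacement (> 0).
#' @param eps target error (> 0).
#' @return an integer count.
#' @examples
#' a_priori_iterations(0.45, 1, 1e-6) # 19
#' @export
a_priori_iterations <- function(k, d1, eps) {
  if (!(k > 0 && k < 1)) stop("no contraction certificate: need 0 < k < 1")
  stopifnot(d1 > 0, eps > 0)
  if (d1 / (1 - k) <= eps) return(0L)
  n <- max(0L, floor(log(eps * (1 - k) / d1) / log(k)) - 2L)
  while (k^n * d1 / (1 - k) > eps) n <- n + 1L
  as.integer(n)
}
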