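# Grid-based solvers: cumulative-trapezoid Picard iteration for the integral
# form (arbitrary continuous weights/operators) and pinned fixed-point
# iteration for the discrete classical form. Values live on a uniform grid of
# [0,1] with endpoints included; compositions f(E(t)) use piecewise-linear
# interpolation, which preserves [0,1] containment and non-expansiveness.

#' Construct a grid function on [0,1]
#'
#' @param values numeric vector of node values, or \code{NULL} if \code{fun}
#'   is given.
#' @param fun a vectorized function sampled on the grid when \code{values} is
#'   \code{NULL}.
#' @param n_points number of uniform grid nodes (endpoints included, >= 3).
#' @return an object of class \code{grid_fn} with fields \code{x},
#'   \code{values}, \code{n_points}.
#' @examples
#' grid_function(fun = identity, n_points = 101)
#' @export
grid_function <- function(values = NULL, fun = NULL, n_points = 1001L) {
  if (is.null(values)) {
    stopifnot(is.function(fun))
    x <- seq(0, 1, length.out = n_points)
    values <- fun(x)
  } else {
    n_points <- length(values)
    x <- seq(0, 1, length.out = n_points)
  }
  stopifnot(n_points >= 3L, is.numeric(values), all(is.finite(values)))
  structure(list(x = x, values = values, n_points = as.integer(n_points)),
            class = "grid_fn")
}

#' @export
print.grid_fn <- function(x, ...) {
  cat(sprintf("grid function on [0,1]: %d nodes, range [%.4g, %.4g]\n",
              x$n_points, min(x$values), max(x$values)))
  invisible(x)
}

gf_interp <- function(f, xout) {
  stats::approx(f$x, f$values, xout = xout, rule = 2)$y
}

# cumulative trapezoid of g sampled on a uniform grid (first node weight 0)
cum_trapz <- function(g, h) {
  n <- length(g)
  c(0, cumsum((g[-n] + g[-1L]) / 2) * h)
}

#' One numeric Picard step for the integral form
#'
#' For each node \eqn{x_j}, evaluates
#' \eqn{\int_0^{x_j} \sum_i w_i(x_j,t) f(E_i(t)) dt}
#' by composite-trapezoid quadrature with piecewise-linear interpolation of
#' \eqn{f} at \eqn{E_i(t)}. Weights that do not depend on \eqn{x} use an
#' O(n) cumulative sweep; \eqn{x}-dependent weights fall back to a per-node
#' quadrature. Node 0 of the result is exactly 0.
#'
#' @param model a validated \code{integral_model}.
#' @param f the current iterate, a \code{grid_fn}.
#' @return the next iterate, a \code{grid_fn}.
#' @export
picard_step_numeric <- function(model, f) {
  stopifnot(inherits(model, "integral_model"), inherits(f, "grid_fn"))
  x <- f$x
  h <- x[2L] - x[1L]
  comp <- lapply(model$terms, function(term) {
    e <- op_eval(term$op, x)
    bad <- which(e < -1e-12 | e > 1 + 1e-12)
    if (length(bad))
      stop(sprintf("operator output %.6g outside [0,1] at node %d (t=%.6g)",
                   e[bad[1]], bad[1], x[bad[1]]))
    gf_interp(f, pmin(1, pmax(0, e)))
  })
  t_only <- all(vapply(model$terms, function(term) wf_t_only(term$weight),
                       logical(1)))
  if (t_only) {
    g <- rep(0, length(x))
    for (i in seq_along(model$terms))
      g <- g + wf_eval(model$terms[[i]]$weight, NA_real_, x) * comp[[i]]
    vals <- cum_trapz(g, h)
  } else {
    vals <- numeric(length(x))
    for (j in seq_along(x)[-1L]) {
      tt <- x[seq_len(j)]
      g <- rep(0, j)
      for (i in seq_along(model$terms))
        g <- g + wf_eval(model$terms[[i]]$weight, x[j], tt) * comp[[i]][seq_len(j)]
      vals[j] <- sum((g[-j] + g[-1L]) / 2) * h
    }
  }
  vals[1L] <- 0
  grid_function(values = vals)
}

make_solve_result <- function(solution, iterations_used, delta_history, tol,
                              warnings = character(0)) {
  final_delta <- if (length(delta_history)) delta_history[length(delta_history)]
                 else 0
  structure(list(solution = solution,
                 iterations_used = iterations_used,
                 final_delta = final_delta,
                 converged = final_delta <= tol,
                 delta_history = delta_history,
                 tol = tol,
                 warnings = warnings),
            class = "op_solution")
}

#' Solve the integral equation by grid Picard iteration
#'
#' Iterates \code{\link{picard_step_numeric}} until the sup-norm of the
#' successive difference drops to \code{tol} or \code{max_iter} is reached.
#' Non-convergence is reported (\code{converged = FALSE}), not raised.
#'
#' @param model a validated \code{integral_model}.
#' @param gamma0 initial iterate (\code{grid_fn}); default samples
#'   \eqn{\Gamma_0(x)=x} on \code{n_points} nodes.
#' @param tol sup-norm stopping tolerance.
#' @param max_iter iteration cap.
#' @param n_points grid size used when \code{gamma0} is not supplied.
#' @return an object of class \code{op_solution}.
#' @export
solve_integral <- function(model, gamma0 = NULL, tol = 1e-10, max_iter = 1000L,
                           n_points = 1001L) {
  stopifnot(tol > 0, max_iter >= 1L)
  f <- gamma0 %||% grid_function(fun = identity, n_points = n_points)
  deltas <- numeric(0)
  iters <- 0L
  repeat {
    nxt <- picard_step_numeric(model, f)
    d <- max(abs(nxt$values - f$values))
    deltas <- c(deltas, d)
    f <- nxt
    iters <- iters + 1L
    if (d <= tol || iters >= max_iter) break
  }
  make_solve_result(f, iters, deltas, tol)
}

discrete_apply <- function(model, f) {
  x <- f$x
  x * gf_interp(f, op_eval(model$g1, x)) +
    (1 - x) * gf_interp(f, op_eval(model$g2, x))
}

#' Solve the discrete learning equation by pinned fixed-point iteration
#'
#' Iterates \eqn{(Tf)(x_j) = x_j f(g_1(x_j)) + (1-x_j) f(g_2(x_j))} with
#' linear interpolation, pinning \eqn{f(0)=0} and \eqn{f(1)=1} each sweep,
#' starting from \eqn{f_0(x)=x}. Warns (in the result, not as a condition)
#' when the classical boundary conditions \eqn{g_1(1)=1}, \eqn{g_2(0)=0}
#' fail, when an operator is not a contraction, or when the delta sequence
#' stagnates (ratio above 0.999 for 50 consecutive sweeps).
#'
#' @param model a \code{discrete_model}.
#' @param n_points grid size.
#' @param tol sup-norm stopping tolerance.
#' @param max_iter iteration cap.
#' @return an object of class \code{op_solution}.
#' @examples
#' s <- solve_discrete(preset_model("lyubich_shapiro", a1 = "3/10", a2 = "3/10"))
#' max(abs(s$solution$values - s$solution$x)) # f(x) = x when a1 = a2
#' @export
solve_discrete <- function(model, n_points = 1001L, tol = 1e-10,
                           max_iter = 1000L) {
  stopifnot(inherits(model, "discrete_model"), tol > 0, max_iter >= 1L)
  warnings <- character(0)
  if (abs(op_eval(model$g1, 1) - 1) > 1e-12 || abs(op_eval(model$g2, 0)) > 1e-12)
    warnings <- c(warnings,
                  "classical boundary conditions g1(1)=1, g2(0)=0 do not hold")
  k1 <- lipschitz_constant(model$g1)$kappa
  k2 <- lipschitz_constant(model$g2)$kappa
  if (max(k1, k2) >= 1) warnings <- c(warnings, "non-contractive")
  f <- grid_function(fun = identity, n_points = n_points)
  deltas <- numeric(0)
  iters <- 0L
  stagnant <- 0L
  repeat {
    vals <- discrete_apply(model, f)
    vals[1L] <- 0
    vals[length(vals)] <- 1
    d <- max(abs(vals - f$values))
    if (length(deltas) && deltas[length(deltas)] > 0 &&
        d / deltas[length(deltas)] > 0.999) stagnant <- stagnant + 1L
    else stagnant <- 0L
    deltas <- c(deltas, d)
    f <- grid_function(values = vals)
    iters <- iters + 1L
    if (d <= tol || iters >= max_iter) break
    if (stagnant >= 50L) {
      warnings <- c(warnings, "slow/non-contractive")
      break
    }
  }
  make_solve_result(f, iters, deltas, tol, warnings)
}

#' Sup-norm residual of a candidate solution
#'
#' Returns \eqn{\|f - Tf\|_\infty} on the grid, where \eqn{T} is the model's
#' fixed-point operator (integral or discrete).
#'
#' @param model an \code{integral_model} or \code{discrete_model}.
#' @param f a \code{grid_fn} on the model's grid.
#' @return a non-negative number.
#' @export
residual_norm <- function(model, f) {
  stopifnot(inherits(f, "grid_fn"))
  if (inherits(model, "integral_model"))
    max(abs(f$values - picard_step_numeric(model, f)$values))
  else if (inherits(model, "discrete_model"))
    max(abs(f$values - discrete_apply(model, f)))
  else stop("residual_norm needs an integral_model or discrete_model")
}

#' @export
print.op_solution <- function(x, ...) {
  cat(sprintf("fixed-point solve: %s after %d iterations (final delta %.3g, tol %.1g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations_used, x$final_delta, x$tol))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  print(x$solution)
  invisible(x)
}

#' @export
predict.op_solution <- function(object, x = NULL, ...) {
  if (is.null(x)) return(object$solution$values)
  gf_interp(object$solution, x)
}

#' @export
residuals.op_solution <- function(object, model, ...) {
  f <- object$solution
  if (inherits(model, "integral_model"))
    f$values - picard_step_numeric(model, f)$values
  else f$values - discrete_apply(model, f)
}

#' @export
as.data.frame.op_solution <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(x = x$solution$x, value = x$solution$values, row.names = row.names)
}

#' @export
plot.op_solution <- function(x, ...) {
  graphics::plot(x$solution$x, x$solution$values, type = "l", xlab = "x",
                 ylab = "f(x)", main = "fixed-point solution", ...)
  invisible(x)
}
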