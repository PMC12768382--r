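# Model construction for operant-learning functional equations.
#
# An integral model is Gamma(x) = int_0^x sum_i w_i(x,t) Gamma(E_i(t)) dt with
# non-negative weights summing to 1 on the triangle 0 <= t <= x <= 1 and
# response operators E_i mapping [0,1] into itself. A discrete model is the
# classical two-operator learning equation f(x) = x f(g1(x)) + (1-x) f(g2(x))
# with boundary values f(0)=0, f(1)=1.

## ---- response operators ----------------------------------------------------

#' Construct an affine response operator
#'
#' An affine learning operator \eqn{t \mapsto s\,t + c} on the probability
#' state space \eqn{[0,1]}. Construction fails unless the image of
#' \eqn{[0,1]} stays inside \eqn{[0,1]}. The Lipschitz (contraction)
#' coefficient \eqn{\kappa = |s|} is carried exactly.
#'
#' @param slope,intercept exact rationals, given as strings (\code{"1/4"}),
#'   integers, or short decimals.
#' @return an object of class \code{response_operator}, kind \code{"affine"}.
#' @examples
#' make_affine_operator("1/4", "1/4") # t -> (t+1)/4, kappa = 1/4
#' @export
make_affine_operator <- function(slope, intercept) {
  s <- q_from(slope); c <- q_from(intercept)
  # image endpoints at t=0 and t=1
  at0 <- c; at1 <- q_add(s, c)
  lo <- if (q_cmp(at0, at1) <= 0) at0 else at1
  hi <- if (q_cmp(at0, at1) <= 0) at1 else at0
  if (q_cmp(lo, q_zero()) < 0)
    stop("affine operator leaves [0,1]: value at endpoint is ", q_to_string(lo))
  if (q_cmp(hi, q_one()) > 0)
    stop("affine operator leaves [0,1]: value at endpoint is ", q_to_string(hi))
  structure(list(kind = "affine", slope = s, intercept = c),
            class = "response_operator")
}

#' Construct a generic (callable) response operator
#'
#' Wraps an arbitrary continuous self-map of \eqn{[0,1]} for use with the
#' numeric engine and the simulator. Containment in \eqn{[0,1]} is checked on
#' a validation grid.
#'
#' @param fun a vectorized function of one numeric argument.
#' @param n_check number of grid points used to check range containment.
#' @return an object of class \code{response_operator}, kind \code{"generic"}.
#' @export
generic_operator <- function(fun, n_check = 201L) {
  stopifnot(is.function(fun))
  v <- fun(seq(0, 1, length.out = n_check))
  if (any(!is.finite(v)) || min(v) < -1e-12 || max(v) > 1 + 1e-12)
    stop("generic operator leaves [0,1] on the validation grid")
  structure(list(kind = "generic", fun = fun), class = "response_operator")
}

op_is_affine <- function(op) op$kind == "affine"

op_eval <- function(op, t) {
  if (op_is_affine(op)) q_to_double(op$slope) * t + q_to_double(op$intercept)
  else op$fun(t)
}

#' @export
print.response_operator <- function(x, ...) {
  if (op_is_affine(x)) {
    cat(sprintf("affine response operator: t -> (%s)*t + (%s)   [kappa = %s]\n",
                q_to_string(x$slope), q_to_string(x$intercept),
                q_to_string(q_abs(x$slope))))
  } else cat("generic response operator (callable)\n")
  invisible(x)
}

## ---- weight functions ------------------------------------------------------

#' Construct a bivariate polynomial weight function
#'
#' A weight \eqn{w(x,t)} given as a sum of monomials
#' \eqn{c \, x^{i} t^{j}} with exact rational coefficients. These are the
#' only weights the exact Picard engine accepts.
#'
#' @param xdeg,tdeg integer vectors of monomial degrees.
#' @param coef coefficients (rational strings or numerics), one per monomial.
#' @return an object of class \code{weight_fn}, kind \code{"poly"}.
#' @examples
#' poly_weight(0, 1, "1")        # w(x,t) = t
#' poly_weight(c(0, 0), c(0, 1), c("1", "-1")) # w(x,t) = 1 - t
#' @export
poly_weight <- function(xdeg, tdeg, coef) {
  stopifnot(length(xdeg) == length(tdeg), length(tdeg) == length(coef))
  terms <- lapply(seq_along(coef), function(i)
    list(xd = as.integer(xdeg[i]), td = as.integer(tdeg[i]), c = q_from(coef[[i]])))
  terms <- Filter(function(tm) !q_is_zero(tm$c), terms)
  structure(list(kind = "poly", terms = terms), class = "weight_fn")
}

#' Construct a callable weight function
#'
#' For the numeric engine only: an arbitrary continuous weight
#' \eqn{w(x,t)} on the triangle \eqn{0 \le t \le x \le 1}.
#'
#' @param fun a function of \code{(x, t)}, vectorized in \code{t}.
#' @param t_only logical; set \code{TRUE} if \code{fun} ignores \code{x}
#'   (enables the O(n) quadrature path).
#' @return an object of class \code{weight_fn}, kind \code{"callable"}.
#' @export
callable_weight <- function(fun, t_only = FALSE) {
  stopifnot(is.function(fun))
  structure(list(kind = "callable", fun = fun, t_only = isTRUE(t_only)),
            class = "weight_fn")
}

wf_is_poly <- function(w) w$kind == "poly"

wf_t_only <- function(w) {
  if (wf_is_poly(w)) all(vapply(w$terms, function(tm) tm$xd == 0L, logical(1)))
  else isTRUE(w$t_only)
}

wf_eval <- function(w, x, t) {
  if (wf_is_poly(w)) {
    v <- rep(0, length(t))
    for (tm in w$terms)
      v <- v + q_to_double(tm$c) * x^tm$xd * t^tm$td
    v
  } else w$fun(x, t)
}

## ---- models ----------------------------------------------------------------

#' Construct an integral operant-control model
#'
#' @param weights list of \code{weight_fn} objects.
#' @param operators list of \code{response_operator} objects, same length.
#' @param p optional outcome-probability parameter recorded for four-outcome
#'   models (rational string or numeric in \eqn{[0,1]}).
#' @param preset optional name recorded for provenance.
#' @param validate logical; check the model on construction (default TRUE)
#'   and fail if invalid.
#' @return an object of class \code{integral_model}.
#' @export
integral_model <- function(weights, operators, p = NULL, preset = NULL,
                           validate = TRUE) {
  stopifnot(length(weights) == length(operators), length(weights) >= 2L)
  stopifnot(all(vapply(weights, inherits, logical(1), "weight_fn")),
            all(vapply(operators, inherits, logical(1), "response_operator")))
  m <- structure(list(terms = Map(function(w, o) list(weight = w, op = o),
                                  weights, operators),
                      p = if (!is.null(p)) q_from(p) else NULL,
                      preset = preset),
                 class = "integral_model")
  if (validate) {
    rep <- validate_integral_model(m)
    if (!rep$valid)
      stop("invalid integral model: ",
           paste(vapply(rep$violations, function(v) v$rule, character(1)),
                 collapse = "; "))
  }
  m
}

#' Construct a discrete two-operator learning model
#'
#' The classical learning equation \eqn{f(x) = x f(g_1(x)) + (1-x) f(g_2(x))}
#' with boundary values \eqn{f(0)=0}, \eqn{f(1)=1}.
#'
#' @param g1,g2 \code{response_operator} objects.
#' @param classical logical; assert the classical boundary structure
#'   \eqn{g_1(1)=1}, \eqn{g_2(0)=0}.
#' @param preset optional name recorded for provenance.
#' @return an object of class \code{discrete_model}.
#' @export
discrete_model <- function(g1, g2, classical = TRUE, preset = NULL) {
  stopifnot(inherits(g1, "response_operator"), inherits(g2, "response_operator"))
  if (isTRUE(classical)) {
    if (abs(op_eval(g1, 1) - 1) > 1e-12 || abs(op_eval(g2, 0)) > 1e-12)
      warning("classical boundary conditions g1(1)=1, g2(0)=0 do not hold")
  }
  structure(list(g1 = g1, g2 = g2, classical = isTRUE(classical),
                 preset = preset),
            class = "discrete_model")
}

#' @export
print.integral_model <- function(x, ...) {
  cat(sprintf("integral operant-control model (%d terms%s)\n",
              length(x$terms),
              if (!is.null(x$preset)) paste0(", preset '", x$preset, "'") else ""))
  for (i in seq_along(x$terms)) {
    op <- x$terms[[i]]$op
    opdesc <- if (op_is_affine(op))
      sprintf("(%s)*t + (%s)", q_to_string(op$slope), q_to_string(op$intercept))
    else "generic"
    cat(sprintf("  term %d: weight %s, operator %s\n", i,
                x$terms[[i]]$weight$kind, opdesc))
  }
  invisible(x)
}

#' @export
print.discrete_model <- function(x, ...) {
  cat(sprintf("discrete learning model f(x) = x f(g1(x)) + (1-x) f(g2(x))%s\n",
              if (!is.null(x$preset)) paste0("  [preset '", x$preset, "']") else ""))
  cat("  g1: "); print(x$g1)
  cat("  g2: "); print(x$g2)
  invisible(x)
}

## ---- validation ------------------------------------------------------------

# triangular validation grid 0 <= t <= x <= 1
validation_grid <- function(n = 201L) {
  xs <- seq(0, 1, length.out = n)
  grid <- expand.grid(t = xs, x = xs)
  grid[grid$t <= grid$x, , drop = FALSE]
}

#' Validate an integral model
#'
#' Checks that the weights sum to one on the triangle \eqn{0 \le t \le x \le 1}
#' (exactly for polynomial weights, to tolerance \code{1e-12} on a 201x201
#' triangular grid for callables), that every weight is non-negative there,
#' and that every operator maps \eqn{[0,1]} into \eqn{[0,1]}. Violations are
#' reported, never raised.
#'
#' @param model an \code{integral_model}.
#' @param n_grid validation grid resolution per axis.
#' @return an object of class \code{validation_report} with fields
#'   \code{valid} and \code{violations}.
#' @export
validate_integral_model <- function(model, n_grid = 201L) {
  stopifnot(inherits(model, "integral_model"))
  violations <- list()
  note <- function(rule, location, magnitude)
    violations[[length(violations) + 1L]] <<- list(rule = rule,
                                                   location = location,
                                                   magnitude = magnitude)
  weights <- lapply(model$terms, `[[`, "weight")
  all_poly <- all(vapply(weights, wf_is_poly, logical(1)))
  if (all_poly) {
    # exact: collect sum of all monomials, must equal the constant 1
    acc <- list()
    for (w in weights) for (tm in w$terms) {
      key <- paste(tm$xd, tm$td)
      acc[[key]] <- if (is.null(acc[[key]])) tm$c else q_add(acc[[key]], tm$c)
    }
    for (key in names(acc)) {
      target <- if (key == "0 0") q_one() else q_zero()
      if (!q_eq(acc[[key]], target)) {
        note("weight-sum != 1 (exact)", paste0("monomial x^t degrees ", key),
             abs(q_to_double(q_sub(acc[[key]], target))))
        break
      }
    }
  }
  grid <- validation_grid(n_grid)
  wsum <- rep(0, nrow(grid))
  for (i in seq_along(weights)) {
    wv <- wf_eval(weights[[i]], grid$x, grid$t)
    wsum <- wsum + wv
    if (min(wv) < -1e-12)
      note("weight negative on triangle",
           sprintf("term %d at (x=%.3f, t=%.3f)", i,
                   grid$x[which.min(wv)], grid$t[which.min(wv)]),
           -min(wv))
  }
  if (!all_poly && max(abs(wsum - 1)) > 1e-12)
    note("weight-sum != 1 (grid)",
         sprintf("(x=%.3f, t=%.3f)", grid$x[which.max(abs(wsum - 1))],
                 grid$t[which.max(abs(wsum - 1))]),
         max(abs(wsum - 1)))
  ts <- seq(0, 1, length.out = n_grid)
  for (i in seq_along(model$terms)) {
    ov <- op_eval(model$terms[[i]]$op, ts)
    bad <- which(ov < -1e-12 | ov > 1 + 1e-12)
    if (length(bad))
      note("operator leaves [0,1]",
           sprintf("term %d at t=%.3f", i, ts[bad[1]]),
           max(pmax(-ov[bad], ov[bad] - 1)))
  }
  structure(list(valid = length(violations) == 0L, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$valid) cat("model valid: all weight and operator constraints hold\n")
  else {
    cat("model INVALID:\n")
    for (v in x$violations)
      cat(sprintf("  - %s at %s (magnitude %.3g)\n", v$rule, v$location,
                  v$magnitude))
  }
  invisible(x)
}

## ---- presets ---------------------------------------------------------------

#' Built-in operant-control models
#'
#' @description
#' Returns a fully constructed and validated model:
#' \describe{
#'   \item{\code{"example1"}}{pigeon-type integral model with weights
#'     \eqn{t}, \eqn{1-t} and operators \eqn{E_1(t)=(t+1)/4},
#'     \eqn{E_2(t)=(t+2)/5}.}
#'   \item{\code{"pigeon"}}{weights \eqn{t}, \eqn{1-t} with user-supplied
#'     operators (defaults: the example1 operators).}
#'   \item{\code{"example2"}, \code{"four_outcome"}}{four-term reward model
#'     with weights \eqn{pt}, \eqn{(1-p)t}, \eqn{p(1-t)}, \eqn{(1-p)(1-t)}
#'     and operators \code{ops} (defaults: all \eqn{E_i(t)=(t+1)/5});
#'     \code{p} defaults to \code{"1/2"}.}
#'   \item{\code{"lyubich_shapiro"}}{discrete predator-choice model
#'     \eqn{g_1(x)=(1-a_1)x+a_1}, \eqn{g_2(x)=(1-a_2)x}, requiring
#'     \eqn{0 < a_1 \le a_2 < 1}.}
#'   \item{\code{"berinde_khan"}}{integral model with weights \eqn{x},
#'     \eqn{1-x} and discrete-type operators \code{g1}, \code{g2}
#'     (defaults: the \code{lyubich_shapiro} operators with
#'     \eqn{a_1=3/10}, \eqn{a_2=6/10}); reduces to the discrete form via
#'     \code{\link{reduce_to_discrete}}.}
#' }
#'
#' @param name preset name.
#' @param ... preset parameters: \code{p}, \code{a1}, \code{a2},
#'   \code{ops} (list of \code{response_operator}), \code{g1}, \code{g2}.
#' @return an \code{integral_model} or \code{discrete_model}.
#' @examples
#' preset_model("example1")
#' preset_model("lyubich_shapiro", a1 = "3/10", a2 = "3/10")
#' @export
preset_model <- function(name, ...) {
  params <- list(...)
  w_t <- poly_weight(0, 1, "1")
  w_1mt <- poly_weight(c(0, 0), c(0, 1), c("1", "-1"))
  switch(name,
    example1 = integral_model(
      list(w_t, w_1mt),
      list(make_affine_operator("1/4", "1/4"),
           make_affine_operator("1/5", "2/5")),
      preset = "example1"),
    pigeon = {
      ops <- params$ops %||% list(make_affine_operator("1/4", "1/4"),
                                  make_affine_operator("1/5", "2/5"))
      stopifnot(length(ops) == 2L)
      integral_model(list(w_t, w_1mt), ops, preset = "pigeon")
    },
    example2 = ,
    four_outcome = {
      p <- q_from(params$p %||% "1/2")
      if (q_cmp(p, q_zero()) < 0 || q_cmp(p, q_one()) > 0)
        stop("p must lie in [0,1]")
      ops <- params$ops %||% replicate(4, make_affine_operator("1/5", "1/5"),
                                       simplify = FALSE)
      stopifnot(length(ops) == 4L)
      pm1 <- q_sub(q_one(), p)
      # weights p*t, (1-p)*t, p*(1-t), (1-p)*(1-t)
      ws <- list(
        poly_weight(0, 1, list(p)),
        poly_weight(0, 1, list(pm1)),
        poly_weight(c(0, 0), c(0, 1), list(p, q_neg(p))),
        poly_weight(c(0, 0), c(0, 1), list(pm1, q_neg(pm1))))
      integral_model(ws, ops, p = p, preset = name)
    },
    lyubich_shapiro = {
      a1 <- q_from(params$a1 %||% "3/10"); a2 <- q_from(params$a2 %||% a1)
      if (!(q_cmp(a1, q_zero()) > 0 && q_cmp(a1, a2) <= 0 &&
            q_cmp(a2, q_one()) < 0))
        stop("lyubich_shapiro requires 0 < a1 <= a2 < 1")
      discrete_model(
        g1 = make_affine_operator(q_sub(q_one(), a1), a1),
        g2 = make_affine_operator(q_sub(q_one(), a2), q_zero()),
        preset = "lyubich_shapiro")
    },
    berinde_khan = {
      a1 <- q_from(params$a1 %||% "3/10"); a2 <- q_from(params$a2 %||% "6/10")
      g1 <- params$g1 %||% make_affine_operator(q_sub(q_one(), a1), a1)
      g2 <- params$g2 %||% make_affine_operator(q_sub(q_one(), a2), q_zero())
      integral_model(
        list(poly_weight(1, 0, "1"),
             poly_weight(c(0, 1), c(0, 0), c("1", "-1"))),
        list(g1, g2), preset = "berinde_khan")
    },
    stop("unknown preset: ", name)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- reduction to the discrete form ---------------------------------------

#' Reduce an integral model with weights x, 1-x to the discrete form
#'
#' An integral model whose two weights are exactly \eqn{x} and \eqn{1-x}
#' (constant in \eqn{t}) specializes, on evaluating the integrand at
#' \eqn{t = x}, to the classical discrete learning equation
#' \eqn{f(x) = x f(g_1(x)) + (1-x) f(g_2(x))}.
#'
#' @param model an \code{integral_model} with exactly two such weights.
#' @return a \code{discrete_model} carrying the same operators.
#' @export
reduce_to_discrete <- function(model) {
  stopifnot(inherits(model, "integral_model"))
  if (length(model$terms) != 2L)
    stop("reduction requires exactly two terms")
  w <- lapply(model$terms, `[[`, "weight")
  if (!all(vapply(w, wf_is_poly, logical(1))))
    stop("reduction requires polynomial weights")
  canon <- function(wf) {
    out <- c(`0 0` = 0, `1 0` = 0)
    for (tm in wf$terms) {
      if (tm$td != 0L) stop("reduction requires weights constant in t")
      key <- paste(tm$xd, tm$td)
      if (!key %in% names(out)) stop("reduction requires weights x and 1-x")
      out[key] <- out[key] + q_to_double(tm$c)
    }
    out
  }
  c1 <- canon(w[[1]]); c2 <- canon(w[[2]])
  if (!(identical(unname(c1), c(0, 1)) && identical(unname(c2), c(1, -1))))
    stop("reduction requires weights exactly x and 1-x (in that order)")
  discrete_model(model$terms[[1]]$op, model$terms[[2]]$op, classical = FALSE,
                 preset = model$preset)
}
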