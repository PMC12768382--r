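# Stochastic simulation of the operant-learning Markov process on [0,1].
#
# Two-choice process: from state x, with probability x apply g1, otherwise
# g2; the fixation probability f(x) satisfies the discrete learning equation
# by first-step analysis. Four-outcome process: outcome i is drawn with the
# reward-table probabilities p*x, (1-p)*x, p*(1-x), (1-p)*(1-x) evaluated at
# the current state, then the matching operator is applied.
#
# Replicate seeds are derived from the master seed by a fixed counter-based
# scramble so replicates are independent and reproducible in any order.

derive_seed <- function(master, i) {
  s <- (as.double(master) %% 2147483647)
  as.integer((s * 69069 + as.double(i) * 1000003 + 12345) %% 2147483647)
}

classify_state <- function(x, eps) {
  if (x >= 1 - eps) "fixated_high" else if (x <= eps) "fixated_low" else NA_character_
}

run_path <- function(step_fun, x0, seed, max_steps, eps, keep_states = TRUE) {
  stopifnot(x0 >= 0, x0 <= 1, eps > 0, eps < 0.5, max_steps >= 1)
  set.seed(seed)
  states <- if (keep_states) numeric(max_steps + 1L) else NULL
  if (keep_states) states[1L] <- x0
  x <- x0
  steps <- 0L
  outcome <- classify_state(x, eps)
  while (is.na(outcome) && steps < max_steps) {
    x <- step_fun(x)
    if (x < 0) x <- 0 else if (x > 1) x <- 1
    steps <- steps + 1L
    if (keep_states) states[steps + 1L] <- x
    outcome <- classify_state(x, eps)
  }
  if (is.na(outcome)) outcome <- "censored"
  structure(list(states = if (keep_states) states[seq_len(steps + 1L)],
                 outcome = outcome, steps = steps, seed = seed),
            class = "trial_path")
}

#' @export
print.trial_path <- function(x, ...) {
  cat(sprintf("operant trial path: %d steps, outcome %s (seed %d)\n",
              x$steps, x$outcome, x$seed))
  if (!is.null(x$states))
    cat("  final state:", x$states[length(x$states)], "\n")
  invisible(x)
}

#' Simulate one two-choice operant learning path
#'
#' From state \eqn{x}, response 1 occurs with probability \eqn{x} and moves
#' the state to \eqn{g_1(x)}; otherwise the state moves to \eqn{g_2(x)}.
#' The path stops on entering a fixation band \eqn{[0,\epsilon]} or
#' \eqn{[1-\epsilon,1]}, or is censored at \code{max_steps}.
#'
#' @param model a \code{discrete_model}.
#' @param x0 initial response probability in \eqn{[0,1]}.
#' @param seed integer RNG seed; identical seeds reproduce identical paths.
#' @param max_steps trial horizon.
#' @param eps half-width of the fixation bands, in (0, 1/2).
#' @return an object of class \code{trial_path} with fields \code{states},
#'   \code{outcome} (\code{fixated_high}/\code{fixated_low}/\code{censored}),
#'   \code{steps}, \code{seed}.
#' @export
simulate_two_choice <- function(model, x0, seed = 1L, max_steps = 1e5L,
                                eps = 1e-6) {
  stopifnot(inherits(model, "discrete_model"))
  g1 <- model$g1; g2 <- model$g2
  step_fun <- function(x)
    if (stats::runif(1) < x) op_eval(g1, x) else op_eval(g2, x)
  run_path(step_fun, x0, seed, max_steps, eps)
}

#' Monte-Carlo estimate of the fixation probability
#'
#' Runs independent replicate paths (seeds derived from the master seed by a
#' counter scheme) and estimates the probability of fixating on the high
#' band. Censored paths are excluded from the estimate's denominator and
#' reported separately.
#'
#' @param model a \code{discrete_model}.
#' @param x0 initial state.
#' @param n_reps number of replicates (>= 1).
#' @param seed master seed.
#' @param max_steps,eps as in \code{\link{simulate_two_choice}}.
#' @return an object of class \code{fixation_summary}: \code{n_reps},
#'   \code{x0}, \code{p_hat}, \code{se} (binomial standard error
#'   \eqn{\sqrt{\hat p(1-\hat p)/n}}), \code{censored_count}, \code{seed}.
#' @examples
#' m <- preset_model("lyubich_shapiro", a1 = "3/10", a2 = "3/10")
#' estimate_fixation_probability(m, x0 = 0.5, n_reps = 200, seed = 1)
#' @export
estimate_fixation_probability <- function(model, x0, n_reps, seed = 1L,
                                          max_steps = 1e5L, eps = 1e-6) {
  stopifnot(inherits(model, "discrete_model"), n_reps >= 1)
  g1 <- model$g1; g2 <- model$g2
  step_fun <- function(x)
    if (stats::runif(1) < x) op_eval(g1, x) else op_eval(g2, x)
  high <- 0L; censored <- 0L
  for (i in seq_len(n_reps)) {
    path <- run_path(step_fun, x0, derive_seed(seed, i), max_steps, eps,
                     keep_states = FALSE)
    if (path$outcome == "fixated_high") high <- high + 1L
    else if (path$outcome == "censored") censored <- censored + 1L
  }
  n_eff <- n_reps - censored
  p_hat <- if (n_eff > 0) high / n_eff else NA_real_
  structure(list(n_reps = n_reps, x0 = x0, p_hat = p_hat,
                 se = if (n_eff > 0) sqrt(p_hat * (1 - p_hat) / n_eff) else NA_real_,
                 censored_count = censored, seed = seed),
            class = "fixation_summary")
}

#' @export
print.fixation_summary <- function(x, ...) {
  cat(sprintf("fixation estimate at x0 = %g: p_hat = %.4f (se %.4f, n = %d, censored %d)\n",
              x$x0, x$p_hat, x$se, x$n_reps, x$censored_count))
  invisible(x)
}

#' Simulate one four-outcome reward-learning path
#'
#' At state \eqn{x}, one of four outcomes is drawn with probabilities
#' \eqn{p x}, \eqn{(1-p) x}, \eqn{p(1-x)}, \eqn{(1-p)(1-x)} (the
#' reward-predictability table evaluated at the current state) and the
#' matching operator is applied. The four probabilities sum to 1 for every
#' \eqn{(p, x)}.
#'
#' @param p outcome-probability parameter in \eqn{[0,1]}.
#' @param ops list of four \code{response_operator} objects.
#' @param x0,seed,max_steps,eps as in \code{\link{simulate_two_choice}}.
#' @return a \code{trial_path}; attribute \code{"outcomes"} records the
#'   outcome index drawn at each step.
#' @export
simulate_four_outcome <- function(p, ops, x0, seed = 1L, max_steps = 1e5L,
                                  eps = 1e-6) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1, length(ops) == 4L,
            all(vapply(ops, inherits, logical(1), "response_operator")))
  outcomes <- integer(0)
  step_fun <- function(x) {
    probs <- c(p * x, (1 - p) * x, p * (1 - x), (1 - p) * (1 - x))
    k <- findInterval(stats::runif(1), cumsum(probs)) + 1L
    if (k > 4L) k <- 4L
    outcomes[length(outcomes) + 1L] <<- k
    op_eval(ops[[k]], x)
  }
  path <- run_path(step_fun, x0, seed, max_steps, eps)
  attr(path, "outcomes") <- outcomes
  path
}

#' Cross-validate a solved fixation probability against simulation
#'
#' Solves the discrete model on a grid, then compares the solved
#' \eqn{f(x_0)} with the Monte-Carlo fixation estimate at each requested
#' starting point, flagging any discrepancy beyond 3 standard errors.
#'
#' @param model a \code{discrete_model}.
#' @param x_grid starting points to compare at.
#' @param n_reps replicates per point (0 gives an empty report).
#' @param seed master seed.
#' @param n_points solver grid size.
#' @param max_steps,eps simulation controls.
#' @return data frame with columns \code{x0}, \code{f_solved}, \code{p_hat},
#'   \code{se}, \code{z} (\eqn{|diff|/se}), \code{flagged}.
#' @export
compare_to_solution <- function(model, x_grid, n_reps, seed = 1L,
                                n_points = 1001L, max_steps = 1e5L,
                                eps = 1e-6) {
  stopifnot(inherits(model, "discrete_model"), n_reps >= 0)
  if (n_reps == 0L || length(x_grid) == 0L)
    return(data.frame(x0 = numeric(0), f_solved = numeric(0),
                      p_hat = numeric(0), se = numeric(0), z = numeric(0),
                      flagged = logical(0)))
  sol <- solve_discrete(model, n_points = n_points)
  out <- lapply(seq_along(x_grid), function(i) {
    x0 <- x_grid[i]
    fs <- gf_interp(sol$solution, x0)
    est <- estimate_fixation_probability(model, x0, n_reps,
                                         seed = derive_seed(seed, 104729L * i),
                                         max_steps = max_steps, eps = eps)
    z <- if (is.finite(est$se) && est$se > 0) abs(fs - est$p_hat) / est$se
         else if (isTRUE(all.equal(fs, est$p_hat))) 0 else Inf
    data.frame(x0 = x0, f_solved = fs, p_hat = est$p_hat, se = est$se, z = z,
               flagged = z > 3)
  })
  do.call(rbind, out)
}

#' Simulate replicate operant paths from a discrete model
#'
#' S3 \code{\link[stats]{simulate}} method: returns \code{nsim} independent
#' trial paths started at \code{x0}.
#'
#' @param object a \code{discrete_model}.
#' @param nsim number of paths.
#' @param seed master seed.
#' @param x0 initial state.
#' @param ... passed to \code{\link{simulate_two_choice}}.
#' @return list of \code{trial_path} objects.
#' @export
simulate.discrete_model <- function(object, nsim = 1, seed = 1L, x0 = 0.5, ...) {
  lapply(seq_len(nsim), function(i)
    simulate_two_choice(object, x0 = x0, seed = derive_seed(seed, i), ...))
}
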