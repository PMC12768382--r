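---
title: "Operant-control functional equations: exact Picard iteration, contraction certificates, and stochastic cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operant-control functional equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operantfe)
```

## The model

Two-choice operant learning is modelled as a Markov process on the response
probability $x \in [0,1]$: each trial applies one of two learning operators,
$g_1$ with probability $x$ and $g_2$ with probability $1-x$. First-step
analysis gives the classical functional equation for the fixation
probability $f$,
$$ f(x) = x\,f(g_1(x)) + (1-x)\,f(g_2(x)), \qquad f(0)=0,\ f(1)=1, $$
with the predator prey-choice specialization $g_1(x) = (1-a_1)x + a_1$,
$g_2(x) = (1-a_2)x$, $0 < a_1 \le a_2 < 1$.

The package's central object is the Volterra-type integral generalization
$$ \Gamma(x) = \int_0^x \alpha(x,t)\,\Gamma(E_1(t)) +
   \beta(x,t)\,\Gamma(E_2(t))\,dt , $$
with continuous non-negative weights satisfying $\alpha+\beta \equiv 1$ on
the triangle $0 \le t \le x \le 1$, continuous response operators
$E_i:[0,1]\to[0,1]$, and the built-in initial condition $\Gamma(0)=0$
(automatic, because the integration range collapses — no condition on
$E_i(0)$ is needed). An $m$-term variant covers the four-outcome
reward-predictability model with weights $pt,\ (1-p)t,\ p(1-t),\
(1-p)(1-t)$. Evaluating the two-term integrand at $t=x$ with weights $x$ and
$1-x$ recovers the discrete equation, which is why the package treats both
forms and a reduction between them (`reduce_to_discrete`).

When each $E_i$ is a contraction with coefficient $\kappa_i$ and
$k = \sum_i \kappa_i < 1$, the operator $T$ defined by the right-hand side
satisfies $\|T\Gamma - T\Gamma'\|_\infty \le k\,\|\Gamma-\Gamma'\|_\infty$
with the linear comparison function $\varphi(t) = kt$, so the Picard
sequence $\Gamma_{n+1} = T\Gamma_n$ converges to the unique fixed point from
any starting function with $\Gamma_0(0)=0$.

### What the solution is

The integral equation is linear and homogeneous with $\Gamma(0)=0$, so the
zero function is a solution; under the contraction condition it is *the*
unique one. The package therefore does not claim a nontrivial limit for the
integral form: the scientifically interesting outputs are (i) the exact
Picard iterates themselves, which are the worked quantities of this model
family, (ii) the certificate $k<1$, and (iii) the observed sup-norm decay
$\|\Gamma_{n+1}-\Gamma_n\|_\infty \to 0$, which `picard_iterates` reports as
its convergence diagnostic. For the discrete form the pinned boundary
$f(0)=0,\ f(1)=1$ selects the nontrivial fixation-probability solution;
without the pins the homogeneous operator would again admit only trivial
limits, which is why `solve_discrete` re-imposes them every sweep.

A note on the certificate: the per-step bound
$|\Gamma(E_i(t)) - \Gamma'(E_i(t))| \le \kappa_i\|\Gamma-\Gamma'\|$ used to
derive the factor $k$ does not follow from $E_i$ being a contraction alone
(it bounds a composition, not a difference of arguments). Empirically the
first-difference ratio for the two-term worked model is about
$0.463 > \kappa_1+\kappa_2 = 0.45$. The solvers therefore expose $k$ as the
stated certificate but stop on observed delta decay, never asserting the
per-step rate $k$; `contraction_report` prints the certificate, and the
delta history in every solve result shows the realized ratios.

## The exact engine

For polynomial weights and *affine* operators $E(t) = st + c$ every iterate
is a polynomial with rational coefficients: composition with an affine map
preserves degree, multiplication by a monomial $c\,x^i t^j$ and term-wise
integration $\int_0^x t^m dt = x^{m+1}/(m+1)$ keep coefficients rational.
The engine restricts itself to this class (all worked models are in it);
generic continuous operators and weights are the numeric engine's job.

Coefficients are held as arbitrary-precision rationals (sign + base-$10^6$
limb integers, schoolbook multiplication and division, Euclidean gcd),
reduced to lowest terms after every operation — the form in which the
worked examples print their values, and the only way to keep numerators and
denominators from growing faster than necessary. Degree grows by
$1 + \deg_t w$ per step (by 2 for the pigeon-type model; by 1 for the
four-outcome model, whose $t$-linear weight terms cancel when the four
operators coincide), so deep exact iteration is expensive; `picard_iterates`
caps the depth at 25 by default, raisable explicitly.

```{r exact}
m <- preset_model("example1")
tr <- picard_iterates(m, n = 2)
tr$iterates[[3]]
coefficient_query(tr$iterates[[3]], 3)
```

The four-outcome model's iterates are independent of the outcome parameter
$p$ (the four weights sum to 1 and its operators coincide, collapsing the
integrand); the package verifies this by constructing the model at several
exact $p$ values and comparing iterates coefficient-by-coefficient, rather
than by carrying $p$ symbolically. One consequence the exact engine makes
visible: integrating the four-outcome model's own intermediate integrand
gives the quadratic coefficient $3/125$ in the second iterate, and the
engine reports that exactly-integrated value.

## The numeric engine

`picard_step_numeric` discretizes $[0,1]$ on a uniform grid (endpoints
included, default 1001 nodes) and evaluates the Volterra integral by
composite trapezoid with cumulative prefix sums — $O(n)$ per sweep when the
weights depend only on $t$, falling back to per-node quadrature when they
depend on $x$ as well. Compositions $f(E_i(t))$ use piecewise-linear
interpolation, chosen over cubic because linear interpolation cannot
overshoot and therefore preserves both $[0,1]$ containment and
non-expansiveness of the discretized operator. The quadrature and
interpolation errors are both $O(h^2)$; against the exact iterates the
observed error shrinks fourfold per grid doubling, which the test suite
asserts on the 501/1001/2001 ladder.

Stopping: sup-norm successive difference $\le$ `tol` (default $10^{-10}$)
within `max_iter` (default 1000); non-convergence is reported in the result
(`converged = FALSE`), not raised. The discrete solver additionally flags —
again in the result, not as an error — models that violate the classical
boundary structure $g_1(1)=1,\ g_2(0)=0$, models whose operators are not
contractions, and delta sequences that stagnate (ratio above 0.999 for 50
consecutive sweeps). Degenerate inputs behave by construction: the zero
grid function is fixed in one iteration, and identity operators return the
starting function with a non-contractive flag.

```{r discrete}
s <- solve_discrete(preset_model("lyubich_shapiro", a1 = "3/10", a2 = "3/10"))
max(abs(s$solution$values - s$solution$x)) # closed form f(x) = x when a1 = a2
```

## The simulator

`simulate_two_choice` runs the underlying Markov process directly: from
state $x$, draw a uniform variate, apply $g_1$ if it falls below $x$, else
$g_2$. The model family speaks of a "final" fixation probability without a
stopping rule, so the simulator adopts explicit fixation bands
$[0,\varepsilon]$ and $[1-\varepsilon,1]$ with $\varepsilon = 10^{-6}$ and
a horizon of $10^5$ steps; paths that exhaust the horizon are reported as
*censored* and excluded from the fixation-probability denominator, never
silently assigned to either class. Replicate seeds derive from the master
seed by a fixed counter scramble, so replicates are independent,
order-insensitive, and bit-for-bit reproducible.

Two closed forms anchor the calibration tests: for $a_1 = a_2$ the state
process is a martingale and the fixation probability equals the starting
state exactly, and for $g_1 \equiv 1, g_2 \equiv 0$ fixation is a single
Bernoulli trial. For asymmetric models `compare_to_solution` checks the
Monte-Carlo estimate against the numeric fixed point within three binomial
standard errors. The four-outcome simulator draws outcomes with the
reward-table probabilities $px, (1-p)x, p(1-x), (1-p)(1-x)$ evaluated at
the *current state* (the experiment's description), even though the
integral form writes its weights in the trial variable $t$ — the two
conventions are not reconciled in the source model family, and the package
keeps them deliberately distinct: weights-in-$t$ for solving,
probabilities-in-$x$ for simulating. Whether the four-outcome process is
absorbing is likewise left open; with the default operators (all
contracting to the interior point $1/4$) paths are censored, and the
simulator reports that rather than forcing a fixation class.

```{r simulate}
d <- preset_model("lyubich_shapiro", a1 = "3/10", a2 = "6/10")
compare_to_solution(d, c(0.25, 0.5, 0.75), n_reps = 1000, seed = 3)
```

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `tol` | both solvers | $10^{-10}$ | sup-norm successive-difference stop; well above double rounding on 1001-node sums |
| `n_points` | numeric engine | 1001 | $O(h^2)$ error $\approx 10^{-8}$ against exact iterates; refinement invariance checked at 501/2001 |
| `max_iter` | both solvers | 1000 | certificate $k^n$ decay makes hundreds of sweeps ample for $k < 1$ |
| `eps` | simulator | $10^{-6}$ | fixation band half-width; small enough that band entry is effectively absorption for affine operators |
| `max_steps` | simulator | $10^5$ | horizon; geometric approach to the bands makes later fixation negligible for contractive models |
| `max_n` | exact engine | 25 | degree/coefficient growth cap, raisable explicitly |
| `norm_grid` | diagnostics | 10001 | sup norms of iterates are polynomial maximizations; grid evaluation is accurate to grid resolution and cheap |

Problem sizes in the tests and the reproduction script follow the worked
examples: two to three exact Picard steps, 1001-node grids, and $10^4$
Monte-Carlo replicates per starting state.

## What the synthetic conditions do and do not show

All inputs are model specifications — weight functions, operators, and
parameters printed in the worked examples — so "data" here is generated by
the models themselves. Passing tests show that the solvers reproduce exact
symbolic computations, that the numeric discretization converges at its
theoretical rate, and that the simulator is internally consistent with the
fixed-point solutions. They do not show that any of these models describe
real behavioral data: no operator or $p$ is fit to observations (fitting is
out of scope), the affine-operator class excludes state-dependent learning
rates, and the fixation bands are a modelling convention, not an observed
stopping rule.

## Known limitations

* The exact engine requires affine operators and polynomial weights;
  everything else goes through the $O(h^2)$ numeric path.
* Contraction certificates for generic operators are grid estimates and are
  never marked `certified`.
* The a-priori bound `a_priori_iterations` uses the linear comparison
  function only; general nonlinear comparison functions are out of scope.
* Exact coefficient queries return numerator/denominator as doubles (exact
  below $2^{53}$) alongside an always-exact decimal string.
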