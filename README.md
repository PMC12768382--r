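# operantfe

Solvers and simulators for functional-equation models of operant learning.

## The problem

In mathematical psychology, two-choice learning is classically modelled by a
Markov process on the probability state space [0,1]: after each trial the
response probability `x` is moved by one of two *learning operators*
`g1`, `g2` (applied with probabilities `x` and `1-x`). The probability
`f(x)` of ultimately fixating on the first response, started from state `x`,
satisfies the discrete functional equation

    f(x) = x f(g1(x)) + (1 - x) f(g2(x)),   f(0) = 0, f(1) = 1,

the form studied for predator prey-choice behavior (with
`g1(x) = (1-a1)x + a1`, `g2(x) = (1-a2)x`) and for operant-conditioning
experiments. A Volterra-type integral generalization replaces the fixed
state-weights by trial-dependent weight functions:

    Gamma(x) = ∫₀ˣ [ α(x,t) Gamma(E1(t)) + β(x,t) Gamma(E2(t)) ] dt,
    α + β ≡ 1,  α, β ≥ 0 on 0 ≤ t ≤ x ≤ 1,  Gamma(0) = 0,

with continuous response operators `E1, E2 : [0,1] → [0,1]` (and an
m-term variant, e.g. the four-outcome reward-predictability model with
weights `pt, (1-p)t, p(1-t), (1-p)(1-t)`). When the `Ei` are contractions
with coefficients `κi` and `Σ κi < 1`, the Picard sequence
`Γ_{n+1} = TΓ_n` converges to the unique solution, with the linear
Matkowski comparison function `φ(t) = (Σ κi) t` as certificate. Because the
equation is homogeneous with `Γ(0) = 0`, that unique fixed point is the zero
function, and the iterates decay accordingly — the interesting objects are
the exact iterates themselves and the contraction certificate.

The package provides, for this family of models:

* **Exact symbolic Picard iteration** (`picard_iterates`,
  `picard_step_exact`): for polynomial weights and affine operators every
  iterate is a polynomial with rational coefficients, computed in
  arbitrary-precision rational arithmetic and reported in lowest terms.
* **Numeric fixed-point solvers** (`solve_integral`, `solve_discrete`,
  `picard_step_numeric`): cumulative-trapezoid quadrature with linear
  interpolation for arbitrary continuous weights/operators, and boundary-
  pinned iteration for the discrete classical form.
* **Contraction analysis** (`contraction_report`, `lipschitz_constant`,
  `phi_iterate`, `a_priori_iterations`): exact Lipschitz constants for
  affine operators, certificate checks `Σ κi < 1` and `2 max κi < 1`, and
  the Banach a-priori iteration bound `kⁿ d₁/(1-k) ≤ ε`.
* **A stochastic simulator** (`simulate_two_choice`,
  `estimate_fixation_probability`, `simulate_four_outcome`,
  `compare_to_solution`): the underlying operant Markov process, with
  Monte-Carlo fixation estimates that cross-validate the solvers.
* **I/O and a CLI** (`load_model_config`, `write_iterates_csv`,
  `exec/operantfe`): JSON model configs with exact `"num/den"` rationals and
  CSV iterate tables (`x, Gamma0, ..., GammaN`).

## Worked example

```r
library(operantfe)

# pigeon-type model: weights t and 1-t, E1(t) = (t+1)/4, E2(t) = (t+2)/5
m <- preset_model("example1")
contraction_report(m)
#> contraction certificate
#>   operator 1: kappa = 1/4  (exact)
#>   operator 2: kappa = 1/5  (exact)
#>   aggregate k = 9/20
#>   Matkowski/Theorem condition sum(kappa) < 1: satisfied
#>   corollary condition 2*max(kappa) < 1: satisfied
#>   comparison function: phi(t) = 9/20 * t
#>   certificate status: certified (all kappa exact)

tr <- picard_iterates(m, n = 2)   # Gamma0 = x, two exact Picard steps
tr$iterates[[3]]
#> (61/2400000)*x^5 + (13/76800)*x^4 + (3217/480000)*x^3 + (3577/320000)*x^2 + (619/3750)*x
coefficient_query(tr$iterates[[3]], 3)
#>   numerator denominator
#>        3217      480000
```

The aggregate contraction coefficient 9/20 < 1 certifies a unique solution;
the second iterate's exact coefficients (e.g. `3217/480000` for `x^3`) are
the quantities the exact engine exists to produce. On the discrete side:

```r
d <- preset_model("lyubich_shapiro", a1 = "3/10", a2 = "6/10")
s <- solve_discrete(d)            # fixation probability f on a 1001-node grid
predict(s, c(0.25, 0.5, 0.75))
#> [1] 0.05060891 0.17735442 0.45340405
compare_to_solution(d, c(0.25, 0.5, 0.75), n_reps = 2000, seed = 3)
#>     x0   f_solved  p_hat          se         z flagged
#> 1 0.25 0.05060891 0.0515 0.004942052 0.1803079   FALSE
#> 2 0.50 0.17735442 0.1640 0.008279614 1.6129278   FALSE
#> 3 0.75 0.45340405 0.4475 0.011118537 0.5310097   FALSE
```

The Monte-Carlo fixation estimates agree with the solved fixed point within
sampling error at every starting state (`z` is the discrepancy in standard
errors).

From the shell, the same computations:

```sh
./exec/operantfe check --preset example1
./exec/operantfe solve-exact --preset example1 --n 2 --coeff 3   # 3217/480000
./exec/operantfe simulate --preset lyubich_shapiro --a1 0.3 --a2 0.3 \
    --x0 0.5 --reps 1000 --seed 1
```

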