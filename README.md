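# ffde

Fuzzy fractional differential equation solvers for predator–prey models.

## What this is for

Predator–prey dynamics are usually written as a pair of coupled ODEs for
prey density *u* and predator density *v*. Two kinds of uncertainty make
the crisp classical model optimistic: biological systems carry **memory**
(aggregate, power-law-like lags that an integer-order derivative cannot
express), and **initial densities are rarely known exactly**. `ffde`
addresses both for coupled systems

    ᶜDᵝ¹ u(t) = f₁(t, u, v),   ᶜDᵝ² v(t) = f₂(t, u, v),   β₁, β₂ ∈ (0, 1]

with the Caputo fractional derivative ᶜDᵝ (constants differentiate to
zero, classical initial conditions apply; β = 1 is the ordinary system)
and fuzzy initial conditions represented by triangular or exponential
fuzzy numbers propagated through their r-cut intervals.

The numerical core is a pair of one-step schemes derived from the
generalised Taylor expansion in powers t^{nβ}/Γ(nβ+1):

* the **fractional Euler method** (FEM), step factor h^β/Γ(β+1), and
* the **fractional modified Euler method**, which re-evaluates the
  right-hand side at a predictor offset X₁ = Γ(β+1)h^β/Γ(2β+1) — the
  fractional analogue of the classical midpoint rule, which it becomes at
  β = 1 (order 2 instead of FEM's order 1).

Both are deliberately memoryless one-step maps; see the vignette
(`vignettes/fuzzy-fractional-predator-prey.Rmd`) for exactly what that
implies for β < 1 and for the predictor-convention ambiguity that
`mode = "corrected"/"as_printed"` resolves.

Audience: ecological and epidemiological modellers who want envelope
(uncertainty-band) solutions of small fractional interaction models, and
numerical-methods users who want the schemes themselves with a serious
verification harness around them.

Two model families ship as presets with their standard fuzzy initial
conditions: a time-varying-coefficient predator–prey model
(`make_case_rhs(1)`, `make_case_rhs(2)`) and the non-dimensionalised
Lotka–Volterra system u(l − ku − v) / v(−1 + αu) with (l, k, α) = (5, 1, 2)
(`make_lv_rhs()`, `nondimensionalize()`).

## Worked example

Propagate triangular fuzzy initial conditions u(0) = (0.15, 0.25, 0.35),
v(0) = (0.1, 0.2, 0.3) through the Lotka–Volterra preset at fractional
order 0.9, for the grade ladder r ∈ {0.5, 0.9, 1}:

```r
library(ffde)
p  <- preset("lotka_volterra")
ft <- solve_fuzzy(p$rhs, p$u0$triangular, p$v0$triangular,
                  r_grid = c(0.5, 0.9, 1),
                  grid = time_grid(h = 0.1, horizon = 2), beta1 = 0.9)
#> Warning: 42 interval-ordering violation(s) (lower > upper); results are
#> reported as computed, not repaired
ft
#> <fuzzy_trajectory> lotka_volterra(l=5,k=1,alpha=2) | modified/corrected | coupling = endpoint
#>   beta = (0.9, 0.9), h = 0.1, 21 nodes x 3 grades (r: 0.5, 0.9, 1.0)
#>    42 interval-ordering violation(s)
head(as.data.frame(ft), 3)
#>     t   r   u_lower   u_upper   v_lower   v_upper
#> 1 0.0 0.5 0.2000000 0.3000000 0.1500000 0.2500000
#> 2 0.1 0.5 0.3604951 0.5262813 0.1412530 0.2434164
#> 3 0.2 0.5 0.6345723 0.8921927 0.1404417 0.2553828
```

Row 1 is the r = 0.5 cut of the inputs ([0.2, 0.3] × [0.15, 0.25]); later
rows are those interval endpoints advanced by the modified scheme, prey
surging and predator initially declining (f₂ < 0 at the start state). The
warning is the package surfacing — not repairing — the known defect of
endpoint coupling (lower-with-lower, upper-with-upper stepping is not an
interval enclosure when f₁ decreases in v); `check_nesting(ft)` locates
every violation, and `coupling = "extension"` gives a corner-extension
diagnostic that preserves ordering.

Verification-side, the β = 1 reductions carry their classical orders:

```r
convergence_order("fem", problem = make_benchmark("linear_decay_beta1"),
                  h_list = c(0.1, 0.05, 0.025, 0.0125), horizon = 1)
#> Convergence report: fem on linear_decay_beta1, T = 1
#>       h       error
#>  0.1000 0.019201001
#>  0.0500 0.009393519
#>  0.0250 0.004647001
#>  0.0125 0.002311297
#>   fitted log-log slope: 1.0179
```

and the modified scheme beats FEM on identical inputs
(`compare_methods("fppm_case1", r = 0.9, beta1 = 0.9, h = 0.1)`).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/ffde run --preset lotka_volterra --beta1 0.9 --horizon 2
Rscript inst/cli/ffde converge --method modified
```

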