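---
title: "Fuzzy fractional predator-prey dynamics: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy fractional predator-prey dynamics: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffde)
```

## The problem

Ecological interaction models depend on quantities — growth and death
rates, initial densities — that are rarely known precisely. This package
addresses two such sources of model uncertainty at once for predator-prey
systems:

* **memory effects**, by writing the dynamics with Caputo fractional
  derivatives of order $\beta \in (0, 1]$, so that the classical
  Lotka-Volterra-type system is the $\beta = 1$ special case; and
* **imprecise initial states**, by replacing crisp initial densities with
  fuzzy numbers and propagating their membership-grade intervals (r-cuts)
  through the solver.

The model family is the coupled system
$$
{}^C D^{\beta_1} u(t) = f_1(t, u, v), \qquad
{}^C D^{\beta_2} v(t) = f_2(t, u, v),
$$
with $u$ the prey and $v$ the predator density. Two concrete families
ship as presets: a time-varying-coefficient model
$f_1 = w(t)u - x(t)uv$, $f_2 = y(t)uv - z(t)v$ (two printed coefficient
cases, `make_case_rhs()`), and the non-dimensionalised Lotka-Volterra
system $f_1 = u(l - ku - v)$, $f_2 = v(-1 + \alpha u)$
(`make_lv_rhs()`, `nondimensionalize()`).

## The steppers

Both schemes are one-step methods built from the generalised Taylor
expansion in powers $t^{n\beta}/\Gamma(n\beta + 1)$, truncated at first
order. The **fractional Euler method** (FEM) advances
$$
u_{j+1} = u_j + \frac{h^{\beta_1}}{\Gamma(\beta_1 + 1)} f_1(t_j, u_j, v_j),
$$
and likewise for $v$ with $\beta_2$. The **fractional modified Euler
method** re-evaluates the right-hand side at a predictor point offset by
$$
X_1 = \frac{\Gamma(\beta_1 + 1)\, h^{\beta_1}}{\Gamma(2\beta_1 + 1)},
$$
the fractional analogue of the classical midpoint offset $h/2$ (which it
becomes at $\beta_1 = 1$).

### The predictor ambiguity

As the modified scheme is sometimes typeset, the increment for $u$ shifts
*both* state arguments by $X_1 f_1(t, u, v)$ and the increment for $v$
shifts both by $Y_1 f_2(t, u, v)$. That form cannot reduce to the
classical explicit-midpoint (RK2) step for a coupled system at
$\beta = 1$, which defeats the purpose of the midpoint construction. Both
readings are therefore implemented in `modified_euler_step()`:

* `mode = "corrected"` (default) shifts each state component by its own
  slope ($u$ by $X_1 f_1$, $v$ by $X_1 f_2$ inside $\Delta u$), the unique
  reading that recovers RK2 at $\beta = 1$ — verified to machine precision
  in the test suite on randomized inputs;
* `mode = "as_printed"` reproduces the $f_1/f_1$, $f_2/f_2$ pattern
  exactly, kept for fidelity and covered by tests.

### What these schemes are *not*

The Caputo derivative is a history integral, and a faithful discretisation
(product-rectangle Adams-type methods) must accumulate memory over all past
nodes. These one-step schemes deliberately do not: each step is locally
matched to the fractional Taylor expansion, then the state is advanced as
if the process restarted. The consequence is exactly quantifiable on
${}^C D^\beta u = c$: after $N$ steps the schemes give
$u_0 + N c h^{\beta}/\Gamma(\beta+1)$, while the exact solution is
$u_0 + c (Nh)^{\beta}/\Gamma(\beta+1)$. For $\beta < 1$ the two disagree
for every $h$, so **the schemes are not globally convergent to the exact
fractional solution for $\beta < 1$**; they are a structured family of
fractional-flavoured one-step maps whose $\beta = 1$ member is classical.
The verification harness therefore asserts convergence orders only at
$\beta = 1$ (orders 1 and 2), and for $\beta < 1$ asserts only first-step
exactness and fixed-$h$ cross-method comparisons. `convergence_order()`
refuses $\beta < 1$ problems outright rather than fit a slope to a limit
that does not exist.

## Fuzzy initial conditions

A triangular fuzzy number $(m, n, o)$ has linear membership rising from
$m$ to 1 at the core $n$ and falling to $o$; its r-cut is
$[(n-m)r + m,\; o - (o-n)r]$. An exponential fuzzy number decays as
$\exp(-(n-x)/(n-m))$ left of the core (mirrored right), truncated to
$[m, o]$; its r-cut is $[n + (n-m)\log r,\; n - (o-n)\log r]$.

Two boundary decisions were genuinely open:

* **Grade domain of the exponential cut.** The log-form diverges at
  $r = 0$, and for $r < e^{-1}$ the cut leaves the membership support
  $[m, o]$ (membership at the support edge is $e^{-1}$, so no point of the
  support has membership below that). `rcut()` accepts $r \in (0, 1]$,
  computes the formula as written, and attaches a classed warning
  (`ffde_support_warning`) below $e^{-1}$; the default exponential r-grid
  floor in `run_config()` is 0.05. Callers who want envelopes strictly
  inside the support should floor their grid at $e^{-1}$.
* **Degenerate triangular numbers.** Zero-width branches ($m = n$ or
  $n = o$) take their membership by limits — an indicator at the collapsed
  branch point — so a crisp initial value is the zero-width special case
  and the crisp-vs-fuzzy equivalence tests are exact, with no division by
  zero.
* **Logarithm base.** "log" in the exponential cut is the natural
  logarithm: it is the only base for which the cut at $r = e^{-1}$
  recovers the support, matching $\exp(\cdot)$ in the membership function.

### Interval propagation

`solve_fuzzy()` treats each grade $r$ independently. The default
`coupling = "endpoint"` advances the lower endpoints of $u$ and $v$
together as one crisp run and the upper endpoints as another —
lower-with-lower, upper-with-upper, the classical parametric scheme.
Because $f_1$ is *decreasing* in $v$, this pairing is **not** a guaranteed
interval enclosure: lower and upper branches can cross. That behaviour is
deliberate fidelity to the parametric scheme; the package instruments it
rather than repairing it. `check_nesting()` counts interval-ordering and
cross-grade-nesting violations and locates the first of each, and
`solve_fuzzy()` raises a classed warning (`ffde_ordering_violation`) when
any occur. An opt-in `coupling = "extension"` advances each interval by
the min/max of the step map over the four corner combinations — a corner
approximation of the Zadeh extension principle, useful as a diagnostic
(it preserves ordering by construction but can overspread, and it is
exact only when the step map is monotone in each argument).

## Parameters and defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `h` | step size (time units of the model) | 0.1 | the models' standard working resolution; halve it to check sensitivity |
| `beta1`, `beta2` | Caputo orders, $(0, 1]$ | 0.9 in presets | the order used for the method-comparison setting; 1 recovers classical dynamics |
| `horizon` | integration span | 5 | a few prey-predator turnover times for these parameter sets |
| `r_grid` | membership grades | $0, 0.1, \ldots, 1$ (triangular); $0.05, \ldots, 1$ (exponential) | even envelope coverage; exponential floor keeps $\log r$ finite |
| `mode` | predictor convention | `corrected` | the reading consistent with the midpoint construction |
| `coupling` | interval scheme | `endpoint` | the parametric stepping scheme; `extension` is a diagnostic |

The preset initial conditions are the printed triples: for the
coefficient-case model, $u(0) = (1.2, 1.3, 1.4)$ and
$v(0) = (0.5, 0.6, 0.7)$; for the reduced Lotka-Volterra system
($l = 5$, $k = 1$, $\alpha = 2$, i.e. $(a,b,c,e,\rho) = (5,5,10,1,1)$),
$u(0) = (0.15, 0.25, 0.35)$ and $v(0) = (0.1, 0.2, 0.3)$, each in both
triangular and exponential shape.

## Numerical choices

* **Oracles are more accurate than what they check.** The
  Riemann-Liouville integral and Caputo derivative are computed after the
  substitutions $s = (t-\tau)^{\beta}$ and $s = (t-\tau)^{1-\beta}$, which
  absorb the endpoint singularity exactly; `stats::integrate` then sees a
  smooth integrand (relative tolerance $10^{-10}$). Against monomial
  closed forms they agree to about $10^{-10}$, three orders tighter than
  the $10^{-6}$ the test suite demands. When no analytic derivative is
  supplied, the Caputo oracle differentiates by central differences with
  Richardson extrapolation, which requires the function to be evaluable
  slightly outside $[0, t]$.
* **Mittag-Leffler reference.** $E_\beta(z)$ is summed as a truncated
  power series with lgamma-scaled terms; adequate to $\sim 10^{-13}$ for
  the moderate arguments used as first-step references, and not intended
  for large $|z|$.
* **Reference trajectories.** Where no closed form exists (the
  Lotka-Volterra benchmark), the reference is the corrected modified
  scheme on a grid 100x finer — order-2 accuracy at $h_{\mathrm{ref}}
  \le 10^{-3}$ is ample for estimating order-1/order-2 error slopes at
  $h \ge 6 \times 10^{-3}$.
* **Problem sizes.** Convergence slopes use
  $h \in \{0.1, 0.05, 0.025, 0.0125\}$ on $u' = -u$ over $[0, 1]$. On the
  Lotka-Volterra benchmark the prey transient is fast ($u$ grows
  twentyfold), and at $h = 0.1$ the error is not yet in the asymptotic
  regime; its slope ladder is $h \in \{0.05, \ldots, 0.00625\}$. The
  improvement comparison runs the presets to $T = 2$ at $h = 0.1$ against
  an $h/100$ reference.
* **Determinism.** The solvers draw no random numbers; identical inputs
  give bit-identical trajectories. Trajectory TSVs print 17 significant
  digits, so a written table re-read from disk is bit-identical, and the
  JSON run manifest alone reproduces a run exactly.
* **Negative states.** Populations are not clipped at zero; a classed
  warning (`ffde_negative_state`) reports the first offending node. For
  these step sizes and presets, negativity signals the discretisation
  leaving its trust region, and silently clipping would mask it.

## A worked run

```{r lv-run}
p <- preset("lotka_volterra")
ft <- solve_fuzzy(p$rhs, p$u0$triangular, p$v0$triangular,
                  r_grid = c(0.5, 0.9, 1), grid = time_grid(h = 0.1, horizon = 2),
                  beta1 = 0.9)
summary(ft)
```

```{r lv-plot, fig.width = 6, fig.height = 6}
plot(ft, kind = "envelope")
```

At $r = 1$ both shapes collapse to the crisp run from the cores — exactly,
not approximately, since the cut at full membership is the single point
$n$ for both membership shapes:

```{r r1}
tri <- solve_fuzzy(p$rhs, p$u0$triangular, p$v0$triangular, r_grid = 1,
                   grid = time_grid(h = 0.1, horizon = 2), beta1 = 0.9)
expo <- solve_fuzzy(p$rhs, p$u0$exponential, p$v0$exponential, r_grid = 1,
                    grid = time_grid(h = 0.1, horizon = 2), beta1 = 0.9)
identical(tri$u_lower, expo$u_lower)
```

And the method comparison that motivates the modified scheme:

```{r compare}
cmp <- suppressWarnings(
  compare_methods("fppm_case1", r = 0.9, beta1 = 0.9, h = 0.1, horizon = 2))
print(cmp)
```

## What the tests do and do not show

The synthetic benchmarks (`make_benchmark()`) exercise exactly the
regimes where an independent truth exists: constant right-hand sides
(closed-form Caputo solution, any order), linear decay and the smooth
Lotka-Volterra system at $\beta = 1$ (classical references), and the
linear Caputo equation via Mittag-Leffler (first-step only). Passing them
shows the steppers implement their defining formulas, reduce correctly to
the classical schemes, and that the modified scheme's error improvement
is real at $\beta = 1$. They do **not** show that trajectories for
$\beta < 1$ approximate the exact fractional flow (they provably do not
as $h \to 0$), nor that the endpoint-coupled fuzzy envelopes enclose the
true reachable set — `check_nesting()` exists precisely because they can
fail to. Real ecological data would additionally bring observation noise,
parameter (not just initial-condition) uncertainty, and non-autonomous
forcing, none of which the generator emulates.

## Known limitations

* No memory term: not a convergent fractional solver for $\beta < 1$
  (see above); use an Adams-type product-integration method when the
  exact fractional flow matters.
* Endpoint coupling can produce crossed intervals; extension coupling can
  overspread. Neither is a validated enclosure method.
* Exponential envelopes below $r = e^{-1}$ leave the membership support;
  they are computed as the parametric form dictates and flagged.
* `rl_integral()` and `caputo_derivative()` are oracles for scalar smooth
  functions on moderate intervals, not a general fractional-calculus
  toolbox; orders above 1 are rejected.
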