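---
title: "Stochastic control costs of brain state transitions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic control costs of brain state transitions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrlbridge)
```

## The model

`ctrlbridge` treats whole-brain activity across $n$ regions of interest
(ROIs) as an Ornstein--Uhlenbeck (OU) process

$$dx(t) = A\,x(t)\,dt + C\,dw(t),$$

with drift (effective connectivity) matrix $A$ and noise loading $C$; only
$S_C = CC^\top$ enters any computation, and it is assumed nonsingular. When
$A$ is stable the process has a stationary law $N(0, \Sigma_\infty)$ with
$A\Sigma_\infty + \Sigma_\infty A^\top + S_C = 0$, which models the resting
state. A brain-state *transition* is a change of distribution: the system
must reach a target Gaussian $N(\mu_T, \Sigma_T)$ at a horizon $T$ instead
of the marginal the free dynamics would produce.

The cost of a transition is defined in path space. Among all controlled
processes $dx = (Ax + v)\,dt + C\,dw$ that satisfy both marginals, the
optimal one minimizes the Kullback--Leibler divergence of its path law from
the uncontrolled law — a Schrödinger bridge problem. By Girsanov's theorem,
twice that divergence equals the expected quadratic input
$E\!\int_0^T \lVert v\rVert^2_{S_C^{-1}}\,dt$, so the reported cost
$J^\ast$ is simultaneously an energy and (twice) an information divergence.
Both conventions are exposed (`J_total` and `KL = J_total / 2`); every
decomposition below refers to the energy scale.

## Solution structure and cost decomposition

The optimal control is affine, $v^\ast(x, t) = -S_C(\Pi(t)x - m(t))$, where
the feedback potential $\Pi$ solves the matrix Riccati equation
$\dot\Pi = -A^\top\Pi - \Pi A + \Pi S_C \Pi$ and an auxiliary potential $H$
solves the same equation with the opposite quadratic sign. The two are
coupled to the marginals through $\Sigma(t)^{-1} = \Pi(t) + H(t)$, with
$\Sigma(0) = \Sigma_0$ and $\Sigma(T) = \Sigma_T$. The total cost splits
exactly into

- a **mean control cost**
  $J_\mu^\ast = (\mu_T - \Phi(T)\mu_0)^\top M(T)^{-1}(\mu_T - \Phi(T)\mu_0)$,
  with $\Phi(T) = e^{AT}$ and the Gramian
  $M(T) = \int_0^T \Phi(T,\tau) S_C \Phi(T,\tau)^\top d\tau$ — identical to
  the deterministic minimum-energy control cost when the input matrix
  equals the noise loading, and depending only on the marginal means; and
- a **covariance control cost**
  $J_\Sigma^\ast = \int_0^T \mathrm{tr}(S_C \Pi)\,dt -
  \mathrm{tr}(\Pi(T)\Sigma_T - \Pi(0)\Sigma_0)$, depending only on the
  marginal covariances — the price of reconfiguring functional
  connectivity, which a point-to-point (deterministic) analysis cannot see.

Per-node attribution integrates the squared optimal input at each ROI:
$I(k) = E\int \lVert v_k^\ast\rVert^2 dt$ decomposes as
$I(k) = I_\mu(k) + I_\Sigma(k)$ with
$I_\mu(k) = (S_C \int ww^\top dt\, S_C)_{kk}$ for the feedforward part
$w = \Pi\mu - m$ and
$I_\Sigma(k) = (S_C \int \Pi\Sigma\Pi\, dt\, S_C)_{kk}$. When $S_C = I$ the
node inputs sum to $J^\ast$ exactly.

### How the boundary values are computed

The Riccati pair is linear in the inverses $Q = \Pi^{-1}$,
$P = H^{-1}$: $Q(t) = \Phi(t)Q(0)\Phi(t)^\top - M(t)$ and
$P(t) = \Phi(t)P(0)\Phi(t)^\top + M(t)$. Rather than iterating on the
coupled boundary conditions, the package computes $\Pi(0)$, $\Pi(T)$ in
closed form: pull the terminal variable back through the flow
($z = \Phi(T)^{-1}x_T$), whiten by the pulled-back Gramian
$N = \Phi^{-1}M\Phi^{-\top}$, solve the resulting *static* Gaussian
entropic coupling between the whitened marginals $s_0, s_1$,

$$C_u = \tfrac{1}{2}\!\left(s_0^{1/2}\big(4\,s_0^{1/2}s_1 s_0^{1/2} +
I\big)^{1/2} s_0^{-1/2} - I\right),$$

and read the terminal potential off the conditional precision of the
coupling ($\Gamma = \mathrm{Cov}(u_1\mid u_0)^{-1} - I$, then
$\Pi_{\mathrm{wh}}(0) = \Gamma(I+\Gamma)^{-1}$). This construction was
chosen because it is non-iterative, exact to rounding (boundary residuals
are reported in `diagnostics` and sit near $10^{-13}$ in the test suite),
and inverse-free in $\Pi(0)$ along the grid, so the zero-cost case
$\Pi \equiv 0$ and near-singular intermediate potentials need no special
branch. It is validated in the tests against an independent scalar
root-finder, a Gaussian Sinkhorn fixed point (during development), and
Monte-Carlo simulation of the controlled SDE.

The grid on $[0, T]$ is uniform with 201 points by default and composite
Simpson quadrature; the solver doubles the grid (up to three times) until
$J_\Sigma^\ast$ changes by less than $10^{-6}$ relative. The two
algebraically equivalent forms of $J_\Sigma^\ast$ (the boundary-term form
above and $\int \mathrm{tr}(\Pi S_C \Pi \Sigma)\,dt$) are always both
computed; a relative gap above $10^{-4}$ raises an internal-consistency
error, and the achieved gap is reported.

## Estimating the model from ROI time series

The estimation pipeline mirrors standard practice for fMRI-derived ROI
series:

1. **Trace normalization.** BOLD amplitudes are not comparable across
   subjects, so each subject's series is divided by the square root of the
   trace of the empirical covariance of its reference segment (the resting
   run, or the task-free moments of a task run). After this the reference
   covariance has unit trace and subjects can be concatenated. All
   downstream cost *ratios* are invariant to any per-subject rescaling.
2. **Sparse VAR(1).** Sampling the OU process at interval $\Delta t$ gives
   exactly $x_{t+\Delta t} = a x_t + \varepsilon$ with $a = e^{A\Delta t}$.
   Each row of $a$ is fitted by lasso regression (with intercept);
   regression pairs never span concatenation boundaries. The penalty is
   chosen by 5-fold cross-validation of one-step-ahead error by default
   (`lambda = "cv"`), because no single fixed penalty is appropriate across
   sample sizes; a fixed value (including exact OLS at 0) can be supplied.
3. **Continuous-time conversion.** $\hat A = \log \hat a / \Delta t$ via
   the principal matrix logarithm (eigenvalues of $\hat a$ must lie inside
   the unit disk and off the closed negative real axis; an imaginary
   residual above $10^{-6}$ aborts with advice to refit at a smaller
   $\Delta t$ rather than silently discarding large imaginary parts), and
   $\hat S_C = -\frac{1}{\Delta t}\,\mathrm{vec}^{-1}\!\big[(I - a\otimes
   a)^{-1}\log(a\otimes a)\,\mathrm{vec}(S_\varepsilon)\big]$, the exact
   inverse of the one-step noise integral. Round-tripping through
   `exact_discretization()` reproduces $(A, S_C)$ to $10^{-8}$.
4. **States.** The rest state uses the pooled empirical mean and
   covariance. A task state uses the mean of task-performing moments
   *minus* the mean of task-free moments (the task-free baseline stands in
   for rest) and the empirical covariance of the performing moments.
   Estimated covariances are shrunk toward their diagonal just enough to
   reach condition number $10^8$ (default) before being used as bridge
   marginals, which must be strictly positive definite.

The sampling interval is a required input with a config default of 0.72
time units, an fMRI-like repetition time; it is deliberately not hidden
inside any function. An exact match between the fitted dynamics' implied
steady state and the empirical rest covariance is *not* enforced: the
intercept-and-empirical-residual fit keeps the two approximately
consistent, and forcing exact agreement would distort $\hat S_C$; the
shrinkage step protects the bridge solver either way. The subject-level
bootstrap (draw $k$ subjects without replacement, estimate, repeat) is
provided by `bootstrap_concatenate()` and drives
`run_transition_analysis()`; the covariance/mean cost ratio is computed
within each replicate and then averaged, never as a ratio of averages.

## What the synthetic cohorts emulate — and what they do not

`generate_cohort()` produces multi-subject rest and task runs from a known
stable OU system: stationary resting runs; task runs alternating task-free
blocks (stationary OU) with task-performing blocks whose samples are pushed
through an affine map, so the performing blocks have mean offset $\delta$
and covariance $L\Sigma_0 L^\top$ *exactly in law*; and positive
per-subject scale factors emulating uninterpretable BOLD magnitude. Task
blocks are transformed stationary samples rather than a second simulated
controlled SDE — the estimation pipeline only consumes block moments, and
the affine construction makes the ground truth exact. The generator does
not model hemodynamics, physiological noise, scanner drift, or
nonstationarity within blocks; passing tests therefore demonstrate
correctness of the estimation and cost machinery under the linear-Gaussian
model, not robustness to fMRI artifacts.

`simulate_controlled_paths()` is the independent Monte-Carlo oracle: it
integrates the optimally controlled SDE by Euler--Maruyama (step at most
$T/500$, enforced) with the gridded $\Pi, m$ interpolated linearly, and
records endpoint laws, the quadratic cost, and per-node costs. The
validation suite runs it with 20,000 paths at step $T/1000$ and checks
agreement with the analytic costs within three standard errors.

## Numerical choices

- Integrals $\int_0^T e^{As} Q e^{A^\top s}ds$ use the Van Loan
  block-exponential identity, extended to long horizons by the doubling
  recurrence $M(2t) = \Phi(t)M(t)\Phi(t)^\top + M(t)$ (the raw block
  exponential contains $e^{-A^\top T}$ and overflows for strongly stable
  systems at large $T$).
- The steady state solves the continuous Lyapunov equation in the
  eigenbasis of $A$ (Kronecker fallback for defective drifts); the
  stationary-integral form is retained only as a test oracle.
- Stability demands $\max \mathrm{Re}\,\lambda(A) < -10^{-10}$ where a
  steady state is needed; operations that do not need it accept any drift.
- Symmetric outputs are symmetrized; asymmetry beyond $10^{-8}$ relative
  warns instead of passing silently.
- All random generation (systems, trajectories, cohorts, bootstrap,
  controlled paths) flows through explicit integer seeds and restores the
  caller's RNG state; identical seeds give identical results bit for bit.
- Default horizon $T = 1.0$ time unit, the representative transition
  horizon; `run_transition_analysis()` accepts any horizon and the CLI
  sweeps a list of them.

## Validation problem sizes

The shipped validation suite exercises: zero-cost identities and boundary
residuals on random systems up to $n = 8$; Monte-Carlo oracle agreement at
$n = 1, 2, 3$ with 20,000 paths; minimum-energy correspondence at
$n \le 5$ with a $10^{-3}$ discretization; dynamics recovery at $n = 10$
from a 100,000-step resting run (relative Frobenius errors around 0.05 for
$A$ and 0.02 for $S_C$); and a directional end-to-end bootstrap at
$n = 6$, 20 subjects, 10 replicates of 10 subjects, where a mean-only task
effect ($\delta = 0.5$ on two ROIs, roughly one resting standard deviation
in normalized units) yields a covariance/mean cost ratio far below one and
a covariance-only effect ($L = I + 0.18 \cdot$ random mixing) yields a
negligible mean cost. These sizes were chosen as the smallest that give
statistically decisive checks.

## A worked example

```{r example, eval = FALSE}
sys <- make_random_stable_system(6, sparsity = 0.5, seed = 42)
rest <- steady_state(sys)
task <- gaussian_state(c(0.4, 0.4, 0, 0, 0, 0),
                       1.2 * rest$sigma + 0.05 * diag(6))
prob <- bridge_problem(sys, rest, task, horizon = 1)
sol <- solve_schrodinger_bridge(prob)
sol
node_inputs(prob, sol)
```

## Known limitations

- The input matrix is tied to the noise loading ($B = C$, equivalently the
  cost metric is $S_C^{-1}$); general input matrices are out of scope.
- Marginals must be Gaussian and nondegenerate; rank-deficient noise is
  rejected.
- The Kronecker-based noise-rate conversion builds an $n^2 \times n^2$
  system; it is comfortable to $n \approx 60$ and is not intended for
  parcellations much beyond a few hundred ROIs without a dedicated Stein
  solver.
- The pipeline estimates *optimal* transition costs under the fitted
  resting dynamics; it does not estimate the inputs a real brain actually
  used.
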