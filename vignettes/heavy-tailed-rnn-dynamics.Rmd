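---
title: "Methods: finite-size dynamics of heavy-tailed recurrent networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finite-size dynamics of heavy-tailed recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`levyrnn` studies the discrete-time rate network

$$x_i(t+1) = \tanh\Big(\sum_{j=1}^N W_{ij}\, x_j(t) + I_i(t)\Big),$$

whose weights $W_{ij}$ are i.i.d. draws from the centered symmetric Lévy
$\alpha$-stable family with characteristic function
$\varphi(k) = \exp(-|\sigma k|^\alpha)$ and scale
$\sigma = g/N^{1/\alpha}$. The gain $g$ is the control parameter. Two
conventions matter throughout and are locked package-wide:

* **Scale convention.** At $\alpha = 2$ the law above is $N(0, 2\sigma^2)$ —
  variance $2\sigma^2$, not $\sigma^2$. All bookkeeping (for instance the
  Gaussian transition at $N\,\mathbb{E}[W^2] = 1$) depends on this factor
  of 2, so any external sampler used for cross-checks must be mapped into
  this convention first.
* **No truncation.** Heavy-tailed matrices contain rare, enormous entries
  ("mega-synapses"). These outliers are the phenomenon, not a numerical
  nuisance, so no clipping is applied by default (`sample_weight_matrix()`
  exposes an optional `clip` for sensitivity analyses only).

Sampling uses the exact Chambers–Mallows–Stuck construction,
$X = \frac{\sin(\alpha U)}{(\cos U)^{1/\alpha}}
\big(\frac{\cos((1-\alpha)U)}{E}\big)^{(1-\alpha)/\alpha}$ with $U$ uniform
on $(-\pi/2, \pi/2)$ and $E$ exponential. The $\alpha = 1$ branch is the
tangent of a uniform angle (standard Cauchy) and is evaluated geometrically
as the coordinate ratio of a uniform direction in the unit disk, which
avoids a `tan` call in the innermost loop; $\alpha = 2$ reduces to
$2\sin(U)\sqrt{E} \sim N(0,2)$. Uniform deviates come from an internal
xoshiro256+ stream seeded from R's RNG at entry of each compiled routine,
so everything is reproducible under `set.seed()` while annealed sweeps that
redraw an $N \times N$ matrix every step remain fast. Distributional
contracts (variance 2 at $\alpha=2$, Cauchy quartiles, empirical
characteristic functions, symmetry, moment normality) are enforced by the
test suite.

# Finite-size transition theory

Linearizing around the quiescent state $x = 0$ (where $\tanh' = 1$) gives
the random linear recursion $\varepsilon(t+1) = W(t)\,\varepsilon(t)$ — a
Kesten process when the weights are redrawn each step (the *annealed*
approximation, equivalently a constant-width feedforward network). For
i.i.d. stable rows, $W\varepsilon$ is distributed as
$\sigma \lVert\varepsilon\rVert_\alpha \cdot z$ with $z$ a vector of
unit-scale stable variates, so the log $\alpha$-norm performs a random walk
with mean step $\ln g + \Xi_{N,\alpha}$, where

$$\Xi_{N,\alpha} = \mathbb{E}\Big[\tfrac{1}{\alpha}
  \ln\Big(\tfrac{1}{N}\sum_{j=1}^N |z_j|^\alpha\Big)\Big],
  \qquad z_j \sim L_\alpha(1).$$

The annealed critical gain is therefore $g^* = \exp(-\Xi_{N,\alpha})$:
below it the quiescent state attracts, above it perturbations grow.

Two reading choices in this formula were genuinely open and are resolved as
follows:

* **Expectation outside the logarithm.** With the expectation inside,
  $\mathbb{E}|z|^\alpha$ diverges for every $\alpha < 2$ and the expression
  is undefined. The outside placement is what the norm-process derivation
  produces, reproduces the Gaussian limit, and yields the
  $(\ln N)^{-1/\alpha}$ asymptotics. $|z_j|^\alpha$ uses absolute values
  (fractional powers of negative reals are undefined; $\alpha$-norms
  require them).
* **Gaussian limit constants.** The self-consistent Gaussian limit is
  $\Xi_{\infty,2} = \ln\sqrt{2}$, hence $g^* = 1/\sqrt{2}$, which recovers
  the classical transition at $N\,\mathbb{E}[W^2] = 2(g^*)^2 = 1$.
  Renderings of these constants elsewhere as $\ln 2$ and $1/2$ drop the
  radicals and are inconsistent with the derivation; the package follows
  the self-consistent values, and the exact finite-$N$ Gaussian formula
  below makes the choice testable.

For $\alpha = 2$, $(1/N)\sum z_j^2 \sim (2/N)\chi^2_N$ and
$\mathbb{E}\ln\chi^2_N = \ln 2 + \psi(N/2)$, giving the closed form
$\Xi_{N,2} = \tfrac12(\psi(N/2) + \ln(4/N))$ (`xi_gaussian()`), used as the
default $\alpha = 2$ path of `critical_gain()` and as an independent oracle
for the Monte-Carlo estimator at all sizes. For $\alpha < 2$,
`xi_monte_carlo()` averages i.i.d. replicates of the log normalized
$\alpha$-power sum (default $10^4$ replicates, standard errors reported;
replicate averaging happens on $\Xi$, which is then exponentiated).
`asymptotic_gain_check()` regresses $\ln g^*$ on $\ln\ln N$; for
$\alpha < 2$ the slope is near $-1/\alpha$ (slowly varying corrections make
the finite-grid slope slightly shallower), while the Gaussian $g^*$ is flat
in $N$ almost immediately.

# Linearized dynamics without overflow

`simulate_linear()` propagates the linearization in annealed mode (fresh
matrix per step, generated row-by-row on the fly and never materialized) or
quenched mode (one fixed matrix). At gains away from $g^*$ the state
magnitude traverses hundreds of powers of $e$ in a hundred steps, far
outside double range; the state is therefore stored as a unit 2-norm
direction plus an accumulated log magnitude, renormalized every step.
Per-step log growth of both the 2-norm and the $\alpha$-norm is recorded;
the $\alpha$-norm series is what the scalar Kesten recursion predicts and
is compared against it distributionally in the tests (two-sample
Kolmogorov–Smirnov).

The quiescence order parameter $f_{<\epsilon}$ is the *fraction* of final
components within $\epsilon$ of zero — 1 in the quiescent phase, 0 above
the transition. It is evaluated in log space
($\log|\mathrm{dir}_i| + \log\mathrm{mag} < \ln\epsilon$), so super-critical
runs whose true magnitudes overflow are handled exactly. Defaults follow
the study conditions: threshold $\epsilon = 0.1$, depth $T = 100$, initial
components i.i.d. uniform on $(-1, 1)$ (the initial-condition law is not
otherwise pinned down; uniform is recorded here as the package's choice),
10 realizations. The quenched protocol fixes one base matrix per
realization, drawn at unit gain with scale $N^{-1/\alpha}$, and rescales
the *same* realization by every gain in the sweep, sharing the initial
vector across the grid.

# Lyapunov spectra

`lyapunov_spectrum()` implements the Benettin QR method: an orthonormal
frame of $m$ tangent vectors is pushed through the exact per-step Jacobian
$\mathrm{diag}(1 - x(t+1)^2)\,W$, re-orthonormalized by economy QR with the
sign convention $\mathrm{diag}(R) > 0$, and $\ln R_{ii}$ accumulated after
a warmup during which the state evolves but nothing is accumulated.
Numerical choices:

* **Contraction floor.** Trajectories in deep quiescence hit exact zero in
  floating point ($R_{ii} = 0$, $\ln R_{ii} = -\infty$). Per-step log
  contractions are clamped at $\ln(\text{machine eps}) \approx -36$ and the
  result flagged, so gain-0 runs return finite, labeled values.
* **Protocols.** Maximal-exponent sweeps follow the horizon $T = 3000$ with
  accumulation over the final $K = 100$ steps (warmup $T - K$);
  full-spectrum runs use a fixed warmup (default 500). The full-spectrum
  cost is $O(N^2 m)$ per step, so all $N$ exponents are computed by default
  only for $N \le 1000$, with a top-$m$ frame (default 100) otherwise.
* **Trial policy.** By default each trial draws a fresh weight matrix,
  initial condition, and input stream (realization averaging — the right
  notion for autonomous sweeps); an input-averaging policy that fixes one
  matrix is available (`trial_policy = "input"`).
* **Linear hook.** `activation = "linear"` replaces tanh by the identity,
  for which the exponents converge to sorted $\ln|\mathrm{eig}(W)|$ — the
  eigendecomposition oracle used in the tests.

**Transition-gain estimation.** `estimate_transition_gain()` interpolates
the first negative-to-nonnegative crossing of the trial-averaged exponent
curve. Near the transition, however, the trial average sits on a long
near-zero plateau: realizations split into quiescent (exponent pinned just
below 0) and chaotic (just above 0) branches, so the averaged curve's
crossing is fragile. The package therefore also provides the estimator
actually used for critical-gain summaries: run the sweep with
`share_matrix = TRUE` (each realization rescaled across the whole gain
grid, as in the quenched protocol), interpolate each realization's own
sharp crossing, and average (`realization_crossing_gains()`). The
per-realization dispersion of these crossings is itself informative: it
shrinks with $N$ and is much larger, relative to the mean, for heavy tails.

**Kaplan–Yorke dimension.** With sorted exponents and $k$ the largest index
whose cumulative sum is nonnegative,
$D_{KY} = k + (\sum_{i\le k}\lambda_i)/|\lambda_{k+1}|$. The denominator
uses the absolute value ($\lambda_{k+1} < 0$ by construction of $k$; that
is the only reading with $D_{KY} \ge k$). Edge conventions: $\lambda_1 < 0$
gives 0 (no expanding direction); a nonnegative full sum returns the
tracked length $m$ (the tracked spectrum cannot bound the attractor).

# Dimensionality of activity

`empirical_covariance()` computes the mean-centered covariance of the final
$K$ retained states with divisor $K - 1$; the retained window, not the full
trajectory length, enters the normalization. $K > N$ is a conditioning
recommendation, enforced as a warning rather than an error. Eigenvalues are
clipped at zero (roundoff) and, before the participation ratio, at
$10^{-12}$ of the leading eigenvalue (rank-deficient regimes). The
participation ratio is
$\mathrm{PR} = (\sum_i \tilde\lambda_i)^2 / \sum_i \tilde\lambda_i^2$,
ranging from 1 (one mode) to $N$ (uniform variance) — the only reading of
the formula consistent with that range. An all-zero spectrum (a fully
collapsed trajectory) leaves PR undefined and raises an error; the
experiment layer records such trials as `NA`.

The dimensionality comparison across $\alpha$ is evaluated at $1.5\times$
each ensemble's estimated crossing: exactly at the crossing roughly half
the realizations are still quiescent (no attractor, $D_{KY} = 0$, PR
undefined), and just past it the quiescent/chaotic mixture still dominates
trial averages; $1.5\times$ is the smallest relative gain at which every
realization reliably carries an attractor while the mean maximal exponent
remains small (near-critical chaos), which is the regime whose
dimensionality the tradeoff concerns. Defaults there: $T = 1500$, warmup 500, top 100
exponents, $K = 500$ retained states — sizes chosen so the full battery is
desk-runnable; the same code runs full-scale configurations
($N = 1000$–$10^4$, $T = 3000$) unchanged.

# The delayed-XOR reservoir task

`run_xor_reservoir()` drives the network with a random bit stream through a
fixed random input vector and trains a ridge readout (intercept
unpenalized, penalty $10^{-4}$) on post-washout states to predict the XOR
of the bits at lags `delay` and `delay + 1` (default: lags 1 and 2), with
2000/1000 train/test steps and input scale 0.5. All task parameters are
package choices, exposed in the interface.

One encoding decision deserves emphasis: the bits are injected as
$u \in \{0, 1\}$, not as a centered $\pm 1$ stream. With the odd activation
$\tanh$, a centered stream makes the post-transient state an (asymptotically)
odd function of the input history, while the XOR target is an even function
of it; a linear readout of an odd feature map is then at chance *by
symmetry*, for every $\alpha$ and gain — which is exactly what we measured
with $\pm 1$ inputs (occasional heavy-tailed successes traced to
symmetry-broken attractors). The 0/1 encoding breaks the symmetry and makes
the task cleanly learnable near the edge of chaos, where the comparison of
interest — how gracefully accuracy degrades as the gain moves away from the
edge for heavy versus light tails — becomes observable.
`accuracy_window_width()` summarizes the gain interval sustaining a given
accuracy.

# What the generator emulates, and what it does not

All inputs are generated internally: stable weight matrices, uniform
initial conditions, Gaussian drive (variance 0.01 per unit and step when
enabled), and Bernoulli bit streams. The defaults *are* the study
conditions (transition sweeps at $T = 100$, $\epsilon = 0.1$, 10
realizations; exponent sweeps at $T = 3000$, $K = 100$, 10 trials;
$\alpha$ grid anchored at $\{1, 2\}$ with other values configurable). The
model is an untrained, homogeneous rate network: no spiking, no Dale's law,
no cell-type structure, no plasticity, discrete time only, tanh only
(plus the linear test hook). Passing tests therefore certify the dynamics
of this idealized ensemble, not of biological circuits; the connection to
data is through the qualitative tradeoff the ensemble exhibits.

# Known limitations and observations

* Quenched transition locations fluctuate across realizations and their
  theory is out of scope; only the annealed $g^*$ is predicted, and the
  recurrent-network crossing sits systematically slightly above it
  (about 7–11% at $N = 500$, $\alpha = 2$) — consistent with the annealed
  prediction being a lower-edge estimate of the quenched onset.
* The "breadth" of the edge-of-chaos regime depends on the units in which
  gain intervals are measured. At desk scale ($N = 500$) the interval where
  the trial-averaged maximal exponent stays within $\pm 0.05$ is *not*
  wider for $\alpha = 1$ than for $\alpha = 2$ in absolute gain units: the
  Gaussian window is inflated by the quiescent/chaotic coexistence plateau
  and by the fact that it sits at twice the gain scale. Heavy-tailed
  robustness shows instead in gain-*ratio* units ($g/g^*$), in the much
  larger relative dispersion of per-realization transition points, and in
  the reservoir task's slower accuracy decay beyond the edge. The
  acceptance suite states the absolute-units comparison as specified and
  reports its outcome honestly.
* Monte-Carlo $\Xi$ for small $\alpha$ has heavy-tailed replicate
  distributions; reported standard errors are still finite (the log tames
  the tails) but convergence in $N$ is slow, which is precisely the
  finite-size phenomenon of interest.
* Full spectra above $N \approx 1000$ require the top-$m$ frame; the
  Kaplan–Yorke index can then saturate at $m$ in strongly chaotic regimes
  (reported as the tracked length by convention).
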