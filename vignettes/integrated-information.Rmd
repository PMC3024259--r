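---
title: "Measuring integrated information from stationary time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring integrated information from stationary time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phitime)
```

## The quantity being measured

Integrated information, written Φ, formalizes the intuition that a complex
system is more than the sum of its parts: it is the information that a
system's state transitions generate *as a whole*, over and above the
information generated by its parts considered independently. High Φ
requires the coexistence of integration (the whole is dynamically
coherent) and differentiation (the parts are dynamically distinct) — a
combination of interest wherever coupled dynamical networks arise, and
especially in computational neuroscience, where Φ has been proposed as a
correlate of conscious level.

`phitime` implements the family of Φ measures that are computable for
stationary stochastic systems directly from covariance matrices, either
analytically from a generative model or empirically from recorded
multi-trial time series:

* **Φ_E** — effective information based on the *empirical* (stationary)
  distribution of the past state. For a bipartition
  \(B = \{M^1, M^2\}\) of the elements, the effective information at lag
  τ is
  \[
  \varphi(B,\tau) \;=\; I(X_{t-\tau}; X_t)\;-\;\sum_{k=1,2}
     I(M^k_{t-\tau};\, M^k_t),
  \]
  mutual information of the whole minus the sum over the parts.
* **Φ̃_E** — the *stochastic interaction* variant, replacing mutual
  informations by conditional entropies:
  \(\sum_k H(M^k_{t-\tau}\mid M^k_t) - H(X_{t-\tau}\mid X_t)\).
* **Φ_AR** — the auto-regressive reading of Φ_E in terms of linear
  regression prediction error. Because the residual covariance of a
  linear regression equals the partial covariance for *any* distribution,
  the Gaussian computational recipe applied to non-Gaussian data yields
  exactly Φ_AR. In this package the two measures share one code path and
  differ only in the label carried by the result.
* **Φ_DM (Gaussian extension)** — an adaptation of the discrete/Markovian
  expected-Φ to continuous Gaussian MVAR(1) systems, replacing the
  (undefined, on the real line) maximum-entropy prior by a surrogate in
  which every element is independent and Gaussian with its stationary
  mean and variance.

All information quantities are in **nats** (natural logarithms
throughout).

## The minimum information bipartition

Φ is the effective information across the system's informational weakest
link. Every bipartition is scored by its effective information
*normalized* by
\[
K(B) \;=\; \min_k H\!\big(M^k\big),
\]
the smaller of the two parts' stationary entropies. The minimum
information bipartition (MIB) minimizes the normalized value, and Φ is
the **non-normalized** effective information there. Normalization biases
the search toward balanced splits — without it, single-element splits
would almost always win and Φ would be trivially small — while reporting
the non-normalized value preserves Φ's meaning as a quantity of
information.

This construction is also the measure's main fragility. When two
bipartitions have nearly equal normalized values but very different raw
values, tiny perturbations (of parameters, or of finite-data estimates)
flip the MIB and Φ jumps discontinuously even though each bipartition's
effective information varies continuously. `connection_sweep()` and the
record table attached to every `phi_result` expose this mechanism
directly; the test suite constructs such a near-tie by weakening one
node's couplings in a reciprocal ring.

Only bipartitions are searched (the standard restriction, for
computational efficiency); exhaustive enumeration covers the
\(2^{n-1}-1\) canonical splits and refuses above \(n = 20\) unless the
cap is raised. General multi-partitions are a documented extension point,
not implemented.

## Analytic computation: MVAR models and the Lyapunov equation

A stationary Gaussian system is equivalent to a multivariate
autoregressive process
\(x_t = \sum_{k=1}^p A_k x_{t-k} + \epsilon_t\)
(`mvar_model()`, row = target, column = source). Stationarity holds iff
the block-companion matrix has spectral radius below 1; the package tests
this with tolerance `1e-9` at construction. The stationary covariance
solves the discrete-time Lyapunov equation
\(\tilde\Sigma = \tilde A \tilde\Sigma \tilde A^\top +
\tilde\Sigma(\epsilon)\)
on the companion embedding, solved here by kronecker vectorization and
verified against a fixed-point residual bound of
\(10^{-8}\,\lVert\tilde\Sigma\rVert_F\). Lagged auto-covariances beyond
the companion order follow the Yule–Walker recursion
\(\Gamma_j = \sum_k \Gamma_{j-k} A_k^\top\), with the convention
\(\Gamma_\tau = \mathrm{Cov}(X_{t-\tau}, X_t)\) (past indexes rows). Any
lag τ and any order p are supported this way; τ is the timescale over
which integration is measured, and for an MVAR(1) process Φ_E(τ) peaks
at τ = 1.

Gaussian entropies and mutual informations reduce to log-determinants,
always computed via Cholesky — never via explicit determinants — so that
a singular covariance surfaces as the defined error rather than as a
quiet `-Inf`. Negative differential entropies are legal values; only the
normalization guard treats them specially: a bipartition whose K falls
below `eps_k = 1e-6` nats is excluded from the MIB search (small-variance
parts make K → 0 and the normalized ratio meaningless), and an explicit
error is raised if no admissible bipartition remains. Effective
information itself may be negative (redundancy-dominated systems) and is
reported as-is.

## Empirical computation

`empirical_moments()` estimates \(\Sigma\) and \(\Sigma(\tau)\) from
multi-trial recordings: each trial is demeaned separately (trials are
independent realizations, so a global mean would leak across-trial
variance into the covariances), (past, present) pairs are pooled with no
cross-trial pairs, and the unbiased \(1/(T_{\mathrm{eff}}-1)\)
normalization is used — the difference from \(1/T_{\mathrm{eff}}\) is
O(1/T) and far below any tolerance in this package. The stationary
covariance is the symmetrized average of the past-block and present-block
estimates. `phi_empirical()` then computes Φ per trial (default, the
reporting convention for stability experiments: mean ± sd and the
coefficient of variation) or from pooled covariances.

`fit_mvar1()` recovers a generative model from data via the covariance
identities \(\hat A = \hat\Sigma(1)^\top\hat\Sigma^{-1}\) and
\(\hat\Sigma(\epsilon) = \hat\Sigma -
\hat\Sigma(1)^\top\hat\Sigma^{-1}\hat\Sigma(1)\); it is needed to compute
the Φ_DM extension from data. A fitted model that fails the stationarity
check is returned with a warning and flag rather than an error.

## The Φ_DM extension

For the whole system the surrogate prior
\(\Sigma^{\max} = \mathrm{diag}(\Sigma)\) is propagated one step through
the MVAR(1) dynamics; Bayes' rule gives the posterior precision
\((\Sigma^{\max})^{-1} + A^\top \Sigma(\epsilon)^{-1} A\) of the past
given the present, hence \(H(X_0\mid X_1)\). For a part, states external
to it carry the surrogate distribution and enter as extra effective
noise, \(\Sigma(\epsilon)_{MM} + A_{MM^c}\,\Sigma^{\max}_{M^cM^c}\,
A_{MM^c}^\top\). The expected effective information of a bipartition is
\(\sum_k H(M^k_0\mid M^k_1) - H(X_0\mid X_1)\), normalized for the MIB
search by the smaller part's surrogate entropy. When the stationary
covariance is already diagonal — as for the chain and the unidirectional
ring — the surrogate *is* the stationary distribution and Φ_DM = Φ_E
exactly; correlated networks (reciprocal ring, homogeneous) give close
but distinct values. The extension is defined at a single time step and
for p = 1 only.

## Canonical networks and what the simulator emulates

`make_network()` regenerates the canonical 8-element examples: an open
unidirectional chain, a unidirectional ring, a reciprocal ring (all link
strengths 0.25), and a homogeneous all-to-all network with entries 1/14
(total afference 0.5 per element), all driven by unit-variance
independent Gaussian noise. Their analytic values at τ = 1 order as
chain < uni-ring < recip-ring with approximate doubling at each step, and
the homogeneous network scores low for its density — integration without
differentiation.

`simulate_mvar()` emulates stationary recordings from these models: zero
initial history, a burn-in of 1000 samples discarded before recording
(the dynamics here mix fast — spectral radii ≤ 0.5 — so equilibrium is
reached orders of magnitude sooner; the default is deliberately
conservative), and either Gaussian innovations or independent
exponential innovations with mean and variance 1. The exponential option
emulates the right-skewed aggregate activity of Poissonian spiking
populations; it is generated uncentered, as all downstream estimation
demeans. What the simulator does *not* emulate: measurement noise,
non-stationarity, line noise or filtering artifacts, and temporal
aggregation of real recordings — passing tests on these fixtures shows
estimator correctness under the model class, not robustness on real
neural data.

A note on finite-sample behavior: per-trial empirical Φ_E at 3000 points
is an honest but noisy estimator. For the chain — the smallest-Φ
canonical network — the across-trial coefficient of variation of 10-trial
sets concentrates around 0.13, and the per-trial MIB search adds
selection effects for networks with many near-equivalent balanced splits.
Longer trials, pooling, or fixing the MIB analytically all reduce the
variance; the per-trial default reproduces the standard reporting
protocol.

## Optimizing topology for high Φ_E

`evolve_networks()` runs a genetic algorithm with analytic Φ_E (τ = 1) as
fitness over 8-element MVAR(1) networks, in two constraint regimes:
`fixed` (every element receives exactly 2 afferents of 0.25; mutation
rearranges 2 connections) and `vary` (total afference 0.5 per element,
all afferents to an element equal and positive; initialization gives on
average 2 afferents per element; mutation adds, removes or swaps 2
connections with equal probability, then renormalizes). Defaults are a
population of 30 and 200 generations, which lets fitness asymptote.

Where the scheme was underdetermined, this package chooses: rank-based
selection with weight proportional to fitness rank, sampling with
replacement; exactly one elite copied unmutated per generation, so the
best-so-far trace is monotone and testable; non-stationary mutants are
rejected and re-mutated (rare, since afference ≤ 0.5 bounds the spectral
radius by 0.5); and the whole run is a pure function of its seed.
Landscape probes accompany the GA: `mutation_sensitivity()` reports
percentage drops in Φ_E under single mutations, and `connection_sweep()`
exposes discontinuities at MIB switches under continuous weight change.
Evolved `fixed`-condition networks reliably exceed the reciprocal ring's
0.1283 — heterogeneous topologies out-integrate uniform rings.

## Numerical and design choices, in brief

* Natural logarithms everywhere; values in nats.
* Cholesky for every determinant and solve; Cholesky failure *is* the
  singularity error.
* Stationarity margin `1e-9` on the companion spectral radius; Lyapunov
  residual bound `1e-8` (relative, Frobenius).
* MIB ties broken by smaller first part, then enumeration order (by part
  size, then lexicographic) — deterministic and recorded in the result.
* `eps_k = 1e-6` nats admissibility floor for the normalization.
* Mutual information clipped to zero only within `-1e-10` (floating
  point); anything more negative warns.
* Moving-average components, order selection, non-stationary extensions
  and non-Gaussian entropy estimators (kernel, nearest-neighbor) are out
  of scope.

## Problem sizes used in the tests

The shipped test suite works at the canonical scale: 8-element networks,
127-bipartition exhaustive searches, 10 trials of 3000 points for
stability checks, series of \(10^4\)–\(10^5\) points for estimator
consistency, Monte-Carlo oracles of \(10^5\)–\(5\times10^5\) samples, and
GA runs of 30 × 200 at full scale (seed sweeps of 5). These sizes were
chosen so every statistical assertion has comfortable margin under its
fixed seed while the whole suite stays fast on one CPU.

## A worked example

```{r example, eval = FALSE}
net <- make_network("recip_ring")
phi_analytic(net, tau = 1)              # 0.1283 nats, MIB {1,2,3,4}|{5,6,7,8}
phi_analytic(net, measure = "phi_e_tilde")$value  # 0.1387
phi_dm(net)$value                       # 0.1313

sim <- simulate_mvar(net, T_points = 3000, trials = 10, seed = 1)
phi_empirical(sim, tau = 1)             # per-trial mean/sd/cv
```
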