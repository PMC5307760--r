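---
title: "Combined model reduction for controlled biochemical networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined model reduction for controlled biochemical networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netreduce)
```

## The problem and the model class

Mechanistic models of signalling pathways are systems of stiff, nonlinear
ODEs in the species concentrations, often with tens to hundreds of states.
When only an input-output relationship matters - an extracellular ligand
level driving a downstream phosphorylation readout, a drug scaling a
binding rate and a clinical biomarker being observed - most of that state
is redundant. `netreduce` reduces such models while preserving that
relationship.

The working representation is the control-affine state space

$$\dot x = f(x) + \sum_{i=1}^{l} g_i(x)\,u_i(t), \qquad y = h(x),$$

with $x \in \mathbb{R}^n$ the concentrations, $u$ the declared inputs and
$y = h(x)$ the observed combination of species. Inputs enter in one of two
modes: *additive-rate* (the input feeds a species' balance directly, as a
supply flux) or *parameter-scale* (the input multiplies a named rate
constant; every rate law must then be affine in that constant, which is
checked symbolically and enforced - a model nonlinear in its input is
rejected rather than silently linearised). The reduced model keeps the same
form with $\tilde n < n$ states, and its quality is the maximal relative
output error

$$E = \sup_t \frac{\lvert y_i(t) - \bar y_i(t)\rvert}{\lvert y_i(t)\rvert}$$

under a declared perturbation protocol. Time points where
$\lvert y_i(t)\rvert < \delta \max_t \lvert y_i(t)\rvert$ (default
$\delta = 10^{-3}$) are masked: the metric as written divides by the
output, and outputs that start at or cross zero would otherwise make $E$
infinite for reasons that say nothing about reduction quality.

## The reduction chain

`run_combined_reduction()` chains four stages, each of which consumes and
produces a `controlled_system`, so the composition is itself a system that
can be simulated, differentiated and reduced further.

**Nondimensionalisation.** Fifty candidate scalings are sampled (a time
scale from the reciprocal of a sampled pseudo-first-order rate, one global
concentration scale from the pool of initial values and conserved totals);
each is scored by the order-of-magnitude spread
$\sigma = \log_{10}(\max\tilde p / \min\tilde p)$ of the resulting
dimensionless parameters and the minimiser is applied. One deliberate
design choice: the concentration scale is *shared by all species*. A
per-species scale looks more flexible, but a proper lump is a plain sum of
concentrations, and summing differently-scaled states turns it into a
weighted sum - during development this destroyed the lumpability of an
exactly proportional pair (error 0.25 instead of $3\times10^{-5}$ on the
phosphorelay fixture). With a common unit, every downstream step is
invariant and only floating-point conditioning changes.

**Conservation analysis.** Conserved moieties are the left null space of
the stoichiometry matrix, computed by Householder QR (base R's LAPACK
factorisation) with a relative rank tolerance of $10^{-9}$ on the diagonal
of $R$; the orthonormal basis is row-reduced and rescaled to
smallest-integer coefficients so relations read as moiety totals. One
species per relation is then replaced by its algebraic expression. Which
species matters: the algorithm ranks states slow-to-fast by the absolute
Jacobian diagonal at the unperturbed steady state (the outgoing rate of
concentration) and eliminates the *slowest*, keeping fast species - the
ones lumping needs - dynamically explicit. Relations are processed
most-constrained-first (fewest candidate species), and a candidate is
accepted only if the growing eliminated submatrix of $\Gamma$ stays
invertible; this is the tie rule when two relations share their slowest
species. Totals are stored as the map $\Gamma x_0$, not as frozen numbers,
so later perturbations of the initial condition update them automatically.

**Proper lumping (forward selection).** At each step every unordered pair
of current states is trialled with two generalised inverses - the
steady-state inverse $\bar L = X L^{\mathsf T}(L X L^{\mathsf T})^{-1}$,
$X = \mathrm{diag}(x^*)$, and the time-averaged inverse whose pair weights
are $\frac{1}{T}\int_0^T x_h/(x_h + x_k)\,dt$ - each candidate is
simulated under the protocol, and the (pair, inverse) with the smallest
$E$ is applied through the Galerkin projection
$\tilde f(\tilde x) = L f(\bar L \tilde x)$. Ties prefer the lower
resulting stiffness, then lexicographic pair order. The loop exits when
the best candidate would exceed the error budget, when the stiffness
coefficient $\chi$ (ratio of extreme Jacobian eigenvalue *moduli* at the
reference state, with moduli below $10^{-9}$ of the largest excluded so
exact conservation's zero modes don't make $\chi$ infinite) falls below
the critical value $\chi_c$, or at one state. The greedy assumption - the
best $k$-dimensional lump extends the best $(k{+}1)$-dimensional one - is
adopted without backtracking; the test suite re-verifies each greedy step
against brute-force enumeration on the fixtures. The Moore-Penrose
inverse (equal weights) is implemented and exposed but not trialled by
default: on every fixture it is at best as good as the better of the other
two, and the averaged inverse already covers the zero-steady-state case
that motivates it. $T$ for the averaged inverse defaults to the trajectory
horizon; with nonzero steady states it converges to the steady-state
inverse as $T$ grows.

**Empirical balanced truncation.** The controllability Gramian is
assembled from impulse-type perturbations: the state is kicked from $x^*$
along each input channel direction $g_i(x^*)$ with strengths sampled
uniformly (default $0.2$-$1.8\times$ the reference input magnitude), and
the $1/c^2$-weighted covariance of the state deviations is averaged over
magnitudes and channels by trapezoidal quadrature. The observability
Gramian perturbs each initial-condition component multiplicatively about
$x^*$ (additively, with a unit fallback scale, where a component's steady
state is exactly zero - a multiplicative perturbation of zero would never
excite that state), records the output responses and averages the
$1/(c_j c_k)$-weighted response inner products. Before every observability
simulation the conserved totals are recomputed from the perturbed
full-model initial condition through the system's `from_full` hook, so no
perturbation can violate conservation. This construction makes both
empirical Gramians converge to the Lyapunov-equation Gramians on stable
linear systems, which the test suite uses as the arbiter of correctness
(within 5 % elementwise after trace normalisation). Step-shaped input
perturbations were rejected for the controllability Gramian because the
deviation-from-$x^*$ covariance then diverges with the horizon for any
input that moves the equilibrium.

Balancing follows the square-root method: Cholesky factors of
$\mathcal P$ and $\mathcal Q$ (rank-revealing pivoted factorisation when a
Gramian is semi-definite, so a dead direction appears as a zero Hankel
value instead of being masked by a ridge), SVD of the factor product, and
the projection pair $T_1 = \Sigma_1^{-1/2} V_1^{\mathsf T} R$,
$S_1 = L^{\mathsf T} U_1 \Sigma_1^{-1/2}$, which renders both transformed
Gramians equal to $\mathrm{diag}(\Sigma_1)$. Truncation applies the same
Galerkin projection, with one important refinement: the projection acts on
*deviation variables centred on the unperturbed steady state*. The
Gramians are covariances of deviations about $x^*$, and centring makes
$x^*$ an exact fixed point of every truncated model; projecting absolute
states instead requires $x^*$ to lie in the retained subspace and produced
order-of-magnitude larger errors during development. Because Hankel
ordering does not guarantee monotone error for nonlinear systems, the
pipeline tries every reduced dimension from $\tilde n - 1$ downward and
keeps the smallest one meeting the budget. A truncated candidate whose
simulation blows up is recorded as infeasible, not an error - on stiff
systems this is the expected failure mode that the lumping preconditioner
exists to avoid, and if the Gramian stage itself fails the report returns
the best lumped model with a diagnostic.

**Importance indices.** From the Gramian diagonals,
$\nu_{o,i} = \sqrt{Q_{ii}}/\max_j\sqrt{Q_{jj}}$,
$\nu_{c,i} = \sqrt{P_{ii}}/\max_j\sqrt{P_{jj}}$ and the input-output index
$\nu_i = \nu_{o,i}\nu_{c,i}/\max_j(\nu_{o,j}\nu_{c,j})$ quantify, per
state (or lump), how strongly the input reaches it and how strongly it
shapes the output; a zero means the state is irrelevant to the
input-output map.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `max_error` | 0.05 | error budget for the returned model (fraction of output, dimensionless); exits are inclusive at the boundary |
| `chi_c` | 250 | critical stiffness ending the lumping stage (dimensionless eigenvalue ratio) |
| `n_nondim_candidates` | 50 | sampled nondimensionalisations |
| `delta` (error guard) | 1e-3 | relative output floor below which time points are masked |
| `rank_tol` | 1e-9 | relative QR tolerance for the conservation rank decision |
| design `n_sims` | 10 | sampled perturbation magnitudes per Gramian direction |
| design `range` | 0.2-1.8 | uniform multiplier range on the unperturbed value |
| design `horizon` | auto | Gramian quadrature horizon; by default the time for the slowest stable mode at $x^*$ to decay to $10^{-4}$ |
| solver `rtol`, `atol` | 1e-8, 1e-10 | lsoda tolerances (stiff-capable, analytic Jacobian supplied) |

The defaults for `max_error` and `chi_c` reflect the regime the method is
intended for: a 5 % output error is below the reproducibility of most
concentration measurements, and $\chi \lesssim 250$ is where repeated
perturbed simulation stops being fragile in practice.

The error protocol starts each model at its *own* unperturbed steady state
before applying the input step (`from_steady_state = TRUE`). This is the
adapted-state experiment the method targets; it also means the metric
measures the input response rather than the relaxation of an arbitrary
initial condition, part of which is deliberately discarded by truncation.
Set `from_steady_state = FALSE` to score transients from a declared
initial state instead.

## What the synthetic fixtures emulate - and what they do not

`make_lti()` generates stable linear systems with exact Lyapunov Gramians
and Hankel values attached; these are oracles, not biology. They certify
the Gramian estimator and the balancing algebra, and the classical bound
$\lVert y - \tilde y\rVert_2 \le 2\,(\sigma_{r+1}+\dots+\sigma_n)\,
\lVert u\rVert_2$ is asserted on them with finite-energy inputs.

`make_conserved_network()` assembles closed mass-action networks from
reversible-conversion chains coupled by cross-group catalysis, with a left
null space of exactly the requested dimension; it exercises conservation
detection and elimination.

`make_phosphorelay()` is the study condition for the full pipeline: a
ligand-controlled kinase A autophosphorylates (the input scales `k_auto`),
transfers phosphate to a response regulator through a transient complex,
and the phosphorylated regulator exchanges rapidly between two
conformations (Yp, Yq) before dephosphorylation. The exchange runs
`stiff_ratio` times faster than the slow block (default base rates 0.3-10
per time unit, the range typical of signalling steps), the two protein
totals are conserved, and the output is total phosphorylated regulator.
At the default design point (`stiff_ratio = 1000`) the stiffness
coefficient at the initial condition is a few thousand, the exchange pair
is the brute-force optimal first lump, and one lump strips essentially all
stiffness. Below `stiff_ratio` of order ten the extreme eigenvalue comes
from the binding block rather than the exchange, so $\chi$ only grows
cleanly with the ratio once the exchange dominates.

What passing on these fixtures does **not** show: performance on models
with hundreds of states (combinatorics of pairwise search grow
quadratically per step), rate laws far from mass action (Hill or
Michaelis-Menten kinetics are supported symbolically but not stressed),
multi-input/multi-output interaction, or parameter uncertainty - the
reduced model is only guaranteed locally to the given parameterisation.

## Numerical choices and degenerate inputs

* Steady states: long integration in expanding windows, then damped
  Newton with the analytic Jacobian; the Newton polish only engages once
  integration has closed in (residual below $10^{-2}$ of scale), so a
  limit-cycle trajectory raises a non-convergence error instead of being
  silently projected onto an unstable root.
* Trajectory comparison: the candidate is resampled onto the reference
  grid by monotone (Fritsch-Carlson) cubic interpolation.
* A lumped block whose steady state is entirely zero makes the
  steady-state inverse singular; this is a classed error, and the averaged
  inverse (quadrature guarded against a vanishing pair total) covers the
  case.
* Simulation blow-ups carry the failure time and are treated as
  infeasibility signals throughout the search stages.
* Problem sizes in the shipped tests (4-7 state fixtures, 10-state
  Gramian designs, 1.5k-point quadrature grids) were chosen so every
  oracle comparison is tight at its stated tolerance while the whole
  suite stays interactive.

## Known limitations

Improper (overlapping) lumping, nonlinear lumping maps, cross-Gramian or
frequency-weighted balancing, unstable systems, SBML events / rules /
delays, and reductions guaranteed over a parameter *region* (rather than a
point) are out of scope. The importance indices inherit the
interpretability of the lumping that preconditioned them: a lump mixing
unrelated species yields an index that is hard to read biologically.
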