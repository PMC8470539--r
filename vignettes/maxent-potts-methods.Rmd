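---
title: "Maximum-entropy Potts models on networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy Potts models on networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pottsmaxent)
```

## The model

`pottsmaxent` infers the least-biased probability distribution over the
configurations of a network whose nodes take one of $Q$ discrete states,
subject to reproducing two families of training observables:

* the per-state densities $s_i(\sigma) = \frac{1}{N}\sum_k
  \delta_{\sigma_k, i}$, and
* the near-neighbour couple densities $c_{ij}(\sigma) =
  \frac{1}{L}\sum_{(h,k)\in E}\delta_{\{\sigma_h,\sigma_k\},\{i,j\}}$,
  where $E$ is the edge set and $L = |E|$; each *unordered* edge is counted
  once, and the symmetric matrix $c$ carries the shared unordered density at
  $(i,j)$ and $(j,i)$.

By the maximum-entropy principle the solution is a Boltzmann distribution
over a Potts (multi-state Ising) Hamiltonian with one field per state and
one symmetric coupling matrix per edge class,

$$ P(\sigma) = \frac{e^{-E(\sigma)}}{Z}, \qquad
   E(\sigma) = \sum_k h_{\sigma_k} + \sum_{(h,k)\in E} J_{\sigma_h \sigma_k}. $$

In density units this is $H = \sum_i h_i s_i + \sum_{i\le j} J_{ij} c_{ij}$
up to the $N$ and $L$ normalisations.  Positive $J_{ij}$ is repulsion
between states $i$ and $j$; negative is attraction.

### Why the Boltzmann exponent is extensive

The per-configuration exponent could be read either in density units
("intensive", $e^{-H}$ with $H$ as above) or in count units ("extensive",
as implemented).  The two differ only by a reparameterisation of $(h, J)$,
but one reading has to be fixed for parameter files to be meaningful, and
only the extensive reading is self-consistent with the other two anchors of
the method:

* the non-interacting initialisation $h_i = -\log\langle s_i\rangle$,
  $J = 0$ must *reproduce the target densities*.  Under the extensive
  exponent it is exactly the product distribution with marginals
  $\langle s_i\rangle$ on every node; under an intensive exponent its
  marginals would be $\propto \langle s_i\rangle^{1/N}$, which is wrong for
  every $N > 1$;
* the thermodynamic-integration entropy (below) anchors its boundary term
  on the Shannon–Fano entropy of that starting distribution, which again
  holds only for the extensive reading.

Every parameter file therefore records
`"energy_scale": "extensive"` alongside
`"pair_counting": "unordered"`.  `potts_energy()` evaluates both scales.

## Gauge freedom

The observables obey exact linear constraints ($\sum_i s_i = 1$,
$\sum_{i\le j} c_{ij} = 1$, and degree-regularity relations on regular
graphs), so some parameter directions cannot change the distribution — e.g.
shifting every $h_i$ by a constant.  The package handles this the way the
observables themselves dictate: the covariance matrix $\Sigma$ of the flat
observable vector over the training set is diagonalised, eigendirections
below a relative cutoff ($10^{-8}$ by default, with an absolute floor of
$10^{-14}$ for numerically-zero spectra) are flagged as the kernel, and the
$\chi^2$ metric uses the pseudo-inverse restricted to the informative
subspace.  The number of informative directions is the number of degrees of
freedom used in the convergence test.

For comparisons in *parameter* space (e.g. recovery tests) the projector is
built instead from the count-scaled covariance $D\Sigma D$ (with $D$ the
vector of count normalisations), whose kernel coincides exactly with the
gauge directions of the extensive energy.

## Training

Training minimises the gauge-projected
$\chi^2 = (x - x^{h,J})^{\top} \Sigma^{+} (x - x^{h,J})$ between the target
observables $x$ and the model averages $x^{h,J}$:

1. start from the non-interacting solution;
2. draw an equilibrium ensemble by single-site Metropolis at the current
   ("anchor") parameters;
3. take Polak–Ribière conjugate-gradient steps (restarted every `dof`
   iterations) with an Armijo backtracking line search that starts from the
   Gauss–Newton step along the search direction — the curvature comes for
   free from the same reweighted observable covariance as the gradient, and
   a well-scaled first trial is what keeps the step count in the tens
   rather than the hundreds — evaluating $\chi^2$ and its analytic gradient
   on the anchor ensemble via importance reweighting
   $\rho_i \propto e^{-E_{\text{new}}(\sigma_i) + E_{\text{anchor}}(\sigma_i)}$;
   the gradient uses the Boltzmann-family identity
   $\partial \langle x_a\rangle / \partial \theta_b = -\mathrm{Cov}_\rho(x_a, y_b)$
   with $y = Dx$ the count observables, and is verified against finite
   differences in the test suite;
4. when the effective-sample-size ratio
   $(\sum_i \rho_i)^2 / (N_{\text{conf}} \sum_i \rho_i^2)$ falls below the
   threshold $\eta$ (default $0.5$), refresh the ensemble with a new
   Metropolis run;
5. stop when $\chi^2$ per degree of freedom falls below the threshold
   (default $1$): the model then reproduces the training observables within
   their stochastic accuracy.

The $\chi^2$ metric uses the covariance *of the target estimate* — the
per-configuration sample covariance divided by the training-set size — so
"converged" means "within the error bars of the training means".

Three safeguards around importance reweighting are worth stating because
they are easy to get wrong:

* **Trust-region line search.**  A trial step must keep the ESS ratio of
  its own weights above $\eta/2$; steps that collapse the weights are
  shortened rather than trusted, because both the reweighted $\chi^2$ and
  the recorded path observables would otherwise be computed from a few
  effective samples.
* **Bounded excursions.**  At most `max_cg_per_refresh` (default 20) CG
  steps are taken from one anchor ensemble even at high ESS.  The ESS ratio
  measures weight variance *on the sampled configurations*; it cannot
  detect configurations the anchor never sampled.  A long excursion can
  therefore look healthy while the true model drifts into a region the
  anchor cannot represent (rare strongly-coupled pairs are the typical
  failure).
* **Fresh-ensemble convergence.**  Convergence is only declared when
  $\chi^2/\text{dof}$ is below threshold on a freshly sampled ensemble with
  uniform weights, never on a reweighted one.
* **Data-seeded chains.**  When a training ensemble is available, each
  Metropolis refresh starts from one of its configurations.  At strong
  couplings a randomly initialised chain quenches into frozen defects it
  cannot anneal away; the model observables then miss the target no matter
  how far the couplings grow, and the optimisation runs away.  Starting in
  the data mode removes the quench, and at moderate couplings the burn-in
  re-equilibrates the chain regardless.

### Small training sets

The method is usable down to a single training sequence, but then the
training-set covariance is undefined.  With fewer than `min_cov_conf`
(default 10) configurations, $\Sigma$ is estimated from a model ensemble
sampled at the non-interacting start and divided by the training count, and
it is re-estimated at every Metropolis refresh so that the metric reflects
the stochastic accuracy *under the model* as the model approaches the data.
Without the re-estimation, observables whose target value sits at the
boundary (e.g. a flip density of exactly 0 in a frozen trajectory) keep the
inflated variance of the initial guess and the fit stops far too early.

States with target density exactly zero are excluded from the optimisation
and their field is pinned at a large finite value (default 30, i.e.
probability $\sim e^{-30}$), keeping all arithmetic finite.

## Entropy by thermodynamic integration

Using $d\log Z / d\theta_a = -\langle y_a \rangle$, the entropy of the
fitted model follows from the recorded training path $\theta(\xi)$ with no
extra sampling:

$$ S = S_{\text{SF}} + \langle E\rangle_{\text{final}}
     - \langle E\rangle_{\text{initial}}
     - \int_0^1 \langle y\rangle_{\theta(\xi)} \cdot
       \frac{d\theta}{d\xi}\, d\xi, $$

where $S_{\text{SF}} = -N \sum_i \langle s_i\rangle \log\langle s_i\rangle$
is the Shannon–Fano (mean-field) entropy of the non-interacting start.  The
line integral is discretised by the trapezoidal rule over consecutive path
snapshots (one per accepted CG step, each storing the reweighted model
observables); the integrand is written against the *parameter increments*,
which is the unique reading that reproduces $S = \langle E\rangle + \log Z$
for Boltzmann distributions — verified in the tests against exact
enumeration, where a 20-step straight-line path reproduces
$-\sum_\sigma P\log P$ to better than $10^{-3}$ on two-node systems.
Snapshots are recorded at every accepted step rather than only at
refreshes; recording only refresh points would bias the integral whenever
several steps are taken between refreshes.

The estimate is variational: $S_{\text{exact}} \le S_{\text{MaxEnt}} \le
S_{\text{SF}}$, with strict inequality on the right whenever the fitted
couplings are nonzero.  Reports always include per-site values and values
normalised by $\log Q$, the units in which lattice-model entropies are
usually quoted.  The `entropy_bounds()` helper checks the ordering against
exact enumeration wherever the state space allows it.

Two estimators are provided, because accuracy on a *recorded* path is
limited by the quality of its snapshots:

* `path_entropy(fit)` integrates along the recorded training path at no
  extra sampling cost.  Accepted steps are recorded at quarter-step
  resolution so the trapezoidal rule stays fine even for well-scaled
  steps, and at every Metropolis refresh the previous segment's snapshots
  are re-estimated from the fresh ensemble and combined with the forward
  estimates by inverse-MSE (squared-ESS) weights — the fresh ensemble has
  support exactly where the old anchor's reweighting fails.  The residual
  error tracks the optimiser's trajectory: if the fit detours through a
  slowly-mixing parameter region, that bias is inherited.
* `ti_entropy(params, target_s, topology)` is the refined estimator:
  entropy is path-independent, so it integrates along the straight line
  from the non-interacting solution to the fitted parameters, with a fresh
  Metropolis run per integration point and chains annealed from point to
  point (each chain starts where the previous one ended, staying in the
  adiabatically connected basin).  On enumerable systems it agrees with
  $-\sum P\log P$ to a few $10^{-3}$ per site at 20 steps.

## Dynamical extension

A time sequence $\{\sigma\}_t$ on a base network is one configuration on a
time-extended network: one copy of the base graph per frame (edge class
`spatial`, couplings tied across frames — stationarity) plus `temporal`
edges joining each node to its own copy at the next timestep.  The temporal
couple densities are the self-time correlations; their off-diagonal mass is
the probability of a node changing state between consecutive frames.  The
full $Q \times Q$ temporal matrix is constrained (the scalar flip
probability is its off-diagonal marginal); constraining only
time-independent observables reduces to the static fit on pooled frames,
which the test suite checks.  The dynamical entropy is the static estimator
on the extended network, reported per base-node per timestep.

Longer temporal memory (lags above 1) and cross-node time-lagged couplings
are out of scope.

## Fixture generators and what they do (and do not) emulate

* **Exact-Potts generator** — i.i.d. draws from the enumerated Boltzmann
  table (or thinned Metropolis for larger systems).  Ground truth for
  parameter-recovery and oracle tests.
* **Hopfield network** — $J = (1-\epsilon/2) S + (\epsilon/2) A$ with
  uniform $[-1,1]$ off-diagonal entries, zero diagonal, synchronous sign
  threshold updates and a fair-coin tie rule; dilution removes unordered
  pairs with probability $d$, so $d = 0$ is fully connected.  (The removal
  probability reading is adopted; an average link count of $dN(N-1)/2$
  would contradict "fully connected" at $d \to 0$.)  Trajectories are
  mapped $-1 \to 0$, $+1 \to 1$ for fitting.  The entropy scan
  (`hopfield_entropy_scan()`) fits each single-neuron trajectory
  separately, 200 recorded frames after a 100-step transient, and averages
  the normalised dynamical entropy over neurons and realizations; the mean
  rises abruptly along the asymmetry axis as the dynamics turns chaotic.
* **Predator–prey lattice** — a Wa-Tor-class rule set (random agent order;
  probabilistic prey movement and breeding; predators eat adjacent prey,
  move with the mobility probability `p_shark_move`, breed into vacated
  sites and starve after a fixed horizon).  The default parameters are a
  coexistence regime chosen so that a $40 \times 40$ run fluctuates around
  stable densities (predator-prey cycles of roughly 60 steps); absorbing
  outcomes (prey saturation, extinction) are flagged, never returned as
  steady states.  The rule set is this package's own design: it reproduces
  the qualitative phenomenology (steady state, absorbing states, a
  predator-mobility knob), not any particular published parameterisation.
* **Synthetic tissue images** — a ground-truth state grid drawn from a
  known Potts model on an open-boundary grid, rendered as coloured cell
  blocks with optional Gaussian pixel noise.  The default four classes are
  background (black), green, red and blue.  A first-order mean-field
  correction $h \leftarrow h - \bar{d}\, J \rho$ keeps realised class
  densities near their nominal values in the presence of couplings; without
  it, attractive classes inflate (and past the ordering transition a single
  class can swallow the lattice).  What the generator does *not* emulate:
  microscope point-spread, per-cell segmentation error, class-dependent
  brightness, or spatially varying illumination.  Passing tests on this
  generator therefore demonstrate the inference machinery, not robustness
  to real staining artefacts.

## Missing-state inference

Hidden-marker prediction clamps every cell whose observed state is visible,
frees the cells whose observed state is hidden or background, restricts the
free alphabet to hidden-plus-background (the published protocol; an
unrestricted mode exists behind a flag) and reads per-cell marginals off
the clamped Metropolis ensemble (default 1000 stored configurations).  When
ground truth is available the summary score is the mean predicted
probability at the true hidden locations, compared with the hidden base
rate among free cells.  Two properties of this score are worth knowing:
it is a *calibration-sensitive* comparison — a single truth draw whose
hidden-class count fluctuates above the conditional expectation can sit
above the mean predicted probability even when the spatial ranking is good
— and its discrimination power comes mostly from couplings between the
hidden class and *visible* classes, which survive conditioning, rather than
from self-clustering of the hidden class, which is largely exchangeable
across the free region.  The synthetic-tissue conditions used in the tests
reflect this: mild blue self-attraction, strong blue-green attraction,
moderate blue-background repulsion, and a background-red attraction that
anchors the background to a visible class as well — so a free cell's
identity is voted on by visible neighbours from both sides, which both
sharpens the per-cell marginals and stabilises the hidden-class count.

## Numerical choices and conventions

* Flat observable/parameter layout: the $Q$ state densities, then the
  upper triangle (including diagonal, row-major) of each edge class's
  couple matrix.  Frozen and recorded in every serialized file.
* Node indexing is 0-based everywhere, including files; lattice nodes are
  flattened row-major.  Built lattices default to periodic boundaries;
  image grids are open (an image has borders).
* Disconnected topologies are accepted with a warning — nothing in the
  model requires connectivity.
* Metropolis defaults: 1000 burn-in sweeps, stride 10, 1000 kept
  configurations; one sweep is one proposal per free node; proposals are
  uniform over the other allowed states; runs are bit-reproducible given a
  seed.  The per-neuron chain fits inside the Hopfield scan use lighter
  settings (800 kept, burn-in 200, stride 2) sized to those
  single-node-chain problems.
* Enumeration is capped at $10^6$ states by default and refuses larger
  systems with a pointer to the sampler.
* Degenerate training sets (every observable constant, e.g. a frozen
  trajectory) short-circuit: the non-interacting start is returned as
  converged with zero informative degrees of freedom and
  $S = S_{\text{SF}}$.

## Problem sizes used in the shipped checks

The test suite validates every oracle-checkable claim on systems with
$Q^N \le 4096$ (exact enumeration), uses 500-draw training sets for
recovery experiments, $10^5$ kept samples for sampler-versus-enumeration
distances, a 6-point asymmetry grid with 2–3 network realizations for the
Hopfield scan, and 20 seeds of $20\times20$ synthetic tissue for the
inference-beats-chance check.  These sizes were chosen so each check is
decisive at desk scale; all of them scale up by changing the corresponding
arguments.

## Known limitations

* Single-site Metropolis mixes slowly across strong-coupling barriers;
  cluster updates are not implemented.  Oracle-equivalence checks use
  moderate couplings for this reason, and strongly ordered systems should
  be sampled with longer strides.
* The entropy of a fitted path inherits Monte Carlo noise; on enumerable
  systems it agrees with the exact entropy to $\sim 10^{-2}$ per site, but
  the variational ordering can be violated within that noise.
* With a single training sequence the fitted model reproduces boundary
  observables (exact zeros) only to the $1/T$ stochastic accuracy, so
  "deterministic" trajectories fit to near- rather than exactly-zero
  entropy.
* Pseudolikelihood or mean-field inversion shortcuts, regularisation, and
  weighted or directed graphs are out of scope.
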