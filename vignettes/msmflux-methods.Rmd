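---
title: "Markov state models and reactive flux decomposition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov state models and reactive flux decomposition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmflux)
```

# The model

A Markov state model describes a molecular trajectory as a memoryless
jump process on a discrete set of conformational microstates. Given a
lag time $\tau$, the transition matrix $T(\tau)$ collects the
conditional probabilities $T_{ij} = P(x_{t+\tau} = j \mid x_t = i)$;
its leading left eigenvector is the stationary (Boltzmann) weight
$\rho$, and the sub-dominant eigenvalues $\lambda_i$ define the
implied relaxation timescales $t_i = -\tau / \ln \lambda_i$. The
central assumption is that at the chosen lag the discretized dynamics
is Markovian: the model is only as good as (a) the discretization's
ability to resolve the slow degrees of freedom and (b) the lag's
position past the Markov time. Both are testable, and the package
tests both (implied-timescale convergence and the Chapman–Kolmogorov
test).

Transition-path theory then asks how reactive trajectories flow from
a source set $A$ to a sink set $B$. The forward committor solves

$$q^+_i = \sum_{j \in B} T_{ij} + \sum_{j \notin A \cup B} T_{ij}\, q^+_j,
\qquad q^+|_A = 0,\; q^+|_B = 1,$$

a linear system solved directly (LU); under detailed balance the
backward committor is $q^- = 1 - q^+$, which is why the reversible
estimator is the default. The reactive (effective) flux
$f_{ij} = \rho_i q^-_i T_{ij} q^+_j$ and net flux
$f^+_{ij} = \max(f_{ij} - f_{ji}, 0)$ form a conservative flow whose
total equals both the net flux out of $A$ and into $B$; the package
asserts this identity to $10^{-10}$ relative.

# Pipeline stages and their tunables

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| frame spacing `dt` | 0.1 | ns | typical stride of a production MD campaign |
| TICA / MSM lag | 10 | frames (1 ns) | smallest lag at which implied timescales flatten in the target application; one shared lag keeps the kinetic embedding and the model consistent |
| TICA retained dim (`estimate_tica`) | 95% kinetic variance | — | keeps components in proportion to their squared autocorrelation |
| TICA retained dim (pipeline preset) | 10 | components | on sin/cos-embedded dihedral data the kinetic-variance rule retains hundreds of noise components whose $\lambda^2$ add up; a fixed small count comfortably above the number of sought macrostates keeps clustering sharp and fast |
| k-means k | 10 | clusters | documented preset for the bromodomain-like pipeline; `k_grid` switches on VAMP-2 selection |
| k-means restarts | 10 | — | best-of-restarts guards against local optima |
| VAMP-2 components | 5 | singular values | one per targeted macrostate; scores then plateau once the discretization resolves the planted processes |
| MSM estimator | reversible | — | detailed balance gives a real spectrum (required by PCCA+) and the committor complement relation |
| CK test `k_max` | 5 | multiples of τ | deviations grow monotonically with k; 5 spans half a decade |
| CK pass rule | max relative deviation ≤ 5% on entries with propagated probability ≥ 0.01 | — | "both sides close" read as an entrywise bound; tiny entries are excluded because their relative error is sampling-dominated |
| PCCA+ m | 5 | macrostates | matches the five conformational classes the pipeline targets |
| endpoint window | 100 | frames | the source/sink are the modal macrostates of the first/last window across trajectories |
| pathway stop | residual < 0.1% of total | — | the tail of the decomposition carries no interpretable flux |

# Numerical choices

* **TICA.** Covariances are estimated over all within-trajectory
  lagged pairs; the mean is taken over both pair ends, $C_\tau$ is
  symmetrized ($ (C + C^\top)/2 $), and the generalized eigenproblem
  is solved by whitening on the numerically nonzero subspace of
  $C_0$ (relative eigenvalue threshold $10^{-12}$) plus a ridge
  $\varepsilon \cdot \mathrm{tr}(C_0)/d$ with
  $\varepsilon = 10^{-8}$. The ridge exists for nearly collinear
  features (sin/cos pairs of narrowly distributed angles); lagged
  pairs never straddle trajectory boundaries because runs are
  independent.
* **k-means.** k-means++ seeding, Lloyd iterations (`stats::kmeans`,
  300 iterations max); an empty cluster triggers one logged
  re-seeding of the restart. Assignment ties go to the lowest center
  index so labeling is deterministic.
* **Reversible estimation.** Fixed-point iteration on symmetric edge
  weights, converged when $\max |\Delta T| < 10^{-10}$, error after
  $10^6$ iterations. Row-normalization is used for the
  non-reversible variant, with the stationary vector from the leading
  left eigenvector.
* **PCCA+.** Right eigenvectors are obtained through the symmetric
  conjugate $D^{1/2} T D^{-1/2}$ (real spectrum guaranteed); the
  inner-simplex vertex search picks the row farthest from the
  centroid and then successively the row farthest from the affine
  span of the chosen vertices; memberships are the linear map onto
  those vertices, with small negative entries clipped to zero and
  rows renormalized. A substantial infeasibility (entries below
  −0.2) raises a warning, an empty crisp macrostate an error.
* **Pathways.** Iterated widest-path extraction: a Dijkstra variant
  maximizes the bottleneck edge, with ties broken toward the
  lexicographically smallest path so decompositions are
  reproducible; the bottleneck edge is zeroed exactly at each
  subtraction, so the loop terminates after at most one iteration
  per edge.
* **Degenerate inputs.** Constant features, lags longer than the
  shortest trajectory, non-stochastic matrices, disconnected count
  graphs, trapped committor states and empty selections all raise
  errors that name the offending row, state, model or residue.

# The synthetic generators

The package is validated entirely on data with known ground truth:

* `sample_markov_chain()` draws exact realizations of a given
  transition matrix (inverse-CDF per row), so count-matrix,
  transition-matrix, timescale, committor and CK estimators can be
  compared with closed forms.
* `make_metastable_chain()` builds a reversible block chain from
  symmetric edge weights (self-weight 1, intra-block scale
  `p_intra = 0.4`, inter-block scale `p_inter = 0.01` by default):
  detailed balance holds by construction and the slowest
  $n_\mathrm{blocks} - 1$ processes are separated by a spectral gap,
  giving PCCA+ an exactly recoverable target.
* `simulate_langevin()` integrates overdamped Euler–Maruyama
  dynamics, $x_{t+1} = x_t - \nabla V \, \Delta t / \gamma +
  \sqrt{2 k_B T \Delta t / \gamma}\, \xi$, on harmonic and
  double-well potentials — the simplest scheme whose invariant
  density error is $O(\Delta t)$ and whose equilibrium statistics
  (equipartition variance, symmetric well occupancy, committor 1/2
  at the barrier) are known.
* `emulate_dihedral_dataset()` emulates the shape of a real
  dihedral-featurized simulation campaign: by default 10
  trajectories × 5000 frames × 139 angular features at 0.1 ns
  spacing, driven by a hidden 5-state metastable chain with mean
  dwell ≈ 200 frames (`p_hop = 0.005`) and wrapped-Gaussian
  emissions (σ = 25°) around distinct per-state mean angle vectors,
  wrapped to (−180°, 180°]. Trajectories start in a designated state
  and can be conditioned (by redraw) to end in another, so endpoint
  auto-detection has a planted answer. The 139-dimensional feature
  count is treated as a free parameter: how a particular published
  count arises from a given protein's residues is a featurization
  recipe the user supplies, not something the emulator guesses.

What the generator does *not* emulate: anharmonic within-state
structure, state-dependent noise, slow drifts, and the
rugged free-energy landscape of a real protein. Passing tests
therefore demonstrate the correctness of the estimators and the
pipeline plumbing, not that any particular protein's kinetics is
Markovian at 1 ns.

# Design choices at genuinely open points

* **Angles vs embedded pairs.** Whether published dihedral feature
  matrices hold raw angles or sin/cos pairs is often unstated; both
  paths are supported and the pipeline embeds by default (the
  covariance-based TICA stage requires seam-free features).
* **TICA lag and dimension.** With no published TICA-specific lag,
  the MSM lag is reused; the retained dimension is a preset (see the
  table above), not an inference about any published recipe.
* **k selection.** The "simplified elbow" idea is realized as a grid
  search scored by cross-validated VAMP-2 with a one-standard-error
  tie-break toward smaller k; splits are over whole trajectories
  because frames are autocorrelated.
* **CK criterion.** "Close" is read as ≤ 5% maximum relative
  deviation on well-populated entries; an aggregate-norm reading
  would be laxer.
* **TPT route.** Committors and fluxes are computed on the
  microstates and then aggregated onto macrostates (net flux summed
  across boundaries and re-antisymmetrized); computing TPT directly
  on a coarse-grained macrostate matrix is also possible through the
  same functions, and both conserve the total flux.
* **Macrostate order.** SA and SB are fixed by endpoint detection;
  the remaining states are numbered S1, S2, … by decreasing
  stationary weight — a labeling convention only.
* **Percentage denominators.** When reproducing published tables the
  percentage denominator is the printed (possibly rounded) total,
  because published percentages are computed against it; otherwise
  the exact sum of decomposed path fluxes is used.
* **Flux units.** Fluxes are reported per lag step by default; the
  per-second conversion through the physical lag time is opt-in
  (`flux_table(per_second = TRUE)`) since published unit labels
  cannot always be reconstructed from the totals.

# Problem sizes

The test suite exercises chains of $10^5$–$5 \times 10^5$ steps,
Langevin runs up to $10^6$ steps, and the full-size synthetic dataset
(10 × 5000 × 139); these sizes put sampling error comfortably below
the asserted tolerances (e.g. transition-probability entries to
±0.01, timescales to ±5%) while the whole suite stays fast enough to
run routinely.

# Known limitations

* No Bayesian posterior sampling of transition matrices, no hidden
  Markov models, no Koopman reweighting, no fuzzy-membership flux
  propagation (crisp sets feed TPT).
* The Chapman–Kolmogorov test on crisply coarse-grained macrostates
  of a projected process typically shows larger deviations than the
  microstate model itself (projection and recrossing error); the
  package reports the deviation rather than hiding it, and small
  synthetic systems routinely exceed the 5% rule at short lags.
* `read_multi_model_pdb()` handles the fixed-column PDB format only;
  binary MD formats (DCD/XTC/NetCDF) are out of scope for the core
  and should be converted upstream.
* SASA radii come from a small built-in element table and loop
  selections are user configuration; observable outputs are
  qualitative comparators, not calibrated against any particular
  force field.
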