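---
title: "Dating deep protein paralogs with photoclock: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating deep protein paralogs with photoclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoclock)
```

## The problem

Type II photosynthetic reaction centers carry two families of core
proteins: the oxygenic pair D1/D2 of Photosystem II and the anoxygenic
pair L/M. All four descend from one ancestral protein, so the tree of
these sequences contains ancient gene-duplication nodes — most importantly
`D0`, the D1/D2 duplication — whose ages bear directly on when oxygenic
photosynthesis arose. Two quantities summarize the analysis:

* **ΔT**, the span between the posterior mean age of `D0` and that of the
  ancestral *standard* D1 (the last common ancestor of the G3/G4 forms
  that carry a complete Mn-cluster ligand set). A large ΔT means the
  evolutionary trajectory toward standard Photosystem II occupied a long
  stretch of the Archean.
* **ν(t)**, the per-node rate of evolution in amino-acid substitutions
  per site per Ga. The data force fast early rates (ν_max at `D0`) that
  decay toward the very slow Proterozoic baseline (ν_min, the average
  over Group-4 D1 and D2 nodes).

photoclock implements the full chain of computation behind these
quantities — likelihood, priors, sampler, and derived statistics — plus
forward simulators so every stage can be validated on data with known
truth.

## Model

### Substitution process

Sequences evolve by a reversible 20-state Markov process with rate matrix
$q_{ij} = S_{ij}\pi_j$, normalized to one expected substitution per site
per unit branch length. The Poisson model sets all exchangeabilities
$S_{ij}$ equal and $\pi_i = 1/20$; the LG model uses the published
empirical exchangeabilities and frequencies; any matrix in the standard
PAML layout (190 lower-triangle values then 20 frequencies) can be
supplied as a file. Among-site rate variation is discrete-gamma:
`nCategories` equal-probability categories (4 by default, the
conventional choice) whose rates are the category means of
$\Gamma(\alpha,\alpha)$; mean- rather than median-based discretization is
used because the category means average exactly to one. Gaps and `X` are
treated as missing data — the likelihood sums over all states at those
tip positions. The richer site-heterogeneous mixture models used in parts
of the original analyses (CAT) are deliberately out of scope; the
empirical-matrix route reproduces the LG-based results only.

The likelihood is Felsenstein pruning over site patterns (identical
columns collapsed with weights), computed in C++ with per-node scaling,
so alignments of at least 1,000 sites by 100 tips evaluate without
underflow. Branch lengths in expected substitutions are
$\bar r \,(t_\text{parent} - t_\text{child})$ with $\bar r$ the
arithmetic mean of the endpoint node rates (the Kishino–Thorne
convention, which makes the *node* rate the primary object, as in the
rate-versus-time figures); the uncorrelated clock instead uses the child
node's own rate as the branch rate.

### Time prior

Node ages are measured in Ga before present; all tips are contemporaneous
at age 0, and non-ultrametric input is rejected rather than silently
re-rooted. The root age has a normal prior (mean and sd in Ga, truncated
to positive ages and renormalized). Fossil calibrations anchor the MRCA
of named tip sets:

* **hard** bounds are uniform inside and impossible outside;
* **soft** bounds place a stated probability mass outside each limit —
  2.5% per two-sided boundary and 5% for a single minimum — via a uniform
  core, a power-shaped lower tail $\propto t^\theta$ matched for
  continuity at the minimum, and an exponential upper tail matched at the
  maximum. Each density integrates to exactly 1, which the tests verify
  by quadrature. A minimum-only calibration needs an upper core limit;
  inside the joint prior this is taken as the root-prior mean plus five
  standard deviations.

Uncalibrated internal ages are uniform given the ordering constraints and
the root age. This contributes a $-m\log t_\text{root}$ volume term ($m$
free internal nodes); the choice is a standard dating default — the
original analysis names no between-calibration time prior — and is the
main switchable assumption a user should be aware of.

### Rate prior (relaxed clocks)

Two rate processes are implemented:

* **Autocorrelated log-normal** (`acln`): for a child node $j$ with
  parent $p$,
  $\log r_j \sim N(\log r_p - \sigma^2\Delta t/2,\ \sigma^2\Delta t)$.
  The half-variance term keeps $E[r_j] = r_p$, so the process is a
  martingale in the rate itself; it is exactly consistent under edge
  subdivision (verified by Monte Carlo in the tests). $\sigma^2$ has
  units of 1/Ga.
* **Uncorrelated gamma** (`ugam`): branch rates are i.i.d. gamma with
  mean equal to a global rate and a free shape.

$\sigma^2$ (or the gamma shape), the site-rate shape $\alpha$, and the
root/global rate carry broad proper log-normal hyperpriors with unit
standard deviation on the log scale, centred on the values in the
`ClockModel`/`SubstitutionModel` objects (defaults: $\sigma^2$ 0.1/Ga, a
mid-scale root rate of 0.5 subs/site/Ga between the Proterozoic baseline
~0.12 and the inferred early peak ~5, and $\alpha$ 1). The original
publication states none of these hyperpriors; broad proper choices are
required for a proper posterior and their influence is what the
root-prior and sd scans are designed to expose.

## Sampler

`runChain()` is a Metropolis–Hastings sampler over internal-node ages,
node rates and hyperparameters. Moves per sweep: a uniform
independence window on each internal age over its admissible interval
`[max child age, parent age]`; a root-age multiplier; a multiplier per
node rate; multipliers for $\sigma^2$/shape (several per sweep — they
cost no likelihood evaluation), the global rate, and $\alpha$ (one per
sweep — it forces a full likelihood recomputation); and a compensating
move that shifts an internal age while rescaling its rate to preserve
the parent-edge expected length (Jacobian included in the acceptance
ratio). Multiplier scales auto-tune toward 20–45% acceptance during
burn-in (default 25% of iterations) and are frozen afterwards. The
likelihood engine caches per-edge messages and recomputes only the path
from a touched edge to the root, with double-buffered state so
reject/accept never copies.

Every source of randomness flows from the config seed; a chain is
bit-reproducible from `(inputs, config)`, and `runChains()` derives chain
seeds from a master seed by fixed offsets. Initial rates are drawn from
the clock prior (starting at the strict-clock point biases short runs of
$\sigma^2$ low); initial ages scale node heights to the root-prior mean
and are repaired into any hard bounds, with contradictory hard
calibrations reported by name.

Convergence is assessed across chains with between-chain R-hat (floored
at 1), an autocorrelation-based effective sample size, and the largest
cross-chain difference in node-age posterior means; the default pass
thresholds (R-hat < 1.05, ESS > 100, discrepancy < 0.05 Ga) match the
two-decimal precision at which ages are reported.

## Derived statistics

* `computeDeltaT()` subtracts posterior mean ages; the reported range
  combines the two ±1 sd envelopes (this reproduces the published
  "ΔT (range)" columns, e.g. 3.44±0.21 vs 2.27±0.24 → 1.17 with range
  1.62–0.71), with a quantile mode on the per-sample age difference as an
  alternative. Clades are resolved by MRCA of tip sets, never by node
  indices.
* `extractRateSeries()` / `nuExtrema()` produce the per-node (age, rate)
  series and the ν_max / ν_min summary: ν_max is the posterior mean rate
  at a named node with its posterior sd; ν_min averages the per-node mean
  rates over baseline clades, with the sd of that set of node means.
* `fitExponentialDecay()` fits $y_\infty + A e^{-x/\tau}$ in time since
  the root by Levenberg–Marquardt least squares with multi-start over a
  grid of $\tau$ values; constant series are flagged degenerate rather
  than forced. `fitPowerLaw()` is log–log OLS of ν_max on ΔT. Both are
  scale-equivariant under changes of time unit.
* `timeToIdentity()` computes the expected observable identity between
  two lineages diverging at trajectory $\nu(s)$,
  $I(t) = 100\sum_j \pi_j [P(2d(t))]_{jj}$ with
  $d(t)=\int_0^t\nu(s)\,ds$, and inverts it by root-finding. For the
  Poisson model this is the closed form
  $1/20 + (19/20)e^{-40d/19}$. No identity below the equilibrium
  $100\sum_j\pi_j^2$ is reachable. The published "~168 Ma to 50%
  identity" figure comes from an unstated computation, so this operation
  is a documented model of the same idea, not a reproduction of that
  number.
* `percentIdentity()` implements the longest-as-100% rule column-wise on
  the master alignment: matches over the larger of the two non-gap
  lengths. Whether the original identities were computed on full
  sequences or the trimmed alignment is unstated, so a column mask is
  exposed rather than guessing. `fitIdentityRegression()` is OLS of
  identity on time with the slope reported per Ga (divide by 10 for the
  per-100-Ma figure).

## Synthetic data: what it emulates, and what it does not

The generators make the full pipeline testable with no external data:

* `simulateChronogram()` draws a topology by successive random
  coalescence with sorted-uniform internal ages (root age pinned) — the
  simplest defensible null shape; a Yule alternative would change tree
  balance but none of the tested contracts.
* `simulateRates()` runs the autocorrelated log-rate walk, optionally
  around a decaying trend
  $\nu(t) = \nu_\infty + A\,e^{-(t_\text{root}-t)/\tau}$ (fast early,
  slow late). With a trend the expected log-rate change over an edge
  equals the trend difference; without one the walk carries the same
  half-variance correction as the inference prior, so
  recovery studies are exactly well-specified.
* `simulateAlignment()` evolves sites forward with one gamma category
  per site, matching the likelihood's assumption.
* `generateIdentityPairs()` produces the identity-versus-time table; its
  default slope of −8 %/Ga (0.8% per 100 Ma) emulates the observed
  just-under-1%-per-100-Ma decay.
* `reactionCenterFixture()` is a deterministic 74-taxon chronogram
  shaped like the reaction-center family — D1 groups G0–G4, D2, L and M
  clades, eukaryote tips nested inside G4 D1 and D2 — with anchor ages
  (root 3.6 Ga, `D0` 3.3, ancestral standard D1 2.55, crown
  Cyanobacteria 2.48, eukaryotes 1.3) and the cross-calibrated
  fossil-style profiles `table5_calibration1/2` (crown-Cyanobacteria
  minimum 2.45 or 2.70 Ga) attached to its clades. It is a synthetic
  stand-in: passing tests on it demonstrate that the machinery is
  correct, not that real reaction-center alignments would yield the same
  ages.

What the simulations do not emulate: indels (alignments are generated
ungapped), site-heterogeneous profiles (CAT-style), non-contemporaneous
tips, alignment error, and model misspecification between generator and
inference. Recovery results on synthetic data are therefore a
correctness floor, not a field performance claim.

## Problem sizes and numerical choices

The packaged studies are sized for a desk machine: the replicate recovery
study runs 20 chains of 800 sweeps on 20 tips × 300 sites (coverage of
truth within two posterior sds for the root age and $\sigma^2$); the
prior-sampling validation draws 5,000 thinned states; the two-tip
quadrature comparison uses 30,000 sweeps; the 74-taxon fixture
demonstration uses short chains of a few hundred sweeps. Soft-bound
densities are validated by adaptive quadrature to 1e-6; transition
matrices are built from the symmetrized eigendecomposition (stable for
reversible models) with tiny negative entries clamped to zero; the decay
fitter multi-starts $\tau$ over `{0.05, 0.1, 0.25, 0.5, 1, 2}` times the
age span; ages round-trip through annotated Newick to 1e-9 Ga.

## Known limitations

* The CAT mixture and amino-acid GTR exchangeability estimation are out
  of scope, so the headline figures of the non-parametric analyses
  (e.g. ΔT ≈ 1.02 Ga under CAT+GTR+Γ) are not reproducible here; the
  empirical-matrix (LG) route is.
* No proportion-of-invariant-sites term is fitted.
* The node-time prior between calibrations is uniform-given-root; other
  choices (birth–death) would shift posterior ages, which is why the
  root-prior scan interface exists.
* Topology is fixed input; there is no tree search and no tip dating.
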