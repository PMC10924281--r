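---
title: "Selecting coarse-grained representations by nested-sampling model evidence"
author: "nsrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting coarse-grained representations by nested-sampling model evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nsrep)
```

## The problem

Integrative structural modeling determines the architecture of
macromolecular assemblies by combining sparse, noisy experimental
restraints -- chemical crosslinks, low-resolution density maps -- with
physical priors such as chain connectivity and excluded volume.  Before
any sampling can start, the modeler must choose a *representation*: how
many contiguous residues each spherical bead stands for.  Fine beads
(1 residue per bead) translate restraints precisely but are expensive to
sample and easy to overfit; coarse beads (50 residues per bead) sample
quickly but blur the data.  The choice is usually made ad hoc.

`nsrep` makes the choice a Bayesian model-selection problem.  Each
candidate representation $R$ defines a statistical model whose parameters
$\theta$ are the bead coordinates.  Candidates are compared by their
*model evidence* (marginal likelihood)

$$Z_R = \int L(\theta)\,\pi(\theta)\,d\theta,$$

the likelihood of the data averaged over the whole prior.  Evidence
automatically trades goodness-of-fit against model complexity: enlarging
the parameter space without a matching gain in the high-likelihood region
lowers $Z$.  Two representations are compared by the Bayes factor
$K = Z_1/Z_2$ (equal prior odds on the representations themselves).

## Nested sampling

The evidence integral is intractable in the dimension of a bead model, so
it is converted into a one-dimensional integral over the *prior mass*

$$X(\lambda) = \int_{L(\theta) > \lambda} \pi(\theta)\, d\theta, \qquad
  Z = \int_0^1 L(X)\, dX .$$

Nested sampling maintains $N$ "live points" drawn from the prior.  At
every iteration the worst live point (likelihood $L_i$) is removed, the
evidence is incremented by $L_i\,\Delta X_i$, and the point is replaced by
a fresh prior sample constrained to likelihood at least $L_i$.  The
remaining prior mass after $i$ iterations is taken at its expectation
$X_i = e^{-i/N}$ (the deterministic-shrinkage approximation; sampling the
shrinkage factors instead is a known alternative we do not implement).

Quadrature on the $(X, L)$ curve is trapezoidal by default: the $i$-th
increment uses the width $X_{i-1} - X_i$ and the average of the two
adjacent dead-point likelihoods (the first increment falls back to the
rectangle rule).  Written this way the widths telescope *exactly*:
$\sum_i \Delta X_i + X_{\text{final}} = 1$ to machine precision, which is
asserted in the tests for every run.  A rectangle rule is available via
`integration = "rectangle"`.

At termination the live-point remainder
$X_{\text{final}} \cdot \overline{L}_{\text{live}}$ is added.  Without it
any run stopping on a likelihood plateau would understate $Z$; with it a
constant likelihood $L_0$ yields $\log Z = \log L_0$ exactly, a property
the test suite checks to $10^{-6}$.

### Termination

A run stops when any of three conditions is met:

* **failure limit** -- constrained replacement failed `maxFailures`
  (default 4) consecutive batches.  As $X$ shrinks, fresh samples from
  the modified prior rarely beat the rising threshold; this is the
  natural stopping point of the batch-replacement scheme.
* **plateau limit** -- `maxPlateau` (default 20) consecutive iterations
  in which the likelihood grows more slowly than the prior mass shrinks,
  $\log L_{i+1} - \log L_i < 1/N$ (strict inequality at the boundary).
* **iteration cap** -- `maxIterations` (default 10000), a backstop set
  high so that convergence normally happens through the first two rules.

The constrained-replacement criterion is *non-strict*
(`logLik >= threshold`).  A strict inequality would make likelihood
plateaus unpassable -- no strictly better sample exists on a plateau --
so plateau termination could never engage; with the non-strict rule the
sampler keeps producing plateau samples and the plateau detector stops
the run, which is the intended interplay of the two rules.

## The modified prior: posterior repartitioning

Nested sampling is inaccurate when the prior is very dissimilar from the
posterior.  In integrative modeling the natural prior (stereochemistry
only) is nearly uninformative while the posterior is concentrated, so the
package *repartitions* the restraint set: a random subset of the
crosslinks (`fraction`, default 30%) is moved into the prior alongside
the stereochemistry restraints, and the remaining crosslinks plus the
optional density restraint form the likelihood.  The product
$\pi(\theta) L(\theta)$ -- and therefore the posterior and the evidence
of the *full* restraint set -- is unchanged by the split; the test suite
asserts the invariance of `modifiedLogPrior + logLikelihood` across
random partitions to $10^{-9}$.  Density restraints stay on the
likelihood side by default because low-resolution shape information is
comparatively insensitive to the coarse-graining.

## Scoring model

**Stereochemistry.**  Harmonic penalties:
bonded neighbours pay $k_c \max(0, d - r_i - r_j - s)^2$ beyond a slack
$s$ (default 2 Å), non-bonded pairs pay
$k_{ev} \max(0, r_i + r_j - d)^2$ for overlap ($k_c = k_{ev} = 1$ Å$^{-2}$
by default).  Pairs inside one rigid body are skipped (their geometry is
fixed), and intra-chain pairs at bead separation $\le 2$ are excluded
from the overlap sum, mirroring the 1-2/1-3 exclusions of molecular force
fields: at one residue per bead the sphere radius (3.14 Å for a 130 Å$^3$
residue volume) exceeds half the 3.8 Å C$_\alpha$ spacing, so sequence
neighbours overlap in every physically real conformation and would
otherwise be penalized unconditionally.

**Crosslinks.**  Each link contributes
$\log[\psi + (1 - 2\psi) S(d)]$ with
$S(d) = \tfrac12\left(1 - \mathrm{erf}\!\big((d - d_0)/(\sigma\sqrt2)\big)\right)$,
$d_0$ the linker length (21 Å for DSS/BS3 by default), $\psi$ the
false-positive weight (0.05) and $\sigma$ a fixed structural uncertainty
(10 Å) that also absorbs the positional blur of coarse-graining.  The
distance $d$ is the *bead-surface* distance (center distance minus both
radii, floored at zero) so that coarse beads are not spuriously penalized
for their size.  $\sigma$ and $\psi$ are fixed per run rather than
sampled as nuisance parameters, keeping $Z$ directly comparable across
representations.  Every per-link term is bounded in
$[\log\psi, \log(1-\psi)]$.

**Density.**  An experimental map enters as a Gaussian mixture (the
standard text format is read and written by `readGmmText` /
`writeGmmText`).  The model is converted to a mixture with one isotropic
component per bead (variance = radius$^2$, weight proportional to residue
count) and scored by the normalized Gaussian overlap
$cc = \langle f, g\rangle / (\lVert f\rVert\,\lVert g\rVert)$, computed
in closed form from pairwise Gaussian product integrals and verified
against grid quadrature in the tests.  The score is
$w_{em} \log cc$ with $cc$ clamped to $[10^{-12}, 1]$.

## Sampling

Models are sampled from the modified prior by replica-exchange
Metropolis MCMC: 4 replicas on a geometric temperature ladder up to 2.5,
swap attempts between adjacent replicas every 10 steps, snapshots from
the cold replica every 10 steps.  Movers are symmetric: a uniform-ball
translation of one flexible bead (default 4 Å) or a rigid-body
translation plus small rotation about the body centroid (2 Å, 0.2 rad).
The prior is truncated to a cubic box (half-side 300 Å) so its mass is
proper.  Constrained replacement starts a fresh MCMC segment from a
randomly chosen live point, discards the first half of the segment as
burn-in, and returns the first snapshot at or above the threshold --
independence between live points is therefore approximate, which is one
reason independent runs are collated.  Per-step sampling time is the
wall-clock time of a batch divided by steps times replicas; it is the
efficiency axis of the selection rule.

Initial live points are obtained by randomizing each model (rigid bodies
uniformly in the central half of the box with random orientation,
flexible runs regrown from their nearest placed neighbour) and
equilibrating with one MCMC batch.  A run that cannot produce a single
finite-likelihood starting point signals a relaunchable failure; the
workflow relaunches such runs with fresh seeds up to a retry budget.

## Collation and the selection rule

Each representation is run `nRuns` (default 5) times independently.  The
collated estimate reports the mean log-evidence, its standard error
(sample SD over $\sqrt{n}$), and the mean per-step time.  Selection then
proceeds in two steps:

1. **Top-evidence group**: every scheme whose interval
   mean $\pm$ 1 SEM overlaps the interval of the best-evidence scheme.
   The 1-SEM multiplier is configurable (`semMultiplier`).
2. **Efficiency band**: within that group, schemes whose mean per-step
   time is within `fold` (default 3) times the *fastest member of the
   group* are optimal.  Anchoring the band inside the group (rather than
   on the global fastest) lets a slower-but-better-fitting scheme group
   win when the global fastest has poor evidence.

More than one optimal representation can exist; the full flagged table is
returned and `plotEvidence` displays evidence and cost side by side.

## Synthetic data

The generator builds assemblies with known ground truth so that the full
pipeline is testable without external data.  Chains are self-avoiding
random walks with a fixed 3.8 Å C$_\alpha$ bond and a 3.0 Å steric
minimum; a `compactness` parameter in $[0,1]$ biases steps toward the
running centroid (0 gives an extended coil, 1 a collapsed globule with
realistic dimensions, e.g. $R_g \approx 10$ Å for 100 residues).
Crosslinks are simulated on the *reference* coordinates -- so ground
truth is representation-independent -- with true positives drawn from
pairs within `dMax` (25 Å), decoys beyond it, and intra-chain pairs
closer than 5 residues excluded as chemically uninformative.  Densities
are simulated by k-means partitioning of the reference positions into a
requested number of Gaussians with a resolution blur added to each
covariance.

Three fixed-seed presets bundle these pieces: `"extended"` (one 100
residue disordered coil), `"globular"` (one compact 100-residue chain
with a rigid structured core), and `"mixed"` (a compact chain with rigid
core plus an extended chain, 60 links, 10-component density).  What the
generator does *not* emulate: real crosslinker chemistry and solvent
accessibility, ambiguous residue assignments, multi-copy stoichiometry,
and voxel-level map noise.  Passing tests therefore demonstrate correct
behaviour of the estimator and selection machinery on controlled inputs,
not performance on experimental data.

## Numerical choices and problem sizes

* Deterministic shrinkage $X_i = e^{-i/N}$; single replacement per
  iteration.
* Default run settings follow the recommended small-budget protocol:
  5 runs, 50 live points, 50 MCMC steps per batch.  The test suite and
  the reproduction script run reduced settings (3 runs, 25 live points)
  on the presets, which we chose as the smallest configuration at which
  the ranking behaviour is interpretable; per-run log-evidence scatter at
  these settings is large (SD of several log units on the presets), which
  is why conclusions are always drawn from collated means with errors.
* The live-point count should be at least the free-parameter bound
  $3n + 6m$ ($n$ flexible beads, $m$ rigid bodies); `runNestedSampling`
  warns otherwise.
* All randomness flows from a single integer seed per run; workflow runs
  derive per-run seeds from (master seed, scheme label, run index), so
  results are identical for any thread count.  Wall-clock per-step times
  are, unavoidably, not bitwise reproducible.
* Ties and degenerate inputs: an empty crosslink set leaves a
  stereochemistry-only prior (with a warning); a single collated run
  reports SEM 0 with a warning; selection ties are reported in full,
  ordered by evidence then time.

## Known limitations

* With fixed forward-model parameters every crosslink term has the same
  representation-independent maximum, and the bead-surface distance
  convention means very coarse beads satisfy links -- including decoys --
  over a large share of their prior.  Mean evidence therefore tends to
  favour coarser schemes on crosslink-dominated setups, and fine-scheme
  preference for extended chains emerges only through the error bars.
  Recovering a sharp fine-scheme preference would require a likelihood
  whose attainable maximum grows as the forward model sharpens (e.g.
  sampled nuisance uncertainties), which is deliberately out of scope
  here to keep evidences directly comparable.
* Evidence comparisons are unreliable when candidate representations
  differ only in a small part of the system, or when data on the varied
  region are sparse: the shared regions dominate $Z$ and the error bars
  grow.
* The batch-filter replacement scheme terminates at stochastic depths;
  at small live-point counts this dominates the run-to-run scatter of
  $\log Z$.  Increase live points, runs, and steps per batch -- in that
  order -- to shrink the errors.
* Plateau detection can stop a run early on rugged likelihoods; the
  live-point remainder term limits, but does not eliminate, the
  resulting bias.
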