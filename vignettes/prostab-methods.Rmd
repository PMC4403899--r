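---
title: "Methods: structure-based prediction of stability changes upon mutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based prediction of stability changes upon mutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostab)
```

## Overview

`prostab` predicts the change in the free energy of unfolding, ddG
(kcal/mol, negative = stabilizing), caused by single- or multi-point
substitutions in a protein of known 3D structure.  The method makes no
attempt to remodel side chains or relax the structure: a mutant is the
wild-type structure with residue types relabeled.  All signal therefore
comes from (i) knowledge-based statistical scoring functions evaluated on
the fixed geometry, and (ii) simple global and site-local descriptors, fed
into a small ensemble of regression agents.

## Statistical scoring functions

Three potentials of mean force are compiled from a reference set of
structures:

* two distance-dependent residue-pair functions over CA-CA and CB-CB
  distances (Sippl-style), and
* a contact function over the number of CA atoms within a radius of each
  residue (a solvent-exposure surrogate).

For pair type $(a,b)$ and distance bin $d$ the observed energy is
$E^o_{ab}(d) = -\ln(\delta_{ab}(d)/\rho(d))$, where $\delta_{ab}$ is the
pair type's relative distance frequency and $\rho$ the pooled reference
distribution (count-weighted sum of all pair distributions).  Each pair
type also gets an expected energy, the $\rho$-weighted mean of its energy
profile, which serves as its sequence-independent background.  The contact
function is built identically over contact counts.

To score one structure, the $n$ observed energies and their $n$ expected
counterparts are ranked jointly (midranks on ties) and the rank sum $W$ of
the observed set is standardized with the Wilcoxon null moments
$\mu_W = n(2n+1)/2$ and $\sigma_W = \sqrt{n^2(2n+1)/12}$, giving a
z-score-like quantity $s$ per scoring function.  The three scores combine
by Stouffer's rule, $s_c = (s_{\alpha} + s_{\beta} + s_{c})/\sqrt{3}$.  A
mutant's `deltaScore` is $s_c(\text{mutant}) - s_c(\text{wild type})$;
negative values predict stabilization.

Numerical choices, all exposed as arguments and recorded in the persisted
model files:

* distance bins: 1 A over [3, 15) A; pairs outside the range are ignored;
* minimum intra-chain sequence separation 2 (inter-chain pairs always
  count, so multimer interfaces contribute);
* contact radius 10 A, counts clamped at 30;
* additive pseudocount 1 on every count cell before normalization, which
  prevents $-\ln 0$ in sparse cells and makes empty compilations exactly
  uniform (zero energies);
* $\sigma_W$ is used without a tie correction, matching the printed null
  form; ties only arise through the midranks.

## The nine agent inputs

1.-3. the per-function score differences (CA pair, CB pair, contact);
4. protein size (residue count of the scored unit);
5. the secondary-structure state at the site, encoded helix = 0,
   strand = 0.5, coil = 1 (frozen injective map);
6. relative accessible surface area at the site;
7.-9. substitution deltas: mass (average residue masses), Hopp-Woods
   hydrophilicity and isoelectric point, from frozen TSV tables shipped in
   `inst/extdata`.

For multi-point mutants the site-local features (5, 6) are averaged over
the mutated sites and the substitution deltas are summed, keeping the
vector at nine values.

Secondary structure is assigned from CA geometry alone with P-SEA-style
distance windows (helix: d(i,i+3) in [4.6, 5.8] and d(i,i+4) in
[5.5, 6.9] A; strand: d(i,i+2) in [6.2, 7.2] and d(i,i+3) >= 9.4 A),
with minimum segment lengths of 4 (helix) and 3 (strand); anything else,
including degenerate geometry, is coil.  The assignment is deliberately
isolated behind one function so a different assignment scheme can be
swapped in.

Accessibility uses a coarse residue-level Shrake-Rupley estimate: one
sphere per residue at its (possibly virtual) CB with a frozen
type-specific radius, a 1.4 A probe, and 256 deterministic golden-spiral
test points; the result is normalized by the isolated-sphere area so an
unoccluded residue scores 1.  Because the point grid is fixed in space the
estimate is rigid-motion invariant only up to its sampling resolution
(about 0.01-0.02 in relative ASA), which is far below the signal the
agents use.

Glycine (and any residue whose CB is missing from the file) receives a
virtual CB from ideal tetrahedral geometry (|CB-CA| = 1.53 A, L
chirality), so CB-based scoring and the disulfide gate treat all residue
types uniformly.

## Agents, consensus and confidence

Seven agents are trained on z-scaled inputs (scaling statistics are stored
with the model and applied at prediction):

* one multiple linear regression (ordinary least squares);
* three neural-network agents (general, stabilizing-specialist,
  destabilizing-specialist): each agent partitions its training records
  into ten folds and per rotation trains one 9-H-1 network (tanh hidden
  layer, linear output) on eight folds, checkpointing the BFGS
  optimization against the generalization fold and measuring the test
  fold; the hidden size is picked from {3, 5, 7, 9, 12} by mean test-fold
  error and the ten member networks predict by averaging.  Weight decay
  (1e-3) provides the regularization backbone alongside the
  generalization-fold checkpointing;
* three epsilon-SVR agents with Gaussian kernels (same specialization
  scheme); gamma and cost are chosen by 10-fold cross-validated MSE over
  log-2 grids, then refit on all records.

Specialists train on the sign classes of the experimental ddG; records
with ddG = 0 are assigned to the destabilizing class.  At prediction time
the general ANN and SVR agents predict first and the sign of each general
prediction routes to the matching specialist.  The consensus pool is the
five values {MLR, ANN-general, ANN-specialist, SVR-general,
SVR-specialist}.  Outliers are pruned iteratively: the value farthest from
the mean of the others is removed when its distance exceeds twice the
standard deviation of the others, until no outlier remains or two values
are left.  The consensus ddG is the mean of the retained values, and the
confidence is

$$c_{pred} = \begin{cases}0 & \sigma_r > \sigma_{max}\\
1 - \sigma_r/\sigma_{max} & \text{otherwise}\end{cases}$$

with $\sigma_r$ the retained values' standard deviation and
$\sigma_{max}$ four times the training-set ddG standard deviation.  Note
that the literal iterated removal rule can prune beyond the first obvious
outlier when the remaining values are tightly clustered; the procedure
stops at the two-value floor by construction.

Open design points resolved here (the underlying publications leave them
unstated): the agents receive wild-type-relative score *differences*
rather than absolute scores, because absolute rank-sum scores are
dominated by protein size; the consensus pool is the routed five-value
set; and the secondary-structure encoding above is this package's frozen
choice, stored with any trained model.

## Mutation scanning

Three searches over n-point mutants under user constraints (positions,
wild-type types, relative-ASA interval, allowed substitutions; a site
never offers its own wild type):

* `optimalScan` enumerates every candidate (the count is the elementary
  symmetric polynomial of the per-site substitution counts, e.g.
  $\binom{a}{n}19^n$ unrestricted) and is the correctness oracle;
* `greedyScan` extends the current mutant by the best single addition,
  re-predicting the full mutant at each step; exact under additivity,
  trappable by epistasis;
* `eaScan` is a multi-population evolutionary algorithm: tournament
  selection (size 3), uniform site-wise crossover repaired to exactly n
  distinct sites, per-gene mutation (probability 0.1; substitution
  resample or site move, 50/50), ring migration of the top 2 every 10
  generations, elitism, defaults 4 populations of 50 for 200 generations.
  The published description names the operators but not the parameter
  values; these defaults were chosen once as conventional mid-size EA
  settings.  All randomness flows from one seed; results are
  bit-reproducible, and predictions are cached on the canonical mutation
  string.

## Disulfide-bond design

Candidate pairs are all residue pairs with CB-CB distance at most 5 A
(virtual CBs included) and author-numbering separation of at least 2
within a chain.  Each pair is mutated to double cysteine (an existing
cysteine is left as-is) and scored by three components: the predicted ddG
and two geometric penalties $P_\beta = 1 - f(d_{CB CB})$ and
$P_{\alpha\beta} = 1 - f(d_{CA CA} - d_{CB CB})$, where the relative
frequency histograms are compiled from disulfide-bonded cysteine pairs
(SG-SG <= 2.5 A) in a reference set.  Histogram bins are 0.25 A over
[2.5, 6] A and [-2, 2] A; out-of-range geometry gets penalty 1.  Within
one structure's candidate list each component is z-transformed and
$S_{ss} = (z_{ddG} + z_{P_\beta} + z_{P_{\alpha\beta}})/\sqrt{3}$ ranks
the pairs (ablation modes rank by ddG only, delta-score only, or
penalties only).  A zero-variance component contributes z = 0 with a
warning.  The z-transform is per structure; pooling across structures is
deliberately not done.

## Synthetic study system

Because full-scale reference compilations and curated thermodynamic sets
are external data, the package ships a generator that builds the whole
test bench in code:

* toy structures with ideal backbone geometry (NeRF construction from
  standard bond lengths/angles): alpha-helix (phi -57, psi -47), extended
  strand (-139, 135), a two-strand hairpin, and a compact quasi-random
  cluster (3.8 A packing floor) for burial and disulfide geometry;
* training tables with a linear ground truth: random mutants are
  featurized through the full pipeline and labelled
  $\Delta\Delta G = \beta^\top x + \varepsilon$.  The frozen coefficient
  vector `demoBeta()` was chosen once so the resulting tables resemble
  curated stability sets (ddG mean about +0.4 kcal/mol, sd about 1.9,
  roughly one third stabilizing); the default noise sd is 0.5 kcal/mol;
* a parser for experimental-style TSV tables that applies a pH window
  [5.5, 8.5], picks among duplicate measurements the conditions closest
  to 25 C / pH 7 (temperature normalized by 10 C, pH by 1 unit), and
  collapses exact-condition ties to the median ddG.  A recency rule for
  two-way ties cannot be honoured without publication metadata; the
  parser falls back to first occurrence.

What passing tests on this bench does and does not show: the bench proves
the machinery end to end - potential compilation, rank-sum scoring,
feature assembly, agent training, consensus, searches and the disulfide
screen - and that the ensemble recovers a known signal (10-fold pooled
Pearson r >= 0.9 at n = 2000, noise sd 0.5; the suites use that size, with
smaller n for the per-operation unit checks).  It does not demonstrate
accuracy on real mutations: real ddG data are not linear in these nine
features, real structures are not ideal-geometry toys, and a production
potential must be compiled from a large non-redundant structure set
supplied by the user.

## Limitations

* No side-chain modelling or relaxation: predictions for mutations that
  require backbone accommodation inherit that blindness.
* NMR ensembles are handled by predicting per model and reporting
  mean +/- sd; the choice of aggregation is this package's convention.
* The searched SVR/ANN grids are conventional, not exhaustive; the
  hidden-size grid and log-2 grids can be overridden in `agentConfig()`.
* Multi-point site features are averaged; strongly interacting sites are
  represented only through the joint score differences.
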