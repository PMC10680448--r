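---
title: "Structure and species importance in sponge host-guest networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure and species importance in sponge host-guest networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Reef sponges host a remarkably diverse guest fauna — shrimps, brittle
stars, polychaetes, fishes, molluscs — and the web of who lives in whom
forms a bipartite interaction network. `reefguest` implements a complete
analysis chain for such networks: it quantifies network-level
architecture (nestedness and modularity) against null models, scores
every host sponge with seven complementary structural descriptors,
collapses those into a single importance index, and asks which host
traits — accumulated geographic area on reef, growth form, taxonomic
order — predict that importance.

This vignette explains the models and the design decisions; the README
shows a worked example.

## The qualitative network

Interaction records from heterogeneous literature sources differ in
sampling effort and in how "interaction frequency" was counted, so the
analysis deliberately uses a *binary* (qualitative) incidence matrix:
`A[i, j] = 1` if host `i` was ever recorded hosting guest `j`. Records
are first filtered to species-level host names — a binomial with an
optional parenthesised subgenus; entries such as `"Ircinia sp."` are
removed. The filter is a regular expression, not a taxonomic service:
name harmonization against external registries is out of scope, and the
ecoregion label is taken from the input rather than derived from
coordinates. A "location" in the dataset summary is a coordinate pair
rounded to 3 decimals (about 100 m), a configurable choice since the
source literature does not define one.

## Nestedness and modularity

**NODF** measures nestedness via paired overlap under decreasing fill:
for rows (and, symmetrically, columns) with strictly decreasing
marginal totals $k_i > k_j$, the pair contributes
$100\,|N_i \cap N_j| / k_j$, and pairs with equal totals contribute
zero. The score averages over the full set of row and column pairs, so
it ranges from 0 to 100.

**Barber's bipartite modularity** of a partition $g$ is

$$Q = \frac{1}{m} \sum_{ij} \left(A_{ij} - \frac{k_i d_j}{m}\right)
\delta(g_i, g_j),$$

with $k_i$, $d_j$ the host and guest degrees and $m$ the link count. A
single shared module gives exactly 0. `optimize_modules()` searches for
the best partition by simulated annealing in the QuanBiMo family:
single-species reassignments (to an existing or a fresh module) mixed
with whole-module merges, accepted with probability
$\exp(\Delta Q / T)$ under geometric cooling from $T_0 = 10/m$ to
$10^{-2}/m$. The temperature scale is tied to $1/m$ because that is the
natural magnitude of single-move changes in $Q$. The best partition
seen is then polished by a deterministic hill-climb (best single moves
to convergence), so the reported $Q$ is a local optimum and is never
below the best annealed value. The default budget is $10^5$ proposals
with two restarts; on planted two- and three-block networks the
optimizer recovers the exact blocks from essentially any seed.

### Null models and significance

Two binary null models are provided. The default, `"fill"`, scatters
the observed number of links uniformly over the matrix, preserving
dimensions and connectance only. `"marginals"` runs curveball trades
from the observed matrix and preserves every row and column total
exactly; it is the conservative alternative for sensitivity analysis.
The default follows the fixed-connectance description of the original
study design; which quantity a null should fix is a genuinely open
choice, so both are first-class options.

Significance is the one-sided upper tail of the observed metric in the
null ensemble, with the $(r+1)/(n+1)$ estimator so that $p$ is never
exactly zero. For modularity, every null matrix is optimized with the
same annealing budget as the observed one — an expensive but necessary
symmetry, since comparing an optimized observed value with unoptimized
nulls would inflate significance.

## Seven species-level descriptors

For every host sponge the package computes:

* **degree** — number of guest species (row sum);
* **betweenness** and **closeness** — computed on the full two-mode
  graph over hosts and guests, so paths alternate levels. Betweenness
  uses Freeman normalization $(n-1)(n-2)/2$ over the full vertex count;
  closeness is component-restricted,
  $(\text{reachable}-1)/\sum \text{distances}$, and 0 for isolated
  vertices. A one-mode host projection is available behind the
  `projection` flag for sensitivity, but the two-mode graph is the
  default because the descriptor definitions speak of paths between
  *any* two species;
* **Katz centrality** — $((I - \alpha B)^{-1} - I)\mathbf{1}$ on the
  full adjacency $B$, the closed form of the attenuated walk count.
  The attenuation defaults to $\alpha = 0.9/\lambda_{\max}$: always
  convergent, while keeping long walks influential. No principled
  single value exists, so the parameter is exposed;
* **among-module connectivity** $c_i = 1 - \sum_s (k_{is}/k_i)^2$, the
  participation coefficient across modules;
* **within-module degree** $z_i$ — the species' link count into its
  own module, standardized against all members (hosts and guests) of
  that module; a zero spread yields $z_i = 0$;
* **nestedness contribution** $cn_i$ — the focal host's row is
  replaced `n_rand` times (default 1000) by a random row of the same
  degree, partners drawn with probability proportional to the mean of
  row fill and column fill (the probabilistic cell null), and
  $cn_i = (\mathrm{NODF}_{obs} - \overline{\mathrm{NODF}}_{rand}) /
  \mathrm{sd}(\mathrm{NODF}_{rand})$.

The contribution loop is the only compiled code in the package
(`src/cni_loop.cpp`): a degree-preserving row swap leaves host
marginals unchanged, so each draw needs only the focal row's overlap
terms and a rank-2 correction of the column overlaps, evaluated at C
speed. The kernel is verified in the tests against a naive R resampler
that rebuilds the matrix and recomputes NODF from scratch under the
same RNG stream.

A note on the sign of $cn_i$: it is *not* guaranteed positive for hubs
in nested matrices. The fill-weighted replacement rows can colonize
empty or low-fill columns and break degree ties, both of which can
raise NODF above the observed value; even the hub of a perfect
staircase scores a mildly negative contribution. What does hold — and
what the tests assert — is the comparative property: placing a hub's
links on the highest-fill guests scores a strictly higher contribution
than placing them on the lowest-fill guests.

## The importance index

The seven descriptors are strongly inter-correlated on nested
networks, which is the premise for collapsing them by principal
coordinate ordination (classical metric scaling of Euclidean
distances; on such distances the axis scores equal centered
principal-component scores, and the tests pin this duality). Axis 1 is
sign-oriented so it correlates positively with degree. Scores are then
shifted to start at zero and square-rooted:
`importance = sqrt(PCO1 - min(PCO1))`, a monotone transform that
compresses the long right tail created by hub hosts.

**Standardization.** By default the descriptor columns enter the
distance *unstandardized* (`standardize = FALSE`, with the z-scored
variant one flag away). The descriptors live on very different scales
(counts, proportions, z-scores), so without standardization the
largest-scale column — Katz centrality and degree, which are nearly
collinear here — dominates axis 1. That choice is deliberate: the
reference analyses of this system report axis-1 shares near 99.8% and
importance values up to ~24 (hence raw axis ranges in the hundreds),
magnitudes that only arise from unstandardized input; z-scored input
caps the axis range at a few units and spreads variance over more
axes. Under either setting the index remains a monotone proxy for
structural contribution; the tests require Spearman correlation with
degree above 0.9 across seeded replicates.

Negative PCoA eigenvalues cannot occur for Euclidean input, so their
appearance is treated as a numerical contract violation (an error),
not silently corrected.

## Accumulated geographic area

Each occurrence record contributes a circular buffer of 10 m² (the
radius is inflated by ~0.08% so the inscribed 64-gon has *exactly* the
nominal area), built in a local tangent-plane projection centred on
the record — at metre scale the projection is area-true to well below
0.1%, whereas degree-space buffers would be numerically degenerate.
The buffer is intersected with the reef polygons by clipping each ring
against the convex buffer polygon (Sutherland–Hodgman), holes
subtracting; geometry predicates, clipping and areas are implemented
directly in the package because the analysis needs only
convex-against-arbitrary clipping at a fixed, tiny scale.

Per-species areas are *summed* by default ("accumulated" area; two
records half-overlapping count twice). `union_overlaps = TRUE` instead
counts overlapping buffers once, via grid integration over clusters of
mutually overlapping records; at 10 m² per record the difference only
matters for near-duplicate coordinates, which is why the sum is the
default and the union a reported alternative. Results are in km², so
one fully-on-reef record contributes exactly `1e-5`.

Degenerate reef rings are skipped loudly at load time (closure is
repaired, self-intersection is not; a full polygon-repair pass is out
of scope and flagged in the documentation of `read_reefs()`).

## Trait models

* **Poisson GLM** of importance on accumulated area (log link, IRLS
  via `stats::glm`). The response is continuous and non-negative, so
  the Poisson family acts as a quasi-likelihood working model: the
  coefficient estimates solve the Poisson score equations, and
  standard errors are evaluated at dispersion 1 to match a plain
  Poisson fit. This mirrors the reference analysis and is documented
  prominently rather than hidden; the IRLS solution is tested against
  a numerical likelihood maximizer.
* **One-way ANOVAs** of importance across functional morphologies
  (Crust-like, Massive, Cup-like, Erect) and across taxonomic orders,
  with per-group means and standard errors (a flag switches to SDs).
  A completely flat response returns $F = 0, p = 1$; zero
  within-group variance with real group differences is an error.
* **Publication-bias meta-analysis** of per-ecoregion publication
  counts as proportions of the total effort: logit transform,
  inverse-variance random effects with maximum-likelihood $\tau^2$
  (`metafor::rma`), Cochran's Q heterogeneity, and the Thompson–Sharp
  asymmetry test (weighted regression of effect on standard error
  with multiplicative overdispersion, `metafor::regtest(model =
  "lm")`). Zero counts get the conventional 0.5 continuity
  correction. When all standard errors coincide the asymmetry
  regression is rank-deficient; the slope is reported as 0 with an
  undefined p, since no small-study trend is expressible.

## The synthetic-data generator

Because the deposited empirical tables cannot be redistributed with
the package, every stage is exercised on synthetic bundles whose
defaults emulate the study system: 76 hosts, 268 guests, ~745 expected
links (connectance 0.037), a right-skewed host degree distribution
with a few hubs, and simultaneous nested and modular structure.

Within each of `n_modules` planted blocks the cell probability is
proportional to the product of rank-decay weights
$(1 - (r-1)/R)^{\text{strength}}$ (within-block ranks), scaled to the
target fill and truncated at 1; `module_mixing` rewires that fraction
of links to uniformly random empty cells, diluting both block and
gradient structure. Strength 2 with a single block yields networks
whose NODF is detected against the fill null in essentially every
seed; strength 0 yields networks statistically indistinguishable from
their own null. Empty rows or columns are repaired by resampling the
offending line from its own cell probabilities (five sweeps) and, as a
last resort, forcing a single link drawn from that profile — whole-
matrix rejection is not viable at realistic connectance, where an
empty guest column occurs on almost every draw. The repair adds a
small upward fill bias that stays within sampling noise of the target.

Morphology classes are assigned with probability proportional to
`effect^z`, where `z` is the host's standardized log-degree. The
default effects (Cup-like 2.5, Massive 2.2, Crust-like 1.0, Erect 0.5)
were calibrated once so that the morphology ANOVA, run through the
full importance pipeline, attains roughly 90% power at a 40 x 80
network — while all-equal effects make the assignment exactly
degree-independent, giving a clean type-I null (measured rejection
rate 5% at $\alpha = 0.05$ over 200 seeds). Occurrence counts per
host are geometric (deliberately overdispersed) with mean
$\text{base} \cdot k^{\text{coupling}}$, and coordinates fall
uniformly inside randomly placed rectangular reef polygons, so every
synthetic record lies on reef.

What the generator does *not* emulate: real ecoregion geometry,
taxonomy, spatial autocorrelation of occurrences, observation effort
gradients, or correlated sampling of interactions and occurrences.
Passing tests therefore demonstrate correctness of the algorithms and
recoverability of planted effects, not fidelity of any particular
empirical estimate.

## Problem sizes and numerical choices

The test suite runs entirely on synthetic data in a few minutes: null
ensembles of 100–1000 matrices, annealing budgets of 1500–10^4
proposals on 20 x 40 to 40 x 80 networks, contribution resampling at
`n_rand` 100–500, and calibration batteries of 100–200 seeds. The
acceptance script uses the full study-scale default (76 x 268) with
1000 nestedness nulls, 100 modularity nulls at 5000 proposals each,
and `n_rand = 1000`. These sizes were chosen as the smallest at which
the planted-structure recovery rates are stable; all of them are
arguments, not constants.

Numerical edge cases are handled explicitly: a zero null spread
reports `z = NA` while the rank-based p is still computed;
`sd = 0` within a module gives `z_i = 0`; a saturated focal row (one
possible rearrangement) gives `cn_i = 0`; equal marginal totals
contribute zero to NODF by definition; ties in discrete null metrics
make p-values conservative, which the tests check as stochastic
dominance rather than exact uniformity.

## Known limitations

* The species-level filter is purely syntactic; synonymy and
  misspellings pass through.
* Modularity optimization is stochastic; with very small budgets the
  reported $Q$ underestimates the optimum (the hill-climb gives a
  local-optimality floor).
* The polygon clipper assumes reef rings are simple (non-self-
  intersecting); invalid rings are skipped, not repaired.
* The union mode for overlapping buffers is grid-integrated, accurate
  to about 1% per cluster.
* The meta-analysis emulates the logit random-effects pooling and the
  Thompson–Sharp test only; other transforms and estimator choices of
  full meta-analysis suites are out of scope.
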