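---
title: "Quantifying deterministic and stochastic community assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying deterministic and stochastic community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblyscope)
```

## The scientific question

Microbial communities are structured by a mixture of deterministic
processes (environmental filtering, biotic interactions) and stochastic
ones (dispersal, ecological drift).  assemblyscope implements the
null-model toolkit that microbial ecologists use to apportion pairwise
community turnover among five processes — variable selection,
homogeneous selection, dispersal limitation, homogenizing dispersal and
undominated — and to summarise the overall balance with the normalized
stochasticity ratio (NST) and the Sloan neutral community model.  A
synthetic community simulator with known assembly regimes provides
ground truth, so every stage of the stack can be verified without field
data.

## The inference stack

### betaMNTD and betaNTI

For samples $i, j$, the beta mean nearest taxon distance is

$$\beta\mathrm{MNTD}_{ij} = \tfrac12\Big[\sum_k f_{ik}\,
\min_{l \in j} d_{kl} + \sum_k f_{jk}\, \min_{l \in i} d_{kl}\Big],$$

with $d_{kl}$ the patristic distance and $f$ relative abundance
(`weighted = TRUE`, the default) or $1/\text{richness}$.  A taxon
present in both samples is its own nearest neighbour and contributes 0.
The beta nearest taxon index is the z-score of the observed value
against a null in which tip labels are shuffled across the whole tree
(`n_null` = 999 by default), leaving abundances untouched:
$\beta\mathrm{NTI} = (\mathrm{obs} - \mu_{\mathrm{null}}) /
\sigma_{\mathrm{null}}$.  $|\beta\mathrm{NTI}| > 2$ marks significantly
more ($> 2$, variable selection) or less ($< -2$, homogeneous
selection) phylogenetic turnover than expected.  Because the z-score is
scale-free, betaNTI is invariant to uniform branch-length rescaling (a
property test asserts this).  Null replicates share one tip permutation
across all sample pairs: the tip-shuffle null does not depend on the
pair, so sharing changes nothing statistically while making the
computation a single pass per replicate; results are deterministic
given the seed and independent of pair evaluation order.

On a star phylogeny every tip permutation yields the same betaMNTD, the
null standard deviation is zero, and the pair is reported as `NA` and
excluded (and counted) by the classifier rather than silently dropped.

### RC_bray

Pairs not resolved by betaNTI ($|\beta\mathrm{NTI}| < 2$) are classified
with the Bray–Curtis-based Raup–Crick metric.  Each null community
fixes the observed richness and total count of its real counterpart:
taxa are drawn without replacement with probability proportional to
regional occupancy, then the remaining individuals are assigned
multinomially with probability proportional to regional relative
abundance.  With ties counted at half weight,

$$RC = 2\left[\Pr(\mathrm{null} < \mathrm{obs}) +
\tfrac12\Pr(\mathrm{null} = \mathrm{obs})\right] - 1 \in [-1, 1],$$

which is symmetric around 0 under the null (a property test checks
that RC on communities generated by the null engine itself is roughly
uniform).  $RC > 0.95$ is dispersal limitation, $RC < -0.95$
homogenizing dispersal, the remainder undominated.  Boundary values
($\beta\mathrm{NTI} = \pm 2$, $RC = \pm 0.95$) fall on the
non-significant side — the inequalities are strict.  Per-pair null
draws use sub-seeds derived from (seed, pair index), so RC results do
not depend on which pairs are evaluated or in what order.

The regional pool defaults to the whole analysed table; `pool_samples`
restricts it.  In the pipeline each site-by-treatment cell is analysed
against its own pool (the convention for per-treatment sub-community
analyses), while betaNTI uses the study-wide tree.

### NST

The pipeline's NST uses the same richness- and abundance-constrained
null engine with Bray–Curtis (or Jaccard) dissimilarity.  With observed
dissimilarity $D$, null expectation $E$ and $D_{\max} = 1$:

$$SS = \begin{cases}(D - E)/(D_{\max} - E) & D \ge E\\
(E - D)/E & D < E\end{cases}, \qquad NST = 1 - SS,$$

averaged over within-group pairs and reported in percent, with 50% the
conventional deterministic/stochastic boundary.  The null algorithm
behind published NST pipelines is configurable and not uniquely
determined by their descriptions; this package documents its variant
(proportional richness-preserving null, pluggable metric) rather than
claiming equivalence to any specific implementation.  Group NST is the
arithmetic mean of pairwise values because the aggregation rule is a
free choice; a pair whose null expectation is exactly 0 or 1 is
undefined and excluded with a warning.  Null rows are drawn in sorted
sample-id order so results are invariant to input row order.

### Sloan neutral community model

The model predicts a taxon's occurrence frequency from its mean
relative abundance $p$ under drift with immigration:
$F(p) = 1 - \mathrm{Beta}_{\mathrm{CDF}}(d;\ N\!m\,p,\ N\!m(1-p))$,
with detection limit $d = 1/N$ by default ($N$ = mean sample total).
$Nm$ is fitted by least squares with a log-scale line search over
$[10^{-3} N, 10^6]$ — the objective is one-dimensional and unimodal in
practice, so a bracketed search is more robust than general nonlinear
least squares.  The 95% band is the Wilson binomial interval of the
predicted frequency across the number of samples.
`simulate_sloan_community()` draws each local relative abundance from
the stationary island-model marginal
$\mathrm{Beta}(N\!m\,p, N\!m(1-p))$ and converts to counts by rounding,
which makes detection exactly $q \ge 0.5/N$; fits on such tables should
pass `detection_limit = 0.5/N` to match.  Parameter recovery on these
tables is within a few percent at 50 samples × 500 taxa.

### Niche breadth and phylogenetic signal

Levins' $B_i = 1/\sum_j q_{ij}^2$ over a taxon's distribution across
samples ($1 \le B \le$ number of samples), and $B_{com}$ is the
unweighted mean over taxa.  The phylogenetic-signal correlogram
computes each taxon's niche value as the abundance-weighted mean of
z-scored environmental covariates, takes Euclidean niche distances, and
tests their Mantel correlation against phylogenetic distance classes
(vegan's `mantel.correlog`: taxon-label permutations, progressive Holm
correction).  Distance classes default to Sturges' rule and classes
with fewer than 30 pairs are masked (`min_pairs`), because per-class
Mantel statistics on a handful of pairs are unstable.  A
Brownian-motion trait used directly as the niche is the positive
control (significant positive $r$ in the shortest class in over 80% of
simulations); a permuted trait calibrates the type-I error at
$\alpha = 0.05$.

### Co-association networks

Counts are square-root transformed and taxa present in no more than
half the samples are removed (majority rule).  The similarity threshold
$S_t$ for the Pearson correlation matrix is chosen by random matrix
theory: at each candidate threshold the eigenvalue nearest-neighbour
spacing distribution (NNSD) of the thresholded matrix is tested against
the Poisson form $e^{-s}$; $S_t$ is the smallest threshold whose NNSD
is Poisson-consistent (chi-square goodness of fit, $p > 0.05$), i.e.,
where random noise correlations have been removed and only modular
structure remains.  Numerical choices: duplicate eigenvalues are
collapsed before unfolding; the cumulative level count is smoothed with
a low-df (8) monotone spline so local spacing fluctuations survive the
unfolding; spacings are binned on $[0, 3]$ into 10 bins merged until
every expected count is at least 5.  A spectrum with too few distinct
levels cannot exhibit level repulsion and is treated as
Poisson-consistent, which makes an identity correlation matrix select
the scan start.  Matrices under 30 nodes trigger an unreliability
warning.  The chi-square decision is conservative on strongly
block-structured spectra (a superposition of a few block spectra is
only asymptotically Poisson), so occasionally no threshold passes; the
error message then suggests widening the scan.

Networks keep edges with $|r| \ge S_t$ (signed), drop isolated nodes,
and find modules by deterministic greedy modularity maximisation
(falling back to the connected-component partition when agglomeration
leaves a non-positive-Q split, as on tiny complete graphs).  The
topology record includes average connectivity $2E/N$, average
clustering (degree-<2 nodes contribute 0), mean geodesic over connected
pairs, diameter within components, density, geodesic efficiency (mean
of $1/d$; unreachable pairs contribute 0 — needed because thresholded
networks are usually disconnected), harmonic geodesic distance,
Freeman centralization of degree, betweenness and stress (stress = the
number of shortest paths through a node; the star-graph maximum is the
denominator), Newman modularity and the positive/negative link split.
Zi–Pi roles use the conventional thresholds: network hub
($Z_i > 2.5$, $P_i > 0.62$), module hub ($Z_i > 2.5$), connector
($P_i > 0.62$), else peripheral; a module with zero within-module
degree variance gives $Z_i = 0$.  The random ensemble is
Maslov–Sneppen degree-preserving rewiring ($10E$ swap attempts per
replicate); graphs without two independent swappable edge pairs (e.g.,
a triangle) are rejected with an error.

## The synthetic community simulator

`simulate_tree()` draws a pure-birth (Yule) phylogeny.
`simulate_community()` generates count tables under four regimes:

* **neutral** — each sample is a multinomial of size $N$ from a
  Dirichlet($N m\,p$) composition around a log-series metacommunity
  $p$: the stationary island-model distribution, so each taxon's local
  relative abundance is marginally Beta($Nm\,p_k$, $Nm(1-p_k)$) and the
  Sloan model is correct by construction.  Defaults $N = 5000$,
  $m = 0.3$ give fits with $R^2 > 0.7$ at a dozen samples.
* **homogeneous / variable selection** — a niche trait evolves by
  Brownian motion on the tree and a Gaussian filter
  $w_k \propto \exp(-(t_k - env_j)^2 / 2\sigma^2)$ weights taxa.
  Sample membership is a Bernoulli draw proportional to $w$ (expected
  richness `target_richness`, default 40) — compositional drift around
  the deterministic filter — and abundances over the members are an
  even Gamma draw (`evenness`, default 5).  Two choices make the
  filter phylogenetically meaningful at desk scale.  First, the trait
  is evolved on an early-burst depth transform of the tree
  (`trait_delta = 0.3`): concentrating Brownian variance on deep
  branches makes the niche conserved at clade level, so a trait window
  corresponds to a phylogenetically coherent set — on an untransformed
  Yule tree the trait tail is a polyphyletic scatter and nearest-taxon
  metrics cannot see the filter.  Second, membership (not just
  abundance) drifts: betaNTI detects selection through *turnover within
  a conserved clade*, and near-identical samples have a degenerate
  tip-shuffle null.  The default optimum sits at the 0.85 trait
  quantile (constant across samples for homogeneous selection; an
  evenly spaced trait-range gradient for variable selection).  With
  these defaults, strong-filtering simulations yield homogeneous
  selection as the modal process and clearly depressed NST relative to
  paired neutral runs.  $\sigma \to \infty$ recovers equal expected
  abundances; $\sigma = 0$ is rejected as a degenerate filter.
* **dispersal_limited** — neutral dynamics, but sample clusters draw
  from independent isolated metacommunities, producing elevated
  between-cluster turnover.

`simulate_study()` lays four cells (2 sites × control/N-addition, 6
samples each, 400 taxa by default) over one shared tree, with pH and
nitrate covariates generated as linear functions of each sample's
selection optimum plus noise so that niche-based downstream analyses
have signal.  The default configuration assembles control cells under
homogeneous selection and N-addition cells neutrally — the pattern in
which nutrient addition relaxes environmental filtering.

What the simulator does **not** emulate: sequencing error and chimeras,
taxon-specific detection bias, compositionality artefacts of relative
abundance data, temporal dynamics, and realistic guild structure.
Passing regime-recovery tests therefore demonstrates that the
statistics respond correctly to known assembly mechanisms in idealised
communities, not that any particular field dataset is measured without
bias.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed, restores the global
RNG state on exit, and derives sub-seeds stably (per pair, per stage)
below $2^{31}$.  Two pipeline runs with the same seed produce
byte-identical numeric outputs.

The shipped analysis scripts and tests use desk-scale sizes chosen to
make each property measurable in seconds to minutes: 24-sample ×
400-taxon studies with 199 null replicates in the workflow; 500-taxon,
10-sample communities with 99 null replicates for regime recovery; a
3-sample × 4-taxon toy against a $10^5$-draw brute-force RC oracle; a
5-tip tree against the exact 120-permutation betaNTI null; 50 samples ×
500 taxa for Sloan parameter recovery.  The statistics scale to real
amplicon tables (thousands of taxa); betaNTI and RC cost grows with
pairs × null replicates, and `n_null = 999` on a full study is a
minutes-to-hours computation, not seconds.

## Known limitations

* betaNTI's magnitude depends on richness and taxon sharing: pairs of
  nearly identical communities have weak or degenerate nulls, and very
  small communities cap attainable $|z|$.
* The NST variant implemented here is one member of a family; absolute
  NST values should be compared within, not across, implementations.
* RMT threshold selection needs enough distinct eigenvalues (roughly
  50+ informative spacings) to be reliable; small or heavily degenerate
  correlation matrices should use a fixed threshold instead.
* The Sloan fit assumes one source metacommunity and equal sample
  sizes; strongly uneven sequencing depths should be rarefied first.
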