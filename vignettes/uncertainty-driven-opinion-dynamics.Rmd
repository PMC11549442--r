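---
title: "Uncertainty-driven opinion dynamics on heterogeneous networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-driven opinion dynamics on heterogeneous networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetcon)
```

## The model

`hetcon` simulates a collective of $N$ agents that hold continuous scalar
opinions about a common quantity and repeatedly exchange them over a
static, connected, undirected network. The package is built to study how
two kinds of heterogeneity shape the path to consensus: heterogeneity of
*information quality* (some agents start better informed than others) and
heterogeneity of *centrality* (some agents have many more neighbors than
others), and how tracking *uncertainty* lets agents adapt to both.

Each agent $i$ starts from a noisy copy of a neutral collective opinion
$x_\mathrm{neutral}$ (interpreted as the ground truth and set to 0 by
default):

$$x_0^{[i]} = x_\mathrm{neutral} + \eta^{[i]}, \qquad
  \eta^{[i]} \sim \mathcal{N}\!\left(0, \sigma_0^{2\,[i]}\right), \qquad
  \sigma_0^{[i]} \sim U\!\left(c_\mathrm{inf} - \tfrac{p_\mathrm{inf}}{2},\,
                              c_\mathrm{inf} + \tfrac{p_\mathrm{inf}}{2}\right).$$

The center $c_\mathrm{inf}$ (default 5) sets the overall noise scale; the
width $p_\mathrm{inf}$ (default 0, studied on $[0, 5]$ so that
$c_\mathrm{inf} - p_\mathrm{inf}/2 > 0$ keeps every standard deviation
positive) sets how unequal the information quality is. Note the
distinction between *diversity* of opinions (the draws $\eta^{[i]}$
differ even when all variances are equal) and *heterogeneity* of
information quality (the variances themselves differ).

### Update rules

All updates are synchronous: every agent computes its new state from the
time-$t$ states of its closed neighborhood $\{i\} \cup \mathbb{N}_i$, so
the result does not depend on agent ordering. Four rules are provided.

**Naive averaging (DeGroot).** The classical linear pooling rule

$$x_{t+1}^{[i]} = w^{[i]} x_t^{[i]} +
  \frac{1 - w^{[i]}}{\lVert\mathbb{N}_i\rVert} \sum_{j \in \mathbb{N}_i} x_t^{[j]},$$

equivalently $x_{t+1} = A x_t$ with a row-stochastic weight matrix $A$
(`build_static_adjacency()`). The self-weight is either a universal
constant $w_\mathrm{global}$ (`rule = "na"`), or locally equal,
$w^{[i]} = 1 / (\lVert\mathbb{N}_i\rVert + 1)$ (`rule = "na-lew"`), which
puts the same weight on every opinion in the closed neighborhood. Because
no universal constant can reflect heterogeneity, we also provide
`optimize_universal_weight()`, which grid-searches
$w_\mathrm{global} \in \{0, 0.1, \dots, 1\}$ for the value minimizing the
Monte-Carlo mean final accuracy error (the tuned rule `"na-ouw"`), and
reports the mean across the whole grid as the untuned baseline (`"na"`).

**Bayesian fusion assuming independence (`"bi-ai"`).** Each agent holds
a Gaussian belief $\mathcal{N}(\mu^{[i]}, \sigma^{2\,[i]})$ and treats
each neighbor's belief as an independent measurement. The fused belief is
the inverse-variance weighted combination over the closed neighborhood:

$$\mu_{t+1}^{[i]} =
  \frac{\sum_{j \in \{i\}\cup\mathbb{N}_i} \mu_t^{[j]} / \sigma_t^{2\,[j]}}
       {\sum_{j \in \{i\}\cup\mathbb{N}_i} 1 / \sigma_t^{2\,[j]}}, \qquad
  \sigma_{t+1}^{2\,[i]} =
  \left(\sum_{j \in \{i\}\cup\mathbb{N}_i} 1/\sigma_t^{2\,[j]}\right)^{-1}.$$

This is a bank of one-dimensional Kalman updates run in parallel; the
test suite checks it against an independently coded sequential Kalman
oracle. Since every neighbor contributes positive precision, variances
decrease strictly and monotonically — agents with more neighbors gain
certainty faster, which is how centrality feeds back into uncertainty.
With homogeneous variances the mean update collapses exactly to the
locally-equal-weight DeGroot step (a useful regression anchor).

**Bayesian fusion assuming unknown dependence (`"bi-ud"`).** After one
round of exchanges opinions are correlated, and tracking the correlations
exactly is intractable, so this rule fuses conservatively: the mean
update is identical to `"bi-ai"`, but the variance is the
precision-squared-weighted average of the neighborhood variances,

$$\sigma_{t+1}^{2\,[i]} =
  \frac{\sum_j 1/\sigma_t^{2\,[j]}}{\sum_j 1/\sigma_t^{4\,[j]}},$$

the scalar form of fast covariance intersection. The fused variance is
always bracketed by the smallest and largest variance in the closed
neighborhood: only agents that start comparatively uncertain gain
certainty, and centrality does not directly reduce uncertainty. We
follow the mean update stated above literally even though generic fast
covariance intersection would weight means by $1/\sigma^4$; the
precision-weighted mean is the modeling choice this package implements.

### Dynamic centrality

For the Bayesian rules the weight matrix is not static: the weight agent
$i$ puts on $j$ is $\left(1/\sigma^{2\,[j]}\right) / \sum_k 1/\sigma^{2\,[k]}$ over the
closed neighborhood (`effective_adjacency()`). Its column sums are the
dynamic in-degree centralities (`in_degree()`): the total influence each
agent currently exerts. This is the only weighting consistent with the
mean update above, and it makes centrality an *observable driven by
relative uncertainty*: a single agent seeded with much lower variance on
an otherwise homogeneous regular graph becomes the most central node in
the first exchange, depresses the centrality of its immediate neighbors
(they mostly listen to it), and loses the centrality peak within a few
steps as certainty propagates outward
(`reproduce_centrality_shift()`).

## Network generators

The network axis of heterogeneity is the spread of the degree
distribution, summarized by the population standard deviation
$\sigma_\mathrm{net}(d) = \sqrt{\tfrac{1}{N}\sum_i (d_i - \langle d\rangle)^2}$
(`degree_std()`; population, not sample, normalization). The star graph
is the centralized extreme; k-regular graphs are the homogeneous
reference ($\sigma_\mathrm{net} = 0$).

* `add_links_model(n, p_w)` adds each peripheral pair to the star
  independently with probability $p_w$, sweeping star → complete graph.
  Degree heterogeneity falls roughly linearly in $p_w$, but the mean
  degree grows, so spectra change along the sweep.
* `replace_links_model(n, p_r)` keeps the mean degree approximately
  constant: add links with probability $p_r$ (recording the count $m$),
  remove $m$ links uniformly from all current links, then reconnect the
  components pairwise (one uniformly chosen node in each of two
  uniformly chosen components per added link) until connected. The
  removal pool deliberately includes the star's own links — the
  the algorithm draws removals from every current link without
  exclusion — and no compensation pass follows reconnection, so the
  mean degree carries a small reconnection surplus (one extra link per
  component left after removal; the acceptance script measures the
  resulting mean degree at $N = 100$). We accept this bias rather than
  silently deleting extra links the algorithm never specifies.
  Experiments use $p_r \in [0, 0.3]$; the heterogeneity reduction
  saturates near the upper end.

Both generators always return connected graphs (the star backbone or the
explicit reconnection loop guarantees it), which the spectral summary
certifies: the leading eigenvalue modulus of any row-normalized weight
matrix on a connected graph is exactly 1 (`spectral_summary()`).
k-regular graphs are sampled with igraph's pairing generator and
resampled until connected, since no particular construction is implied
by the model.

## Mismatched uncertainty assignment

To study errors in uncertainty quantification, opinions are drawn with
the *true* noise ($c^\mathrm{true} = 5$, $p^\mathrm{true} = 0$:
homogeneous information) while the variances agents carry are assigned
differently:

* **Uncorrelated errors** (`sample_mismatched_uncorrelated()`): assigned
  standard deviations drawn from a uniform window centered at
  $c^\mathrm{model} \in [2.5, 7.5]$ with width $p^\mathrm{model} \in [0, 5]$,
  independent of the true noise. $c^\mathrm{model} < 5$ makes the
  collective over-confident on average; $> 5$, under-confident.
* **Centrality-correlated errors**
  (`assign_centrality_correlated_sigma()`):
  $\sigma_0^{[i]} = K^\mathrm{model}\,(1 - \rho^\mathrm{model}\, \lVert\mathbb{N}_i\rVert / N)$,
  with $\rho^\mathrm{model} \in [-1, 1]$ sliding from under-confident
  hubs to over-confident hubs. The scale $K^\mathrm{model}$ is not
  pinned down by the study design; we default it to 5 so the assigned
  scale matches the information scale $c_\mathrm{inf}$, and expose it as
  a parameter. For $\rho \in [-1, 1]$ the assignment is automatically
  positive ($\sigma_0 \ge K/N$); the constructor validates positivity in
  general.

## The Monte-Carlo sweep runner

`run_sweep()` crosses a parameter grid with a set of update rules and
runs `n_reps` full pipeline replicates per cell (fresh graph, fresh
beliefs, `t_steps` updates, final-step metrics). Three design choices
matter for interpreting its output:

* **Paired comparisons everywhere.** Replicate seeds are derived once
  from the master seed and reused in every cell, and all rules within a
  replicate consume the identical graph and initial beliefs. These
  common random numbers sharpen comparisons across rules *and* across
  grid cells substantially; the monotone trend of the normalized
  precision error across an information-heterogeneity grid is within
  Monte-Carlo noise of invisible at small replicate counts without
  them. Cells remain logically independent: dropping a cell changes no
  other cell's numbers.
* **The untuned naive baseline** (`"na"`) is the arithmetic mean of the
  final errors across the 11-point universal-weight grid, computed on
  the same replicates as every other rule; the tuned variant
  (`"na-ouw"`) picks the grid weight with the smallest Monte-Carlo mean
  final accuracy error within the cell and reports that weight's
  replicate metrics.
* **Log-scale heterogeneity grids.** `log_grid()` spaces positive grid
  points geometrically below the maximum with an explicit 0 endpoint,
  concentrating samples near the homogeneous (or star) end where the
  dynamics shift fastest. The spacing ratio (default three decades over
  the grid) is a reporting choice, not a model parameter.

### Performance metrics

`error_decomposition()` splits the mean squared deviation of the
expected opinions from the neutral opinion (accuracy error $E^A$) into
the spread about the collective mean (precision error $E^P$, the
consensus-distance proxy) and the squared bias of the collective mean
(trueness error $E^T$); $E^A = E^P + E^T$ is an algebraic identity that
the suite checks to $10^{-10}$ relative tolerance. Because the horizon
is fixed, the *final precision error normalized by the initial one*
(`E_P_norm`) measures convergence speed. For the Bayesian rules the
expected opinion is the belief mean; for the naive rules it is the
scalar opinion, so the metric applies uniformly.

## Default study conditions and problem sizes

The shipped defaults mirror the study design this package implements:
$N = 100$ agents, $T = 10$ synchronous steps, $c_\mathrm{inf} = 5$,
$x_\mathrm{neutral} = 0$, 100 Monte-Carlo samples per configuration for
published-scale runs. The test suite and the acceptance script run
scaled-down profiles ($N = 50$, 20 replicates per cell for trend tests;
200 seeds for generator statistics), chosen so that each property check
completes in seconds while the qualitative contrasts (Bayesian vs naive
under heterogeneity, the over-confident-central-corner effect) remain
well outside Monte-Carlo noise. A power note: with small replicate
counts the *strict* rank ordering of the normalized precision error
across a six-point information-heterogeneity grid is at the edge of
detectability — adjacent cells in the middle of the grid differ far
less than the endpoints do — so the endpoint contrast is the robust
summary of that trend (the acceptance script reports both the rank
correlation and the endpoint ratio at 100 replicates).

## Numerical choices

* Precision sums are accumulated in double precision with a fixed
  (index-ordered) summation order, so trajectories are bit-reproducible
  for a given seed and agent labeling; relabeling agents permutes
  trajectories up to last-ulp differences from reordered sums.
* Variance positivity is validated at every construction; uniform
  windows must satisfy $c - p/2 > 0$.
* `spectral_summary()` checks row-stochasticity to $10^{-8}$ before
  decomposing and returns moduli sorted descending; eigenvalues come
  from LAPACK via base `eigen()`.
* Ties in the universal-weight search are broken toward the smaller
  weight (first grid minimum), which favors faster averaging.
* Seeds derived from a master seed stay below $2^{31}$ so they are valid
  R RNG seeds on all platforms.

## What the generators do and do not emulate

The synthetic conditions cover: connected static topologies spanning a
centralization spectrum at (approximately) constant mean degree;
Gaussian initial noise with uniformly distributed per-agent standard
deviations; and systematic mis-assignment of variances, uncorrelated or
degree-correlated. They do *not* emulate: dynamic or directed networks,
non-Gaussian or multimodal opinion noise, communication noise, bounded
confidence, zealots or adversarial agents, or multivariate opinions.
Passing tests therefore speak to the model's internal consistency and
its behavior under these stylized conditions, not to any particular
empirical collective.

## Known limitations

* The replacement generator's mean degree is biased high by the
  reconnection surplus (see above); comparisons across $p_r$ hold the
  *approximate*, not exact, mean degree fixed.
* The independence-assuming rule's variances shrink geometrically, so
  after many steps they underflow toward zero; with the default
  $T = 10$ this is far from machine limits, but very long horizons
  would make the effective weights degenerate.
* `optimize_universal_weight()` optimizes offline for a parameter
  setting, as defined; it is not an online adaptive scheme.

## A minimal session

```{r example, eval = FALSE}
g <- replace_links_model(100, p_r = 0.1, seed = 1)
b <- sample_initial_beliefs(100, c_inf = 5, p_inf = 5, seed = 2)
traj <- simulate_opinions(g, b, "bi-ai", record_in_degree = TRUE)
final_metrics(traj)

sw <- run_sweep(data.frame(p_inf = c(0, 5), p_r = 0.1),
                rules = c("bi-ai", "bi-ud", "na-lew", "na"),
                n_reps = 20, n_agents = 50, master_seed = 1)
sw$cells
```
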