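# hetcon

Uncertainty-driven collective opinion dynamics on degree-heterogeneous
networks.

`hetcon` is an R package for simulating how a connected collective of
agents — fish shoals, sensor networks, robot swarms, human groups —
reaches consensus on a continuous quantity when two kinds of
heterogeneity interact: unequal **information quality** (some agents
start with much less noisy estimates) and unequal **centrality** (some
agents have many more neighbors). It is aimed at researchers in
collective behavior and distributed estimation who want a small,
reproducible test bed for comparing static and uncertainty-adaptive
opinion-update rules.

## The model in brief

Each agent `i` starts from a noisy copy of a neutral opinion
(ground truth, 0 by default):

    x0[i] = x_neutral + eta[i],   eta[i] ~ N(0, sigma0[i]^2),
    sigma0[i] ~ U(c_inf - p_inf/2, c_inf + p_inf/2)

with `c_inf = 5` and `p_inf in [0, 5]` controlling the heterogeneity of
information quality. Agents then update synchronously for `T = 10`
steps under one of four rules:

* **na** — DeGroot averaging with a universal self-weight
  `w_global` (the package also reports the mean over the grid
  `{0, 0.1, ..., 1}` as the untuned baseline, and the best grid weight
  as **na-ouw**);
* **na-lew** — DeGroot averaging with locally equal weights
  `w[i] = 1/(deg_i + 1)`;
* **bi-ai** — Bayesian fusion assuming independence: each agent fuses
  its closed neighborhood by inverse-variance weighting (a bank of 1-D
  Kalman updates), `mu' = (Σ mu/σ²)/(Σ 1/σ²)`, `σ²' = 1/(Σ 1/σ²)`;
* **bi-ud** — Bayesian fusion assuming unknown dependence: same mean
  update, conservative variance `σ²' = (Σ 1/σ²)/(Σ 1/σ⁴)` (scalar fast
  covariance intersection).

Performance is scored by the error decomposition
`E_A = E_P + E_T`: precision error (spread about the collective mean,
a convergence-speed proxy at fixed horizon), trueness error (squared
collective bias), accuracy error (total). Centrality is the column sum
of the row-stochastic weight matrix, which for the Bayesian rules is
*dynamic* — weights follow relative uncertainties
(`effective_adjacency()`).

Networks come from two generators spanning a centralization spectrum:
`add_links_model()` (star → complete, adding peripheral links with
probability `p_w`) and `replace_links_model()` (add with probability
`p_r`, remove the same number of links uniformly, reconnect components
— approximately constant mean degree while the degree heterogeneity
`degree_std()` falls). Mismatched uncertainty assignment
(`sample_mismatched_uncorrelated()`,
`sample_centrality_correlated()`) models collectives that misjudge
their own information quality, uniformly or as a function of degree.

## Worked example

```r
library(hetcon)

g <- replace_links_model(100, p_r = 0.1, seed = 1)
degree_std(g)            # 1.893  (star would be 9.751, k-regular 0)

b <- sample_initial_beliefs(100, c_inf = 5, p_inf = 5, seed = 2)
b
#> <belief_state> 100 agents
#>   mu:     mean 0.09635, range [-14.76, 14.95]
#>   sigma2: mean 26.79, range [6.429, 55.42]

traj <- simulate_opinions(g, b, "bi-ai")
traj
#> <opinion_trajectory> rule bi-ai, 100 agents, 10 steps
#>   final: x_col = -0.07202, E_P = 0.2503, E_T = 0.005187, E_A = 0.2555
head(traj$metrics, 4)
#>   step  x_col     E_P    E_T     E_A E_P_norm
#> 1    0 0.0964 36.9094 0.0093 36.9187   1.0000
#> 2    1 0.2953  9.8594 0.0872  9.9466   0.2671
#> 3    2 0.2884  3.9625 0.0832  4.0457   0.1074
#> 4    3 0.2193  1.9271 0.0481  1.9752   0.0522
```

The initial opinion spread (`E_P = 36.9`, matching the mean assigned
variance) collapses by two orders of magnitude over ten fusion steps,
while the collective mean stays within a fraction of an opinion unit of
the neutral truth (`E_T` small): fast, nearly unbiased consensus.

Comparing rules under low and high information heterogeneity
(20 paired Monte-Carlo replicates, 50 agents):

```r
sw <- run_sweep(data.frame(p_inf = c(0, 5), p_r = 0.1),
                rules = c("bi-ai", "bi-ud", "na-lew", "na"),
                n_reps = 20, n_agents = 50, master_seed = 1)
sw$cells[, c("p_inf", "rule", "E_A")]
#>   p_inf   rule    E_A
#> 1     0  bi-ai 1.5260
#> 2     0  bi-ud 2.2025
#> 3     0     na 5.6479
#> 4     0 na-lew 2.2025
#> 5     5  bi-ai 1.4827
#> 6     5  bi-ud 1.5853
#> 7     5     na 7.1288
#> 8     5 na-lew 2.7832
```

With homogeneous information (`p_inf = 0`) the conservative Bayesian
rule coincides exactly with locally-equal-weight averaging (equal
variances stay equal), and the untuned universal-weight baseline is far
worse than either. Under high heterogeneity (`p_inf = 5`) both
uncertainty-driven rules pull ahead of every static scheme because
their weights adapt to who actually knows more.

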