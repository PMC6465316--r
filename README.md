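# netrecover

Reconstruction of partially observed networks whose missing part was
produced by an **adversarial, degree-targeted node-removal process** —
not by random sampling.

## The problem

Many real networks are observed only after an attacker has removed part of
them: viral attackers interfere with hub proteins in interactomes, targeted
failures strip hubs from infrastructure, and injected agents hide inside
social networks. An attacker that removes one node per step with
probability

```
A_alpha(d_i, t) = d_i^alpha / sum_j d_j^alpha        (degrees of the current graph)
```

reshapes the distribution of the missing structure: for `alpha > 0` the
removed nodes are hubs, for `alpha < 0` boundary nodes, and `alpha = 0` is
the uniform deletion that classical network-completion methods assume.
Ignoring the attack therefore biases any model fitted to the residual
network.

`netrecover` infers both the generative model of the original network and
its missing substructure by combining:

* a **multifractal network generator (MFNG)** `G_k = (m, k, P, L)`: every
  node carries a category sequence `c` in `{1..m}^k`, and nodes `i, j`
  link independently with probability `p(c_i, c_j) = prod_l P[c_i(l), c_j(l)]`;
* the **attack model** above, entering the complete-data log-likelihood
  with a discount weight `gamma`
  (`log P = log P_model + gamma * log P_attack`; `gamma = 0` is the
  attack-blind baseline);
* a **Monte-Carlo EM** loop: the E-step Gibbs-samples removal trajectories
  and category assignments (exact rejection draws of restoration paths,
  Metropolis edge-rewiring, link-toggle and category-swap chains), and the
  M-step updates `P` by batch gradient ascent on the Monte-Carlo
  Q-function with a step-halving ascent guarantee.

Outputs are the fitted generating measure, per-pair posterior link scores
for the missing structure, and evaluation metrics (permutation-aligned
Frobenius error `e_F`, signed divergence of link probabilities, degree
Kolmogorov-Smirnov distance `e_KS`, ROC/PR areas, log-likelihood), plus an
injected-node coverage analysis for hidden-agent studies.

## Worked example

Attack a synthetic MFNG network, then reconstruct it with the attack-blind
baseline (`gamma = 0`) and the causal likelihood (`gamma = 1`):

```r
library(netrecover)
set.seed(7)

truth <- random_mfng_measure(m = 2, k = 6, range = c(0.4, 0.95))
assignment <- enumerate_categories(truth, paste0("v", 1:64))
g0 <- sample_network(truth, assignment)     # 64-node original network
attack <- simulate_attack(g0, alpha = 10, steps = 19)  # hub attack, 30%

cfg <- em_config(K = 2000, B = 500, sigma = 1, swap_steps = 60,
                 proposal_budget = 20, tol = 1e-4, max_iter = 20)
fit_base <- run_em(attack$residual, steps = 19,
                   intervention_model(alpha = 10, gamma = 0),
                   cfg, m = 2, k = 6, n_starts = 3)
fit_caus <- run_em(attack$residual, steps = 19,
                   intervention_model(alpha = 10, gamma = 1),
                   cfg, m = 2, k = 6, n_starts = 3)

c(e_F_baseline = frobenius_error(fit_base$measure, truth),
  e_F_causal   = frobenius_error(fit_caus$measure, truth))
#> e_F_baseline   e_F_causal
#>    0.4559714    0.2982896
c(kl_baseline = signed_kl_divergence(truth, fit_base$measure),
  kl_causal   = signed_kl_divergence(truth, fit_caus$measure))
#> kl_baseline   kl_causal
#>  0.08457015  0.01940900
head(fit_caus$scores[order(-fit_caus$scores$score), ], 3)
#>        from  to     score
#> 42 latent_1 v61 0.2040000
#> 27 latent_1 v41 0.1913333
#> 1  latent_1  v3 0.1893333
```

The attack-blind baseline underestimates the link probabilities of the
missing hubs: its measure-recovery error `e_F` is half again as large and
its signed divergence is strongly positive, while the causal fit sits
close to the truth. `fit$scores` ranks candidate missing links by their
posterior frequency (here the posterior is diffuse — one removed hub has
many plausible attachments — which the scores report honestly).
`run_em(..., n_starts = 3)` averages permutation-aligned restarts, which
stabilises the non-convex fit.

The same machinery drives three packaged studies
(`run_synthetic_recovery()`, `run_real_reconstruction()`,
`run_injection_coverage()`), a fixture generator (`make_fixture()`), and a
CLI (`inst/cli/netrecover.R`) with `recover-synthetic`, `recover-real`,
`injection` and `fixtures` subcommands (`--paper-scale` switches to the
full-size configuration `n = 1024`, `K = 40000`, `B = 10000`; hours-long).
Loaders are provided for SNAP-style edge lists, adjacency CSVs and
two-column interaction tables.

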