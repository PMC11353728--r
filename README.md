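# spreadrank

Ranking influential spreaders (superspreaders) in undirected networks from
spatiotemporal ego-subnetwork features.

## The problem

In epidemic and information-diffusion settings, a node's *influence* is its
spreading ability: the expected final outbreak size of a
susceptible–infected–recovered (SIR) epidemic seeded at that node. Classical
centralities (degree, k-shell, betweenness, ...) are static proxies for this
dynamic quantity. `spreadrank` implements a learned ranking pipeline for
epidemiologists and network scientists who need to find superspreaders in
empirical contact, infrastructure or social networks:

1. **Ground truth by simulation.** Discrete-time SIR Monte-Carlo with
   recovery probability 1: a newly infected node infects each susceptible
   neighbour independently with probability β, then recovers. The per-node
   mean outbreak size over many repetitions is the influence label
   `Rank ∈ ℝ^N`. By default β is the degree-based mean-field epidemic
   threshold β_th = ⟨k⟩/⟨k²⟩, the critical infection rate.
2. **Structure-matched training networks.** Instead of training on the
   empirical network itself (or on a generic random graph), a dk-series
   null model copies its structure at increasing fidelity: 0k (size and
   mean degree), 1k (degree distribution P(k)), 2k (joint degree
   distribution P(k₁,k₂)), 2.25k (+ mean clustering C̄) and 2.5k
   (+ degree-dependent clustering C̄(k)), realised by constraint-preserving
   double-edge swaps with greedy clustering targeting.
3. **Ego-subnetwork features.** Each node gets a fixed-size subnetwork: the
   node plus its L−1 highest-degree neighbours (padded when fewer), where L
   is the rounded mean degree of the top-10% highest-degree nodes. Six
   centralities computed on the induced subgraph — DC, EC, HITS, CC, BC,
   k-shell — min-max scaled per subnetwork, give an N×L×6 feature tensor.
4. **A spatiotemporal scorer.** Per subnetwork, a graph convolutional
   encoder (H⁽ˡ⁺¹⁾ = σ(D̃^−1/2 Ã D̃^−1/2 H⁽ˡ⁾ W⁽ˡ⁾), Ã = A+I) produces a
   spatial representation, and an LSTM over the member sequence — each
   step's input is the member's features concatenated with its row of an
   N×N *history matrix* of earlier subnetworks' results — produces a
   temporal one; both are batch-normalised and summed. A heuristic local
   loop trains the encoders on the subnetwork MAE loss and writes the
   output with the best Kendall agreement into the history matrix; an MLP
   head over history rows, trained on the network-wide MAE loss, yields the
   global influence score Is ∈ ℝ^N.
5. **Evaluation.** Kendall rank correlation τ against SIR labels, classical
   baselines (including DC⁺ = deg(v) + Σ_{u∈N(v)} deg(u)), and
   multi-source spreading experiments seeded at the top-5 ranked nodes at
   β = 1–2 × β_th.

All neural components are transparent base-R matrix code with analytic
gradients (verified against finite differences in the test suite); the SIR
engine is compiled C++ driven by R's RNG, so every result is reproducible
from a single seed.

## Worked example

```r
library(spreadrank)
g <- karate_club()
network_summary(g)
#> Network summary
#>   nodes N:              34
#>   edges (undirected):   78   [ordered-pair count: 156]
#>   mean degree 2E/N:     4.588   [doubled convention: 9.176]
#>   mean clustering:      0.571
#>   max k-shell:          4
#>   epidemic threshold:   0.129

labels <- sir_labels(g, reps = 10000, seed = 1)   # beta = 0.129 (threshold)
fit <- spreadrank(g, labels = labels, epochs = 5, local_steps = 5, seed = 1)
summary(fit)
#> Spatiotemporal node-influence model
#>   N = 34, L = 15, epochs = 5, local steps = 5
#>   final global MAE:        0.00327
#>   training-network Kendall: 0.9929

top_spreaders(fit$scores, 5)
#> [1] 34  1 33  3  2
kendall_tau(baseline_scores(g, "dc"), labels)
#> [1] 0.7656738
```

The summary says: with subnetwork size L = 15 the fitted scores agree with
the simulated SIR influence ranking at Kendall τ = 0.993, versus 0.766 for
plain degree centrality. The top-5 spreaders are the two club leaders
(nodes 1 and 34) and their lieutenants — exactly the nodes whose seeding
maximises outbreaks:

```r
spread_experiment(g, top_spreaders(fit$scores, 5), reps = 10000, seed = 1)
#>   multiplier      beta mean_recovered mean_fraction
#> 1        1.0 0.1287129        12.1338     0.3568765
#> 2        1.2 0.1544554        13.5499     0.3985265
#> ...
#> 6        2.0 0.2574257        19.0079     0.5590559
```

For the transfer setting — train on a structure-matched copy, rank the
real network — generate a null model first:

```r
nm  <- generate_null(g, order = "2.5k", tol = 0.05, seed = 1)
fit <- spreadrank(nm$graph, reps = 10000, seed = 1)
scores <- predict(fit, g)
```

A thin command-line wrapper over these functions is installed at
`inst/cli/spreadrank.R` (subcommands `label`, `nullmodel`, `generate`,
`rank`, `evaluate`, `spread`, `pipeline`), and `run_pipeline()` executes
the whole chain from a YAML/JSON config with a reproducible manifest.

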