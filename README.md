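# molpath — chain-aware graph neural networks for molecular property prediction

Most molecular graphs are chains with few triangles: the average clustering
coefficient of drug-like datasets sits near zero. Under ordinary
message-passing GNNs this topology forces information between distant atoms
through many rounds of fixed-width neighbourhood averaging, where it gets
squashed. `molpath` implements a chain-aware alternative for anyone fitting
molecular property models (regression or multi-task classification) from
SMILES: convolution along exact-length shortest paths.

## The model

For a molecular graph with embedded atom features
`H(0) = X W_in + b_in`, layer *k* = 1..K computes

```
H~      = BatchNorm( (1 − λ) H(0) − λ Σ_{j<k} H(j) )        # IRDC input
enc(p)  = LSTM over H~ rows of each length-k geodesic p,
          traversed end-to-start; final hidden state kept
H(k)_v  = MLP( LayerNorm( Σ_{p starts at v} enc(p) + H(k−1)_v ) )
```

where a *geodesic* of length k is a simple path whose length equals the
graph distance between its endpoints, enumerated by depth-limited DFS (at
most `n·b^K` paths, `b` = max degree ≤ 4 for organic skeletons). The IRDC
(initial residual difference connection) feeds each layer the initial
features minus what previous layers already extracted, suppressing
inter-layer redundancy. The readout weighs hop distances per atom,

```
ω_{v,k} = softmax_k( ⟨W_att H(0)_v , W_att H(k)_v⟩ / d )
H_g     = MeanPool_v( H(0)_v + Σ_k ω_{v,k} H(k)_v )
ŷ       = MLP(H_g)
```

Classification trains with masked binary cross-entropy on logits,
regression with the L1 loss; metrics are macro ROC-AUC and RMSE. The whole
network — LSTM backpropagation through time, both normalizations, the
attention softmax, Adam — is implemented in base R matrix operations and
validated against finite differences.

## Worked example

The synthetic benchmark generates low-clustering chain molecules whose
target — the number of atom pairs exactly 4 bonds apart — is a long-range
structural count by construction:

```r
library(molpath)
train <- generate_chain_molecules(96, c(8, 16), target = "distance_pair_count",
                                  k_star = 4, noise_sd = 0.1,
                                  relative_noise = TRUE, seed = 1)
valid <- generate_chain_molecules(32, c(8, 16), target = "distance_pair_count",
                                  k_star = 4, noise_sd = 0.1,
                                  relative_noise = TRUE, seed = 2)
dataset_topology(train)
#> <topology_report> 96 graphs, 1141 nodes
#>   average clustering coefficient: 0.0000
#>   max degree b: 4

fit <- molpath(train, valid = valid, K = 4, hidden = 32, lambda = 0.5,
               lr = 3e-3, epochs = 25, seed = 0)
print(fit)
#> Chain-aware path-convolution model (regression, 1 task)
#>   K = 4 layers, hidden = 32, lambda = 0.50, pool = mean
#>   trained 25 epoch(s); best validation epoch 22 (RMSE = 1.158)

predict(fit, c("CCCCC", "CCCCCCCCC"))
#>   distance_pair_count
#> 1            1.554467
#> 2            5.158400
```

Pentane has exactly 1 atom pair 4 bonds apart and nonane has 5; the model
recovers both from SMILES alone. `evaluate_molpath(fit, valid)` reports the
validation RMSE (1.16 here, against a target spread of ~5), and
`run_ablation()` / `lambda_sweep()` refit the no-IRDC and no-attention
variants or sweep λ under identical seeds.

Real datasets enter through `read_dataset("data.csv", "smiles", task_cols,
task_type)` with `split_dataset(..., method = "random" | "scaffold")`. A
command-line front end (`inst/cli/molpath.R`) wires the same functions into
`stats`, `synth`, `train`, `predict` and `ablate` subcommands with a JSON
run manifest.

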