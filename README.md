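# hetdta

Drug-target binding affinity (DTA) prediction for computational chemists and
method developers who want the whole pipeline — from SMILES strings,
protein sequences and contact maps to evaluated predictions — in one R
package with no external services.

Most graph-network DTA models encode each drug and protein in isolation.
`hetdta` additionally builds one **dataset-level heterogeneous graph**: all
drugs and proteins are nodes, connected by

- drug-drug Tanimoto similarity of Morgan/ECFP fingerprints,
  `|a∧b| / (|a|+|b|−|a∧b|)`,
- protein-protein Needleman-Wunsch global-alignment similarity (BLOSUM62,
  affine gaps), normalised by self-alignment scores, and
- the observed drug-protein affinity block `B` (training pairs only — test
  labels never enter the graph).

The block adjacency `Â = [[S_d, B], [Bᵀ, S_p]]` is pruned by two **learnable
thresholds**, `φ(Â) = [[ReLU(S_d − w1), B], [Bᵀ, ReLU(S_p − w2)]]`, updated
by backpropagation, so the model learns how much similarity structure to
keep. Node features `ψ(H) = [D | φ(Â)₁]` (type one-hot next to the
binarised adjacency) are propagated by two symmetric-normalised
graph-convolution layers. Per-molecule branches run in parallel: two
multi-head graph-attention (GAT) layers over the drug's atom graph plus a
fingerprint embedding, and three graph-isomorphism (GIN) layers with
self-attention top-k pooling (ratio 0.5: a 961-node residue graph keeps 481
nodes) over the protein's residue graph. The concatenated embeddings feed a
three-layer head trained with Adam on mean squared error (or
cross-entropy for binary interaction data).

The forward pass *and* the exact reverse-mode gradients — including the
gradient of the loss with respect to the pruning thresholds through the
degree normalisation — are implemented in the package itself (base R matrix
code plus small C++ kernels), verified against finite differences.
Regression metrics are MSE, concordance index (CI) and rm²; classification
adds precision, recall, F1, AUROC and AUPR, with a top-percentile error
report that groups large errors by compound and by target.

## Worked example

Generate a self-contained synthetic dataset (valid drug-like SMILES, random
protein sequences with banded contact maps, affinities planted as
`5·tanimoto(d, d_ref) + 3·nwsim(p, p_ref) + N(0, 0.1²)`), fit the model at
desk scale, and inspect it:

```r
library(hetdta)

ds  <- synthetic_dataset(synthetic_spec())   # 20 drugs x 30 proteins, seed 42
cfg <- hetdta_config(profile = "desk", epochs = 200, seed = 42)
fit <- hetdta(ds$drugs, ds$proteins, ds$affinities, cfg,
              Sd = ds$Sd, Sp = ds$Sp)
print(fit)
#> Heterogeneous-graph drug-target affinity model
#>   variant: full | task: regression | profile: desk
#>   20 drugs x 30 proteins, 600 affinity records
#>   trained 82 epochs (best validation at 32)
#>   test: MSE 0.0156 | CI 0.9154 | rm2 0.9792 (n=100)

coef(fit)            # learned edge-pruning thresholds
#>        w1        w2
#> 0.1427256 0.1119367
```

The test MSE (0.0156) sits close to the planted noise floor (σ² = 0.01) and
the concordance index says 92% of comparable test pairs are ranked
correctly; both thresholds drifted up from their 0.1 start — the model
chose to prune the weakest similarity edges on both sides. `plot(fit)` shows the
loss curve and the threshold trajectories; `predict(fit, pairs)` scores new
pairs of known molecules; `outlier_report()` breaks down the largest errors
by compound and protein. `hetdta_config(profile = "paper")` switches to the
full-scale published hyperparameters (embeddings 256/1024/128, head
1024/512/1, batch 512, 4000 epochs available via `epochs`).

Every building block is exported and usable alone: `morgan_fingerprint()`,
`tanimoto()`, `nw_score()` / `nw_score_blosum()`, `smiles_to_graph()`,
`contact_map_to_graph()`, `drug_similarity_matrix()`,
`protein_similarity_matrix()`, `dynamic_threshold()`, `gcn_propagate()`,
`gat_update()`, `gin_update()`, `sag_pool()`, `concordance_index()`,
`rm2()`, and so on. A thin command-line wrapper lives at
`inst/cli/hetdta.R` (`synth`, `build-sim`, `train`, `evaluate`).

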