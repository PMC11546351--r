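# nfsadti

Drug–target interaction (DTI) prediction from SMILES strings and protein
sequences, for computational chemists and method developers who want a
fully inspectable, single-machine implementation of a bilinear-attention
DTI architecture with molecular-level interpretability.

## The model

A pair (drug `G`, protein `P`) is mapped to an interaction probability
`p ∈ [0,1]`:

* **Protein encoder** — a learnable residue embedding (23-token vocabulary,
  zero pad row) followed by three valid 1D convolutions (kernels 3/6/9,
  batch norm, ReLU) and a multi-head self-attention enhancing unit over the
  sequence axis, giving substructure representations
  `Hp ∈ R^{M×e}` (`M = L − 15` for sequence length `L`).
* **Drug encoder** — the SMILES is parsed to a molecular graph (atom
  element/degree/charge/aromaticity features, typed bonds, self-loops). A
  trainable *neural fingerprint* `f = Σ_i softmax(relu(v_i Hh) Wo)` — with
  `v_i` the sum of atom `i`'s and its neighbors' embeddings — conditions
  three message-passing layers (`m_ij = relu(W[h_i, h_j, e_ij])`, sum
  aggregation, `h_i' = relu(W[h_i, m_i, f])`), giving per-atom states
  `Hd ∈ R^{N×h}`.
* **Fusion** — per attention head, the low-rank bilinear interaction map
  `I = ((1 qᵀ) ∘ relu(Hd U)) relu(Hp V)ᵀ ∈ R^{N×M}` scores every
  atom–substructure pair; bilinear pooling (shared U, V) gives a joint
  vector, and *attention pooling* reweights it by softmax cell weights
  `W_ij = softmax(b_aᵀ tanh(u_a I_ij))`. Head outputs are summed.
* **Decoder** — one hidden ReLU layer and a sigmoid. Training minimizes
  `L = −Σ_i [y_i log p_i + (1−y_i) log(1−p_i)] + (λ/2)‖Θ‖²` with Adam;
  the best-validation-AUROC checkpoint is kept, and accuracy / sensitivity /
  specificity are reported at the optimal-F1 threshold frozen on the
  validation set.

Gradients come from a small reverse-mode autodiff engine built into the
package (R has no autograd framework); it is verified against finite
differences in the test suite. SMILES parsing uses OpenBabel via
ChemmineOB/ChemmineR.

Because real DTI benchmarks need large downloads and long training, the
package ships a synthetic benchmark generator with a *planted* mechanism:
a pair interacts iff the drug contains a carboxylate fragment AND the
protein contains a 4-mer motif, with stratified negatives, configurable
positive:negative ratio, and label noise. The planted ground truth makes
end-to-end learning and attention-based binding-site recovery objectively
checkable.

## Worked example

Training a 500-pair noiseless synthetic benchmark (about 4 minutes on one
CPU):

```r
library(nfsadti)

syn <- generate_dti_dataset(synthetic_spec(n_samples = 500, label_noise = 0, seed = 41))
fit <- nfsa_dti(syn$data, dti_config_small(epochs = 40L, lr = 3e-3,
                                           batch_size = 16L, lambda = 1e-3),
                seed = 5)
print(fit)
#> Drug-target interaction model (neural fingerprint + self-attention)
#> DTI model configuration
#>   protein: max_len 120 | embed 32 | kernels 3/6/9 | filters 32/32/32 | SA heads 2
#>   drug:    max_nodes 290 | embed 32 | hidden 32/32/32 | fingerprint 32
#>   fusion:  bilinear 64 x 2 heads | attention pooling (global)
#>   train:   lr 0.003 | epochs 40 | batch 16 | lambda 0.001
#>   data:    350 train / 50 validation / 100 test
#>   best epoch 33 of 40 | validation AUROC 0.9840 | threshold 0.9800 (validation)

dti_evaluate(fit)          # held-out test metrics at the frozen threshold
#> AUROC 0.9345 | AUPRC 0.9612 | acc 0.8700 | sens 0.7636 | spec 1.0000 (threshold 0.9800; 55 pos / 45 neg)

## interpretability on a held-out positive pair
idx <- as.integer(rownames(fit$split$test))
k <- idx[which(syn$truth$has_drug_motif[idx] & syn$truth$has_protein_motif[idx])[1]]
syn$data$smiles[k]                       # planted carboxylate = atoms 9-11
#> [1] "C(c1ccccc1)C(C(=O)O)C"
e <- explain(fit, syn$data$smiles[k], syn$data$sequence[k])
round(e$atoms$scores, 3)   # per-atom simplex, SMILES atom order
#>  [1] 0.005 0.022 0.055 0.098 0.071 0.098 0.055 0.006 0.164 0.227 0.145 0.054
```

`print(fit)` reports the data split, the best epoch by validation AUROC,
and the frozen threshold; `dti_evaluate()` reports AUROC/AUPRC plus
accuracy, sensitivity and specificity at that threshold. Atom scores are
the head-summed, zero-clipped row marginals of the bilinear interaction
map, normalized over real atoms: here the three planted carboxylate atoms
carry 0.54 of the attention mass against a uniform baseline of 0.25.
Across all held-out pairs with a planted drug marker, the mean mass ratio
over the uniform baseline is 4.2 (one-sided permutation p = 0.005,
`motif_recovery()`).

A thin command-line front end over the same functions lives at
`inst/cli/nfsa.R` (`train` / `eval` / `predict` / `explain` / `synth`).

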