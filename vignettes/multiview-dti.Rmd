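---
title: "Multiview heterogeneous-network drug-target interaction prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiview heterogeneous-network drug-target interaction prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The prediction problem

Drug-target interaction (DTI) prediction asks, for a small molecule $u$ and a
protein $v$, whether the pair interacts. `hetdti` treats the question as link
prediction on a heterogeneous biological network with four node types (drugs,
proteins, diseases, side effects) and six undirected binary edge types
(drug-protein — the prediction target — plus drug-drug, protein-protein,
drug-disease, protein-disease and drug-side-effect associations). Three views
of the data are fused:

1. **Drug structural view.** Each SMILES string is parsed into a heavy-atom
   graph with bond adjacency $A$ and interatomic distances $D$. A stack of
   multi-head self-attention layers scores atom pairs with a three-component
   mixture per head $i$:
   $$\mathcal{A}^{(i)} = \left(\mu_b\,\rho\!\left(\tfrac{Q_iK_i^\top}{\sqrt{d_k}}\right) + \mu_a\, g(D) + \mu_c\, A\right) V_i,$$
   where $\rho$ is a masked row-wise softmax and $g(D)$ a row-stochastic
   distance kernel. Residual connections and feed-forward sublayers follow
   each attention sublayer; masked mean pooling over real atoms yields the
   drug vector $S_{\mathrm{drug}}$.
2. **Protein sequence view.** Sequences are sanitized to the 20 standard
   amino acids plus the universal token X (B, O, U, Z map to X), embedded
   per residue, and mean-pooled:
   $S_{\mathrm{protein}} = \frac1n \sum_{i=1}^n H_i$.
3. **Relational view.** Two meta-paths supply higher-order neighborhoods:
   drug-protein-drug (drugs sharing a target) and
   protein-disease-protein-drug (drug context reached through
   disease-mediated protein similarity). For a node $v$ with meta-path
   neighbors $N_v$, node-level attention aggregates
   $$f_v = \sigma\!\left(\tfrac1K \sum_{k=1}^{K} \sum_{u \in N_v} \alpha_{uv}\, W_k f_0(u)\right), \qquad
   \alpha_{uv} = \mathrm{softmax}_{u \in N_v}\!\big(\mathrm{AconC}(a_k^\top [W_k f_0(u) \,\|\, W_k f_0(v)])\big),$$
   with $f_0$ the learnable free node embeddings and AconC the adaptive
   activation $(p_1-p_2)\,x\,\mathrm{sigmoid}(\beta (p_1-p_2) x) + p_2 x$.
   Semantic-level attention (`semantic_attention()`) weighs several
   meta-paths per node set; with the two default paths each node type sees
   exactly one path, so the semantic softmax is a singleton and the weights
   are 1.

The fusion heads map each side to a common space:
$$f_{\mathrm{drug}} = \mathrm{L2Norm}\big(\mathrm{ReLU}([\,\mathrm{mate}_{DPD} \,\|\, E_{\mathrm{drug}} + \mathrm{L2Norm}(S_{\mathrm{drug}})\,] W_0 + b_0)\big)$$
and analogously for proteins with $\mathrm{mate}_{PDPD}$ and
$S_{\mathrm{protein}}$. Pairs are scored with the inner-product decoder
$p_{uv} = \mathrm{sigmoid}(f_u^\top f_v)$, and training minimizes
$$\mathcal{L} = \mathcal{L}_{CE} + \lambda_1 \lVert \hat A_{\mathrm{drug}} - A_{\mathrm{drug}}\rVert_F^2 + \lambda_2 \lVert \hat A_{\mathrm{protein}} - A_{\mathrm{protein}}\rVert_F^2,$$
with $\mathcal{L}_{CE}$ the summed cross-entropy over drug-protein training
pairs and $\hat A = \mathrm{sigmoid}(F F^\top)$ the graph-autoencoder
reconstruction of the within-type adjacencies from the fused rows.

# Tunable parameters

`train_config()` carries the defaults: 3000 optimizer steps (Adam), batch
size 128, learning rate 0.001, dropout 0.1 (applied to the concatenated
fusion input, inverted-dropout scaling), relational-view width 1024, 16
molecular attention heads, stack depth 8, and 10 sampled negatives per
positive. $\lambda_1 = \lambda_2 = 1$. The attention mixture weights
$(\mu_a, \mu_b, \mu_c)$ default to equal thirds and the AconC parameters to
$(p_1, p_2, \beta) = (1, 0, 1)$; both are fixed hyperparameters rather than
trained, exposed through `mat_params()` and `attention_params()`. The
node-level attention uses $K = 1$ head and an ELU output nonlinearity by
default; `score_activation = "leaky_relu"` restores the classic
graph-attention scoring.

For the synthetic study bundle shipped with the package we use a
relational-view width of 64 and 500 optimizer steps — the bundle has 100
drugs and 150 proteins, and these sizes are well matched to a problem two
orders of magnitude smaller than a public DTI network.

# Design choices in detail

**Distance source for molecular graphs.** `smiles_to_graph()` can take
interatomic distances from a generated 3D conformer (`distance = "embed3d"`,
OpenBabel forcefield embedding) or from topological shortest paths on the
bond graph. Conformer generation is not seedable from R and produces
slightly different geometries on repeated calls, so the training pipeline
defaults to topological distances; every result in the package is then a
pure function of the configured seed. The `distance_source` field records
which source produced a graph, and embedding failures fall back to
topological distances rather than aborting a run.

**Distance kernel $g(D)$.** Row-wise softmax of $-D$ restricted to real
atoms (default), or row-normalized $\exp(-D)$. Both keep all three attention
components row-stochastic so the $\mu$ weights are directly comparable.

**Atom features.** Element one-hot over C/N/O/S/P/F/Cl/Br/I plus "other",
degree scaled by 1/4, a cyclic-environment flag (2-core membership of the
bond graph), and formal charge. Hydrogens are implicit: heavy atoms only,
which keeps the 100-atom cap meaningful.

**Protein encoder.** The built-in encoder hashes the 3-mer starting at each
residue (X-padded at the end) into 512 buckets and assigns each bucket a
fixed row of a seeded Gaussian projection. It is deterministic, needs no
downloaded weights, and exercises every downstream contract. A pretrained
protein language model can be plugged in by implementing an
`embed_sequence()` method for its own encoder class with the same
one-row-per-residue output; its embeddings would simply replace the hashed
features. Only inference-time embedding is in scope.

**Frozen encoders with trainable adapters.** The drug and protein encoders
act as deterministic, seeded featurizers; their pooled outputs are
column-centered (pooled outputs of untrained encoders carry a large
component shared by every entity; centering exposes the discriminative
part), row-normalized, and passed through a trainable linear adapter per
view — the encoder's final projection trains jointly with the rest of the
model, while the attention stacks beneath stay fixed. Gradients flow through
the relational view, the free embeddings, the adapters and the fusion head;
all backward passes are hand-derived and verified against central finite
differences in the test suite.

**Stability under class imbalance.** With 10 negatives per positive, the
summed cross-entropy applies a near-uniform repulsive pressure to almost
every pair, and because ReLU + L2 normalization makes fused rows
nonnegative, "every unit dead" is an absorbing state that plain minibatch
SGD reliably falls into. Two measures prevent this, both enabled by
`balanced_batches = TRUE` (default): each minibatch is stratified to hold
equal numbers of positive and negative pairs, and the reconstruction terms
are computed per step on balanced entry minibatches (all within-type
positive entries plus an equal-size random sample of zeros). The exact dense
Frobenius form remains the definition in `reconstruction_loss()` and is what
tests assert against. Setting `balanced_batches = FALSE` restores uniform
sampling with dense reconstruction.

**Zero-row safety.** L2 normalization of an all-zero row returns the zero
row, so ReLU-silenced rows can never produce NaNs; such rows score
$\mathrm{sigmoid}(0) = 0.5$ against everything. Probabilities inside the
cross-entropy are clipped to $(10^{-7}, 1 - 10^{-7})$.

**Meta-path conventions.** A node is never its own meta-path neighbor (the
diagonal is zeroed): self-information already enters through the free
embedding, and self-loops would dominate attention. Path counts are
binarized by default (`count_paths = TRUE` keeps multiplicities) because the
attention weights, not path counts, decide neighbor importance. Nodes left
without meta-path neighbors on sparse graphs fall back to their own
transformed embedding, which keeps the softmax well-defined. The
protein-disease-protein-drug path ends at drugs; proteins attend over the
drugs it reaches, which is how a protein-side meta-path feature of protein
dimensionality arises.

**Edge splitting.** Positives are partitioned into $k = \mathrm{round}(1 /
\mathit{test\_fraction})$ folds by a permutation that depends only on the
seed, so the $k$ folds of one seed partition the positive set exactly once.
Negatives are sampled uniformly without replacement from unobserved pairs,
once per seed, and partitioned into the same folds — train and test both
keep the configured ratio. Held-out positives are removed from the
drug-protein adjacency before meta-path construction, so no test edge leaks
into message passing. Indices are 1-based throughout (split manifests record
`index_base` explicitly).

# The synthetic data generator

`synthetic_spec()` defaults describe the standard study bundle: 100 drugs,
150 proteins, 30 diseases, 30 side effects, rank-4 Gaussian latent factors,
edge density 0.04 for drug-protein (600 positives — enough for 10-fold
splitting at a 10:1 ratio) and 0.05 for the auxiliary types, and feature
coupling 0.8. Drug-protein edges are the top-density fraction of the latent
scores $UV^\top/\sqrt r$; auxiliary edge types mix the corresponding factor
products with Gaussian noise at the coupling strength, so meta-paths carry
signal about the planted interactions and degrade to pure noise at coupling
zero. Features couple through prototypes: drugs (proteins) are clustered on
their latent factors, each cluster shares a prototype SMILES (sequence), a
drug keeps its prototype with probability equal to the coupling, and
sequences are point-mutated at rate one minus the coupling.

What the generator emulates: a low-rank interaction structure with
correlated auxiliary networks and feature views, realistic class imbalance,
and messy sequence input (occasional B/O/U/Z letters). What it does not:
real pharmacology, the degree distributions of public DTI networks,
meaningful chemistry beyond SMILES validity, or any relation between a
prototype molecule's actual structure and its interaction profile. Passing
the recovery and ablation tests therefore shows that the architecture can
extract a planted multi-view signal end to end — not that it reaches any
particular accuracy on real data.

```{r example}
library(hetdti)

bundle <- simulate_bundle(synthetic_spec(seed = 1))
split <- split_edges(bundle$network, test_fraction = 0.1, neg_ratio = 10,
                     fold_id = 1, seed = 1)
config <- train_config(steps = 500, batch_size = 128, han_input_size = 64,
                       seed = 1)
model <- train_model(bundle$network, bundle$smiles, bundle$sequences,
                     split, config)
evaluate_model(model, split)
```

# Numerical notes and limitations

* Softmaxes subtract the row maximum before exponentiation; fully masked
  rows return all-zero rows instead of NaN.
* Disconnected molecular fragments (multi-fragment SMILES) get topological
  distance equal to the atom count, one more than any realizable path.
* The reconstruction losses include the diagonal of
  $\hat A$; its gradient is radial and is projected out by the row
  normalization, so it adds a constant-like offset without steering
  training.
* Training is full-batch in the nodes (every step recomputes all fused
  rows), which is simple and exact but quadratic in node count for the
  reconstruction and unsuitable beyond a few thousand nodes per type.
* AUPR is computed by step integration (average precision) over the
  score-sorted list with ties kept in input order; with heavy score ties the
  value depends on that order, which matters only for degenerate constant
  scores.
* F1 and MCC default to a 0.5 cutoff; since unit-norm rows bound scores to
  $[\mathrm{sigmoid}(-1), \mathrm{sigmoid}(1)] \approx [0.27, 0.73]$, the
  best-F1 threshold reported alongside is usually the more informative
  number.
* The 3D conformer path is available but non-deterministic; the package
  never uses it inside seeded pipelines.
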