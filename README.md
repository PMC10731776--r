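# mdlink

Microbe–disease association prediction from a sparse binary association
matrix, using multi-view similarity networks, similarity network fusion,
a multi-scale variational graph autoencoder with an optimal-transport
(2-Wasserstein) prior, and gradient-boosted-tree classification of
embedding pairs.

## Who this is for

Microbiome researchers who have a curated table of known microbe–disease
associations (HMDAD, Disbiome, MicroPhenDB or Peryton all distribute the
required two-column pair format) and want a ranked list of candidate
microbes for a disease of interest, together with cross-validated
estimates of how reliable those rankings are. The package also ships a
planted-block synthetic generator, so the entire pipeline is testable and
demonstrable without downloading anything.

## The method

Let `A ∈ {0,1}^{nm×nd}` be the association matrix (microbes × diseases).

**Similarity views.** Per axis, several similarity matrices are built:

- *Disease semantic similarity* from rooted ontology DAGs: each ancestor
  `d` of disease `D` contributes `C_D(d) = Ω^depth(d)` (decay `Ω = 0.5`,
  max over paths), the semantic value is `V(D) = Σ_d C_D(d)`, and
  `DSS1(D1,D2) = Σ_{d∈T1∩T2} (C_{D1}(d)+C_{D2}(d)) / (V(D1)+V(D2))`.
- *Symptom similarity*: cosine between nonnegative disease×symptom
  weight vectors.
- *Gaussian interaction profile (GIP) kernel*:
  `K(i,j) = exp(−η‖p_i−p_j‖²)` over rows (microbes) or columns
  (diseases) of `A`, with bandwidth `η = η′ / mean_k ‖p_k‖²`.
- *Functional similarity*: two microbes are similar when their disease
  sets are similar under a base disease similarity — each member of
  either set is matched to its best counterpart and the matched scores
  are averaged over both directions. The same construction over drug
  sets is merged in when microbe–drug data is supplied.

**Fusion.** Similarity network fusion: each view is normalized into a
row-stochastic status matrix `P` (half the mass on the node itself) and a
K-nearest-neighbor local kernel `S`; repeatedly
`P_v ← S_v · mean(P_{w≠v}) · S_vᵀ` (re-symmetrized and renormalized), and
the final status matrices are averaged (K = 5 for diseases, 30 for
microbes).

**Embedding.** One variational graph autoencoder per axis, with the fused
network as weighted adjacency and rows of `A` (or `Aᵀ`) as node features:
two shared graph-convolution layers, then parallel variational heads at
latent scales 16, 32 and 64 giving per-node means and log-variances;
reparameterized samples are concatenated (112 dims) and decoded through
(i) an inner-product adjacency decoder and (ii) two perceptrons that
reconstruct the first- and second-layer activations (multi-order
embedding reconstruction). The latent prior `N(0, I)` is enforced with a
2-Wasserstein penalty: each scale's embedding cloud is Sinkhorn-matched
to an equal-size standard-normal draw. Training is full-graph Adam with a
step-decayed learning rate; gradients are hand-derived and verified
against finite differences.

**Prediction.** Each (microbe, disease) pair is the concatenation of its
two embeddings; known associations are positives, an equal number of
negatives is drawn uniformly from unknown cells, and an XGBoost
classifier is evaluated under stratified tenfold cross-validation
(AUROC, AUPR, F1, precision, recall, accuracy), then refit on all pairs
to rank novel candidates.

## Worked example

```r
library(mdlink)

world <- make_planted_association(nm = 150, nd = 30, n_clusters = 4,
                                  p_in = 0.3, p_out = 0.02,
                                  flip_noise = 0.01, seed = 1)
res <- mdlink_run(world$A,
                  disease_dags = make_dag_forest(world, seed = 1),
                  symptom_profiles = make_symptom_matrix(world, seed = 1),
                  cfg = mdlink_config(seed = 1))
glance(res)
#> # A tibble: 1 × 8
#>   auroc  aupr    f1 precision recall accuracy folds threshold
#>   <dbl> <dbl> <dbl>     <dbl>  <dbl>    <dbl> <int>     <dbl>
#> 1 0.827 0.794 0.762     0.759  0.767    0.761    10       0.5

predict_candidates(res, "d001", top_k = 5)
#> # A tibble: 5 × 3
#>    rank microbe score
#>   <int> <chr>   <dbl>
#> 1     1 m045    0.980
#> 2     2 m129    0.977
#> 3     3 m081    0.961
#> 4     4 m113    0.956
#> 5     5 m065    0.955
```

The tenfold AUROC of 0.83 on this synthetic world sits essentially at
its information ceiling: within a planted block, associated and
unassociated cells differ only by independent coin flips, so a classifier
working from per-node embeddings can exploit block membership and degree
but not the individual cells (see the methods vignette for the
analysis). On real databases, where association patterns are strongly
structured, cross-validated scores are much higher.

`autoplot(res$cv)` draws the pooled out-of-fold ROC and precision–recall
curves; `autoplot(res$vgae_microbe)` the training-loss history;
`tidy(res)` the per-fold metric table.

A command-line front end with `simulate`, `similarity`, `fuse`, `embed`,
`evaluate` and `predict` subcommands is installed at
`system.file("cli", "mdlink.R", package = "mdlink")`.

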