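# stamix

Clustering of spatially resolved transcriptomics and proteomics data into
spatial domains or cell types, using the morphology image as a direct source
of label information.

## The problem and who this is for

Spatial omics platforms (CosMx, Stereo-seq, Xenium, CODEX, ...) produce a
units × features matrix *X* (spots or cells × genes or proteins), per-unit
2-D coordinates, and often a whole-tissue image. Identifying spatial domains
— contiguous regions of units with shared molecular profiles — is a core
analysis step. Methods that use the image usually do so by *enhancing*
expression with image features, which can corrupt genes whose products have
no visual correlate. `stamix` instead links image similarity straight to the
predicted labels: units whose image patches look alike are pushed to share
soft cluster labels, the way a pathologist calls a region from morphology
alone. The package is for computational biologists analysing spatial omics
matrices with matched images, and for methodologists who want a compact,
fully testable reference implementation of this model class.

## The model

A Gaussian mixture variational autoencoder whose encoder is a single-hop
graph attention network over the units' KNN graph:

- generative: y ~ Uniform(k); z | y=j ~ N(μⱼᵖʳⁱᵒʳ, σⱼᵖʳⁱᵒʳ²);
  x | z ~ N(μˣ, σˣ²) with a *unit-wise* diagonal Gaussian output;
- inference: a GAT over each unit and its neighbours feeds a k-way softmax
  head (the soft label Ŷᵢ) and per-component posterior heads
  N(μᵢⱼᵖᵒˢᵗ, σᵢⱼᵖᵒˢᵗ²);
- objective, maximised over units:
  Σᵢ ( −Lᵢᵢᵐᵃᵍᵉ + log pθ(xᵢ) − JSᵢ ), where
  Lᵢᵢᵐᵃᵍᵉ = Σ_{j ∈ image-nbrs(i)} −log(Ŷᵢ·Ŷⱼ) over the 8 nearest in-batch
  image neighbours (cosine distance on patch embeddings), log pθ(xᵢ) is
  taken as the responsibility-weighted GMVAE ELBO, and JSᵢ is the mean
  base-2 Jensen–Shannon divergence to the spatial neighbours' soft labels.

Everything — preprocessing, exact KNN graphs, mini-batch neighbour
sampling, patch embedding, the GMVAE with hand-derived exact gradients,
integrated-gradients feature attribution, and ARI/FMI/silhouette metrics —
is implemented in base R on top of standard matrix algebra. See the methods
vignette (`vignettes/stamix-methods.Rmd`) for the full account.

## Worked example

```r
library(stamix)

# a seeded synthetic tissue: 2000 units on a grid, 4 contiguous domains,
# 60 features (3 planted markers per domain), and a matched toy image
ds  <- generate_synthetic(synthetic_spec(n_units = 2000, k_domains = 4,
                                         m_features = 60, seed = 11))
dsp <- preprocess_dataset(ds)   # filter, HVG, library-size, log1p, z-score
dsp$image <- ds$image

fit <- stamix(dsp, k_cluster = 4, epochs = 60, batch_size = 1024,
              seed = 1, patch = patch_spec(size = 17))
fit
#> stamix fit: 2000 units, 4 clusters
#>   graph: spatial KNN, k = 8; image loss: on
#>   epochs: 60, seed: 1, final total loss: 172572.978
#>   cluster sizes: 573 313 510 604

adjusted_rand_index(ds$labels, fit$labels)
#> [1] 0.9866804
fowlkes_mallows(ds$labels, fit$labels)
#> [1] 0.9901733

rk <- rank_svgs(fit, dsp)          # integrated-gradients feature ranking
rk$top_features[[1]][1:3]
#> [1] "feature_3" "feature_2" "feature_1"
```

The fit recovers the planted domains almost exactly (ARI ≈ 0.99; 1.0 would
be a perfect match to the ground-truth partition), and the top
integrated-gradient features of each cluster are that domain's planted
markers. `predict()` applies a fitted model to new data; `plot(fit)` draws
the spatial label map; `write_cluster_result(fit, dir)` exports labels, soft
assignments and embeddings as TSV. A thin command-line wrapper with
`fit` / `predict` / `evaluate` / `synth` subcommands lives in
`inst/cli/stamix-cli.R`.

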