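# fwec — entropy-weighted fuzzy clustering with a bounded kernel distance

`fwec` clusters numeric sample-by-feature matrices — expression-style data,
morphometrics, any table where the interesting structure may live in a
subset of noisy, differently informative features. It is aimed at analysts
who want fuzzy (soft) cluster assignments, per-cluster feature relevance
weights, and robustness to gross outliers, together with the classical
baselines and the standard external validity indices needed to evaluate a
partition against known labels.

## The model

For data `X` (N samples × M features) the algorithm minimizes

    F(U, C, W) = Σ_i Σ_j Σ_l  u_ij · w_jl · d_l(x_il, c_jl)
               + λ Σ_ij u_ij log u_ij  +  γ Σ_jl w_jl log w_jl

subject to row-stochastic memberships U (N×K) and per-cluster feature
weights W (K×M), with the bounded per-feature dissimilarity

    d_l(x, c) = 1 − exp(−δ_l (x − c)²),   δ_l = 1 / var_l.

The kernel saturates at 1, so outliers cannot dominate a center; δ_l makes
it scale-free per feature. The two Shannon-entropy penalties (temperatures
λ, γ) keep memberships and weights soft and give closed-form softmax
updates; centers take one kernel-reweighted-mean (majorize–minimize) step
per sweep. Fitting is block-coordinate descent with a monotone objective,
multi-restart, best restart chosen by lowest objective.

Also included: K-means, weighted K-means (global feature weights, exponent
β) and fuzzy c-means (fuzzifier m) baselines sharing the same
initialization protocol; ACC (optimal one-to-one cluster↔class matching via
an internal Hungarian solver), Rand index and NMI; seeded Gaussian-blob
generators with uniform noise features and outlier contamination; and
experiment drivers for parameter sweeps, Euclidean-vs-kernel comparison and
noise robustness.

## Worked example

```r
library(fwec)

d <- make_blobs(blob_spec(n_per_cluster = c(60, 60, 60), m_informative = 3,
                          m_noise = 2, separation = 8, seed = 42))
d
#> <fwec_data> 180 samples x 5 features, 3 label classes

fit <- fwec(d, fwec_config(K = 3, gam = 30, restarts = 10, seed = 1))
fit
#> <fwec_fit> K = 3, non_euclidean distance
#>   best objective -125.41 over 10 restart(s); best run: 72 sweep(s), converged
#>   cluster sizes: 59 60 61

partition_metrics(fit$hard_labels, d$labels)
#> <partition_metrics> ACC 0.9944 | RI 0.9926 | NMI 0.9742

round(fit$model$W, 3)
#>       [,1]  [,2]  [,3]  [,4]  [,5]
#> [1,] 0.183 0.271 0.190 0.176 0.180
#> [2,] 0.237 0.207 0.199 0.180 0.177
#> [3,] 0.183 0.275 0.195 0.173 0.174
```

180 samples in 3 blobs (3 informative features, 2 uniform-noise columns)
are recovered at ACC 0.994; every cluster assigns its lowest weights to the
two noise columns (4–5). Here `gam = 30` keeps the weights soft at N = 180
— with the protocol default `gam = 1.4` the weight softmax saturates on
large N (see the vignette).

## Command line

```sh
Rscript inst/scripts/fwec simulate --n-per-cluster 50,50 --m-informative 2 --out sim
Rscript inst/scripts/fwec fit --data sim_data.csv --label-col label --k 2 --restarts 10 --out run
Rscript inst/scripts/fwec evaluate --pred run_labels.csv --truth truth.csv --out metrics.json
```

Subcommands: `fit` (also `--variant kmeans|wkmeans|fcm`), `evaluate`,
`simulate`, `sweep`, `compare-distance`, `noise-exp`; results are written
as CSV + JSON.

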