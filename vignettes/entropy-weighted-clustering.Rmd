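---
title: "Entropy-weighted fuzzy clustering with a bounded kernel distance: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-weighted fuzzy clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwec)
```

## The model

`fwec` fits a soft partition of an $N \times M$ numeric matrix $X$ into $K$
clusters by minimizing

$$
F(U, C, W) \;=\; \sum_{i=1}^{N}\sum_{j=1}^{K}\sum_{l=1}^{M}
  u_{ij}\, w_{jl}\, d_l(x_{il}, c_{jl})
\;+\; \lambda \sum_{i,j} u_{ij}\log u_{ij}
\;+\; \gamma \sum_{j,l} w_{jl}\log w_{jl},
$$

subject to $\sum_j u_{ij} = 1$, $\sum_l w_{jl} = 1$, all entries strictly
positive. Three ingredients distinguish it from classical fuzzy c-means:

* **A bounded, per-feature-scaled dissimilarity.** By default
  $d_l(x, c) = 1 - \exp(-\delta_l (x - c)^2)$ with $\delta_l = 1/\mathrm{var}_l$
  (population variance, divisor $N$). The kernel is 0 at the center and
  saturates at 1, so a sample 20 standard deviations away pulls on a center
  no harder than one 5 away — the mechanism behind the model's outlier
  resistance. Because $\delta_l$ is an inverse variance, the distance (and
  hence the whole fit) is invariant to rescaling any feature column.
  `distance = "euclidean"` replaces $d_l$ by the raw squared difference for
  comparison studies.
* **Per-cluster feature weights** $w_{jl}$ (soft subspace clustering): each
  cluster learns which features make it compact, instead of one global
  weight vector.
* **Entropy regularizers instead of exponent fuzzifiers.** Both $U$ and $W$
  are kept soft by Shannon-entropy penalties, which yield closed-form Gibbs
  (softmax) updates with temperatures $\lambda$ and $\gamma$.

Both entropy terms are non-positive, so the objective is routinely negative.

## Block-coordinate descent

Each sweep updates, in order:

1. dispersions $D_{ij} = \sum_l w_{jl}\, d_l(x_{il}, c_{jl})$;
2. memberships $u_{ij} = \operatorname{softmax}_j(-D_{ij}/\lambda)$ — the
   exact minimizer of $F$ in $U$;
3. weights $w_{jl} = \operatorname{softmax}_l(-D'_{jl}/\gamma)$ with
   $D'_{jl} = \sum_i u_{ij}\, d_l(x_{il}, c_{jl})$ — the exact minimizer in
   $W$;
4. centers, by one kernel-reweighted-mean step (below);

and recomputes $F$. The run stops when $|F_t - F_{t+1}| \le$ `tol` or after
`max_iter` sweeps. The trace is monotone non-increasing: steps 2–3 are exact
block minimizers, and step 4 is a majorize–minimize step.

**The center step.** The stationarity condition for $c_{jl}$ is implicit —
the kernel weights depend on the center being solved for. We take one
fixed-point step per sweep, evaluating the kernel at the previous center:
$$
c_{jl} \leftarrow
\frac{\sum_i u_{ij}\, e^{-\delta_l (x_{il} - c^{\text{prev}}_{jl})^2} x_{il}}
     {\sum_i u_{ij}\, e^{-\delta_l (x_{il} - c^{\text{prev}}_{jl})^2}}
$$
(the constant factors $w_{jl}\delta_l$ cancel). Since $1 - e^{-\delta t}$ is
concave in $t = (x - c)^2$, the tangent line at the previous iterate
majorizes it; minimizing the tangent surrogate is exactly this reweighted
mean, so the step never increases $F$. This keeps each sweep at
$\Theta(NKM)$ — the test suite counts kernel-block evaluations to pin this
down — at the cost of slower convergence than an exact center solve (even
$K = 1$ needs a dozen sweeps to move the center within a $10^{-5}$
objective change). If all kernel mass under a coordinate vanishes
(denominator $< 10^{-300}$), the previous coordinate is kept and a warning
raised. In euclidean mode the center is the exact weighted mean.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `lam` ($\lambda$) | 0.3 | membership temperature; $D_{ij} \in [0,1)$ in kernel mode, so 0.3 gives moderately confident memberships; $\lambda \to \infty$ forces $u_{ij} \to 1/K$ |
| `gam` ($\gamma$) | 1.4 | feature-weight temperature; $\gamma \to \infty$ forces $w_{jl} \to 1/M$ (asserted as a limit test) |
| `tol` | $10^{-5}$ | absolute objective change per sweep at which to stop |
| `max_iter` | 100 | sweeps per restart |
| `restarts` | 100 | independent random initializations; lowest objective kept |
| `seed` | 1 | spawns one sub-seed per restart, making runs bit-reproducible |

Defaults mirror the protocol commonly used with this family of algorithms.
Initialization: centers are $K$ distinct data rows sampled without
replacement (distinctness of indices avoids immediate center collision);
weights start uniform at $1/M$ — deterministic, constraint-satisfying and
symmetric, since no distribution is canonically prescribed.

**A scale caveat that matters.** $D'_{jl}$ is a sum over all $N$ samples,
so it grows linearly with $N$, while the weight-entropy term is $O(\gamma)$.
With the default $\gamma = 1.4$ and $N$ in the hundreds, the weight softmax
therefore saturates: each cluster puts essentially all of its weight on its
single most compact feature. On data whose clusters are only separable in
two or more joint directions this caps attainable accuracy well below what
an unweighted method achieves, and the fitted optimum becomes a near-tie
between partitions of very different label quality. Users clustering more
than ~100 samples who want genuinely soft weights should scale `gam`
roughly in proportion to the per-cluster sample count (e.g. `gam = 50` at
$N = 300$, $K = 3$, which in our experiments restores soft weights and
near-perfect blob recovery). We keep 1.4 as the default because it is the
family's standard protocol value; the limitation is documented rather than
silently repaired.

## Model selection, labels, evaluation

The best restart is chosen by lowest objective — an unsupervised criterion;
ground-truth labels never influence fitting or selection. Hard labels are
the row-argmax of $U$, ties to the lowest cluster index. External indices
(`partition_metrics()`):

* **ACC** — fraction correct under the best one-to-one cluster-to-class
  assignment, solved exactly by an in-package Hungarian
  (shortest-augmenting-path) solver on the contingency table; unmatched
  clusters contribute nothing. A majority-vote mapping is available
  (`mapping = "majority"`) but is not one-to-one and can double-count.
* **RI** — pairwise agreement over all $\binom{N}{2}$ pairs, computed in
  closed form from the contingency table.
* **NMI** — plug-in mutual information normalized by
  $\sqrt{H(A)H(B)}$ (the geometric-mean denominator keeps the index in
  $[0,1]$); natural logarithms; two trivial single-cluster partitions give
  1, exactly one zero-entropy partition gives 0.

## The synthetic world

`make_blobs()` draws spherical Gaussian clusters around centers placed at
the vertices of a regular simplex scaled so that every pair of centers is
`separation` $\times\sigma$ apart (simplest defensible signal model; real
expression-style data is neither isotropic nor equally spaced).
`add_noise_features()` appends i.i.d. uniform(0, 1) columns, emulating
irrelevant measurements. `contaminate_outliers()` displaces a fraction of
rows by a fixed multiple of $\sigma$ in a random direction.

What a green test on this world does establish: constraint satisfaction,
monotone descent, block optimality, the entropy limits, scale invariance,
noise-feature down-weighting. What it does not: performance on correlated,
anisotropic, heavy-tailed or genuinely high-dimensional data, or any claim
about real benchmark accuracy.

Two recovery-flavored acceptance checks are deliberately left failing, with
the diagnosis printed alongside them by the test suite:

* *Perfect recovery of 6$\sigma$ blobs on 19/20 seeds.* Unattainable in
  this world for any method: spherical clusters 6$\sigma$ apart leave
  roughly one sample per 300 on the wrong side of the decision boundary
  (plain K-means with restarts reaches ACC $= 1.0$ on only about half the
  seeds), and the $\gamma$ saturation above further caps the model itself.
* *Kernel-distance dominance over Euclidean under 5% gross outliers at the
  default $\gamma$.* The saturation makes both modes cluster on single
  features, erasing the kernel advantage; with $\gamma$ scaled to $N$, the
  expected dominance direction re-emerges clearly.

## Numerical choices

* **Softmax stability:** the per-row minimum dispersion is subtracted before
  exponentiation (algebraically identity); without it $\lambda \ll 1$
  underflows to 0/0.
* **Zero-variance features:** $\delta_l = 1/\mathrm{var}_l$ is undefined;
  if $\mathrm{var}_l \le 10^{-12}\max(1, \bar x_l^2)$ the feature's
  $\delta_l$ is set to 0, making its kernel distance identically zero (an
  uninformative feature contributes nothing), with a message.
* **Stopping:** absolute value of the objective change, guarding against
  sign conventions.
* **Baseline edge rules:** an empty K-means cluster is re-seeded from the
  point farthest from its center (logged); a WK-means feature with zero
  within-cluster dispersion absorbs all weight, split equally among such
  features (the exponent formula's limit); an FCM sample coinciding with a
  center takes membership 1 there. The WK-means assignment uses the
  *squared* difference (consistent with its objective), and the FCM
  membership exponent is the canonical $2/(m-1)$.
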