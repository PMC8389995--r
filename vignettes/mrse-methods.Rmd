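---
title: "Learning collective variables from biased simulations with mrse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning collective variables from biased simulations with mrse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrse)
```

## The problem

Enhanced-sampling simulations bias a few collective variables (CVs) to push a
molecular system over free-energy barriers it would otherwise cross only
rarely. The quality of such simulations stands or falls with the CVs. `mrse`
implements multiscale reweighted stochastic embedding (MRSE): a parametric,
multiscale variant of stochastic neighbor embedding that learns a
low-dimensional CV map $s = f_\theta(x)$ from a high-dimensional feature space
by training a deep neural network — and, crucially, does so on data from a
*biased* simulation, where every sample carries a statistical weight.

Three ingredients distinguish the method from plain parametric t-SNE:

1. **Weight-tempered random sampling** selects training landmarks with
   probability $\propto w^{1/\alpha}$, interpolating between an equilibrium
   representation ($\alpha = 1$) and the raw biased distribution
   ($\alpha \to \infty$).
2. **A multiscale Gaussian mixture** averages neighbor probabilities over a
   ladder of perplexities, removing the single-perplexity choice.
3. **Reweighted kernels** fold the statistical weights into the feature-space
   neighbor probabilities so that the embedding represents the unbiased
   ensemble.

Because validating a CV-learning method needs ground truth, the package ships
a complete well-tempered metadynamics (WT-MetaD) simulator on the analytic
Müller-Brown potential. Every stage — simulation, reweighting, landmark
selection, probability construction, training, free-energy analysis — is an
exported, tested function.

## The simulator and the statistical weights

A single particle (mass 1, $k_B = 1$) moves on the Müller-Brown potential
$U(x,y) = \sum_j A_j e^{p_j(x,y)}$ with the classic coefficient vectors and
amplitudes scaled down by a factor of 5, so the barrier between the two
principal states is $\approx 21\,k_BT$ at $T = 1$ — a rare-event system: an
unbiased run of $10^6$ steps never crosses, while a WT-MetaD run with bias
factor $\gamma = 5$ crosses dozens of times.

Dynamics use the Bussi–Parrinello Langevin integrator: an exact
Ornstein–Uhlenbeck half-step on the velocity on each side of a
velocity-Verlet step. With friction and temperature set to zero it reduces to
plain velocity Verlet, which the tests exploit to check energy conservation.
Defaults ($T = 1$, friction 10, time step 0.005) are the standard settings
for this benchmark system.

WT-MetaD deposits a Gaussian hill every 200 steps with height
$h_0\,e^{-V(s,t)/((\gamma-1)k_BT)}$, $h_0 = 1.2$, width 0.1 in both
coordinates. Forces always come from the exact hill sum; a $500^2$ grid over
$[-5,5]^2$ exists only for the quadrature of the time-dependent offset

$$c(t) = \beta^{-1}\log\frac{\int ds\, e^{\gamma\beta V(s,t)/(\gamma-1)}}
{\int ds\, e^{\beta V(s,t)/(\gamma-1)}},$$

recomputed at every deposition (trapezoidal weights — with uniform node
weights the effective integration domain would depend on the grid
resolution). The per-frame statistical weight is
$w = e^{\beta(V - c(t))}$. Following standard practice the first 20% of a run
is discarded (the bias changes too quickly for reliable weights early on) and
weights are normalized to a maximum of 1, which preserves all ratios.
$c(t)$ grows as hills accumulate; isolated tiny decreases (of order
$10^{-4}\,k_BT$) can occur when a hill lands in a region of low bias, which
is why the tests assert strong net growth rather than strict monotonicity.

`biasFactor = Inf` is an explicit sentinel for non-tempered metadynamics
(constant hill height), not a floating-point limit.

A note on the potential's parameters: the third and fourth Gaussian terms use
the classic signs $a_3 = -6.5$ and $c_4 = +0.7$. With either sign flipped the
"potential" is unbounded below inside the canonical window and has no
barrier, so no simulation would be possible; the package validates this via
the frozen stationary-point fixtures (deepest minimum $-29.34$ at
$(-0.558, 1.442)$, main saddle $-8.13$ at $(-0.822, 0.624)$).

## Landmark selection

`weightTemperedSample()` rescales weights to $w^{1/\alpha}$ and draws without
replacement by exponential-order sampling (Efraimidis–Spirakis keys), so no
training row is duplicated. Whether the original formulation samples with or
without replacement is not decisive at the pool-to-landmark ratios used here;
without replacement is the safer choice for training data. The default
$\alpha = 2$ is the value recommended for this class of problems: for a run
with bias factor $\gamma$ the landmark density along the biased CVs follows
$[P(s)]^{1/\tilde\alpha}$ with

$$\tilde\alpha = \frac{\alpha\gamma}{\alpha + \gamma - 1},$$

so $\alpha = 2,\ \gamma = 5$ gives $\tilde\alpha = 10/6 \approx 1.67$ — a
modest, controlled broadening of the equilibrium distribution. The tests
verify this distributional claim directly: on a synthetic well-tempered
double well, the Kolmogorov–Smirnov distance between the landmark CV density
and $[P(s)]^{1/\tilde\alpha}$ stays below 0.05 at $n = 5000$.

## Feature-space probabilities

For each landmark $x_i$ a reweighted Gaussian kernel
$\tilde K_{\epsilon_i}(x_i, x_j) = \sqrt{w_i w_j}\,
e^{-\epsilon_i\|x_i - x_j\|^2}$ defines a row-stochastic neighbor
distribution ($p_{ii} = 0$). The geometric-mean reweighting factor is the
symmetric convention that reduces to 1 for unit weights and to
$e^{\beta(V_i + V_j)/2}$ for exponential weights; it is exposed as a
pluggable function in `reweightedKernel()`. The row's own weight cancels in
the normalization — what matters is that low-weight samples lose their status
as neighbors of everyone else, which is the mechanism by which the embedding
deprioritizes unimportant high-bias regions.

Each row's scale $\epsilon_i = 1/(2\sigma_i^2)$ is fitted by bisection so the
row's perplexity $2^{H}$ (entropy $H$ in bits) hits a target; entropy is
strictly decreasing in $\epsilon$, so the search is safe. The bracket starts
at $[2^{-20}, 2^{20}]$ over the median squared distance and widens
automatically; tolerance is $10^{-5}$ on the perplexity with at most 64
bisections. Entropy is always computed directly from the normalized row; the
analytic decomposition of the entropy into normalization, distance and
weight-correction terms is used as a test oracle only, since the two are
provably identical.

The multiscale matrix averages the per-perplexity matrices over the ladder
$PP_l = 2^{L-l+1}$, $l = 0..L$, $L = \lfloor \log N \rfloor - 2$. The
logarithm base is not pinned down by convention; the natural log (default)
yields a maximum perplexity of 64 at $N = 2000$, a conventional scale for
SNE-family methods, and base 2 is available. Row-stochasticity is preserved
exactly by the averaging.

## The embedding network and its training

The network is the van-der-Maaten-style parametric t-SNE architecture:
$[k, 500, 500, 2000, d]$, leaky-ReLU (slope 0.2) hidden activations, linear
output. Weights are initialized with the Glorot normal scheme using the
leaky-ReLU gain; biases start at 0.005.
Training minimizes the batched Kullback–Leibler divergence
$D_{KL}(M \| Q)$ between the multiscale feature probabilities $M$ and latent
heavy-tailed (t-distribution, one degree of freedom) probabilities $Q$, with
Adam + AMSGrad, learning rate $10^{-3}$, momenta $(0.9, 0.999)$, weight decay
$10^{-4}$, batch size 500, 100 epochs, seed 111 as defaults.

Two design points deserve a note because the choice was genuinely open:

* **Per-batch probability matrices.** The loss is defined per batch, so $M$
  and its perplexity ladder are rebuilt within each batch of $N_b$ landmarks
  (ladder with $N = N_b$). Slicing a precomputed global $N \times N$ matrix
  would break row normalization. The data are reshuffled every epoch.
* **Joint normalization.** The row-stochastic mixture is divided by $N_b$
  before the KL so that both $M$ and $Q$ are joint distributions over ordered
  pairs. The gradient of the loss with respect to the latent points is the
  generalized t-SNE gradient for asymmetric $P$,
  $\partial L/\partial s_i = 2\sum_j (s_i - s_j) E_{ij}
  [(p_{ij} + p_{ji}) - 2 q_{ij}]$ with $E_{ij} = (1+\|s_i-s_j\|^2)^{-1}$,
  and is backpropagated through the network by a hand-written reverse pass
  (verified against central finite differences).

* **Dropout defaults to off.** Hidden-layer dropout (inverted, training-time
  only) is implemented and exposed, but the default probability is 0 rather
  than the conventional 0.1. The latent coordinates are a weighted sum over
  the 2000-unit last hidden layer, so dropout perturbs each training-time
  latent position by an amount proportional to the embedding's own amplitude
  (roughly $\sqrt{p/(1-p)}$ of it, independent of scale). A factor-isolation
  study on the Müller-Brown pipeline showed this noise stalls the KL loss at
  roughly twice its attainable value and visibly distorts the map, for both
  500 and 2000 landmarks and up to 300 epochs, while every other
  hyperparameter at its default behaves well; switching dropout off restores
  the expected near-isometric recovery of the true coordinates. Users who
  want the regularization for high-dimensional, noisy feature sets can set
  `dropout` in `networkSpec()`.

When dropout is enabled it is active only during training;
`projectEmbedding()` and
`embeddingJacobian()` run in deterministic mode, and the Jacobian
$\partial s/\partial x$ — the quantity a biasing engine needs for the chain
rule — is checked against finite differences to $10^{-4}$. The KL loss is
invariant under orthogonal maps of the latent space, so the absolute
orientation of an embedding is set by the seed; `procrustesAlign()` exists to
rotate embeddings onto reference coordinates for comparison (rotation-only by
default, reflections optional).

## Free-energy analysis

`kdeFes()` estimates $F(s) = -\beta^{-1}\log \hat P(s)$ with a weighted
Gaussian product-kernel KDE on a grid (default $200$ per axis), aligned to
$\min F = 0$, with a density floor of $10^{-12}$ of the maximum below which
cells become `Inf`. Bandwidths default to Silverman's rule,
$h_j = \sigma_j [4/((d+2)n)]^{1/(d+4)}$, but Silverman is a compromise for
unimodal data: on the Müller-Brown surface it oversmooths the narrow basins
badly. `fesMismatch()` reports the RMS discrepancy between the KDE surface
and a discrete weighted histogram so the user can adjust. For the
Müller-Brown analyses in the tests we use $h = 0.0125$: calibrating on
independent draws from the analytic Boltzmann density shows the smoothing
bias in the basin cores falls from $\approx 0.15\,k_BT$ at $h = 0.02$ to
$\approx 0.07\,k_BT$ at $h = 0.0125$, below the sampling noise of the runs
being analyzed, while the narrow basins (width $\approx 0.15$) remain well
populated at the sample sizes used.

`freeEnergyDifference()` integrates probability over two named regions,
either from an FES grid or directly from weighted samples; it is
antisymmetric and invariant to constant shifts of $F$.
`conditionalFes()` restricts samples to an interval of a third CV before the
2-D KDE, the standard device for visualizing three-dimensional CV spaces in
two dimensions. `distancePreservation()` histograms feature-space against
latent-space pairwise distances (both normalized to $[0,1]$); an isometric
embedding concentrates all mass on the diagonal, and reweighted embeddings
are expected to deviate at intermediate distances because weights add a
non-geometric constraint. `varianceFilter()` and `standardizeFeatures()`
implement the feature pre-selection used for distance features (variance
threshold, e.g. $2\times10^{-4}$ nm² for heavy-atom distances, then
per-column standardization; population-variance convention, configurable).

## What the synthetic data do and do not show

`makeFixture()` generates three kinds of ground-truth data: two separated
Gaussian clusters (embedding sanity), k-dimensional Gaussian mixtures with
optional exponential weights (probability machinery), and a 1-D quartic
double well sampled from its well-tempered distribution with the converged
static bias recorded (reweighting and landmark recovery, where
$[P(s)]^{1/\gamma}$ and $[P(s)]^{1/\tilde\alpha}$ are known in closed form).
Together with the Müller-Brown simulator these cover the full pipeline with
exact references. They do not emulate molecular data: features there are
correlated, high-dimensional, and only partially coupled to the biased CVs,
and sampling is far from the idealized regime of an analytic two-dimensional
system. Passing tests demonstrate the correctness of the machinery, not that
two CVs suffice for any particular molecule.

## Problem sizes used in the checks

The package's own verification runs are scaled so the whole suite stays
desk-sized: WT-MetaD runs of $10^6$ steps (crossing statistics, landmark and
embedding pipelines; frames saved every 100 steps give a $10^4$-sample pool)
and $4\times10^6$ steps saved every 25 steps for free-energy reconstruction,
where the longer run tightens the statistical error of basin free-energy
differences below the $0.2\,k_BT$ scale of interest; 500-landmark trainings
with the full $[2,500,500,2000,2]$ network; brute-force oracle comparisons on
$\le 10$ points. The end-to-end check asks the embedding, after Procrustes
alignment, to correlate with the true $(x, y)$ coordinates at $r \ge 0.95$
and to separate the two metastable states with $\ge 95\%$ agreement against
analytic basin labels.

## Known limitations

* The FES and conditional-FES containers support one- and two-dimensional CV
  spaces; higher-dimensional latent spaces can be trained and projected but
  must be analyzed externally.
* No Barnes–Hut or interpolation acceleration: the probability construction
  is dense, sized for up to a few thousand landmarks per batch.
* No iterative bias-and-relearn loop and no coupling to external biasing
  engines; the Jacobian is exposed for that purpose but the loop itself is
  out of scope.
* Landmark selection implements weight-tempered random sampling only;
  farthest-point-style schemes are deliberately absent.
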