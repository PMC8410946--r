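---
title: "Walsh-Hadamard spectral analysis and regularization of fitness landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walsh-Hadamard spectral analysis and regularization of fitness landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiwalsh)
```

## The model

A fitness landscape assigns a real value to every combination of mutations
at $d$ binary sites. Writing a genotype as $x \in \{-1,+1\}^d$ (the
reference state at every site encodes to $+1$), any such map has a unique
multilinear representation

$$f(x) = \sum_{S \subseteq [d]} \alpha_S \prod_{i \in S} x_i,$$

whose coefficients $\alpha_S$ are exactly the epistatic interaction
coefficients: $|S| = 1$ terms are additive site effects, $|S| \ge 2$ terms
are genuine interactions. The vector of all $2^d$ coefficients is the
Walsh-Hadamard (WH) transform of the vector of all $2^d$ function values.
Measured landscapes are typically *spectrally sparse*: a few interactions
with large coefficients plus a larger band of small ones. Observations
follow $y_i = f(x_i) + \varepsilon_e$ with
$\varepsilon_e \sim N(0, \sigma_e^2)$.

Two scale conventions coexist and the package keeps both explicit. The
**multilinear** scale stores the polynomial's $\alpha_S$ (what worked
examples and reported interaction coefficients use); the **unitary** scale
multiplies by $2^{d/2}$ so the transform preserves Euclidean norm
($\tfrac{1}{2^d} H H = I$). Optimization losses use the unitary scale;
`convert_scale()` moves between them exactly.

### Conventions fixed once

* Enumeration: landscape entry $j$ (0-based) is the value at the $\pm 1$
  vector whose coordinate $i$ is $+1$ iff bit $i{-}1$ of $j$ is 0.
* Index/subset bijection: bit $i{-}1$ of an index corresponds to site $i$.
* Reference (absence-of-mutation) state encodes to $+1$. Published
  coefficient signs from other sources may differ by per-site flips when
  their (usually undeclared) assignment differs.
* Ties in `variance_explained_curve()` are broken by ascending mask index
  so the curve is deterministic.

## Spectral regularization of a network

A feed-forward network $g_\theta$ (layers $d \times fd$, $fd \times fd$,
$fd \times d$, $d \times 1$; leaky-ReLU; Xavier-uniform init; Adam) fitted
to scarce data generalizes poorly because nothing constrains its epistatic
spectrum. The exact spectral penalty trains

$$\min_\theta \sum_{i=1}^n (y_i - g_\theta(x_i))^2
  + \alpha \lVert H\, g_\theta(X) \rVert_1,$$

with $H$ unitary and $g_\theta(X)$ the model landscape, re-enumerated at
every update step. The subgradient of the penalty with respect to the
landscape values is $\alpha\, 2^{-d/2} H\, \mathrm{sign}(u)$ (0 at exactly
zero coefficients), so one extra $O(2^d \log 2^d)$ butterfly per step
suffices. This is `train_en()`, feasible for $d \le 25$.

**Defaults with units.** $\alpha = 0.1$ against the unitary-scale penalty
(the $2^{d/2}$ conversion means the same $\alpha$ weighs multilinear
coefficients $2^{d/2}$ times more strongly); learning rate $10^{-2}$
regularized and $10^{-3}$ unregularized; at most 1000 epochs with
validation-MSE early stopping and best-validation checkpointing. The
library default patience is 20 epochs; the benchmark protocol uses a
longer patience (150) because with $n = 60$ an "epoch" is a single
full-batch Adam step and the spectral term improves validation loss slowly
and non-monotonically. This is an optimizer-budget choice, fixed before
the comparison and applied identically to both arms.

**Batch normalization semantics.** The hidden layers carry batch
normalization. A data batch is normalized by its own statistics (updating
running averages); the full-enumeration penalty pass is also normalized by
its own batch statistics — since that batch *is* the entire input space,
these are the population statistics, matching the default
autodiff-through-batchnorm behaviour of mainstream frameworks. Prediction
(validation, test, `model_spectrum()`) uses the running averages. The
backward pass is exact in both regimes (verified against finite
differences).

**Response scaling.** The penalty weight $\alpha = 0.1$ is calibrated for
responses on a unit scale; on raw fitness values with SD $\sigma_y \gg 1$
the data term outweighs the spectral term by an extra factor $\sigma_y$
and the regularizer is effectively disabled. `run_benchmark()` therefore
standardizes responses with train-split statistics for the network
methods (predictions and spectra are mapped back to the raw scale before
any metric is computed; $R^2$ is scale-invariant anyway). `train_en()`
itself does not silently rescale — callers own their units.

## Scaling out: ADMM with a peeling decoder

For $d > 25$ the landscape cannot be enumerated. Introducing
$u = H g_\theta(X)$ as an explicit variable and applying scaled-dual ADMM,
all three steps can be restricted to a subsampled query set $X_T$ designed
by sparse-graph codes:

* $\theta$-step: $\sum_i (y_i - g_\theta(x_i))^2 +
  \tfrac{\rho}{2}\lVert g_\theta(X_T) - H_T u + \gamma \rVert^2$ (Adam);
* $u$-step: $\alpha \lVert u \rVert_0 + \tfrac{\rho}{2}
  \lVert [g_\theta(X_T) + \gamma] - H_T u \rVert^2$ (peeling decoder);
* dual update: $\gamma \leftarrow \gamma + g_\theta(X_T) - H_T u$.

$H_T u$ is evaluated on the fly from $u$'s support
($O(|T| \cdot |\mathrm{supp}(u)|)$); nothing of size $2^d$ is allocated.
Defaults $\alpha = 1$, $\rho = 0.01$; 20 outer iterations with 50 Adam
epochs per $\theta$-step (outer/inner budgets are not externally
prescribed; these are fixed for reproducibility and scale down in the
tests and the benchmark, which say so where they do).

**Initialization.** The alternation starts from the maximum-likelihood
solution, not from random weights: a data-only, validation-checkpointed
warm start (`warmstart_epochs`) precedes the loop, and $u^0$ is the
*unthresholded* spectral projection of the warm-started landscape. Both
matter. With $u^0 = 0$ and an untrained network, the coupling term
$\tfrac{\rho}{2}\lVert g(X_T) - H_T u + \gamma \rVert^2$ simply drags the
landscape to zero and the first projections see nothing above threshold;
starting near the constraint manifold ($u^0 \approx H_T$-projection of
$g_{\theta^0}$) makes the penalty vanish at the first step and lets the
coupling concentrate the model onto the peeled skeleton.

**The hard threshold.** The $u$-step is an $\ell_0$-penalized projection.
On an orthonormal basis its exact proximal solution keeps a recovered
coefficient iff $u_S^2 \ge 2\alpha/\rho$; that is the default rule
(`u_threshold = "prox"`). For a row-subsampled $H_T$ the threshold's scale
is genuinely ambiguous (columns of $H_T$ are not unit-norm), so
`u_threshold = "peel"` is also provided, in which the decoder's
noise-adaptive singleton detection alone carries the sparsity. The
$\ell_1$-relaxed alternative is the soft-thresholding operator with
threshold $\alpha/\rho$, provided as `soft_threshold()` for reference but
not used on the main path. (Statements of this operator with threshold
$\rho/2\alpha$ circulate; the standard derivation of the prox of
$\alpha\lVert u\rVert_1 + \tfrac{\rho}{2}\lVert w-u\rVert^2$ gives
$\alpha/\rho$, which is what is implemented.)

**Model selection.** Validation MSE is recorded after every inner Adam
epoch, not just at outer-iteration boundaries, and the globally best
checkpoint (weights *and* batch-norm running statistics) is returned — the
same granularity as the exact path, so paired comparisons are fair.

**Peeling failure.** If the decoder diverges entirely (no coefficients
survive and bins remain unresolved) the previous $u^t$ is retained rather
than zeroing the constraint; partial recoveries are accepted as-is. The
network landscape is never exactly sparse, so unresolved residual bins are
expected and benign — they act as bounded noise on the dual.

## The sublinear sparse transform

`design_plan()` draws, per group $c = 1..C$, a random $d \times b$ binary
matrix $M_c$ of full column rank over GF(2). Querying
$f(M_c \ell \oplus \delta)$ for all $B = 2^b$ bins $\ell$ and the $d{+}1$
delays $\delta \in \{0, e_1, \dots, e_d\}$, and applying a length-$B$ WH
transform per delay, aliases coefficient $\alpha_S$ into bin $M_c^\top S$
with amplitude $\alpha_S$ and sign pattern $(-1)^{\langle S,
\delta\rangle}$. Bins are classified as:

* **zero-ton** — energy at or below the squared noise scale;
* **singleton** — sign flips across unit delays spell out the mask bit by
  bit; the sign-aligned observations must agree with their common mean
  within $\max(\tau^2, (0.35\,\hat\alpha)^2)$, and the mean must exceed
  the noise scale $\tau$. Noisy detection rules are not externally
  specified; this variance test collapses to an exact test as
  $\tau \to 0$ and tolerates the dense aliased background of
  never-exactly-sparse network landscapes, which a fixed
  relative-amplitude rule cannot (every amplitude is perturbed, so such a
  rule never fires and the ADMM projection stays empty). The recovered
  mask must additionally re-hash to the bin it was found in, else the bin
  is demoted;
* **multi-ton** — everything else; ambiguity always resolves to multi-ton.

Peeling subtracts each singleton from every group and repeats; the query
budget is $|T| = C (d{+}1) 2^b$ rows before deduplication, i.e.
$O(k \log^2 p)$ with the recommended $2^b \ge 2k$, $C = 3$. The noise
scale $\tau$ defaults to twice a median-based estimate
($1.4826 \cdot \mathrm{median}|U|$ — most bins are zero-tons under
sparsity) with a relative floor of $10^{-9}$ for noiseless exactness.
Maximum sweeps default to $2k + 10$ since every productive sweep removes at
least one coefficient.

## The synthetic world

`generate_sparse_landscape()` emulates the assumed structure directly:
`k_large = 5` coefficients with magnitudes uniform on $[8, 16]$ and
`k_small = 20` on $[0.1, 1]$, random signs; mask orders uniform on
$\{1..5\}$, then uniform over masks of that order; observation noise
$\sigma_e$ Gaussian, applied to samples only, never to the stored truth.
The magnitude bands make "a few large, many small" testable as two
disjoint histogram bands; orders 1–5 place substantial mass on
interactions an order-2 linear baseline cannot represent. The benchmark
noise level is $\sigma_e = 0.05 \times$ signal SD (by Parseval, the signal
SD is $\sqrt{\sum_{S \ne \emptyset} \alpha_S^2}$).

What the generator does **not** emulate: global monotone nonlinearities of
measurement scales (the Box-Cox stage exists for real data and is tested
for its own contract, not inside the generator), heteroskedastic or
sequencing-depth-dependent noise, missing genotypes, and correlated
mutational effects. A green benchmark therefore establishes that spectral
regularization helps when the sparse-spectrum assumption holds — not that
it helps on any particular measured landscape.

## Box-Cox stage

Profile log-likelihood over a fixed 101-point grid on $[-2, 2]$ (grid
unspecified upstream; fixed for determinism). Nonpositive inputs are
min-shifted to positivity plus $10^{-3} \times$ range unless `strict`;
the chosen power, shift and exact inverse are returned.

## Numerical choices and degenerate inputs

* Landscapes must have power-of-two length and finite values; constant
  landscapes transform to a single empty-set coefficient and are rejected
  (explicitly) by `variance_explained_curve()`.
* `en_loss`/`train_en` refuse $d > 25$ and point to the ADMM path.
* Subsampling maps are redrawn until full GF(2) column rank, so every bin
  index is reachable and the all-reference row is always queried.
* Adam (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`) on sum (not mean)
  losses; seeds fix initialization, shuffling, plans and noise streams
  separately, so paired method comparisons share data and initialization
  exactly.
* Model selection everywhere uses penalty-free validation MSE, the natural
  generalization proxy.

## Known limitations

* The exact path's per-step cost is $O(2^d \log 2^d)$; it is a reference
  implementation for $d \lesssim 20$ in practice.
* The ADMM path's recovered spectrum is a point estimate whose support
  depends on the plan's random hashes; rare collisions of large
  coefficients in every group would hide them from a given plan.
* The peeling success-rate guarantees are empirical here (Monte Carlo
  tests), not the coding-theoretic proofs of the underlying designs.
* Training budgets at desk scale (small $f$, hundreds of epochs) are
  deliberately below the scale used for real protein landscapes; the
  benchmark's effect sizes, not its absolute $R^2$ values, are the tested
  claim.
* The ADMM path approximates the exact penalty and can trail it when the
  network's spectral amplitudes hover near the proximal threshold
  $\sqrt{2\alpha/\rho}\,2^{-d/2}$: there the projection returns an empty
  spectrum and the coupling provides only shrinkage toward zero, not the
  exact path's graded $\ell_1$ pressure. On marginal instances the gap in
  test $R^2$ can exceed 0.1.
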