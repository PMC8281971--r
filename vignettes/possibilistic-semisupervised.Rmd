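---
title: "Possibilistic clustering-promoting semi-supervised classification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Possibilistic clustering-promoting semi-supervised classification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(possclass)
```

## The model

`possclass` fits a semi-supervised kernel classifier built on the
*clustering assumption* — similar instances should share a label — in a
*possibilistic* form: each instance $x$ carries a per-class membership
$w_m(x) \in [0, 1]$ that is **not** required to sum to one over classes.  A
boundary point or an outlier may therefore hold low membership in every
class, instead of being forced to split a unit of belief among classes the
way fuzzy (sum-to-one) memberships are.

Two functions are learned jointly on $n$ instances of which only
$l \ll n$ are labelled:

* a decision function $f(x) = \sum_{i=1}^n \alpha_i K(x_i, x)$ in the RKHS
  of a Mercer kernel $K$, with one output per class, and
* the membership function $w_m(\cdot)$ on the $u = n - l$ unlabelled
  instances; labelled instances keep fixed one-hot memberships throughout.

Classes are coded by one-hot vectors $c_m$.  Writing $\hat x_i$ for the
*local weighted mean* (LWM) of instance $i$ — the Gaussian-weighted average
of its $k$ nearest neighbours,
$\hat x_i = \sum_{j \in Ne(i)} W_{ij} x_j / \sum_{j \in Ne(i)} W_{ij}$ with
$W_{ij} = \exp(-\gamma\|x_i - x_j\|^2)$ — the joint objective minimized is

$$
\sum_{i \le l} \|f(x_i) - y_i\|^2
+ \lambda_s \sum_{i \le l} \|f(\hat x_i) - y_i\|^2
+ \sum_m \sum_{j > l} w_m(x_j)^2 \|f(x_j) - c_m\|^2
$$
$$
+ \lambda_s \sum_m \sum_{j > l} w_m(x_j)^2 \|f(\hat x_j) - c_m\|^2
+ \lambda \|f\|_{\mathcal H}^2
+ C \sum_m \sum_{j > l} \left( w_m^2 \ln w_m^2 - w_m^2 \right),
$$

subject to $0 \le w_m(x_j) \le 1$.  The membership exponent is fixed at 2:
exponent 1 collapses the problem to hard one-label-per-instance clustering,
and the quadratic form is the standard choice that keeps memberships
smoothly graded.  The last term is the *fuzzy-entropy* regularizer: without
it the trivial solution $w \equiv 0$ would erase all unlabelled terms; with
it, memberships are pushed away from zero in a way that decays
exponentially with the distance between $f$ and the class codes, which is
what lets genuinely far-off instances keep low membership everywhere.

### Alternating closed-form optimization

The objective is biconvex and both coordinate problems have closed forms.

**Decision step.**  With memberships fixed, the objective decouples across
the $M$ output coordinates of $f$ into weighted regularized least squares.
Every row $p$ of $\alpha$ solves the same symmetric linear system
$A\,\alpha_p^\top = b_p$ with

$$
A = K_l K_l^\top + K_u S K_u^\top
  + \lambda_s (\bar K_l \bar K_l^\top + \bar K_u S \bar K_u^\top)
  + \lambda K,
\qquad S = \mathrm{diag}\Big(\sum_m w_m(x_j)^2\Big),
$$

where $K_l, K_u$ are the labelled/unlabelled column blocks of the Gram
matrix and $\bar K$ is the LWM Gram matrix,
$\bar K_{ij} = \langle \phi(x_i), \phi(\hat x_j)\rangle$, computed from $K$
alone because each LWM is a convex combination of neighbours
(`lwmGram()`).  The right-hand sides collect the one-hot targets of the
labelled block and the squared memberships of the unlabelled block.
`solveDecision()` implements this; `decisionGradient()` exposes the exact
gradient so stationarity can be verified externally.

**Membership step.**  With $f$ fixed, each element separates and its
minimizer is the exponential

$$
w_m(x) = \exp\!\left(
  -\frac{\|f(x) - c_m\|^2 + \lambda_s \|f(\hat x) - c_m\|^2}{2C}
\right).
$$

The $\lambda_s$ factor on the LWM distance is kept because it is the exact
stationary point of the joint objective (dropping it would break the
monotone-descent guarantee the alternation relies on); at $\lambda_s = 1$
both conventions coincide.

`pcFit()` starts from labelled data only (unlabelled memberships zero, so
the first decision solve is a labelled-only LWM-regularized kernel ridge),
alternates the two steps, and stops when
$|F_t - F_{t-1}| < \varepsilon\,|F_{t-1}|$ or after `maxIter`
alternations.  Because each step is an exact coordinate minimizer the
objective trace is non-increasing, which the validity method of
`PCModel` and the test suite both enforce (relative tolerance $10^{-10}$).
Note that the trace need not stay positive: the entropy term is negative
and dominates once $C$ is large, so the stopping rule is applied to
$|F_{t-1}|$.

### The hard variant

`pcFitHard()` replaces the membership step by a hard assignment: each
unlabelled instance takes the single class minimizing
$\|f(x_j) - c_m\|^2 + \lambda_s\|f(\hat x_j) - c_m\|^2$ (`hardAssign()`),
i.e. memberships in $\{0, 1\}$ and no entropy term.  This is the classical
self-training-style ablation the soft method is contrasted against: it
commits fully to early decisions, which is exactly what makes it brittle
when the unlabelled pool contains instances that belong to no class.

### Consistency diagnostics

A fitted model predicts two ways — argmax of $f(x)$ or argmax of $w(x)$ —
and the agreement between the routes is a per-instance reliability signal
(`classifyConsistency()`):

* **intrinsic**: $f(x)$ and $f(\hat x)$ share the same argmax, so both
  routes agree for structural reasons;
* **fake_consistent**: the argmaxes differ, but
  $f_j(\hat x) - f_m(\hat x) < (f_m(x) - f_j(x)) / \lambda_s$ for every
  competitor $j$, which is algebraically equivalent to the two routes still
  naming the same class;
* **inconsistent**: neither holds — the instance sits near a decision
  boundary and its prediction should be treated as unreliable.

At $\lambda_s = 0$ the membership is a strictly decreasing transform of
$\|f(x) - c_m\|^2 = \|f\|^2 - 2 f_m + 1$, whose argmin is the argmax of
$f$, so the two routes agree *exactly* on every instance (the acceptance
script recomputes this as a 100% agreement rate).  `consistencySweep()`
refits across a $\lambda_s$ grid and reports both the prediction
consistency rate and the ground-truth (intrinsic) rate, reproducing the
characteristic decay from 100% toward the intrinsic rate as $\lambda_s$
grows.

## Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `lambda` | RKHS ridge penalty | 0.1 | dimensionless |
| `lambdaS` | LWM-consistency weight | 0.1 | 0 disables the LWM coupling |
| `C` | entropy balance | `"auto"` | mean distance of instances from their centroid (`divergenceC()`); same units as the feature space |
| `k` | LWM neighbour count | 5 | capped at $n-1$ |
| `gamma` | graph Gaussian width | `"auto"` | $1/(2\bar d^2)$, $\bar d$ = mean pairwise distance |
| `epsilon` | relative stopping threshold | $10^{-3}$ | |
| `maxIter` | alternation cap | 50 | 0 returns the labelled-only initialization |

Kernels: `linear`, `rbf` ($e^{-\gamma\|\cdot\|^2}$), `laplacian`
($e^{-\sigma\|\cdot\|}$), `inverse_square_distance`
($1/(1+\sigma\|\cdot\|^2)$), `inverse_distance` ($1/(1+\sigma\|\cdot\|)$),
`precomputed`, and `multi`.  A multi-kernel is the orthogonal concatenation
of component feature maps, so its Gram is the elementwise **sum** of the
component Grams (`combineGrams()`); component widths resolve independently
by the same auto heuristic ($\gamma = 1/(2\bar d^2)$ for rbf,
$\sigma = 1/\bar d$ for the distance kernels).  With a precomputed Gram
matrix the neighbour graph is built in the kernel-induced metric
$d^2_{ij} = K_{ii} + K_{jj} - 2K_{ij}$, which keeps the whole training
path Gram-only; out-of-sample membership scoring then requires features.

## The synthetic generator

`makeProblem()` emulates the statistical setting the method assumes:
Gaussian class blobs (adjacent centers `separation` within-class standard
deviations apart, placed on a circle in the first two coordinates, or on a
line in one dimension), a small stratified labelled set (per-class counts
or a round-robin total), and optional outliers drawn uniformly on a shell
at `outlierScale` (default 4) times the inlier data radius — placed on a
shell, rather than drawn heavy-tailed, so "belongs to no class" is
unambiguous and testable by construction.  A single seed governs all draws
in a documented order (class points, label sampling, outliers), so
fixtures are stable.

What the generator does *not* emulate: real EEG feature structure
(correlated channels, nonstationarity, subject effects), class overlap
beyond Gaussian tails, label noise, or covariate shift between labelled
and unlabelled pools.  Passing tests on these fixtures demonstrate the
optimization and the claimed structural properties, not field performance
on physiological data.

## Numerical choices

* **Singular decision systems.**  The system matrix squares the Gram
  matrix's condition number, and wide-auto-width RBF Grams at a few
  hundred points are numerically rank-deficient.  The solve path is:
  direct solve; on failure a diagonal jitter of
  $10^{-10}\,\mathrm{tr}(K)/n$; on failure an SVD minimum-norm
  least-squares solve (relative singular-value cutoff $10^{-12}$), with
  one warning per fit.  The right-hand side lies in the range of $K$, so
  the minimum-norm solution is still an exact stationary point — the
  objective is flat along the discarded directions.
* **Entropy convention** $0 \ln 0 = 0$, so the all-zero initialization has
  a finite objective; membership underflow clamps to 0 and is documented
  in `updateMembership()`.
* **Ties** in nearest-neighbour search and in argmax prediction break
  deterministically to the lowest index / lowest class code; duplicate
  points are legal neighbours with weight $e^0 = 1$.
* **Self-exclusion.**  $Ne(x_i)$ never contains $x_i$; including it would
  bias every LWM toward its own instance and weaken the consistency
  term.  For out-of-sample LWMs one zero-distance training copy is
  excluded, so scoring a training point reproduces its training LWM.  The
  neighbour weights are used per-point as the LWM definition consumes
  them; no symmetrization is applied.
* **Stopping guards**: an absolute floor $|F| < 10^{-12}$ counts as
  converged (protects the relative criterion near zero).

## The two regimes of the entropy balance C

The default `C = "auto"` follows the divergence heuristic, which ties $C$
to the *feature-space* scale.  The membership exponent, however, measures
distances in *label* space, where $\|f - c_m\|^2 \le 2$ for any $f$ inside
the simplex.  This creates two qualitatively different regimes, worth
understanding before trusting defaults:

* **Sharp regime** ($C \lesssim 1$): memberships discriminate strongly
  between classes; on well-separated data the soft and hard variants
  agree, training accuracy is essentially perfect, and out-of-sample
  shell outliers receive near-zero membership in every class — the
  textbook possibilistic behaviour.
* **Flat regime** ($C \gg 1$): all memberships sit near a common value and
  the entropy reward ($-Cw_m^2$ per element at the stationary point)
  dominates the squared losses.  The exact minimizer then pulls $f$
  toward the code centroid, shrinking class margins; run to strict
  convergence, unlabelled accuracy on cleanly separated blobs degrades
  substantially even though the objective decreases monotonically
  throughout (both facts are exercised in the test suite).  The default
  $\varepsilon = 10^{-3}$ stopping rule halts the alternation after a few
  sweeps, well before the collapse completes, which is why moderate
  accuracies are still reached at default settings.

On data whose divergence is of order 1 the heuristic lands in the sharp
regime and the two views coincide.  On widely spread data (the synthetic
blob conditions included), users who want sharply possibilistic
memberships should set `C` explicitly to order 0.1–1 rather than relying
on the heuristic; the package deliberately keeps the heuristic as the
documented default and leaves the choice visible rather than silently
rescaling it.

## Problem sizes used by the tests

The unit suite runs on instances of $n \le 30$ for oracle comparisons
(generic BFGS minimization of the decision objective, 1-D minimization of
the per-element membership term on a log scale) and $n$ of a few dozen to
a few hundred for end-to-end fits; the acceptance checks use the 3-class,
$n = 300$, separation-8, 10-label configuration with 20 replicate seeds,
and 100 randomized small fits for the monotonicity property.  Dense
linear algebra throughout; no attempt is made at large-$n$ scalability.

## Known limitations

* Dense $O(n^3)$ solves per alternation; a few thousand instances is the
  practical ceiling.
* The divergence heuristic for $C$ is scale-sensitive (see above); there
  is no internal rescaling of features.
* Precomputed-kernel models cannot score new feature vectors (no feature
  map is available); they predict on the training set or from
  user-supplied cross-Gram columns via `decisionValues()`.
* Multi-kernel combination uses fixed unit weights; kernel-weight
  learning is out of scope.
* Sum-to-one (fuzzy) memberships are intentionally not provided — the
  point of the possibilistic relaxation is that outliers need not spend a
  unit of belief — so this package is not a drop-in for methods that
  require a membership simplex.
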