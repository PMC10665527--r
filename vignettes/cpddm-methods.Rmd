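---
title: "Possibilistic distribution alignment: the model behind cpddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Possibilistic distribution alignment: the model behind cpddm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpddm)
```

# The problem

Unsupervised domain adaptation: a labeled source sample
$\{(x_i^s, y_i^s)\}_{i=1}^n$ and an unlabeled target sample
$\{x_j^t\}_{j=1}^m$ share a feature space and a label space (classes
$1..C$), but not a distribution — neither the covariates nor the
class-conditional laws coincide. The goal is a target classifier. In the
EEG setting that motivated this method each subject is a domain and the
features are band-power summaries per channel; the package treats the
domains as generic numeric matrices.

Classical kernel alignment minimizes the empirical squared maximum mean
discrepancy, the RKHS distance between the two empirical mean embeddings.
Its weakness is the *mean*: a few far outliers (artifact epochs, mislabeled
trials) translate the empirical mean embedding arbitrarily, and alignment
then actively hurts. Everything in this package follows from replacing the
hard mean with memberships.

# The model

## Possibilistic one-cluster relaxation

Write $\phi$ for the feature map of a PSD kernel $K$ and
$\mu_c = \delta\,\mu_{s,c} + (1-\delta)\,\mu_{t,c}$ for the blended class
centers, $c = 0$ denoting the whole domain. All centers are affine
combinations of mapped samples, so every squared distance
$d_{k,c} = \|\phi(x_k) - \mu_c\|^2$ is computed purely through Gram-matrix
expansions (`class_mean_coefficients()`, `rkhs_mean_distances()`); no
explicit feature space is ever materialized for the alignment.

The alignment objective is

$$\Omega(\lambda) \;=\; \sum_{c=0}^{C}\sum_{k=1}^{N} \lambda_{k,c}^2\, d_{k,c}
\;+\; \beta \sum_{c=0}^{C}\sum_{k=1}^{N}
\left(\lambda_{k,c}^2 \ln \lambda_{k,c}^2 - \lambda_{k,c}^2\right),
\qquad \lambda_{k,c} \in [0,1].$$

The quadratic membership exponent ($b = 2$) avoids the trivial linear-program
solution; the fuzzy-entropy term (weight $\beta$) prevents the all-zero
degenerate optimum and pushes *relevant* samples toward full membership.
The subproblem decouples per entry and has the closed-form stationary point
$$\lambda_{k,c}^2 = \exp\!\big(-(d_{k,c} + e_k)/\beta\big),$$
where $e_k$ is the current classifier residual of sample $k$ (it carries no
class index, so it enters every column identically). Far samples and badly
fit samples are downweighted *exponentially* — this is the entire
robustness mechanism, and `update_memberships()` is verified against a
$10^{-6}$-grid scalar minimization in the tests.

A reading note: the stationarity condition fixes $\lambda^2$, not
$\lambda$, as $\exp(-J/\beta)$. Since every downstream formula consumes
$\lambda^2$, the package implements the $\lambda^2$ form; the alternative
reading would only rescale $\beta$.

## Why minimizing $\Omega$ minimizes the MMD — with corrected constants

The justification for the relaxation is a domination argument: with uniform
memberships of the right size, the one-cluster objective upper-bounds the
empirical MMD, so the relaxation never "cheats" the original criterion.
The chain is
$$\mathrm{MMD}^2 = \|\hat\mu_s - \hat\mu_t\|^2
\le 2\|\hat\mu_s - \mu\|^2 + 2\|\hat\mu_t - \mu\|^2
\le \frac{2}{n}\sum_{i \in s}\|\phi(x_i)-\mu\|^2
  + \frac{2}{m}\sum_{j \in t}\|\phi(x_j)-\mu\|^2,$$
the first step the squared triangle inequality, the second Jensen's
inequality, valid for every $\delta \in [0,1]$. The fixed memberships are
therefore $\varsigma_k = 2/n$ (source) and $2/m$ (target), and the uniform
possibilistic membership that preserves the bound is
$\lambda_k = \sqrt{2/r}$, $r = \min(n,m)$.

This is a deliberate correction: the weights $1/n^2, 1/m^2$ sometimes
quoted for this construction do **not** dominate the MMD — they lose a
factor $2$ in the triangle step and a Cauchy–Schwarz factor $n$ in
$\frac{1}{n^2}\|\sum_i(\phi(x_i)-\mu)\|^2 \le \frac{1}{n}\sum_i
\|\phi(x_i)-\mu\|^2$. Numerically, with both domains drawn from the same
distribution ($n = m = 20$, Gaussian kernel), the $1/n^2$ version falls
*below* the empirical MMD on roughly half of random instances, while the
$2/n$ version holds on all of them (`one_cluster_bound()`; the acceptance
suite checks 200 instances). An expectation calculation shows why: under
equal distributions the $1/n^2$ quantity matches the MMD only to leading
order and sits below it by $O(1/r^2)$ on average.

## Label propagation and the classifier

Target knowledge is inferred by two coupled terms. A symmetrized $k$-NN
graph over the pooled samples with Gaussian affinities
$M_{ij} = \exp(-\|x_i - x_j\|^2 / 2\sigma_g^2)$ and unnormalized Laplacian
$L = D - M$ supplies the smoothness penalty
$\alpha\,\mathrm{tr}(Y^\top L Y)$ (neighboring samples should share
labels). The sign convention matters: with $L = M - D$ the trace is
unbounded below, so the package uses the standard PSD Laplacian.

The classifier is linear in an explicit feature space,
$f(x) = \tilde x^\top W$ with a bias column, penalized by the row-sparsity
norm $\|W\|_{2,1} = \sum_i \|w^i\|_2$ (feature selection, complexity
control). The membership-weighted least-squares term uses per-sample
weights $\omega_k = \sum_{c=0}^{C} \lambda_{k,c}^2$: read literally from
the joint objective, the $k$-th squared residual appears once per class
column, so its total coefficient is the column sum. This choice (rather
than, say, the membership of the sample's current class only) is what makes
the membership update and the classifier update coordinate-descent steps on
*the same* functional — with a per-class weight the membership update would
no longer be the exact block minimizer and the monotonicity guarantee below
would fail structurally. Outlier downweighting is unaffected: an outlier
has a small membership in every column.

`fit_weighted_l21()` solves the convex weighted problem by iteratively
reweighted least squares, alternating
$W = (\tilde X^\top \Omega \tilde X + \rho U)^{-1} \tilde X^\top \Omega Y$
with the majorizer refresh $U_{ii} = 1/(2\|w^i\| + \varepsilon)$,
$\varepsilon = 10^{-8}$. The $1/(2\|w^i\|)$ form is the standard
half-quadratic majorizer whose descent argument is exact; the
$\varepsilon$ floor keeps it defined at zero rows at the cost of an
$O(\rho\varepsilon)$ slack per iteration, which is why the tests assert
monotonicity at $10^{-8}$ rather than machine precision.

## The spectral label update

Substituting the classifier closed form $W = \tilde A Y$ profiles $W$ out
of the objective and leaves $\min_{Y^\top Y = I} \mathrm{tr}(Y^\top H Y)$
with $H = \alpha L + B^\top \Omega B + \rho \tilde A^\top U \tilde A$,
$B = \tilde X \tilde A - I$. Two notes:

* Orthogonality is imposed as $Y^\top Y = I$ ($N \times C$, $N > C$); the
  transposed convention is infeasible at this shape.
* The last term of $H$ is the profiled value of the penalty majorizer
  $\rho\,\mathrm{tr}(W^\top U W)$ at $W = \tilde A Y$. Dropping it (a
  common shortcut, available as `assemble_H(exact_profile = FALSE)`) makes
  the spectral step blind to the penalty and admits small objective
  increases; including it makes the step an exact profiled minimization.
  Both forms have the same heavy-penalty limit $H \to \alpha L + \Omega$.

The minimizer is the span of the $C$ smallest eigenvectors (Ky Fan), which
is only defined up to rotation. The relaxed solution is aligned to the
known one-hot source block by the Procrustes rotation minimizing
$\|Y_{rel}[src]R - Y_s\|_F$, target rows are discretized by row-wise argmax
(ties broken toward the lowest class index), and source rows are restored
— source labels are data, not variables, after the relaxation. Source rows
do participate as free variables *inside* the eigenproblem; freezing them
there would destroy the closed form.

# The alternating solver

`cpddm_fit()` alternates the three closed-form updates (memberships →
classifier → labels), after a hot start in which a source-only classifier
pseudo-labels the target. One structural decision deserves its own
paragraph.

**The relaxed label matrix is the working regression target.** Within the
loop, residuals are measured against — and the classifier is fit to — the
Procrustes-rotated orthonormal $Y$, and after each spectral step the
classifier is materialized as $W = \tilde A Y_{rot}$. The discretized
one-hot $Y$ is used where classification semantics require it: refreshing
the target pseudo-labels that define the class means (dynamic
pseudo-labeling, on by default; `refresh_pseudo_labels = FALSE` freezes
them for ablation), the stopping rule, and all reporting and prediction.
With this arrangement every block update provably does not increase the
relaxed joint objective, and the recorded `theta_relaxed` trace is
non-increasing to numerical precision on every seeded test problem. The
hybrid alternative — fitting $W$ to the discretized labels while tracking a
relaxed objective — was tried first and produced objective *increases* of
order one on the first iteration; it is the discretization, not the
mathematics, that breaks monotonicity there. The only remaining
non-monotone event is a pseudo-label refresh (it moves the class means
$\mu_c$, i.e. changes the objective being descended); empirically the trace
stays monotone because refreshes happen early, while the objective is still
falling steeply.

The stopping rule observes the *discretized* objective:
$|\Theta^z - \Theta^{z-1}| < \varepsilon$ with $\varepsilon = 10^{-5}$
(absolute), capped at $Z = 50$ iterations. Both traces, label-change
counts, and membership quantiles are recorded per iteration
(`state$trace`, exportable with `write_iteration_log()`).

Prediction refits a source classifier on the source rows (true labels) and
a target classifier on the target rows (inferred labels), both weighted by
the final memberships, and fuses their scores with weight $\upsilon = 0.9$
on the source side — source labels are ground truth and deserve most of the
vote; the self-trained target classifier contributes local refinement.

# Parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `alpha` | 1 | Weight of the Laplacian smoothness term. |
| `beta` | 1 | Fuzzy-entropy weight; sets the distance scale at which downweighting begins ($\lambda^2 = e^{-d/\beta}$). |
| `rho` | 1 | $\ell_{2,1}$ penalty; larger values zero out feature rows. |
| `delta` | 0.5 | Source share in the blended means; 0.5 treats domains symmetrically. |
| `upsilon` | 0.9 | Source share in the fused prediction. |
| `k_neighbors` | 5 | Affinity-graph degree; the customary search grid is {3, 5, 10, 15, 17}. |
| `sigma` (kernel) | data-driven | $\sqrt{\mathrm{mean}_i \|x_i\|}$, times $C$ for $C > 2$; a median-pairwise-distance heuristic is available (`default_sigma(method = "median_dist")`). |
| `theta` | 1 | Gaussian bandwidth divisor in $[1, \theta_0]$, $\theta_0 = 10$; only the Gaussian family is $\theta$-parameterized, the other families use `sigma` as a distance multiplier as defined. |
| `epsilon`, `max_iter` | $10^{-5}$, 50 | Stopping rule (absolute) and iteration cap. |

All of `alpha`, `beta`, `rho` are conventionally grid-searched over
$\{10^{-6}, \ldots, 10^{6}\}$ when labeled validation data exists; in the
unsupervised setting the defaults of 1 are used throughout the package's
tests. Class means average *within* classes ($1/n_c$ per member): the
whole-class blend is what "the class-$c$ mean" means; an $1/n$
normalization summed across classes would make every class mean a rescaled
copy of the domain mean and erase the semantic alignment.

Degenerate inputs are handled explicitly: a class with no target members
falls back to its source mean (common in early iterations); a class absent
from both domains is flagged inactive, its distance column is `NA` and its
memberships 0; squared distances in $[-10^{-10}, 0)$ are clamped to 0 and
anything more negative raises an internal-consistency error; membership
exponents below $-700$ underflow to an exact 0; a singular normal matrix at
$\rho = 0$ is solved by pseudo-inverse with a warning; zero-degree graph
nodes are allowed (their Laplacian row is zero).

# The synthetic generator

`make_two_domain_blobs()` is the package's study harness, not a fixture
file: isotropic unit-variance Gaussian classes at simplex vertices scaled
by `class_separation` (default 4 — clearly separated but not trivial at
unit noise), a common random-direction translation of the target
(`shift_magnitude`, default 1), a fraction of source rows replaced by
points at `outlier_scale` × `class_separation` from the class-mean centroid
(default scale 10 — far enough to induce the mean shift the memberships
must absorb), and an exact-count uniform label flip
(`inject_label_noise()`; counts round half away from zero). Identical
seeds give identical bundles; the generator restores the caller's RNG
state.

What it does *not* emulate about real EEG features: anisotropic and
correlated noise (band-power features are strongly correlated across
channels), class imbalance, temporal dependence between epochs, and
structured (non-random) label noise. Passing the package's tests therefore
demonstrates the mechanism — outlier downweighting, noise-tolerant
alignment, monotone optimization — under controlled conditions, not
state-of-the-art accuracy on any particular EEG corpus.

Problem sizes in the tests and the acceptance script (n = m = 60, d = 5,
C = 3, 10–20 seeds per condition) were chosen as the smallest scale at
which the distributional effects are comfortably visible above sampling
noise; the solver itself is dense-linear-algebra bound and handles a few
thousand pooled samples.

# Known limitations

* The $\ell_{2,1}$ penalty needs an explicit feature space, so the
  classifier is linear (identity map) or kernel-approximate
  (`map_type = "random_fourier"`, seeded, dimension 300 by default); there
  is no exact representer-theorem dual for the penalized kernel classifier.
* Per-step descent of the relaxed objective is exact only between
  pseudo-label refreshes; a refresh re-targets the class means and can in
  principle raise the objective (not observed on the test conditions).
* Multi-kernel combination is an unweighted sum of component Grams
  (concatenated feature map); kernel weights are not learned.
* The four cross-validation protocols used in subject-transfer studies and
  semi-supervised target labels are out of scope; the package provides a
  single fit/predict/evaluate path.
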