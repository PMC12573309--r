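---
title: "Sparse longitudinal CCA with latent trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse longitudinal CCA with latent trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tosccamm)
```

## The problem

Canonical correlation analysis (CCA) integrates two feature sets by finding
linear projections — latent variables — that are maximally correlated.
Standard CCA assumes independent observations, which repeated measurements
violate: visits from the same individual are correlated, visit times differ
between the two data sources, and individuals may miss visits in one source
but not the other. This package implements TOSCCA-MM, a sparse CCA for
exactly this setting: two long-format longitudinal views
$X \in \mathbb{R}^{(\sum_i m_i) \times p}$ and
$Y \in \mathbb{R}^{(\sum_i s_i) \times q}$, where individual $i$ contributes
$m_i$ visits at times $t_{x,i}$ to $X$ and $s_i$ visits at times $t_{y,i}$
to $Y$, with no requirement that the two grids match.

The model keeps the canonical weights $w_x, w_y$ **fixed across
measurements** and puts all time dynamics on the low-dimensional latent
variables: $\eta = X w_x$ and $\gamma = Y w_y$ are treated as noisy
observations of smooth individual trajectories
$f(t) = \alpha_i + x(t)^\top\beta$, fitted with linear mixed models. Because
the trajectories live in the latent space, the longitudinal modelling costs
almost nothing even when $p$ is in the tens of thousands.

## The algorithm

One component is estimated by an alternating (NIPALS-type) iteration.
Starting from a seeded random unit vector $w_x^{(0)}$:

1. $\eta \leftarrow X w_x$; fit the X-side trajectory model to
   $(\mathrm{id}, t_x, \eta)$; predict $\tilde\eta$ on Y's $(\mathrm{id}, t_y)$ rows.
2. $\tilde w_y \leftarrow Y^\top \tilde\eta$; threshold to exactly $q_y$
   nonzeros and renormalize; $\gamma \leftarrow Y w_y$ (unit norm).
3. Fit the Y-side trajectory to $(\mathrm{id}, t_y, \gamma)$; predict
   $\tilde\gamma$ on X's rows.
4. $\tilde w_x \leftarrow X^\top \tilde\gamma$; threshold to $p_x$ nonzeros;
   $\eta \leftarrow X w_x$ (unit norm).
5. $\rho \leftarrow \mathrm{cor}(\tilde\gamma, \eta)$; stop when
   $|\rho^{(l)} - \rho^{(l-1)}| \le \xi$.

The trajectory predictions are the device that reconciles the two views'
mismatched grids: each weight update regresses one view's features on the
*predicted* latent values of the other view at that view's own visits.

Subsequent components are extracted after deflating both matrices by the
previous component's unit-norm scores, $X \leftarrow X - \eta(\eta^\top X)$,
which enforces pairwise orthogonality of the latent variables exactly.

### Numerical choices

* **Thresholding.** The sparsity parameter is a cardinality, not a penalty:
  the threshold is the $(k{+}1)$-th largest absolute entry, every entry is
  soft-shrunk by it, and the result is renormalized. For generic inputs this
  leaves exactly $k$ nonzeros; ties at the boundary shrink to zero, which is
  deterministic. An all-zero update yields a flagged degenerate component
  (correlation 0, not converged) rather than an error.
* **Correlation across mismatched grids.** $\eta$ and $\gamma$ live on
  different row sets, so "their correlation" needs a definition: we pair the
  trajectory-predicted $\tilde\gamma$ with $\eta$ on X's rows (the quantities
  the algorithm actually regresses on) and also report the symmetric Y-side
  value. A sign convention flips $w_y$ if needed so the reported correlation
  is nonnegative (the trajectory model is linear in its response, so the
  flip is exact).
* **Convergence** uses the absolute change in $\rho$ (defaults
  $\xi = 10^{-6}$, 100 iterations). The weight update is the covariance form
  $Y^\top\tilde\eta$; the full least-squares form
  $(Y^\top Y)^{-1}Y^\top\tilde\eta$ differs only by column scaling for
  standardized data and is available behind a flag.
* **Standardization.** Feature columns are centered and scaled by default
  (zero-variance columns are centered only); latent scores are normalized to
  unit Euclidean norm, which makes $\rho$ a cosine on centered data and
  keeps deflation exact.
* **Initialization** is a standard-normal draw from a user-supplied seed;
  the seed is required, so every fit is exactly reproducible.

### Trajectory families

Three mixed-model families are provided, all with individual random
intercepts and raw-power time bases: linear, polynomial of degree $d$, and a
change-point model $(1, t, t^2, t^3, t\,1\{t > s\})$ for event-centered time
scales. The change point $s$ is supplied, not estimated, and defaults to 0;
a $(t-s)$ post-change parameterization is available via `shifted = TRUE`
(the two span the same model space when the basis already contains $t$). Raw
powers mirror the model as usually written; for long time ranges they are
ill-conditioned, so centering the time variable is advisable. Estimation is
REML via lme4 (ML optional), refit at every iteration since the algorithm
places the trajectory step inside the loop. Three robustness rules keep the
outer iteration alive: noiseless scores that the basis plus offsets
interpolate exactly are decomposed directly (the mixed-model optimizer
cannot handle zero residual variance); optimizer failure or a singular fit
($\sigma_b^2 \to 0$) falls back to fixed-effects-only least squares with a
flag; and predictions for individuals unseen at fit time use the fixed
curve alone (the BLUP of an unobserved random effect is its prior mean).
A degenerate `passthrough` family returns training scores unchanged; with
one visit per individual it reduces the algorithm exactly to plain
cross-sectional sparse NIPALS, which the test suite exploits as an oracle.

## Model selection

**Sparsity** is chosen per component by cross-validation over a grid of
$(p_x, q_y)$ pairs. Folds partition *individuals* — all visits of an
individual stay together, which is what makes the CV valid under clustering.
The out-of-fold criterion is the aligned correlation between held-out X
scores and the trajectory-predicted Y latent values on the same rows (fixed
curve only, as held-out individuals are unseen); ties prefer the sparser
pair. Features are standardized once on the full data before folding: the
scale parameters are low-variance global summaries, and re-standardizing per
fold changes third-decimal details at most.

**Adjusted CPEV** reports the fraction of a view's total variance captured
by the span of the first $k$ latent scores,
$\mathrm{tr}(M^\top P_k M)/\mathrm{tr}(M^\top M)$ with $P_k$ the orthogonal
projector onto the scores and $M$ the original standardized matrix. The
projector form is the standard adjustment for non-orthogonal sparse
loadings; it depends only on the span, is nondecreasing in $k$, and is
computed via a QR decomposition.

**The number of components** is assessed by permutation. The permutation
unit is the whole individual: Y's individual blocks are re-assigned against
X with each time series kept intact, preserving within-individual
correlation, and the component is refitted on every permuted dataset at the
observed sparsity. The test statistic deserves care. Both views share
whatever population-level time pattern the latent variables carry — the
fitted trend *and* any common misfit of the trajectory family — and no
permutation of individuals can destroy it, so the raw canonical correlation
has essentially no power in the presence of a strong common trend (its null
distribution sits just under the observed value). The default statistic is
therefore the **visit-level residual association**: each view's scores minus
their fitted individual trajectories, centered within time points, and
correlated across the visits present in both views. This measures exactly
the individual-level association that block permutation exchanges. The raw
correlation remains available (`statistic = "rho"`) for data without common
trends. P-values use $(1 + \#\{T^*_b \ge T_k\})/(B+1)$, so the smallest
attainable value is $1/(B+1)$.

A caveat follows from deflation: estimated scores correlate imperfectly with
the true latent series (with unit-variance feature noise over $s$ active
features the ceiling is roughly $\sqrt{v_z/(v_z + 1)}$ for latent variance
$v_z$), so rank-1 deflation leaves a residue of genuinely shared variation
in both views. A calibrated, powered test applied to the next component can
legitimately reject on this residue; a significant third component after two
strong ones is therefore not necessarily evidence of a third mechanism, and
the adjusted CPEV curve should be read alongside the p-values.

## The synthetic-data generator

`generate_dataset()` reproduces a probabilistic-CCA generative process with
a shared dynamic latent variable. Per component, one latent series per
individual drives both views: $z_{k,i}(t) = \mu_k(t) + b_{k,i} +
\varepsilon_{k,i,t}$ with population curves
$\mu_1(t) = \theta_0 t + \sin(\theta_1 t)\,t$ and
$\mu_2(t) = \theta_2 t + (1 + t/\max t)^3$, offsets
$b \sim N(0, \sigma_b^2)$ and i.i.d. visit noise
$\varepsilon \sim N(0, \sigma_\varepsilon^2)$ per component, individual and
visit. Observations are $x_i(t) = \sum_k z_{k,i}(t) w_{x,k}^\top + e$, with
observation noise AR(1) over time (unit marginal variance, correlation
$\rho_t$, independent across features) — the minimal structure with ones on
the noise covariance diagonal and nonzero off-diagonals in time. True
weights have equal magnitude $1/\sqrt{s}$ with alternating signs on fixed,
disjoint supports (10 per component in X, 5 in Y at the reference scale).
Missingness removes exactly `round(miss * n * n_times)` visits per view
uniformly at random — deterministic row counts, and an individual can lose
none, several or all visits.

Reference defaults: $n = 100$ individuals, $p = 10{,}000$ and $q = 200$
features, 10 visits at $t = 1..10$, two components, 20% of X visits and 30%
of Y visits removed. The curve and noise parameters are not dictated by the
design and were fixed once at $\theta_0 = 0.5$, $\theta_1 = 1$,
$\theta_2 = -0.3$, $\sigma_b = \sigma_\varepsilon = 0.5$, $\rho_t = 0.3$:
values that make the trajectories visibly nonlinear (the first curve
oscillates with growing amplitude; a cubic tracks it only imperfectly,
deliberately exercising the misspecified-trajectory regime) while keeping
the signal recoverable at these dimensions. With these choices the
population curve dominates the latent variance, so individual-level
association is a small fraction of the total — the regime in which the
trend-adjusted permutation statistic matters.

What the generator does *not* emulate: non-Gaussian features, count or
compositional data (microbiome abundances are both), feature-feature
correlation beyond the shared latent variable, informative missingness, or
event-centered time rearrangements of real cohorts. Passing tests on this
generator show that the algorithm recovers sparse supports and latent
dynamics under Gaussian noise with time-correlated errors and visit-level
missingness — not that it is robust to the full messiness of real omics
data.

`evaluate_recovery()` matches estimated to true components by maximal
absolute latent correlation (greedy, signs aligned) and reports support
true/false positives plus the correlation between the **estimated mean
latent trajectory** and the true population curve. The estimated mean path
is the per-grid-time mean of the estimated latent scores, not the fitted
trajectory curve: the deliberately misspecified cubic smooths away the
oscillation of $\mu_1$ (their correlation is only about 0.76 on the design
grid), while the scores themselves track it essentially perfectly when the
weights are right.

## Problem sizes used in the shipped checks

The packaged tests exercise the generator at its reference scale
($800 \times 10{,}000$ X rows after missingness) for the end-to-end
recovery, cross-validation and permutation checks ($B = 99$, three
components), and use small instances (tens of individuals, tens of
features) for the algebraic oracles: the plain-NIPALS reduction, exhaustive
sparse-pair search on a $4\times 2$ toy, the dense-projector CPEV check,
and a 50-replicate type-I calibration of the permutation test under
independent noise. These sizes were chosen so the whole suite reflects the
reference study while each individual check stays small enough to iterate
on comfortably.

## Known limitations

* Only two views; no per-time-point weights (dynamics live entirely on the
  latent variables); no random slopes, ARIMA or spline trajectory families;
  the change point is supplied, never estimated.
* Raw polynomial bases can be badly conditioned on long uncentered time
  ranges.
* Score-deflation residue can make permutation p-values for components
  beyond the true rank significant (discussed above).
* The CV criterion is one-sided (X scores against predicted Y values); the
  symmetric criterion would differ slightly on strongly unbalanced designs.
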