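---
title: "Compositional sparse CCA: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional sparse CCA: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cscca)
```

## The problem

Microbiome sequencing yields relative abundances: the per-sample total is
a sequencing artifact, so only ratios between taxa carry information. When
such a table is paired with another omics table (metabolites, transcripts,
or a second compositional table such as fungal taxa), canonical
correlation analysis is the natural tool for asking which combinations of
features co-vary across the two datasets. In high dimensions sparse CCA
(sCCA) adds an l1 penalty so that a small, interpretable set of features
is selected. Plain sCCA, however, treats the log-abundances as
unconstrained covariates; a change of sequencing depth then moves every
log-abundance by a common per-sample shift, and the fitted directions pick
up that artifact.

`cscca` constrains the coefficients of log-transformed compositional
features to sum to zero. For any zero-sum vector $b$, the score
$Z b = \sum_j b_j \log X_j$ is a linear combination of log-ratios, so it
is invariant to per-sample rescaling of the composition and no reference
taxon has to be chosen.

## Model

Let $Y \in \mathbb{R}^{n \times q}$ be the non-compositional table and
$Z = \log X \in \mathbb{R}^{n \times p}$ the log-compositional one, with
$\widehat\Sigma_{YZ}$ their sample cross-covariance. Following the
diagonal-covariance convention common to high-dimensional CCA, the
within-set covariances are replaced by the identity, and the Lagrangian
problem is

$$
\min_{a,\,b} \; -a^\top \widehat\Sigma_{YZ}\, b
  + \lambda_a \lVert a \rVert_1
  + \lambda_b \lVert b \rVert_{1,w}
\quad \text{s.t.}\quad
\lVert a\rVert_2 \le 1,\; \lVert b \rVert_2 \le 1,\; \textstyle\sum_j b_j = 0,
$$

where $\lVert b \rVert_{1,w} = \sum_j w_j |b_j|$ carries optional
per-feature weights. The two-sided variant additionally constrains
$\sum_j a_j = 0$ for a second compositional table.

### Alternating updates

The problem is biconvex and solved by alternating:

* **b-step.** $b \propto g(\widehat\Sigma_{YZ}^\top a, \lambda_b, w)$,
  where $g(h, \lambda, w) = \arg\min_{1^\top b = 0} \tfrac12 \lVert h - b
  \rVert^2 + \lambda \lVert b \rVert_{1,w}$ is the weighted-l1 proximal
  operator on the zero-sum hyperplane, followed by l2 normalization.
* **a-step.** Soft-threshold $v = \widehat\Sigma_{YZ} b$ at $\lambda_a$
  and normalize; if $\lambda_a \ge \lVert v \rVert_\infty$ the side
  collapses to zero and the fit is flagged degenerate.

The prox $g$ is computed by an augmented Lagrangian method: an outer dual
ascent on the zero-sum constraint ($d \leftarrow d + \mu_2 1^\top b$)
around an inner cyclic coordinate descent whose coordinate update has the
closed form $b_j = S(h_j - \mu_1(\sum_{i \ne j} b_i + d), \lambda
w_j)/(1+\mu_1)$, with $S$ the soft-thresholding operator. Both step sizes
default to $\mu_1 = \mu_2 = 1$.

### Adaptive and structure-adaptive weights

The weights $w$ can be estimated jointly with $(a, b)$ by adding
$-\sum_j \log h(w_j; \gamma)$ to the objective, where
$h(w;\gamma) = \exp\{w^{1-1/\gamma}/(1-1/\gamma)\}$ for $0<\gamma<1$ and
$h(w;1)=w$. Minimizing over $w$ inside a feasible set $M$ has closed
forms:

* elementwise box $M=[0, C_U]^p$: $w_j = |b_j|^{-\gamma}$, capped at
  $C_U$ and set to $C_U$ when $b_j = 0$ — the iterative adaptive lasso;
* group set (weights shared within taxonomic groups): one weight per
  group, $(\text{mean}_{j \in S_d} |b_j|)^{-\gamma}$, with $C_U$ for
  all-zero groups.

The group set is a *soft* use of the taxonomy: an informative grouping
drives the penalty on background groups to the cap $C_U$ (effectively
removing them), while a misspecified grouping merely averages magnitudes
within groups and degrades gracefully toward the elementwise behavior.
Weights start at one, so the first iteration coincides with the
non-adaptive fit; weights are recomputed after every b-step. Elementwise
adaptive weights are applied on the a side as well.

## Tuning

Penalties are chosen by two-stage K-fold cross-validation (default
$K = 5$). For a candidate $(\lambda_a, \lambda_b[, \gamma])$ and each
fold: the method is fitted on the training samples, features with zero
coefficients are excluded, and the coefficients are *recomputed* on the
training samples with penalties $(0, 0)$ restricted to the selected
features, keeping the zero-sum constraint on compositional sides. The CV
value is the mean Pearson correlation of the held-out projected scores
under the refitted coefficients; the refit removes the shrinkage bias that
would otherwise favor weak penalties. The maximizing grid point is
selected, ties broken by grid order. Optionally the CV value is averaged
over several independent fold partitions (`n_replications`) to mitigate
the randomness of a single split.

Conventions for degenerate cases: a fold whose stage-1 support is empty —
or has fewer than two features on a zero-sum side, where a single
coefficient cannot sum to zero — contributes correlation 0, as does a
constant held-out score. This penalizes over-sparse candidates instead of
silently dropping folds.

### Penalty grids

Default grids are data-driven: the collapse level of each side (the
penalty at which the first update zeroes out: $\lVert v \rVert_\infty$
for an unconstrained side, half the range of $h$ for a zero-sum side,
whose hyperplane absorbs common shifts) is computed from the initial SVD
direction, and `nlam = 10` evenly spaced values per side span 5%–95% of
it, from a dense fit to the edge of degeneracy. Even spacing follows the
penalized-matrix-decomposition tuning convention; a log-spaced grid
concentrates candidates in the near-zero dense tail where all fits use
nearly every feature and the CV criterion cannot discriminate among
them, which biases the argmax toward over-dense solutions. For adaptive
variants the grid is crossed with $\gamma \in \{0.5, 1\}$. Grid
resolution matters most for the non-adaptive variants, whose selection
relies entirely on $\lambda_b$; the adaptive variants self-sharpen
through the weights and are less grid-sensitive.

## Numerical choices

* **Tolerances.** The prox stops when both the zero-sum residual and the
  max-norm change across an outer iteration fall below `inner_tol`
  (1e-8); the alternation stops at max-norm change `outer_tol` (1e-6) of
  both directions, capped at 200 iterations. Inside cross-validation the
  fits run at looser tolerances (1e-6 / 1e-4, 100 iterations) since only
  the selected supports and held-out correlations are consumed, and both
  are stable well before the final-precision directions.
* **Active-set sweeps.** The inner coordinate descent iterates the cyclic
  sweep over the currently nonzero coordinates and confirms convergence
  with a full sweep over all coordinates, so the fixed point is identical
  to always sweeping everything, at a fraction of the cost on sparse
  solutions.
* **Warm starts.** The prox is warm-started from the previous outer
  iterate (first call: the zero-sum projection of its input). The
  solution is unique by strict convexity, so warm starts affect speed
  only.
* **Sign convention.** $(a, b)$ and $(-a, -b)$ are equivalent; the
  returned pair is oriented so the largest-magnitude entry of $a$
  (lowest index on ties) is positive, making runs reproducible and RMSE
  comparisons well defined.
* **Degenerate fits.** A collapsed side returns the zero vector with a
  flag; the reported sample correlation is 0.
* **Rare alternation cycles.** At strongly sparse penalty pairs the
  alternation can oscillate between two near-degenerate supports; the
  iteration cap then returns the last iterate with a warning. Inside
  cross-validation such candidates score poorly and are never selected.

## The synthetic-data generator

The generator draws a scalar latent variable $\nu_i \sim N(0,
\sigma_\nu^2)$ per sample and sets $\log X_i = \nu_i \omega_X +
\varepsilon_{X,i}$, $Y_i = \nu_i \omega_Y + \varepsilon_{Y,i}$ (for the
two-sided setups, $\log Y_i$), with isotropic $N(0, \sigma_\varepsilon^2)$
noise; $\sigma_\nu/\sigma_\varepsilon$ controls the association strength.
Setups S1–S4 fix the loading patterns: S1 concentrates the compositional
signal in the first 10 coordinates (nine equal positives balanced by one
large negative), exactly filling taxonomic groups; S2 splits six nonzero
entries across two groups containing zeros, emulating noisy structure
information; S3 and S4 are their two-sided analogues with a zero-sum
$\omega_Y$. Defaults: $\sigma_\varepsilon = 1$, $\sigma_\nu = 4$,
$p = q = 100$ with 20 groups, and $n = 100$ samples per replicate — a
sample size of the same order as typical cohort studies in this field and
comparable to the real-data scale the model targets.

What the generator does *not* emulate: zero inflation and the count
sampling layer (the model works on the log scale directly), overdispersed
library-size variation (irrelevant by design — the methods are invariant
to it), correlated noise between features, and non-Gaussian tails.
Passing the simulation suite therefore demonstrates correct recovery under
the stated latent-variable model, not robustness to the full messiness of
real sequencing data; preprocessing utilities (prevalence filtering,
pseudo-count zero replacement) carry that burden in applications.

### Evaluation

Support recovery is scored by TPR, FPR, precision, and Matthews
correlation coefficient against the true nonzero loadings (MCC and
precision defined as 0 on empty margins; degenerate fits score 0
everywhere), and estimation by RMSE against $\omega/\lVert\omega\rVert_2$
after resolving the global sign to the smaller error, since the model
identifies directions only up to sign. The experiment runner tunes every
replicate by the two-stage CV before scoring, so reported metrics include
the tuning variability; means and standard deviations are aggregated over
replicates (30 by default) into a long-format table.

At these desk-scale settings (30 replicates, $n = 100$, the default
grids), the non-adaptive variants' support metrics carry substantial
Monte-Carlo and tuning variability: the 5-fold CV criterion is computed
from 20-sample held-out folds, and its argmax occasionally lands on an
over-dense or over-sparse candidate. The adaptive and structure-adaptive
variants are markedly more stable, since the reweighting sharpens the
selection at any reasonable penalty.

## Design choices made where the formulation was open

* Covariance denominator $n-1$; all fitted directions are invariant to
  positive rescalings of the covariance (penalties scale along), so the
  choice is consequence-free.
* The non-binding branch of the b-update (solutions with
  $\lVert b \rVert_2 < 1$) is intentionally not implemented: only binding
  l2 constraints are meaningful for a correlation-maximizing direction.
* The boundary case $\lambda_a = \lVert v \rVert_\infty$ is assigned to
  the degenerate branch.
* The dual variable of the prox is refreshed once per augmented-Lagrangian
  step (not per coordinate sweep) and reset to zero at every prox call.
* Weight caps apply whenever $|b_j|^{-\gamma} > C_U$, not only at exact
  zeros, keeping weights inside the feasible box.
* The alternation of the adaptive variants stops on the $(a, b)$ change
  only; weight stabilization is implied since weights are deterministic
  functions of $b$.
* Zero replacement (default 0.5, count scale) is user-adjustable for
  relative-abundance inputs; missing values are rejected rather than
  imputed.
* For real-data fits the log-compositional matrix is centered but not
  column-scaled by default (scaling would reweight the zero-sum
  constraint), with a flag to standardize both tables; the simulation
  harness fits on the model scale without standardization.

## Limitations

Single canonical pair only (no deflation for further pairs); diagonal
within-set covariance treatment; no zero-inflation modeling; linear
associations only. The group structure must partition the features —
overlapping or hierarchical taxonomies need to be flattened to one level
before use.
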