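---
title: "Methods: mixed-model score tests for zero-inflated single-cell counts"
author: "scmmst authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model score tests for zero-inflated single-cell counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmmst)
```

This vignette documents the statistical model behind `scmmst`, the
numerical choices made in its implementation, what the built-in simulator
does and does not emulate, and the package's known limitations.

## The generalized linear mixed model

For a single gene, the count $y_i$ of cell $i$ follows

$$ g(\mu_i) = \alpha + g_i B_i \beta + B_i b, \qquad
   b \sim N(0, \sigma_b^2 I_p), \quad
   \beta \sim N(\beta_0 1_p, \sigma_\beta^2 I_p), $$

where $B_i$ is the batch dummy row ($p$ batches), $g_i \in \{0,1\}$ marks
the target cell type (one-against-others), and $g$ is the log link for the
count families (logit for the binary families, which are implemented in
the family layer but are not the package's focus). The batch effects $b$
are random intercepts; the group effects $\beta$ are batch-specific, so
$\sigma_\beta^2 > 0$ expresses *heterogeneous* cell-type effects across
batches. Supported count families are Poisson, quasi-Poisson (dispersion
$\tau$ estimated from the residual deviance) and negative binomial with
dispersion $\theta$ ($\mathrm{Var}(y) = \mu + \mu^2/\theta$).

Testing $H_0\!:\beta = 0$ reduces, under the working assumption
$\beta_0 = 0$, to the variance-component hypothesis
$\sigma_\beta^2 = 0$, whose null model is the intercept-plus-batch fit
$g(\mu_{0i}) = \alpha + B_i b$. The score statistic is

$$ T = (y - \hat\mu_0)^\top \hat\Phi\, G_B G_B^\top \hat\Phi\,
       (y - \hat\mu_0) / \hat\tau, $$

with $G_B$ the group-by-batch interaction design ($j$-th column
$g_i 1\{batch_i = j\}$) and
$\hat\Phi = \mathrm{diag}\{1/(1 + \hat\mu_{0i}/\hat\theta)\}$ for the NB,
the identity otherwise. Under $H_0$, $T$ follows
$\sum_{i=1}^p \xi_i \chi^2_{1,i}$ where $\xi_i$ are the eigenvalues of
$E = G_B^\top \hat P G_B$, with
$\hat P = \hat\Sigma^{-1} - \hat\Sigma^{-1} 1 (1^\top \hat\Sigma^{-1}
1)^{-1} 1^\top \hat\Sigma^{-1}$ and
$\hat\Sigma = \hat V + \hat\sigma_b^2 B B^\top$,
$\hat V = \mathrm{diag}\{(g'(\hat\mu_{0i}))^2 \widehat{\mathrm{Var}}(y_i)\}$
($1/\mu$ for Poisson, $1/\mu + 1/\theta$ for NB). Because the batch
dummies are disjoint, $\hat\Sigma^{-1}$ has a closed per-batch form
(Woodbury identity with a diagonal inner matrix), so $T$, $E$ and the
projection are all computed in $O(np)$ without storing any $n \times n$
matrix. The quasi dispersion $\hat\tau$ divides the statistic only; the
eigenvalues are left on the $\hat V$ scale, which makes $T$ exactly
equivariant under rescaling of $\hat\tau$.

## Observational weights for excess zeros

Dropout produces zeros in excess of what the count family implies. Rather
than modelling zeros inside the GLMM, each count receives an observational
weight — the probability that it belongs to the conventional count
distribution — and the null model is refitted with these weights
multiplying the IRLS working weights. Nonzero counts always have weight 1;
zero counts are downweighted toward 0 as the evidence for excess zeros
grows.

Four estimators are provided. Under a zero-inflated model with mixing
probability $\pi$ the weight of a zero is
$(1-\hat\pi) f(0;\hat\theta) / (\hat\pi + (1-\hat\pi) f(0;\hat\theta))$;
under a zero-truncated model the weight solves
$w n_0 / (w n_0 + n_1) = f(0;\hat\theta)$, giving
$w = n_1 f(0) / (n_0 (1 - f(0)))$ with $n_0$/$n_1$ the zero/nonzero
counts.

* `trpois` — per batch, $\hat\lambda$ solves the truncated-mean equation
  $\lambda/(1-e^{-\lambda}) = \bar y_{>0}$ (bracketed root plus Newton
  polish, residual $< 10^{-10}$).
* `zipois` — per batch, EM for the $(\pi, \lambda)$ mixture; because the
  updates depend on the data only through $n_0$, $n_1$ and the nonzero
  sum, each iteration is $O(1)$.
* `trnb` — per batch, the truncated-NB moment equations reduced to a 1-D
  root in $\log\theta$, with truncated ML as fallback; the batch
  dispersions are pooled by their harmonic mean (failed batches are
  excluded from the pooling), batch means re-solved at the common
  $\theta$, and estimates with $\hat\theta < 2$ carry a low-confidence
  flag — the moment estimator is unstable there.
* `zinb` — a gene-wise zero-inflated NB regression over *all* cells,
  batch fixed effects in both the mean ($\log\mu$) and zero ($\mathrm{logit}\,\pi$)
  models and a gene-level $\theta$, fitted by EM (weighted NB GLM, profile
  $\theta$, fractional-response logistic regression). This is a
  deliberate, self-contained replacement for latent-factor ZiNB
  machinery: batch fixed effects without group effects are exactly the
  structure needed for weight estimation under the null.

The three scalar schemes estimate within batches under the no-group-effect
null; group labels are never consulted. Per-gene failures (all-zero
batches, degenerate samples) fall back to weight 1 with a warning —
conservative, and never silently dropping cells.

For the weighted statistic $T_w$ the weights sandwich the statistic and
the calibration matrix, $E_w' = G_B^\top W \hat P W G_B$, while $\hat P$
keeps its unweighted structural form evaluated at the weighted null fit
($\hat\mu_0$, $\hat V$, $\hat\sigma_b^2$). This approximation is what
makes the closed-form $\hat\Sigma^{-1}$ usable; it degrades as the zero
fraction grows, which is a known property of the approach.

## Null-model estimation

The null GLMM is fitted by penalized quasi-likelihood: IRLS working
responses combined with a one-dimensional REML profile over $\sigma_b^2$.
At each outer iteration the working weights $W_{irls} = w\,\mu'^2/V(\mu)$
and responses are formed, the per-batch sums of $W$, $Wz$ and $Wz^2$ are
accumulated, and the REML criterion — which depends on the data only
through those $3p+2$ numbers — is minimized over $\log\sigma_b^2 \in
[\log 10^{-8}, \log 10^3]$ with `optimize`; the boundary value $10^{-8}$
is reported as 0. The intercept and BLUPs then follow in closed form per
batch. Convergence is declared at relative change $< 10^{-6}$ in
$(\alpha, b, \sigma_b^2)$, with at most 100 outer iterations;
non-convergence is reported via a flag, never as an error.

Choices worth recording:

* **NB dispersion.** $\theta$ is estimated by alternating the PQL fit
  with profile maximum likelihood for $\theta$ given $\hat\mu_0$ (golden
  search on $\log\theta \in [\log 10^{-3}, \log 10^5]$), at most 10
  alternations, stopping at $|\Delta\log\theta| < 10^{-4}$. In weighted
  fits the observational weights act as case weights in the
  $\theta$-likelihood — weighting is applied consistently across the mean
  and dispersion estimation.
* **Weights as relative precisions.** Observational weights are floored
  at $10^{-8}$ (well-posed IRLS systems) and normalized to maximum 1
  before entering the working weights. With the residual scale fixed at
  1, PQL-REML is not invariant to a uniform rescaling of case weights;
  normalization restores the natural invariance (a constant weight vector
  reproduces the unweighted fit exactly) and is a no-op for every real
  weighting scheme, where nonzero counts already carry weight 1.
* **Quasi dispersion.** $\hat\tau$ = residual deviance / $(n-1)$: one
  fixed intercept is counted, shrunken random effects are not. The
  alternative of scaling $\hat\Sigma$ by $\hat\tau$ instead of dividing
  $T$ is not implemented; the statistic divides by $\hat\tau$ as
  displayed above.
* **Degenerate genes.** All-zero genes are non-estimable; the per-gene
  driver maps them (and any other unrecoverable failure) to $p = 1$ with
  a failure flag, so a matrix-wide run never aborts.

## Mixture chi-square tail probabilities

Eigenvalues below $\max_i \xi_i \times 10^{-8}$ are dropped and negative
numerical eigenvalues are clipped to 0 ($E$ is PSD in exact arithmetic).
The tail $P(\sum_i \xi_i \chi^2_{1,i} \ge t)$ is computed by Ruben's
series: with $\beta = \min_i \xi_i$,

$$ P(Q \ge t) = \sum_{k \ge 0} a_k\, P(\chi^2_{p+2k} \ge t/\beta), $$

where the $a_k$ are non-negative and sum to 1, so the truncation error is
bounded by the unused coefficient mass; summation stops when that bound
drops below $10^{-12}$. The geometric structure of the recursion is
exploited for $O(p)$ work per term. Direct adaptive quadrature of the
characteristic-function inversion integral was tried first and discarded:
the integrand's slowly decaying oscillatory tail defeats generic
quadrature at the accuracy required here, while the series is exact with
a computable bound. Equal eigenvalues (and the single-eigenvalue case)
use the scaled chi-square closed form; if the series does not converge
within its term budget — possible when the eigenvalue spread approaches
the clipping ratio — a Liu-type moment-matching approximation
(non-central chi-square, matched through the first four cumulants) is
used. The backend actually used (`exact`, `ruben`, `liu`) is recorded
per gene in the result table.

## Normalization

Library-size normalization enters the GLMM as a per-cell additive offset
$\log(\text{lib size} \times \text{TMM factor} / 10^6)$ on the log-link
scale — the standard GLM offset mechanism. TMM factors are computed by
edgeR's `calcNormFactors` (reference cell by upper quartile, trim 0.30 on
log-ratios and 0.05 on absolute intensities, factors rescaled to
geometric mean 1); the test suite cross-checks them against an
independent brute-force implementation of the trimmed-mean algorithm.
Factors are estimated from raw counts and the GLMM models raw counts with
offsets; CPM values are available separately for inspection but are not
what the model consumes. `norm = "none"` disables offsets and is the
right choice for the built-in simulator's output, which has no depth
variation by construction. The default gene filter removes genes with
fewer than 20 total counts.

## The simulator

`simulate_dataset()` draws, per gene, $b \sim N(0, \sigma_b^2 I_p)$ and —
for the first $\lfloor \text{de\_prop} \cdot G \rfloor$ genes, a
deterministic truth-bookkeeping choice — $\beta \sim N(\beta_0 1_p,
\sigma_\beta^2 I_p)$; counts follow the GLMM above, and a per-count
Bernoulli indicator with keep probability
$\mathrm{logit}^{-1}(\mu_\pi + B_i b)$ zeroes counts to emulate dropout
(larger $\mu_\pi$, fewer excess zeros). Defaults mirror the calibration
study conditions: 250 cells, $p = 5$ batches, two balanced groups dealt
round-robin over the batch-by-group grid (so the test is identifiable in
every batch), $\mu_0 = 5$, $\sigma_b^2 = 0.25$, `de_prop` 0.1. The same
$b$ appears in the count predictor and the dropout logit, as the dropout
probability's displayed form reuses it; because it is ambiguous whether
those effects should be shared, `dropout_batch = "independent"` redraws
them, and both variants are exercised in tests. Per-gene RNG substreams
are derived from the one seed, so generation is reproducible gene by
gene.

What the simulator does *not* emulate: sequencing-depth variation across
cells, outlier expression, library-size factors, or correlation between
genes. Passing calibration and power checks on this generator therefore
demonstrates correctness of the statistical machinery under the model's
own assumptions — batch random intercepts, family-distributed counts,
logit dropout — not robustness to every artefact of real scRNA-seq data.

## Evaluation conventions

The per-comparison error rate is the fraction of *unadjusted* p-values at
or below the declaration level (the declaration rule for null studies);
FDP-TPR curves and ROC AUCs use BH-*adjusted* p-values. Both conventions
are fixed, not configurable. FDP uses the $FP/\max(1, FP+TP)$ guard; AUC
is the tie-aware rank (Mann-Whitney) form, verified in tests against an
$O(n^2)$ pairwise-concordance oracle; ties in adjusted p-values collapse
into a single curve point.

## Validation study sizes

The package's own validation studies (run by the test suite and
`scripts/acceptance.R`) use 10 null datasets of 2,000 genes by 250 cells
per family for calibration, 200 genes at 1,000 cells for variance-
component recovery, and 1,000-gene datasets at $\beta_0 \in \{0, 0.3,
0.5\}$, $\sigma_\beta^2 = 0.25$, $\theta = 2$ (two replicates per
setting) for the power-monotonicity check. These sizes give binomial
standard errors a factor of a few below the effects being checked and
were chosen as the package's validation design.

## Known limitations

* The statistic tests $\sigma_\beta^2 = 0$ under the working assumption
  $\beta_0 = 0$; it is valid for $H_0\!:\beta = 0$ but sacrifices power
  against alternatives dominated by a homogeneous $\beta_0$, where a
  joint test would do better.
* The $E_w'$ approximation to the weighted calibration matrix worsens as
  zeros proliferate; with extreme zero fractions the test becomes more
  conservative.
* The truncated-NB weight estimator is unreliable for $\theta < 2$ and is
  flagged accordingly; `zipois` is the recommended default.
* PQL is known to bias variance components for very small counts; at the
  count scales typical of filtered scRNA-seq data ($\mu_0$ well above 1
  on the log scale) the recovery bias observed in tests is well inside
  25%.
* One random-intercept grouping factor only: no nested or crossed random
  effects, no cell-level random effects, and no latent factors shared
  across genes.
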