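---
title: "Pre-factor item screening: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-factor item screening: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpool)
```

## 1. The screening model

`gpool` addresses a practical failure mode of exploratory item factor
analysis (FIA): a few flawed items in a large initial pool — too extreme,
redundant, or essentially random — cause non-positive definite (NPD)
correlation matrices, improper or unstable solutions, and distorted
dimensionality assessment. The screening is deliberately *pre-factor*:
every index is computable from the raw responses and the inter-item
correlation matrix alone, before any number of factors is chosen.

Each item is summarised by two coordinates.

**Extremeness** is the item mean rescaled linearly to proportion metric,
$P_j = (\bar x_j - \min_j)/(\max_j - \min_j)$. The rescaling uses the
*declared* category range, not the observed one: when an extreme category
goes unused the observed range underestimates the scale, biasing $P_j$
toward the centre. Consequently `response_matrix()` asks for the range and
only falls back to the observed one with a warning. For binary 0/1 items
$P_j$ is the classical difficulty index. A subtlety of the proportion
metric for graded items is that the literature never writes down a single
formula; the linear rescaling of the mean is the only reading under which
the index is normed on $[0,1]$ for every format and reduces to the
endorsement proportion for binary items, and it is what we implement.

**Consistency** is $h_j = \sqrt{h^2_j}$ with
$h^2_j = 1 - 1/(R^{-1})_{jj}$, the squared multiple correlation (SMC) of
the item on the rest of the pool. The SMC is a lower bound of the item's
communality, so it can never reach 1 on a positive-definite matrix — a
property the calibration study exploits (Section 4). Very high $h_j$ is
read as redundancy rather than quality, which motivates treating
consistency as bounded above as well as below.

Two correlation engines back these coordinates. The *linear* route uses
the Pearson matrix of the raw codes; the *graded* route uses the
polychoric matrix under the underlying-variables approach, which makes the
factor model equivalent to the multidimensional two-parameter /
graded-response IRT models. Which route to screen under should match the
model to be fitted afterwards.

## 2. Flagging, MSA, and efficiency indices

The appropriateness region is the rectangle $P \in [.10, .90]$,
$h \in [.20, .75]$ (defaults of `region_config()`), proposed as a common
region for both model routes. Point estimates fluctuate, so flagging is
based on bootstrap percentile intervals (default $B = 500$ row resamples,
95% level): an axis flags an item only when *both* interval limits fall
outside the region on the same side of the same boundary. An interval
that straddles a boundary never flags — the rule is deliberately
conservative, protecting against capitalization on chance. The two axes
are judged independently; an item outside a corner is flagged on each
axis on its own merits. Widening an interval can therefore only remove a
flag, never create one — a property the test suite asserts.

Noisy items — those that relate to the pool essentially at random — are
caught by the per-item measure of sampling adequacy
$\mathrm{MSA}_j = \sum_{k\neq j} r^2_{jk} \big/ (\sum_{k\neq j} r^2_{jk} +
\sum_{k\neq j} q^2_{jk})$, where
$q_{jk} = -(R^{-1})_{jk}/\sqrt{(R^{-1})_{jj}(R^{-1})_{kk}}$ are the
anti-image partial correlations. The point estimate is compared with the
conventional .50 threshold. We implement the standard KMO form; robust
variants of the MSA exist but their formulas are outside this package's
scope. A consequence worth knowing (Section 5): for an item whose true
loading is exactly zero the sampling distribution of the standard MSA is
centred just *below* .50, so the single-item detection rate is around
60–70%, not near certainty — the MSA screen accumulates evidence across a
pool rather than guaranteeing per-item detection.

Efficiency of the surviving items is ranked by prior item efficiency
$\mathrm{PIE}_j = h^2_j P_j (1 - P_j)$ — the marginal approximation of the
expected IRT item information with the SMC standing in for the squared
multidimensional discrimination — and its normed version
$\mathrm{R\text{-}PIE}_j = \mathrm{PIE}_j / (h^2_{upper} \cdot 0.25)$ with
ceiling $h_{upper} = .75$. R-PIE equals 1 for an item of medium
extremeness at the ceiling and may exceed 1 above it; we report the
overshoot rather than capping, since values above 1 are themselves a
redundancy signal. On the accuracy of the marginal approximation:
`info_profile()` exposes the latent-trait information curve, and for a
probit item with unit discrimination the exact normal-weighted average of
$P(\theta)(1-P(\theta))$ is $1/4 - \arcsin(1/2)/(2\pi) = 1/6$, one third
below the marginal value $P(1-P) = 1/4$. The approximation is an upper
guide that tightens as discrimination falls; PIE should be read as a
relative ranking device, not an information estimate.

Two-step selection (`select_items()`) first removes every flagged item
(region axes or MSA), then sorts survivors by R-PIE descending, ties kept
in input order for determinism. `split_sample_check()` supports the
recommended replication workflow: screen one half of the sample, confirm
on the other, and report per-item decision agreement.

## 3. The polychoric engine

No polychoric estimator is available to this package's dependency
footprint, and the estimator sits on the hot path of the calibration
study, so it is implemented natively. Estimation is two-step, matching
standard psychometric practice: thresholds per item from the marginal
cumulative proportions ($\tau_c = \Phi^{-1}(\hat F_c)$), then one bounded
scalar maximization of the pair's multinomial log-likelihood over
$\rho \in [-0.999, 0.999]$ (Brent search) with thresholds held fixed.
Rectangle probabilities are differences of bivariate-normal CDF values,
computed by a compiled Gauss–Legendre quadrature kernel (3/6/10 nodes by
$|\rho|$, with a tail-stable transformed integrand beyond
$|\rho| = .925$), accurate to about $10^{-14}$ and verified in the tests
against one-dimensional quadrature.

Numerical choices, all of which matter at N = 200 with extreme items:

- **Zero cells.** A contingency table containing a zero cell gets 0.5
  added to every cell before likelihood evaluation. Extreme binary items
  at N = 200 produce empty cells routinely; without the correction the
  likelihood is maximized at the $\rho$ bound far more often, inflating
  boundary estimates. How the original calibration handled empty cells is
  not documentable, so this correction is this package's own choice.
- **Empty categories** are dropped from threshold estimation (thresholds
  must be strictly increasing); an item with all mass in one category is
  degenerate and errors.
- **Probability floor** of $10^{-12}$ inside the log-likelihood guards
  $|\rho| \to 1$.
- **Boundary snapping.** Brent's method never returns the exact interval
  end, so an optimum within $10^{-4}$ of the bound is snapped to it when
  the likelihood there is no worse (perfect-association tables).
- **Definiteness** is diagnosed by symmetric eigendecomposition with
  tolerance $10^{-8}$ on the smallest eigenvalue. NPD matrices are
  returned flagged, never smoothed: downstream, NPD is a terminal
  screening outcome, and repairing it would mask exactly the pathology
  the procedure exists to detect. Missing responses are removed listwise
  (with a logged count) because pairwise deletion can itself induce NPD.

One-factor extraction for the calibration cascade is unweighted least
squares (MINRES-style): iterate the leading eigenpair of the reduced
matrix with the diagonal replaced by current communalities, SMC start,
tolerance $10^{-6}$, 200 iterations. A Heywood case is recorded when an
iterate's communality reaches 1 before clipping. Loading signs are fixed
so the loading sum is non-negative.

## 4. The calibration study and what the generator emulates

`run_study()` regenerates the simulation that defines the region. Each
replicate builds a five-item unidimensional pool: four *medium* items
with extremeness targets drawn uniformly from the level intervals 4–7
(`[.30,.39]` … `[.60,.69]`) paired in order with communality bands
`[.30,.34]`, `[.35,.39]`, `[.40,.44]`, `[.45,.49]`, and a *focal* fifth
item whose extremeness and communality levels sweep the full
$10 \times 10$ grid of `[.10(k-1), .10(k-1)+.09]` intervals. The pairing
of medium extremeness levels with communality bands is in listed order;
the two sequences are stated separately in the design and the pairing is
our choice. Communality draws are communalities ($h^2$), with loadings
$\lambda = \sqrt{h^2}$; extremeness levels are read as intervals of the
proportion-metric mean — the only reading under which the level scale and
the plot's x axis coincide for binary items.

Thresholds hitting a target extremeness $P^*$ for $C$ categories place
category probabilities at $\mathrm{Binomial}(C-1, P^*)$ and take normal
quantiles of their cumulative sums. This scheme nests the binary case
exactly (single threshold, top-category probability $P^*$) and pins the
expected proportion-metric mean to $P^*$ *exactly* for every $C$ — a
binomial-mean identity the tests verify. The specific threshold sets used
in the original calibration for 3–5 categories are not recoverable, so
percentages for those columns are comparison references rather than
reproduction targets.

Samples are $N = 200$ draws of $x_j = \lambda_j z + e_j$,
$e_j \sim N(0, 1-\lambda_j^2)$, discretized at the thresholds. Each
sample is classified by the strict cascade, stopping at the first
failure, under both model routes:

1. **npd** — correlation matrix indefinite or not computable (a
   constant-response item makes both engines degenerate; such replicates
   are counted here, and the focal consistency is reported from the
   population since no sample value exists);
2. **heywood** — focal SMC $\ge 1$ (structurally impossible on a PD
   matrix, hence a built-in zero row — the point of using the SMC);
3. **noisy** — focal MSA $< .50$;
4. **biased** — focal ULS loading discrepancy $> .80$ (absolute
   difference on the focal loading; the averaged absolute bias over all
   five items is reported alongside as a secondary diagnostic);
5. **unstable** — sampling instability $> .85$;
6. **ok**.

The *instability* metric deserves a caveat: its original operational
definition ("sampling error variance") is not recoverable, including
whether .85 applies to a variance or a standard deviation. We implement a
declared substitute — the variance of the focal ULS loading over an inner
bootstrap (default 50 resamples) of the replicate, with indefinite inner
resamples dropped and an infinite sentinel when fewer than half survive.
Because loadings are bounded in $[-1,1]$, a variance above .85 requires
sign-flipping resamples and is rare in both models; ordering properties
(extreme/high-communality focal conditions less stable than medium ones;
the polychoric route less stable than the Pearson one) are therefore
asserted on the metric's magnitude, not on threshold exceedance rates.

**Problem sizes.** The package's standard calibration run — used by both
the acceptance script and the test suite — is 200 replicates per cell
over all four category counts and both models (160,000 classifications),
with the cascade truncated after the MSA step; truncation leaves the npd
/ heywood / noisy accounting identical to a full run because those
classifications are decided before the truncation point. The full
cascade, including the inner bootstrap, is exercised at smaller scale.
Replicates run on deterministic RNG substreams indexed by (seed, cell,
replicate), so any parallelism setting reproduces the same study; the
substream layout caps replicates at 500 per cell, beyond the scales used
here.

**What the generator does not emulate.** Real pools are larger than five
items, multidimensional, and carry response styles, local dependence and
missingness; the generator's single factor, exact normal latents and
independent respondents are the calibration's assumptions, not claims
about data. Passing calibration checks shows the machinery reproduces the
stated design under those assumptions — it does not validate the region
boundaries for structurally different instruments.

## 5. Calibration outcomes and known limitations

Running the calibration at the package's standard scale reproduces the
structural results exactly — the Heywood row is identically zero, problem
rates for the graded route fall monotonically as response categories grow
from 2 to 5, and the graded route is uniformly more problem-prone than
the linear route on binary items. The binary NPD rate of the graded route
falls in the published value's vicinity. Three quantitative rates,
however, come out substantially *lower* than the originally published
percentages (binary noisy rates under both routes, and the binary linear
NPD rate), and the discrepancy is worth recording precisely because the
package computes rather than transcribes these numbers:

- A sample Pearson correlation matrix is a Gram matrix and cannot have a
  negative eigenvalue; for the linear route, NPD can only mean a
  degenerate (constant-item) replicate. The rate of constant focal items
  is analytically determined by the level intervals (integrating
  $(1-p)^{200}$ over level-1 draws and $p^{200}$ over level-10 draws
  gives ≈ 0.6–0.8% pooled), far below the published 4.00% — no
  positive-semidefinite accounting reaches that figure.
- The noisy-item rates depend on the sampling distribution of the
  standard per-item MSA, which for a zero-loading item is centred just
  below .50 (detection ≈ 60–70% per replicate, Section 2). Published
  rates of ~24% (graded) would require near-certain detection across the
  two lowest communality rows plus substantial spillover; plausible
  alternative readings of the design (e.g. drawing loadings rather than
  communalities from the stated bands) move individual rates toward some
  published values while moving others away, and no reading reconciles
  all of them. A robust MSA variant, which is out of scope here, would
  also raise detection.

The package therefore reports its computed rates as is. Users should
treat the *structure* of the calibration (which problems dominate where,
and the monotone category effect) as the robust finding, and individual
percentages as implementation-sensitive.

Further limitations: the screening is unidimensional in spirit (the SMC
pools all remaining items regardless of structure); polyserial and
mixed-format correlations are not supported; the procedure flags — it
does not delete, and flagged items should be inspected substantively
before removal, especially for instruments that legitimately need extreme,
highly discriminating items.
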