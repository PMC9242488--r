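---
title: "Comparing informant reports with latent space item response models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing informant reports with latent space item response models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Parent-report and self-report versions of the same questionnaire — the
canonical example being the Child Behavior Checklist (CBCL, filled in by a
parent) and the Youth Self Report (YSR, filled in by the child) — often
disagree, and the disagreement is scientifically interesting: it reflects
what children acknowledge about themselves that parents do not observe,
and vice versa.  Conventional comparisons (syndrome-level Pearson
correlations, item-level Cohen's kappa, Jaccard similarity of item
response vectors) treat items or subscales one pair at a time and ignore
the dependency structure *within* each instrument: which items travel
together, which respondents resemble each other, and which respondents sit
close to which items.

`lsirmdiff` implements a model-based alternative built on the latent
space item response model (LSIRM) and a suite of discrepancy statistics
defined on the two fitted "interaction maps".

## The model

For binary response $y_{ki}$ of respondent $k$ to item $i$,

$$\operatorname{logit} P(y_{ki} = 1) = \beta_i + \theta_k - \lVert w_i - z_k \rVert,$$

where $\beta_i$ is item easiness, $\theta_k$ the respondent's latent
trait, and $w_i, z_k \in \mathbb{R}^d$ are positions in a shared latent
space ($d = 2$ by default, for visualization).  The distance coefficient
is fixed at one; this makes the geometry of two separately fitted maps
commensurable so they can later be matched.  Short distances mean strong
dependency: two items close together are endorsed by the same respondents,
and a respondent close to an item is likely to endorse it beyond what
$\beta_i + \theta_k$ alone predicts.  Because distance obeys the triangle
inequality, item-item and respondent-respondent dependencies are captured
transitively even though the likelihood only involves item-respondent
distances.

Priors: $\beta_i \sim N(0, \tau_\beta^2)$,
$\theta_k \sim N(0, \sigma^2)$,
$\sigma^2 \sim \text{Inv-Gamma}(a_\sigma, b_\sigma)$, and standard
multivariate normal priors on every position.  Defaults
($\tau_\beta^2 = 4$, $a_\sigma = b_\sigma = 1$) are weakly informative:
$\tau_\beta^2 = 4$ admits easiness logits of $\pm 4$ without meaningful
shrinkage, and the unit-scale inverse-gamma keeps the trait variance
proper while letting the data dominate for any realistic sample size.

## Estimation

`lsirm()` runs a Metropolis-Hastings-within-Gibbs sampler (compiled
C++ core):

* Gaussian random-walk proposals, one scale per block ($\beta$, $\theta$,
  rows of $W$, rows of $Z$).  During burn-in each scale is multiplicatively
  adapted every 50 sweeps toward an acceptance band of 0.23–0.44 and then
  frozen, so the post-burn-in chain is a valid fixed-kernel sampler.
* $\sigma^2$ is drawn exactly from its conjugate inverse-gamma full
  conditional, $\text{Inv-Gamma}(a_\sigma + N/2,\; b_\sigma + \tfrac12
  \sum_k \theta_k^2)$.
* Missing responses are handled by Bayesian data augmentation under a
  missing-at-random assumption: every sweep, each missing cell is redrawn
  from its Bernoulli full conditional at the current parameters, and the
  imputations of the retained sweeps are stored with the chain.
* Defaults retain every 5th sweep of 30,000 after a burn-in of 5,000,
  i.e. 5,000 draws.  The log posterior of every retained draw is stored
  with all normalizing constants (including those depending on
  $\sigma^2$), so the maximum-a-posteriori (MAP) draw is well defined;
  ties break to the earliest draw.

Initialization is deterministic given the seed: $\beta$ at the clipped
empirical logit of each item's positive rate, $\theta = 0$, positions
drawn tightly around the origin ($N(0, 0.1 I)$).  Chains are
bit-reproducible from `seed`.

Degenerate inputs: a matrix with a fully unobserved row or column is
refused by name (no information to place that object).  A *fully* missing
matrix is deliberately allowed — the augmentation then makes the chain
explore the prior, which is used as a correctness check (the $\beta$
marginal must revert to $N(0, \tau_\beta^2)$ and the $\theta$ marginal to
the $t_2$ distribution implied by the inverse-gamma mixture).

## Identifiability and map matching

The likelihood depends on positions only through distances, so each draw's
configuration is arbitrary up to rotation, reflection and translation.
`procrustes_align()` fixes the frame *within* a chain: the stacked
$(W; Z)$ of the MAP draw is the target, and every other draw is mapped
onto it by its orthogonal Procrustes solution (SVD of the centered
cross-product; no scaling, since scaling would change distances and hence
the model).  `match_maps()` then puts two fitted instruments in one frame:
the transform is estimated on posterior-mean *item* positions only —
items are the objects shared verbatim between the instruments, while
respondent positions may genuinely differ by informant — and broadcast to
the other instrument's respondent positions and every retained draw.
Whether to match on posterior means or draw-by-draw is not determined by
the problem; posterior-mean anchoring keeps the two chains' internal
geometry intact and is what the package does.  Every distance-based
statistic below is invariant to both operations by construction (rigid
motions are isometries), and the tests verify this to $10^{-10}$.

## Discrepancy statistics

**Item easiness.** `beta_compare()` reports the Pearson correlation of
the two posterior-mean $\beta$ vectors and flags items off the common
linear trend.  The line is a Huber M-estimate (robust regression), not
ordinary least squares: when several items are strongly discrepant — the
situation of interest — an OLS line is dragged by them and its residual
scale inflates, so genuinely shifted items mask one another.  In
controlled experiments with both an easiness-shifted item set and a
displaced item cluster, the OLS-plus-studentized-residual rule recovered
none of the planted shifts, while the robust rule recovers nearly all of
them.  An item is flagged when its absolute residual exceeds 2.5 robust
scales.

**Item-pair distance distributions.** For items $i, j$, the retained
draws give a posterior sample of $\lVert w_i - w_j \rVert$ per
instrument.  `overlap_R()` summarizes the difference between the two
instruments' samples as
$R = \int \min(\hat f_a, \hat f_b)\,dx \in [0, 1]$, computed from
Gaussian kernel density estimates with Silverman's bandwidth per sample,
evaluated on a shared 512-point grid spanning the union support padded by
three bandwidths, and integrated by the trapezoid rule.  $R \le 0.05$
flags a pair as materially different; `overlap_matrix()` applies this to
all pairs and reports the flagged proportion.  No multiplicity correction
is applied across the $P(P-1)/2$ pairs — the flag is a descriptive
screen, as is conventional for this statistic.  `kl_divergence()`
(same grid, densities floored at $10^{-12}$; both directions and the
symmetrized average, since the appropriate direction is
context-dependent) and `ks_compare()` are alternatives; the KS p-value
treats autocorrelated MCMC draws as independent and is therefore
anti-conservative — it is reported for screening only.

**Syndromes.** A syndrome's position is the centroid of its member
items' posterior-mean positions; `syndrome_similarity()` compares
syndrome geometry across instruments through cosine similarity of
centroid vectors (sign and angle, not magnitude — appropriate because
the origin of the map is fixed by the standard normal position prior).
`respondent_syndrome_distances()` gives each respondent's profile of
distances to all syndrome centroids, the basis for individual-level
statements ("this child sits near the externalizing syndromes in the
self-report map but not in the parent map"); a per-draw averaged variant
exists for uncertainty-aware profiles.  `cluster_respondents()` applies
K-means (25 restarts, fixed seed) to those profiles with $k = 4$ by
default; $k$ is a parameter, not an automatically selected quantity.

**Baselines and fit.** The conventional statistics are included for
reference and validation: syndrome sum-score Pearson correlations,
item-level unweighted Cohen's kappa with syndrome means, and
within-instrument Jaccard similarity matrices with the between-instrument
difference and ranked pair table.  Missing data: pairwise-complete
deletion for kappa and correlations, missing treated as "not endorsed"
for Jaccard (with the affected cell count reported) — the missingness
rates this package targets (~0.2%) make the choice immaterial, but it is
explicit.  Goodness of fit follows the classification convention:
predicted positive iff the model probability is at least 0.5 (plug-in at
posterior means by default; a draw-averaged option exists), summarized by
specificity, sensitivity and overall accuracy over observed cells,
in-sample.

## The synthetic-data generator

Real paired CBCL/YSR data at scale are access-restricted, so validation
runs on `simulate_paired()`, which generates from the model itself with a
controllable cross-informant discrepancy structure:

* **Items.** Eight syndromes with canonical relative sizes cover 80% of
  the items; the rest are unassigned, mirroring the real instruments'
  no-syndrome items.  Syndrome poles sit on a radius-2 circle:
  externalizing (RBB, AB) near 0°, internalizing (AD, WD, SC) near 180°,
  the non-extreme syndromes (AP, SP, TP) between, with within-pole angles
  kept within 30° so that within-pole centroid cosine exceeds 0.7 by
  design.  Member items scatter around their pole (sd 0.4); unassigned
  items scatter centrally (sd 1).
* **Respondents.** Four clusters: one at each higher-order pole
  (externalizing 0°, non-extreme 90°, internalizing 180°, radius 1.8) and
  one at the neutral center — matching the empirical observation that one
  respondent cluster typically aligns with no particular syndrome.
  Cluster labels are recorded as ground truth.
* **Rates.** A global intercept offset per instrument is calibrated by
  bisection on the *expected* positive rate, hitting 0.27 (parent) and
  0.43 (self) by default; the intercept spread (`beta_sd = 1.4`) is
  calibrated so the across-item dispersion of realized rates matches
  dichotomized checklist data (SD ≈ 0.18 parent / 0.22 self).
* **Discrepancy.** Instrument b derives from instrument a's truth by
  three perturbations: an easiness shift (+1.5 by default) on a subset of
  unassigned items (the "children endorse what parents don't report"
  phenomenon), a rigid displacement of a small item cluster (a dependency
  present for one informant only), and Gaussian jitter on respondent
  positions.  Zeroing all three (`sim_config_null()`) makes the two
  instruments exact replicates of one truth.
* **Missingness** is completely at random at rate 0.002 — a strict
  subcase of the missing-at-random assumption the estimation relies on,
  sufficient to exercise the augmentation machinery.  Sensitivity to
  non-ignorable missingness is out of scope.

What passing on these data shows — and does not show.  The generator
draws from the fitted model's own family with cluster geometry more
regular than reality, no local item dependence beyond the latent space,
no ordinal structure, and no informant-specific response styles beyond
the modeled perturbations.  Recovery results therefore validate the
*machinery* (sampler, alignment, statistics), not the model's adequacy
for any particular real dataset.

## Problem sizes and numerical choices

The validation experiments in the test suite and `scripts/acceptance.R`
use scaled-down designs chosen to exercise every stage at realistic
signal-to-noise: single-instrument recovery at $N = 300$, $P = 60$;
paired discrepancy recovery at $N = 400$, $P = 60$ with 8 shifted items
and a 6-item displaced cluster; cluster recovery at $N = 400$ with the
full 118-item instrument.  These runs use 8,000 sweeps (burn-in 2,000,
thin 4); full-size analyses should use the 30,000/5,000/5 defaults.  For
cluster recovery the two informants' reports are treated as replicate
measurements of the same children and their distance profiles averaged
before K-means: a single instrument's 118 binary responses leave
per-respondent position uncertainty (~0.5 in map units) of the same order
as the cluster spread, and pooling the replicates is the
information-consistent remedy — the same argument that motivates using
both informants' reports jointly in practice.

Other numerics: rate calibration solves the offset by `uniroot` to
$10^{-10}$; KDE overlap clamps $R$ to $[0, 1]$; cosine similarity is
undefined (error) for zero vectors; Procrustes warns and proceeds via the
SVD when the cross-product is numerically rank-deficient; K-means uses
`iter.max = 100`.

## Limitations

Binary responses only (dichotomize ordinal categories first); no
covariates; no estimation of the distance weight; no generalized
Procrustes for more than two instruments; in-sample fit assessment only.
Convergence tooling (`lsirm_diagnostics()`: acceptance rates,
log-posterior trace, crude effective sample sizes) is advisory, not a
gate.

## A complete run

```{r example}
library(lsirmdiff)

sim <- simulate_paired(sim_config(n_respondents = 400, n_items = 60,
                                  n_shift = 8, n_displace = 6), seed = 1)
cmp <- informant_comparison(sim$data,
                            control = lsirm_control(8000, 2000, 4),
                            seed = 2, out_dir = "comparison_report")
print(cmp)
cmp$beta_comparison$flagged       # items endorsed differently
cmp$overlap$flagged_proportion    # share of item pairs with R <= 0.05
cmp$gof                           # specificity / sensitivity / accuracy
```
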