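# lsirmdiff

Cross-informant discrepancy analysis for binary questionnaires with the
latent space item response model (LSIRM).

## The problem

Parent-report and self-report versions of the same instrument — e.g. the
Child Behavior Checklist (CBCL, parent) and the Youth Self Report (YSR,
child) — routinely disagree. Conventional comparisons (syndrome-level
Pearson correlations, item-level Cohen's kappa, Jaccard similarity)
compare one item or subscale pair at a time and ignore the dependency
structure inside each instrument. `lsirmdiff` is for researchers who want
a model-based comparison: it fits each instrument with a latent space
item response model, puts the two fitted "interaction maps" in one frame,
and quantifies where and how the informants' views differ — at the item,
item-pair, syndrome and respondent level.

## The model

For respondent *k* and item *i*,

```
logit P(y_ki = 1) = beta_i + theta_k - ||w_i - z_k||
```

with item easiness `beta_i`, respondent trait `theta_k`, and latent
positions `w_i, z_k` in R^d (d = 2 by default; distance weight fixed at
one so two maps are commensurable). Short distance = strong dependency.
Priors: `beta_i ~ N(0, tau^2)`, `theta_k ~ N(0, sigma^2)`,
`sigma^2 ~ Inv-Gamma(a, b)`, standard normal positions. Estimation is
Metropolis-Hastings-within-Gibbs (compiled core) with an exact conjugate
update for `sigma^2`, Bayesian data augmentation for missing responses,
and Procrustes post-processing to the MAP draw to resolve the rotation /
reflection / translation invariance of the positions. Two fitted maps are
matched on their item positions (the objects shared across instruments).

On the matched fits the package computes: item-easiness comparison with
robust outlier flagging; posterior item-pair distance distributions with
the density-overlap statistic `R` (pairs with `R <= 0.05` flagged),
KL divergence and Kolmogorov-Smirnov comparisons; syndrome centroids and
cosine-similarity matrices; respondent-to-syndrome distance profiles with
K-means respondent clustering; classification goodness-of-fit
(specificity, sensitivity, overall accuracy); and the conventional
baselines for reference. A synthetic paired-informant generator with
controllable discrepancy (easiness shifts, a displaced item cluster,
respondent jitter) provides ground truth for validation.

## Worked example

Simulate a paired dataset with known discrepancies (5 items easier in the
self report, a 4-item cluster displaced in the self-report map), fit both
instruments, and compare:

```r
library(lsirmdiff)

sim <- simulate_paired(sim_config(n_respondents = 200, n_items = 40,
                                  n_shift = 5, n_displace = 4), seed = 11)
sim$data
#> Paired informant dataset: 200 respondents x 40 items
#>   a: parent report, positive rate 0.269
#>   b: self report, positive rate 0.435

fit_a <- lsirm(sim$data$a, control = lsirm_control(4000, 1000, 3), seed = 12)
fit_a
#> Latent space item response model (parent report)
#>   200 respondents x 40 items, latent dimension 2
#>   1000 retained draws (4000 sweeps, burn-in 1000, thin 3), Procrustes-aligned
#>   acceptance rates: beta 0.39, theta 0.41, w 0.39, z 0.41
#>   posterior mean trait variance sigma^2 = 0.718

fit_b <- lsirm(sim$data$b, control = lsirm_control(4000, 1000, 3), seed = 13)
fit_b <- match_maps(fit_a, fit_b)

beta_compare(fit_a, fit_b)
#> Item easiness comparison: r = 0.851, slope = 0.885
#> 8 item(s) flagged (|residual| > 2.5 robust scales): Item 4, Item 11,
#>   Item 18, Item 28, Item 32, Item 34, Item 37, Item 39

sim$truth$shifted_items
#> [1] "Item 28" "Item 32" "Item 34" "Item 37" "Item 39"

round(gof_metrics(confusion(fit_a)), 3)
#>      specificity      sensitivity overall_accuracy
#>            0.905            0.645            0.835
```

The generator's positive rates (0.269 / 0.435) land on the calibrated
parent/self targets. All five planted easiness shifts are flagged (the
three extra flags sit in the displaced cluster, which genuinely differs
between the instruments too). The goodness-of-fit values are the three
standard classification summaries of in-sample prediction at threshold
0.5. At this modest size the overlap screen `overlap_matrix(fit_a,
fit_b)` flags few pairs — posterior distance distributions are wide at
N = 200; the acceptance script below runs the larger designs where the
displaced cluster is detected through it.

The one-call orchestrator runs the whole workflow (two fits, alignment,
matching, all comparison layers, baselines) and optionally writes CSV/JSON
artifacts:

```r
cmp <- informant_comparison(sim$data, control = lsirm_control(4000, 1000, 3),
                            seed = 2, out_dir = "comparison_report")
```

See `vignette("informant-discrepancy")` for the model, the sampler, every
statistic's definition, and the generator's design rationale.

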