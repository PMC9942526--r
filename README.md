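# ptlearn

Prospect-theory decision models with value learning for an
eight-condition risk/loss/ambiguity gambling task.

## What this is for

Computational psychiatry and decision-science studies often measure
three dissociable attitudes toward uncertainty — **risk aversion**
(curvature ρ of the utility function), **loss aversion** (λ), and
**ambiguity aversion** (multiplicative weights α on the implied value of
options whose magnitude is hidden) — from a points-based gambling task:
138 trials in 7 blocks across 8 conditions, gains on the 10..90 grid,
losses on −90..−10. Because a running score reveals the value of an
ambiguous option whenever it pays out, subjects can *learn* the hidden
values, so the decision rule is crossed with learning rules: a
no-learning baseline, Rescorla–Wagner (single or asymmetric learning
rates), and a Bayesian mean tracker with a variance-adaptive learning
rate, each under three starting-value schemes. Five decision rules × ten
learning rules = a 50-model space.

The model core, per trial:

$$u = \sum_{\text{slots}} p \cdot
      \begin{cases} g^{\rho} & \text{gain} \\
      -\lambda\,|l|^{\rho} & \text{loss} \\
      \alpha\,V_{gain}^{\rho} & \text{ambiguous gain} \\
      -\lambda\,\alpha\,|V_{loss}|^{\rho} & \text{ambiguous loss}
      \end{cases}
  \qquad
  P(\text{gamble}) = \frac{1}{1 + e^{-\gamma\,(u_g - u_s)}}$$

with learning updates $V \leftarrow V + \alpha(o - V)$ (Rescorla–Wagner),
its ±-asymmetric variant, or the mean tracker
$G = v/(v+\theta_\epsilon^2)$, $m \leftarrow m + G\delta$,
$v \leftarrow (1-G)v$.

The package provides: reproducible task-schedule generation, a
synthetic-cohort simulator over the full model space, per-subject MAP
and empirical-Bayes hierarchical fitting with Laplace posterior draws,
WAIC model comparison with stacking weights, Efron's pseudo-R²,
calibration tables, model-agnostic behavioral aversion measures,
subject-exclusion filters (no-ambiguous-choice rule and the Mahalanobis
χ² p < .001 outlier rule), group bias t-tests, and parameter/model
recovery studies. See `vignettes/model-pipeline.Rmd` for the methods
account.

## Worked example

```r
library(ptlearn)

pop <- population_spec("D5-BMT3", n_subjects = 40, seed = 11)
sim <- simulate_cohort(pop)        # choices + true-parameter table
fo  <- fit(sim$choices, "D5-BMT3", mode = "map", seed = 11, draws = 50)
print(fo)
#> ptlearn fit: D5-BMT3 ( map )
#>   subjects: 40  trials: 5520
#>   WAIC: 5799.8  p_waic: 603.4
#>   Efron R2: 0.364
```

`"D5-BMT3"` is the decision rule with four free ambiguity weights plus
the Bayesian mean tracker with separately estimated starting values.
WAIC is on the deviance scale (lower = better fit out of sample;
`p_waic` is the effective-parameter penalty), and the Efron pseudo-R² of
0.36 says the fitted choice probabilities explain ~36% of the squared
deviation of choices from their base rate — simulated agents are noisy,
so this is far from 1 by design.

```r
round(colMeans(compute_measures(sim$choices)[, -1]), 3)
#>  risk_aversion  loss_aversion  amb_sure_gain  amb_sure_loss
#>          0.518          0.125          0.838          0.559
#> amb_risky_gain amb_risky_loss
#>          0.193          0.067

group_bias_tests(sim$choices)[, c("test", "t", "df", "p_value")]
#>        test      t df  p_value
#> 1      risk -10.98 39 1.68e-13
#> 2      loss   3.17 39 2.93e-03
#> 3 ambiguity  -5.16 39 7.64e-06
```

All six behavioral measures are coded so higher = more averse. The
negative risk t (gamble rate above 0.5) is a slight risk preference;
the positive loss t says subjects gamble less when a loss is possible
(condition 1 vs 4).

Recovery studies:

```r
pr <- parameter_recovery("D5-BMT3", n_subjects = 200, seed = 1)
pr$correlations            # true-vs-recovered Pearson r per parameter
mr <- model_recovery(c("D1-none", "D5-none", "D1-RW1"),
                     n_subjects = 100, reps = 10, seed = 1)
mr$confusion               # generating x fitted mean stacking weights
```

## Command line

Thin wrappers in `exec/`: `simulate-schedule`, `simulate-cohort`,
`fit-model`, `measures`, `recover`. All data crosses the boundary as
tab-delimited text (ambiguous magnitudes are empty fields plus a flag,
never 0).

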