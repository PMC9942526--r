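---
title: "Modelling risk, loss, and ambiguity aversion with value learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling risk, loss, and ambiguity aversion with value learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and its model space

`ptlearn` implements a complete simulation-and-inference pipeline for an
eight-condition points-based gambling task in which subjects choose, on
each of 138 trials (7 blocks), between a "gamble" and an alternative.
Conditions 1–6 oppose a 50/50 two-outcome gamble to a sure option;
conditions 7 and 8 oppose two sure options, one of which has a hidden
("ambiguous") magnitude. Gains lie on the 10..90 points grid, losses on
−90..−10. Some outcome slots are ambiguous: their magnitude is hidden at
choice time, but because a running points total is displayed, the subject
learns the hidden value whenever an ambiguous slot pays out. That reveal
structure is what makes *learning* models meaningful here.

The candidate model space crosses **five decision rules** with **ten
learning rules** (50 combinations).

### Decision rules

Utilities follow a prospect-theory form with curvature $\rho$, loss
aversion $\lambda$, and multiplicative ambiguity weights $\alpha$ applied
to the implied value $V$ of ambiguous slots:

$$u(\text{gain slot}) = p \cdot g^{\rho}, \qquad
  u(\text{loss slot}) = -p \cdot \lambda \, |l|^{\rho},$$
$$u(\text{ambiguous gain}) = p \cdot \alpha \, V_{gain}^{\rho}, \qquad
  u(\text{ambiguous loss}) = -p \cdot \lambda \, \alpha \, |V_{loss}|^{\rho},$$

with $p = 0.5$ for gamble slots and $1$ for sure options. Choice is
softmax in the utility difference with inverse temperature $\gamma$:
$P(\text{gamble}) = 1 / (1 + e^{-\gamma(u_g - u_s)})$.

A note on signs: printed prospect-theory tables sometimes write loss
terms with a positive coefficient on $(-l)^\rho$; that form cannot
produce loss-averse behavior and is undefined for non-integer $\rho$.
We therefore treat losses as magnitudes whose utility is negated
($-\lambda |l|^{\rho}$), which is the standard convention and makes
$\lambda > 1$ mean overweighting of losses. Similarly, the ambiguity
weight is applied *outside* the power for both valences
($\alpha V^\rho$); applying it inside is a near-equivalent
reparameterization and is not separately identifiable on this design.

The five variants differ only in how the four ambiguity weights
(risky/sure × gain/loss) are tied: (1) all fixed at 1, (2) one shared
weight, (3) tied by valence, (4) tied by *trial context* — any loss
present in the trial routes the loss-context weight, including the
ambiguous-gain condition 3 — and (5) all four free. Variant 5's slots
map to conditions as: risky gain → 3, 5; sure gain → 6, 7; risky loss
→ 2; sure loss → 8.

### Learning rules

One implied value is tracked per valence; risky and sure ambiguous slots
of the same valence share it, because the reveal stream carries no
risky/sure distinction. The families are:

* **none** — the implied value of an ambiguous option is the mean of all
  unambiguous magnitudes of the same valence in the schedule (the
  "rational" baseline), constant over trials;
* **Rescorla–Wagner** — $V \leftarrow V + \alpha\,(o - V)$ on each
  reveal of that valence, $\alpha \in [0,1]$;
* **asymmetric Rescorla–Wagner** — separate rates $\alpha^{+}$
  (positive prediction error) and $\alpha^{-}$ (negative);
* **Bayesian mean tracker** — Kalman-style: gain
  $G = v/(v + \theta_{\epsilon}^2)$ from the prior variance $v$, mean
  moved by $G\delta$, variance shrunk to $(1-G)v$. Larger error
  variance $\theta_{\epsilon}^2$ means slower learning; $G$ decays
  deterministically with each reveal.

Each family comes in three starting-value schemes: fixed ($+5$ gains,
$-5$ losses), estimated-shared (one magnitude, sign-flipped), and
estimated-separate. With the no-learning baseline this gives the ten
learning rules.

Decisions and updates interleave causally: values used on trial $t$
reflect reveals on trials strictly before $t$; unambiguous outcomes
never update anything; state persists across blocks (the score reset is
cosmetic bookkeeping).

## Parameters, units, and defaults

| parameter | meaning | support | population default |
|---|---|---|---|
| $\rho$ | utility curvature | $>0$ | log-normal, median 0.9, log-sd 0.25 |
| $\lambda$ | loss aversion | $>0$ | log-normal, median 1.5, log-sd 0.3 |
| $\gamma$ | inverse temperature (1/points$^{\rho}$) | $\ge 0$ | log-normal, median 0.15, log-sd 0.4 |
| $\alpha_{rg}, \alpha_{sg}, \alpha_{rl}, \alpha_{sl}$ | ambiguity weights | $>0$ | log-normal, median 1, log-sd 0.3 |
| $\alpha, \alpha^{+}, \alpha^{-}$ | learning rates | $[0,1]$ | logit-normal, median 0.3, logit-sd 0.8 |
| $\theta_{\epsilon}^2$ | mean-tracker error variance (points²) | $>0$ | log-normal, median 50, log-sd 0.5 |
| $V_0$ magnitudes | starting implied values (points) | $>0$ | normal(30, 10), truncated at 1 |

$\gamma \approx 0.15$ puts typical utility differences (tens of
points$^{\rho}$) in the sensitive range of the logistic. The mean
tracker's initial variance is fixed at 100 points² (a weakly
informative start on the points scale) and $\theta$'s median of 50
makes the first learning rate $G_1 = 100/150 \approx 0.67$, decaying
thereafter.

## What the synthetic-data generator emulates — and what it does not

`build_schedule()` reproduces the *design*: 138 trials in 7 blocks,
eight conditions (allocation 18,18,18,17,17,17,17,16 — the design's
total is not divisible by 8; the allocation is configurable), gain/loss
grids in steps of 5, identical trial values across subjects with
within-block order re-randomized per subject, and a fixed block
sequence. The original stimulus lists are not published, so magnitudes
are sampled (stratified to span each condition's grid) under a seed;
condition 4 pairs each gamble with a sure option of equal expected
value, and conditions 5–6 use sure amounts spanning the lower half of
the grid so that choices remain informative. Latent values of ambiguous
slots are constant per valence within the task — one hidden gain, one
hidden loss — drawn from the same grids.

`simulate_cohort()` draws per-subject parameters from the populations
above and generates choices through the full decision/learning loop.
What a green test on these cohorts establishes is *internal*
consistency: the inference machinery recovers what this generator
planted. It does not establish that real subjects behave like the
generator — real data bring lapses, attention drift, condition-order
effects, and population correlations between parameters that the
independent draws here do not emulate.

## Fitting: MAP, empirical-Bayes hierarchy, Laplace draws

The reference implementation fit these models hierarchically with
variational inference. No Bayesian engine of that kind is available to
this package, so it uses a deterministic Gaussian approximation with the
same structure:

* parameters live on unconstrained scales (log, or logit for learning
  rates) with normal priors;
* **MAP mode** maximizes each subject's penalized likelihood
  independently (BFGS, optional multi-start jitter under the seed);
* **hierarchical mode** wraps that in an EM loop: the group-level
  location and scale of each parameter's prior are re-estimated from
  the subject-level modes and curvatures, then subjects are refit —
  empirical-Bayes shrinkage toward the cohort;
* posterior uncertainty comes from a **Laplace approximation** at each
  mode. Draws feed the pointwise log-likelihood matrix used by WAIC and
  stacking; point estimates are posterior means on the natural scale,
  matching the reference's use of the posterior mean.

Numerical choices worth knowing:

* the softmax exponent is clipped at ±500; choice probabilities are
  floored at $10^{-6}$ in the likelihood (a tiny lapse floor). Without
  the floor, a near-deterministic subject plus one wrong-sign posterior
  draw produces pointwise log-likelihoods near −500 and a meaningless
  WAIC penalty;
* Hessian eigenvalues are floored at the smallest prior precision
  before inversion — the penalized posterior cannot be flatter than its
  prior, but numerical Hessians of flat likelihood directions can
  suggest otherwise;
* implied values are floored at $10^{-9}$ in magnitude before
  exponentiation (learned values stay on the correct side of zero by
  construction; the floor guards estimated starting values driven to
  the boundary);
* WAIC is computed on the deviance scale,
  $-2\sum_i(\mathrm{lpd}_i - \mathrm{var}_i)$;
* stacking weights maximize the stacked log pointwise predictive
  density with densities taken on the **WAIC scale** (pointwise lpd
  minus the draw variance). Raw draw-averaged densities reward
  overdispersed approximate posteriors — their luckiest draws dominate
  `log mean exp` — and that artifact, not the data, then decides model
  comparison. The simplex optimization is the monotone mixture-EM
  fixed point, which converges to the global optimum of this concave
  problem;
* zero-variance degenerate cases: a cohort exactly at a test's null
  value reports $t = 0$ (limiting case); zero variance away from the
  null is an error.

## Design choices on open questions

* **Winning combination.** The decision rule with four free ambiguity
  weights plus the mean tracker with separately estimated starts
  (`"D5-BMT3"`) is used as the default "winning" combination for
  recovery studies; the source text names the family but not the
  starting-value scheme, so this is a fixture choice, not a claim.
* **Reveal semantics.** An ambiguous value is learned only when the
  *paying* slot was ambiguous — for a 50/50 option, only when the
  ambiguous branch pays — because the score change discloses only the
  paid outcome.
* **Latent ambiguous values** are constant per valence within the task.
  Per-trial redraws would make the "mean of same-valence unambiguous
  magnitudes" baseline the correct generative answer and learning
  pointless; a constant hidden value is what a learner can actually
  converge to.
* **Reversal set.** For aversion scoring, parameters whose larger raw
  values mean *preference* — $\rho$ and the gain-side ambiguity
  weights — are reversed (cohort max minus value); $\lambda$ and
  loss-side weights already increase with aversion. The shared weight
  of variant 2 spans both valences, has no coherent direction, and is
  left raw.
* **Group bias tests** compare the overall gamble proportion (risk) to
  0.5, the only principled null for equal-expected-value gambles, and
  use paired contrasts of conditions 4 vs 1 (loss) and 4 vs 6
  (ambiguity).

## Known limitations

* Recovery quality is bounded by per-subject information: 138 binary
  choices, of which only ~18 and ~16 trials inform the risky-loss and
  sure-loss ambiguity weights. At the default (deliberately realistic,
  hence narrow) population spreads, the attainable true-vs-recovered
  correlation for $\gamma$ sits near 0.5–0.6 even when optimization is
  started at the true values — an attenuation fact
  ($r \approx \sigma_{pop}/\sqrt{\sigma_{pop}^2 + \sigma_{noise}^2}$),
  not an optimizer defect. Published recovery studies that report
  higher correlations typically draw parameters over much wider ranges.
* The empirical-Bayes EM is a point approximation to a full
  hierarchical posterior: group-level uncertainty is not propagated
  into subject-level draws.
* Unpooled MAP fits overfit per-subject parameters, so nested-model
  WAIC comparisons (e.g. the shared-weight variant at $\alpha = 1$
  versus the no-ambiguity variant) are only expected to agree within
  sampling error under hierarchical shrinkage.
* The full 50×50 model-recovery grid is supported but compute-heavy
  (roughly `reps × 50²` cohort fits; order of days on one CPU at
  n = 479). The bundled studies use small subsets at reduced n, which
  demonstrates the machinery, not the full confusion structure.
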