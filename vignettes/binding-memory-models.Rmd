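---
title: "Measurement models of binding and item memory in serial reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement models of binding and item memory in serial reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bindmem)
```

## The measurement problem

In working-memory span tasks, participants study four words per trial
under varying conditions — short presentation time (simple span), long
uninterrupted time (slow span), long time filled with arithmetic
distraction (complex span), or an intermediate interval (medium) — and
later reconstruct each list by selecting the four studied words, in their
original order, from a grid of eight options (the four targets plus four
never-presented lures). Designs may additionally cross the encoding
instruction (intentional vs. incidental) between groups and the immediate
test (serial recall vs. an unrelated no-recall task) between groups or
within subjects.

Accuracy on such a test is not process-pure. *Free scoring* (the
proportion of selections that are studied words; chance 4/8 = 50%)
reflects mostly item memory, and *serial scoring* (the proportion of
positions whose selection is that position's own word; chance
1/8 = 12.5%) mixes item memory with memory for item–position bindings.
`bindmem` implements two measurement models that decompose the response
categories — **Correct** (the position's target), **Other** (another
target of the trial), **New** (a lure) — into interpretable binding and
item components.

## The two models

Both models describe the probability of the three categories for a single
selection, with set size 4 and a response set of 8.

**Discrete states (MPT).** With probability $P_b$ the item–position
binding is available and the correct word is selected. Otherwise, with
probability $P_i$, item memory supports a guess among the four presented
words (each $1/4$); failing both, the guess is uniform over all eight
options (each $1/8$):

$$\begin{aligned}
P(\text{Correct}) &= P_b + (1-P_b)\tfrac{P_i}{4} + (1-P_b)(1-P_i)\tfrac18\\
P(\text{Other})   &= 3\left[(1-P_b)\tfrac{P_i}{4} + (1-P_b)(1-P_i)\tfrac18\right]\\
P(\text{New})     &= 4\,(1-P_b)(1-P_i)\tfrac18
\end{aligned}$$

**Continuous activations (MMM).** Every option carries a baseline
activation $B$; the four presented words add item activation $A$; the
position's own target adds context (binding) activation $C$. Choice
follows Luce's rule, so with $D = 8B + 4A + C$:

$$P(\text{Correct}) = \frac{B+A+C}{D},\quad
  P(\text{Other}) = \frac{3(B+A)}{D},\quad
  P(\text{New}) = \frac{4B}{D}.$$

Luce probabilities are invariant to scaling $(B, A, C)$ by any positive
constant, so one activation must anchor the scale: `fit_mmm()` fixes
$B = 0.1$ (configurable). Reported activation contrasts are therefore in
units of this anchor. $C$ is truncated at zero — a negative context
activation has no interpretation — and we constrain $A \ge 0$ for the
same reason.

Per subject and condition, the category counts over all scored positions
are multinomial in these probabilities; `aggregate_counts()` produces
that sufficient statistic. Pooling over output positions is deliberate:
the models describe one binding/item estimate per condition, not a
serial-position curve.

## Hierarchical estimation

`fit_mpt()` and `fit_mmm()` estimate the models with MCMC (JAGS), using
the same hierarchy:

* latent scale: probit for $P_b, P_i$; softplus
  ($\mathrm{softplus}(x) = \log(1+e^x)$) for $A, C$. The softplus
  parameterization keeps the activations non-negative in the prior *and*
  the posterior; post-hoc clipping of draws would distort the MCMC
  geometry and the interval estimates.
* per-condition group means $\mu$ with additive per-subject deviations
  $u_s$ shared across conditions (a subject who binds well in one
  condition binds well in all);
* priors: $\mu \sim \mathrm{N}(0, 1)$ on the latent scale and
  half-normal(1) on the between-subject SDs. These are weakly
  informative stand-ins chosen to be explicit and overridable
  (`sampler_config(prior_mu_mean=, prior_mu_sd=, prior_sigma_sd=)`).

Group-level parameters are reported on the natural scale as the value of
a *typical* subject, `link_inverse(mu)` — the same convention the
synthetic-data generator uses, so recovery studies compare like with
like.

Defaults are 4 chains, 500 adaptation + 1000 warmup iterations, 1000
retained draws per chain, and chain seeds derived from one integer seed
(fits are exactly reproducible). Convergence is summarized by split
$\widehat R$ and a bulk effective sample size computed from split chains
with Geyer-truncated autocorrelations; parameters with
$\widehat R > 1.01$ are flagged and raised as a warning, never silently
dropped. The strict 1.01 threshold regularly flags hierarchy-scale
parameters (`sigma_*`) at short chain lengths; this signals Monte-Carlo
noise in those posteriors rather than a defective fit, and disappears
with longer runs.

Two numerical details. First, the MPT likelihood in JAGS mixes the
category probabilities with a uniform floor of $10^{-6}$ so that an
extreme latent excursion (probit of $|x| > 8$) cannot produce an exact
zero probability for an observed category during adaptation; the effect
on estimates is orders of magnitude below reporting precision. Second,
with degenerate data (e.g. every response a lure) the group mean and
between-subject SD of an activation are not separately identified: the
posterior can trade a less negative group mean against a large subject
SD. Subject-level activations
$\mathrm{softplus}(\mu + u_s)$ — the quantities the likelihood actually
constrains — concentrate near zero as they should, and that is what the
test suite asserts.

## Inference conventions

`summarize_draws()` and `contrast()` report posterior means with 95%
*equal-tailed* credibility intervals (2.5% and 97.5% type-7 quantiles;
both conventions are recorded as output attributes for bit-stable
comparisons). An effect is `credible` exactly when its interval excludes
zero — no p-values. Contrasts are computed draw-wise, and the convention
is later/longer minus earlier/shorter (slow − simple, long − short), so
positive binding contrasts are advantages of more time.
Highest-posterior-density intervals are a defensible alternative; the
equal-tailed interval was chosen because it is quantile-based, invariant
to monotone reparameterization of each margin, and reproducible without
a density estimator.

`posterior_predict()` simulates category counts from the joint posterior
(group means plus each subject's deviation), which is the basis for
posterior-predictive checks against the observed per-subject
frequencies.

## What the synthetic-data generator emulates

`design_preset()` encodes four experiment layouts: two between-group
designs crossing simple/slow/complex span with intentional vs. incidental
encoding (10 trials per condition; final sample sizes 43/40 and 43/44),
a variant replacing complex span with a medium uninterrupted interval
(59/51), and a within-subject design crossing short/long time with the
immediate test (9 trials per cell, 61 subjects). These defaults mirror
the study conditions the package is meant to emulate; all counts are
overridable.

`simulate_dataset()` draws each subject's latent parameters from the
hierarchy, samples 4 targets + 4 lures per trial from a synthetic
lexicon (opaque tokens; no psycholinguistic structure), draws a response
category per position from the chosen model's analytic probabilities,
and maps categories to concrete tokens without replacement within class
(Correct: the position's target; Other: uniform over unused other
targets; New: uniform over unused lures).

One category pattern is token-infeasible under the task's
distinct-selection rule: three Corrects plus one Other, which leaves the
Other pick no legal target. The generator resamples that position's
category from the renormalized remaining probabilities and counts the
event (`n_category_resamples`). Two consequences are worth stating
plainly:

* In guessing-to-moderate regimes the pattern is rare and generator
  category frequencies match the analytic probabilities within binomial
  error — this is what the chance-level and frequency-equivalence tests
  verify.
* In high-memory regimes (large $P(\text{Correct}) \cdot
  P(\text{Other})$) the resampling measurably inflates Correct at the
  expense of Other, so fitted parameters recover the generating truth
  with a small systematic bias (at an experiment-scale binding contrast
  of 0.6 the recovered contrast is typically within 0.1–0.15). Real
  participants face exactly the same constraint, and the measurement
  models idealize it away in the same manner; the generator thus mimics
  real data's relation to the models rather than the models' own
  independence assumption. Unit tests of the samplers therefore use
  counts simulated directly from the models' data model (no token
  constraint), while end-to-end recovery uses the trial-level generator
  with a correspondingly wider tolerance.

The generator does not emulate auxiliary tasks (animacy judgments,
arithmetic, digit parity), word-list matching, response times, within-
trial serial-position effects, or correlations between a subject's
binding and item abilities (the two deviations are drawn independently).
Passing recovery tests on these data shows that the estimation machinery
is correct under the models' assumptions plus the selection constraint;
it does not certify the models against violations real data may contain
(e.g. output interference across positions or strategy shifts across
trials).

## Recovery studies and problem sizes

`recovery_study()` repeats simulate → fit → contrast and reports bias,
RMSE, CI coverage of the true value, sign agreement, and the credible
rate. The packaged checks run at the scale of one encoding group of the
between-group designs — 40 subjects, 3 conditions, 10 trials per
condition, 4 positions — with reduced MCMC (2 chains, 300 adaptation +
300 warmup, 400 draws), a size at which one fit takes about a second and
a 20-replication null-coverage study runs in about a minute while still
leaving the headline contrast clearly resolved. For publication-grade
analyses, use the default sampler settings or larger.

## Exclusions and scoring rules

`apply_exclusions()` retains a subject iff all six preregistered-style
flags (quit midway, technical issues, nonconforming encoding, expected
final test, restarted, cheated) are `FALSE`, and reports one row per
flag — the same arithmetic as a recruitment screening table.
`score_trials()` treats positions with a missing response as unscored
(dropped from the denominator, counted in `n_missing`): the task forces
four selections, so missing responses are a recording anomaly with no
principled imputation, and the count keeps the decision auditable.

## Known limitations

* The models assume independent selections per position over the full
  8-option set; neither renormalizes after each pick. Whether one should
  is an open modelling question — the sufficient-statistic structure
  (and hence the fast multinomial likelihood) depends on not doing so.
* $B$ is fixed rather than estimated; only activation *ratios* are
  identified, so all MMM effects are relative to the anchor 0.1.
* Group-level location and spread are weakly identified when a cell's
  data are degenerate (all-New or all-Correct); inspect subject-level
  quantities there.
* The probit/softplus links and the specific weakly informative priors
  are defaults, not estimates; sensitivity to them should be checked on
  real data via `sampler_config()`.
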