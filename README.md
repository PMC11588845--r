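# bindmem

Hierarchical Bayesian measurement models of **binding** and **item**
memory for 8-alternative serial reconstruction data from working-memory
span tasks.

## The problem

In span paradigms (simple, slow, and complex span), participants study
four words per trial and later reconstruct them, in order, from a grid of
the four presented words plus four never-presented lures. Observed
accuracy — whether scored *freely* (any presented word counts, chance
50%) or *serially* (only the position's own word counts, chance 12.5%) —
mixes two latent abilities:

* **binding memory** — remembering a word *tied to its serial position*
  (an item–context binding), and
* **item memory** — remembering that a word was presented at all,
  irrespective of position.

`bindmem` is for memory researchers who want to separate those two
components, compare them across experimental conditions (presentation
time, distraction, intentional vs. incidental encoding, immediate
testing), and validate the whole pipeline on synthetic data with known
ground truth.

## The models

Each selection falls into one of three categories: **Correct** (the
position's target), **Other** (one of the trial's three other targets),
or **New** (one of the four lures). Per-subject category counts are
multinomial with probabilities given by one of two measurement models.

**Multinomial processing tree (MPT)** — discrete states. With binding
probability *Pb* the target is retrieved; otherwise item memory *Pi*
supports a guess among the four presented words, and failing that the
guess is uniform over all eight options:

    P(Correct) = Pb + (1 − Pb)·Pi/4 + (1 − Pb)(1 − Pi)/8
    P(Other)   = 3·[(1 − Pb)·Pi/4 + (1 − Pb)(1 − Pi)/8]
    P(New)     = 4·(1 − Pb)(1 − Pi)/8

**Memory measurement model (MMM)** — continuous activations with Luce's
choice rule. All eight options share baseline activation *B*, presented
words add item activation *A*, and the position's target adds context
(binding) activation *C*; with *D = 8B + 4A + C*:

    P(Correct) = (B + A + C)/D,  P(Other) = 3(B + A)/D,  P(New) = 4B/D

*B* is fixed at 0.1 to anchor the scale (Luce probabilities are invariant
to common scaling); *A* and *C* are kept non-negative by a softplus link,
so the truncation of *C* at zero holds in prior and posterior.

Both models are estimated hierarchically with MCMC (JAGS): per-condition
group means on a latent scale (probit for the MPT, softplus for the MMM),
subject deviations shared across conditions, standard-normal priors on
group means and half-normal(1) priors on group SDs. Effects are reported
as posterior condition contrasts with 95% equal-tailed credibility
intervals; an effect is *credible* when its interval excludes zero.

## Worked example

Simulate one encoding group of an experiment-scale design (40 subjects;
simple, slow and complex span; 10 trials per condition) from a known MMM
truth in which slow span carries a binding advantage of 0.6 over simple
span (C = 0.9 vs. 0.3, A = 0.3 everywhere), then fit and contrast:

```r
library(bindmem)

preset <- design_preset("exp1", n_subjects = c(intentional = 40))
truth  <- generator_truth("mmm", preset$conditions, a = 0.3,
                          c_bind = c(0.3, 0.9, 0.3), seed = 1)
sim    <- simulate_dataset(preset, truth)
counts <- aggregate_counts(sim$trials)

fit <- fit_mmm(counts, sampler_config(seed = 1))
fit
#> Hierarchical MMM fit
#>   subjects: 40  conditions: complex, simple, slow
#>   chains: 4  draws/chain: 1000
#>   NOT CONVERGED (R-hat > 1.01 ): sigma_C
#>  model parameter level condition subject      mean    ci_low   ci_high
#>    mmm         A group   complex    <NA> 0.3204143 0.2502732 0.4040685
#>    mmm         A group    simple    <NA> 0.2747456 0.2102401 0.3480002
#>    mmm         A group      slow    <NA> 0.2343506 0.1751027 0.3059835
#>    mmm         C group   complex    <NA> 0.3064184 0.2149141 0.4067086
#>    mmm         C group    simple    <NA> 0.3738746 0.2785270 0.4831514
#>    mmm         C group      slow    <NA> 1.0930469 0.8951126 1.3244193

contrast(fit, "C", "slow", "simple")
#>   model parameter      contrast      mean    ci_low   ci_high credible
#> 1   mmm         C slow - simple 0.7191722 0.5250855 0.9310339     TRUE

contrast(fit, "C", "complex", "simple")
#>   model parameter         contrast        mean     ci_low    ci_high credible
#> 1   mmm         C complex - simple -0.06745627 -0.1805356 0.04512305    FALSE
```

The group-level binding activations recover the generating values (slow
1.09 vs. truth 0.9 for this dataset; simple 0.37 vs. 0.3), the
slow-minus-simple binding contrast is credible (0.72, CI [0.53, 0.93],
generating value 0.6), and the complex-minus-simple contrast is
correctly flat. `sigma_C` sits marginally above the strict 1.01 R-hat
threshold here; rerunning with more draws clears it.

The same pipeline runs from saved files and run directories:

```r
run_simulate(list(out = "runs/sim", preset = "exp1", model = "mmm",
                  c_bind = c(0.3, 0.9, 0.3), seed = 1))
run_fit(list(out = "runs/fit", trials = "runs/sim/trials.csv",
             model = "mmm", encoding_group = "intentional", seed = 1))
```

or from a shell via the thin wrapper `inst/cli/bindmem.R`
(`Rscript bindmem.R simulate --out runs/sim --preset exp1 --seed 1`).

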