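# Synthetic experiment generator: presets, trial-level simulation,
# determinism, and agreement with the models' analytic probabilities.

test_that("experiment presets encode the four designs", {
  p1 <- design_preset("exp1")
  expect_equal(p1$subjects$n_subjects, c(43L, 40L))
  expect_setequal(p1$conditions, c("simple", "slow", "complex"))
  expect_true(all(p1$cells$n_trials == 10L))
  p2 <- design_preset("exp2")
  expect_equal(p2$subjects$n_subjects, c(43L, 44L))
  p3 <- design_preset("exp3")
  expect_equal(p3$subjects$n_subjects, c(59L, 51L))
  expect_setequal(p3$conditions, c("simple", "medium", "slow"))
  p4 <- design_preset("exp4")
  expect_equal(p4$subjects$n_subjects, 61L)
  expect_equal(sum(p4$cells$n_trials), 36L)
  expect_setequal(p4$conditions,
                  c("simple:serial_recall", "simple:no_recall",
                    "slow:serial_recall", "slow:no_recall"))
  # overrides
  ps <- design_preset("exp1", n_subjects = c(intentional = 5), n_trials = 2)
  expect_equal(ps$subjects$n_subjects, 5L)
  expect_true(all(ps$cells$n_trials == 2L))
})

test_that("perfect binding memory forces perfect serial reconstruction", {
  pr <- design_preset("exp1", n_subjects = c(intentional = 3), n_trials = 2)
  tr <- generator_truth("mpt", pr$conditions, pb = 1, pi = 0.5,
                        sd_binding = 0, sd_item = 0, seed = 3)
  sim <- simulate_dataset(pr, tr)
  sc <- score_trials(sim$trials)
  expect_true(all(sc$serial_score == 1))
  expect_true(all(sc$free_score == 1))
})

test_that("simulated datasets are reproducible and structurally valid", {
  pr <- design_preset("exp4", n_subjects = c(intentional = 4), n_trials = 2)
  tr <- generator_truth("mmm", pr$conditions, a = 0.3, c_bind = 0.5,
                        seed = 9)
  s1 <- simulate_dataset(pr, tr)
  s2 <- simulate_dataset(pr, tr)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$subject_truth, s2$subject_truth)
  expect_no_error(validate_trials(s1$trials))
  # responses distinct and inside the candidate set (checked directly)
  key <- paste(s1$trials$subject_id, s1$trials$trial_index)
  for (k in split(seq_len(nrow(s1$trials)), key)) {
    resp <- s1$trials$response_id[k]
    expect_equal(anyDuplicated(resp), 0L)
    cand <- strsplit(s1$trials$candidate_ids[k[1]], "|", fixed = TRUE)[[1]]
    expect_true(all(resp %in% cand))
  }
  # sidecar truth covers exactly the simulated subjects and conditions
  expect_setequal(unique(s1$subject_truth$subject_id),
                  unique(s1$trials$subject_id))
  expect_setequal(unique(s1$subject_truth$condition),
                  unique(condition_label(s1$trials)))
})

test_that("a guessing truth reproduces the chance levels of both scorings", {
  pr <- design_preset("custom",
    subjects = data.frame(encoding_group = "intentional", n_subjects = 20L),
    cells = data.frame(encoding_group = "intentional",
                       time_condition = "short", distraction = "none",
                       immediate_test = "serial_recall", n_trials = 125L))
  tr <- generator_truth("mpt", pr$conditions, pb = 0, pi = 0,
                        sd_binding = 0, sd_item = 0, seed = 1)
  sim <- simulate_dataset(pr, tr)
  sc <- score_trials(sim$trials)   # 2500 trials, 10000 positions
  n <- nrow(sc)
  expect_lt(abs(mean(sc$free_score) - 0.5), 3 * sd(sc$free_score) / sqrt(n))
  expect_lt(abs(mean(sc$serial_score) - 0.125),
            3 * sd(sc$serial_score) / sqrt(n))
})

test_that("generator category frequencies match analytic probabilities in
          regimes where the distinct-selection rule rarely binds", {
  pr <- design_preset("custom",
    subjects = data.frame(encoding_group = "intentional", n_subjects = 10L),
    cells = data.frame(encoding_group = "intentional",
                       time_condition = "short", distraction = "none",
                       immediate_test = "serial_recall", n_trials = 250L))
  for (pars in list(c(0, 0), c(0.2, 0.3))) {
    tr <- generator_truth("mpt", pr$conditions, pb = pars[1], pi = pars[2],
                          sd_binding = 0, sd_item = 0, seed = 2)
    sim <- simulate_dataset(pr, tr)
    cats <- categorize_responses(sim$trials)
    n <- length(cats)   # 10000 positions
    freq <- as.numeric(table(factor(cats, c("Correct", "Other", "New")))) / n
    p <- as.numeric(mpt_category_probs(pars[1], pars[2]))
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(freq - p) <= 3 * pmax(se, 1e-9)),
                info = paste("pb =", pars[1], "pi =", pars[2]))
  }
})

test_that("token-infeasible category patterns are resampled and logged", {
  # high binding plus appreciable item memory makes the three-Correct +
  # one-Other pattern common; the generator must log its resampling
  pr <- design_preset("exp1", n_subjects = c(intentional = 5), n_trials = 10)
  tr <- generator_truth("mpt", pr$conditions, pb = 0.6, pi = 0.5,
                        sd_binding = 0, sd_item = 0, seed = 4)
  sim <- simulate_dataset(pr, tr)
  expect_gt(sim$n_category_resamples, 0)
  expect_no_error(validate_trials(sim$trials))
})

test_that("a one-replication recovery study is deterministic", {
  pr <- design_preset("exp1", n_subjects = c(intentional = 8), n_trials = 3)
  tr <- generator_truth("mmm", pr$conditions, a = 0.3,
                        c_bind = ifelse(pr$conditions == "slow", 0.9, 0.3),
                        seed = 1)
  r1 <- recovery_study(pr, tr, n_replications = 1, config = quick_config(),
                       cond_a = "slow", cond_b = "simple")
  r2 <- recovery_study(pr, tr, n_replications = 1, config = quick_config(),
                       cond_a = "slow", cond_b = "simple")
  expect_identical(r1$replications, r2$replications)
  expect_equal(r1$summary$true_value, 0.6)
  expect_named(r1$summary,
               c("parameter", "contrast", "true_value", "mean_estimate",
                 "bias", "rmse", "coverage", "sign_agreement",
                 "credible_rate", "n_replications"))
})
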