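# Hierarchical Bayesian estimation: parameter recovery on data simulated
# from the fitters' own hierarchical data model, guards, and reproducibility.

test_that("hierarchical MPT recovers group parameters from simulated counts", {
  cn <- simulate_counts("mpt", n_subjects = 40, n_per_cell = 40,
                        group_values = list(
                          binding = c(simple = 0.6, slow = 0.6),
                          item = c(simple = 0.5, slow = 0.5)),
                        seed = 1)
  cfg <- sampler_config(chains = 2, adapt = 500, warmup = 500, draws = 600,
                        seed = 1)
  fit <- suppressWarnings(fit_mpt(cn, cfg))
  s <- summarize_draws(fit, parameter = c("Pb", "Pi"), level = "group")
  truth <- ifelse(s$parameter == "Pb", 0.6, 0.5)
  expect_true(all(abs(s$mean - truth) < 0.1))
  # identical conditions: binding difference centered near zero
  ct <- contrast(fit, "Pb", "slow", "simple")
  expect_false(ct$credible)
  expect_lt(abs(ct$mean), 0.1)
})

test_that("hierarchical MMM recovers a binding-activation contrast", {
  cn <- simulate_counts("mmm", n_subjects = 40, n_per_cell = 40,
                        group_values = list(
                          binding = c(short = 0.3, long = 0.9),
                          item = c(short = 0.3, long = 0.3)),
                        seed = 1)
  fit <- suppressWarnings(fit_mmm(cn, quick_config()))
  ct <- contrast(fit, "C", "long", "short")
  expect_lt(abs(ct$mean - 0.6), 0.2)
  expect_true(ct$credible)
  # truncation: activations never go negative in the posterior
  d <- fit$draws
  expect_true(all(d$value[d$parameter %in% c("A", "C")] >= 0))
})

test_that("an all-New dataset drives subject-level activations to zero", {
  cn <- data.frame(subject_id = rep(sprintf("s%d", 1:10), each = 2),
                   condition = rep(c("a", "b"), 10),
                   n_correct = 0L, n_other = 0L, n_new = 40L)
  fit <- suppressWarnings(fit_mmm(cn, quick_config()))
  d <- fit$draws
  # group location and spread trade off in degenerate data, but each
  # subject's implied activation softplus(mu + u) must be near zero
  for (pair in list(c("mu_A", "u_A"), c("mu_C", "u_C"))) {
    mu <- d[d$parameter == pair[1] & d$condition == "a", ]
    mu <- mu[order(mu$chain, mu$draw), "value"]
    for (s in fit$subjects) {
      u <- d[d$parameter == pair[2] & d$subject == s, ]
      u <- u[order(u$chain, u$draw), "value"]
      expect_lt(mean(softplus(mu + u)), 0.05)
    }
  }
})

test_that("degenerate inputs are refused before sampling", {
  one <- data.frame(subject_id = "s1", condition = "a",
                    n_correct = 10L, n_other = 5L, n_new = 5L)
  expect_error(fit_mpt(one), "at least 2 subjects")
  two <- rbind(one, transform(one, subject_id = "s2"))
  expect_error(fit_mpt(rbind(two, one), quick_config()),
               "more than one counts row")
  expect_error(fit_mmm(one[, -1], quick_config()), "subject_id")
})

test_that("seeded fits are exactly reproducible", {
  cn <- simulate_counts("mpt", n_subjects = 8, n_per_cell = 20,
                        group_values = list(binding = c(a = 0.5, b = 0.5),
                                            item = c(a = 0.5, b = 0.5)),
                        seed = 2)
  f1 <- suppressWarnings(fit_mpt(cn, quick_config(seed = 7)))
  f2 <- suppressWarnings(fit_mpt(cn, quick_config(seed = 7)))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_mpt(cn, quick_config(seed = 8)))
  expect_false(identical(f1$draws, f3$draws))
})
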