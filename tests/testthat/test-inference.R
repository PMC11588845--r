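# Posterior summaries, contrasts, posterior prediction and convergence
# diagnostics.

test_that("summaries report equal-tailed quantile intervals", {
  # degenerate distribution: the interval collapses onto the point
  d <- make_draws(list("C|slow" = rep(0.6, 200)))
  s <- summarize_draws(d)
  expect_equal(s$mean, 0.6)
  expect_equal(s$ci_low, 0.6)
  expect_equal(s$ci_high, 0.6)
  # large normal sample: CI close to +/- 1.96
  set.seed(1)
  dn <- make_draws(list("C|slow" = rnorm(10000)))
  sn <- summarize_draws(dn)
  expect_lt(abs(sn$ci_low + 1.96), 0.1)
  expect_lt(abs(sn$ci_high - 1.96), 0.1)
  expect_identical(attr(sn, "quantile_type"), 7L)
  # pure function of the draws
  expect_identical(summarize_draws(dn), sn)
})

test_that("draws invariants are enforced", {
  d <- make_draws(list("C|slow" = 1:100 / 100, "C|simple" = 1:100 / 100))
  # a parameter missing from one chain
  broken <- d[!(d$parameter == "C" & d$condition == "simple" & d$chain == 2), ]
  expect_error(summarize_draws(broken), "missing from at least one chain")
  # empty selection names the selector
  expect_error(summarize_draws(d, parameter = "Pb"), "parameter=Pb")
})

test_that("contrasts subtract draw-wise and flag credibility via the CI", {
  v <- rnorm(400, 0.5, 0.2)
  d <- make_draws(list("C|slow" = v, "C|simple" = v))
  ct <- contrast(d, "C", "slow", "simple")
  expect_equal(ct$mean, 0)
  expect_false(ct$credible)
  # exact shift: degenerate contrast at the shift
  d2 <- make_draws(list("C|slow" = v + 0.6, "C|simple" = v))
  ct2 <- contrast(d2, "C", "slow", "simple")
  expect_equal(ct2$mean, 0.6)
  expect_equal(ct2$ci_low, 0.6)
  expect_equal(ct2$ci_high, 0.6)
  expect_true(ct2$credible)
  expect_error(contrast(d, "C", "slow", "complex"), "unknown condition")
})

test_that("posterior prediction reproduces point-mass category probabilities", {
  # hand-built fit whose posterior is a point mass at known activations
  a <- 0.3; cb <- 0.5
  n <- 100
  d <- rbind(
    make_draws(list("mu_A|slow" = rep(inv_softplus(a), n),
                    "mu_C|slow" = rep(inv_softplus(cb), n)),
               level = "hyper"),
    make_draws(list("A|slow" = rep(a, n), "C|slow" = rep(cb, n))))
  us <- make_draws(list("u_A|x" = rep(0, n), "u_C|x" = rep(0, n)),
                   level = "subject")
  us$subject <- "s1"; us$condition <- NA_character_
  fit <- structure(list(model = "mmm", draws = rbind(d, us),
                        conditions = "slow", subjects = "s1",
                        b = 0.1, flagged = character(0)),
                   class = "memfit")
  pp <- posterior_predict(fit, data.frame(condition = "slow", n_trials = 500),
                          n_draws = 20, seed = 1)
  p_true <- as.numeric(mmm_category_probs(a, cb))
  se <- sqrt(p_true * (1 - p_true) / (20 * 2000))
  expect_equal(pp$predicted[match(c("Correct", "Other", "New"), pp$category)],
               p_true, tolerance = 3 * max(se) / min(p_true))
  # empty design -> empty output; unknown condition -> error
  expect_equal(nrow(posterior_predict(fit, data.frame(condition = character(0),
                                                      n_trials = integer(0)))),
               0)
  expect_error(posterior_predict(fit, data.frame(condition = "nope",
                                                 n_trials = 3)),
               "not in the fit")
})

test_that("split R-hat and bulk ESS behave on well-mixed and broken chains", {
  set.seed(5)
  good <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(split_rhat(good), 1.01)
  expect_gt(ess_bulk(good), 1000)
  # agreement with coda on stationary chains
  ml <- coda::mcmc.list(coda::mcmc(good[, 1, drop = FALSE]),
                        coda::mcmc(good[, 2, drop = FALSE]))
  crh <- coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1]
  expect_lt(abs(split_rhat(good) - crh), 0.05)
  # disjoint supports blow up R-hat
  broken <- cbind(rnorm(500, 0, 0.1), rnorm(500, 10, 0.1))
  expect_gt(split_rhat(broken), 3)
  # strong autocorrelation cuts the effective sample size
  ar <- matrix(0, 1000, 2)
  for (j in 1:2) {
    x <- rnorm(1000)
    for (i in 2:1000) x[i] <- 0.95 * x[i - 1] + sqrt(1 - 0.95^2) * x[i]
    ar[, j] <- x
  }
  expect_lt(ess_bulk(ar), 600)
})

test_that("diagnostics summarize per parameter and demand two chains", {
  set.seed(6)
  d <- make_draws(list("C|slow" = rnorm(800), "C|simple" = rnorm(800)))
  res <- diagnostics(d, rhat_threshold = 1.05)
  expect_setequal(res$table$parameter, c("C[slow]", "C[simple]"))
  expect_true(all(res$table$rhat < 1.05))
  expect_length(res$flagged, 0)
  # pathological parameter gets flagged
  bad <- make_draws(list("C|slow" = c(rnorm(400, 0, 0.1),
                                      rnorm(400, 10, 0.1))))
  res2 <- diagnostics(bad, rhat_threshold = 1.01)
  expect_identical(res2$flagged, "C[slow]")
  single <- d[d$chain == 1, ]
  expect_error(diagnostics(single), "at least 2 chains")
})
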