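# Trial schema, I/O, categorization and free/serial scoring.

test_that("responses are categorized as Correct, Other or New by definition", {
  tr <- make_trial(responses = c("t1", "t3", "l2", "t4"))
  expect_identical(categorize_responses(tr), c("Correct", "Other", "New",
                                               "Correct"))
  # missing response -> NA category
  tr$response_id[2] <- NA
  expect_identical(categorize_responses(tr)[2], NA_character_)
})

test_that("free and serial scoring match their definitions", {
  # responses [t1, t3, lure, t4]: 3 of 4 selections are targets, 2 in place
  sc <- score_trials(make_trial(responses = c("t1", "t3", "l1", "t4")))
  expect_equal(sc$free_score, 0.75)
  expect_equal(sc$serial_score, 0.5)
  # perfect serial reconstruction
  sc2 <- score_trials(make_trial())
  expect_equal(sc2$free_score, 1)
  expect_equal(sc2$serial_score, 1)
})

test_that("free score dominates serial score and both live on quarters", {
  set.seed(1)
  trials <- do.call(rbind, lapply(1:50, function(i) {
    resp <- sample(c(paste0("t", 1:4), paste0("l", 1:4)), 4)
    make_trial(trial_index = i, responses = resp)
  }))
  sc <- score_trials(trials)
  expect_true(all(sc$free_score >= sc$serial_score))
  expect_true(all(sc$free_score %in% c(0, .25, .5, .75, 1)))
  expect_true(all(sc$serial_score %in% c(0, .25, .5, .75, 1)))
})

test_that("uniform guessing converges to 50% free and 12.5% serial scoring", {
  set.seed(2)
  n <- 4000
  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    resp <- sample(c(paste0("t", 1:4), paste0("l", 1:4)), 4)
    make_trial(trial_index = i, responses = resp)
  }))
  sc <- score_trials(trials)
  se_free <- sd(sc$free_score) / sqrt(n)
  se_serial <- sd(sc$serial_score) / sqrt(n)
  expect_lt(abs(mean(sc$free_score) - 0.5), 3 * se_free)
  expect_lt(abs(mean(sc$serial_score) - 0.125), 3 * se_serial)
})

test_that("trial tables round-trip through CSV unchanged", {
  trials <- rbind(make_trial(), make_trial(trial_index = 2L,
                                           responses = c("t2", "t1", "l4", "t4")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, path)
  back <- read_trials(path)
  expect_equal(back, trials)
})

test_that("schema violations are rejected with informative errors", {
  trials <- make_trial()
  # missing column named in the error
  expect_error(read_trials(tempfile()), "not found")
  path <- withr::local_tempfile(fileext = ".csv")
  broken <- trials[, setdiff(names(trials), "target_id")]
  write.csv(broken, path, row.names = FALSE)
  expect_error(read_trials(path), "target_id")
  # 7-token candidate set, error carries the row index
  bad <- trials
  bad$candidate_ids <- paste(c(paste0("t", 1:4), paste0("l", 1:3)),
                             collapse = "|")
  expect_error(validate_trials(bad), "8 tokens.*row 1")
  # duplicated output position within a trial
  dup <- trials
  dup$output_position[2] <- 1L
  expect_error(validate_trials(dup), "duplicated output_position")
  # response outside the candidate set
  alien <- trials
  alien$response_id[1] <- "zzz"
  expect_error(validate_trials(alien), "response_id")
  # repeated response violates selection without replacement
  rep2 <- trials
  rep2$response_id <- c("t1", "t1", "t3", "t4")
  expect_error(validate_trials(rep2), "not distinct")
})

test_that("aggregate_counts conserves responses and handles edge cases", {
  set.seed(3)
  trials <- do.call(rbind, lapply(1:10, function(i) {
    make_trial(trial_index = i,
               responses = sample(c(paste0("t", 1:4), paste0("l", 1:4)), 4))
  }))
  cn <- aggregate_counts(trials)
  expect_equal(nrow(cn), 1L)
  expect_equal(cn$n_correct + cn$n_other + cn$n_new, 40L)
  expect_equal(attr(cn, "n_dropped"), 0L)
  # empty input -> empty output
  empty <- aggregate_counts(trials[0, ])
  expect_equal(nrow(empty), 0L)
  # missing responses are dropped and logged
  trials$response_id[1] <- NA
  cn2 <- aggregate_counts(trials)
  expect_equal(cn2$n_correct + cn2$n_other + cn2$n_new, 39L)
  expect_equal(attr(cn2, "n_dropped"), 1L)
})

test_that("condition labels follow task names and the within-subject rule", {
  expect_equal(task_label(c("short", "long", "long", "medium"),
                          c("none", "none", "arithmetic", "none")),
               c("simple", "slow", "complex", "medium"))
  expect_error(task_label("short", "arithmetic"), "long")
  # between-group difference in immediate test: no suffix
  tr <- rbind(make_trial(subject_id = "a"),
              make_trial(subject_id = "b", encoding_group = "incidental",
                         immediate_test = "no_recall"))
  expect_equal(unique(condition_label(tr)), "simple")
  # within-group variation: suffixed labels
  tr2 <- rbind(make_trial(subject_id = "a"),
               make_trial(subject_id = "a", trial_index = 2L,
                          immediate_test = "no_recall"))
  expect_setequal(unique(condition_label(tr2)),
                  c("simple:serial_recall", "simple:no_recall"))
})
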